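# Independent oracles and small fixtures, coded directly from the model
# formulas (no calls into the package's probability/likelihood path).

# direct evaluation of the category probabilities: weights
# exp(alpha * sum_{j<=x} (theta - (beta_j - delta %*% kappa))), normalized
oracle_probs <- function(theta, beta, alpha, delta = 0, kappa = 0) {
  shift <- sum(delta * kappa)
  cum <- c(0, cumsum(alpha * (theta - (beta - shift))))
  w <- exp(cum)
  w / sum(w)
}

# cell-by-cell log likelihood using the oracle probabilities
oracle_loglik <- function(X, theta, beta, alpha, delta, kappa) {
  ll <- 0
  for (n in seq_len(nrow(X))) {
    for (i in seq_len(ncol(X))) {
      x <- X[n, i]
      if (is.na(x)) next
      p <- oracle_probs(theta[n], beta[[i]], alpha[i], delta[i, ], kappa[n, ])
      ll <- ll + log(p[x + 1L])
    }
  }
  ll
}

# dichotomous Rasch (PCM with m = 1, alpha = 1) success probability
oracle_rasch <- function(theta, beta) 1 / (1 + exp(-(theta - beta)))

# multi-resolution exhaustive grid maximization: refine around the best
# point of each stage down to a final step of `step_final`
grid_maximize <- function(f, lower, upper, step_final = 1e-3) {
  k <- length(lower)
  centers <- (lower + upper) / 2
  half <- (upper - lower) / 2
  step <- half / 5
  repeat {
    grids <- lapply(seq_len(k), function(j)
      seq(centers[j] - half[j], centers[j] + half[j], by = step[j]))
    pts <- as.matrix(do.call(expand.grid, grids))
    vals <- apply(pts, 1L, f)
    best <- pts[which.max(vals), ]
    if (all(step <= step_final)) return(list(par = best, value = max(vals)))
    centers <- best
    half <- step * 1.5
    step <- pmax(step / 10, step_final)
  }
}

# tiny two-group GPCM-DIF dataset for fast end-to-end tests
tiny_sim <- function(seed = 1L, n_per_group = 40L, n_items = 4L,
                     categories = 3L, dif_item = NULL, dif_shift = 0,
                     alpha = rep(1, n_items)) {
  m <- categories - 1L
  beta <- lapply(seq_len(n_items), function(i)
    seq(-1, 1, length.out = m) + (i - (n_items + 1) / 2) / 2)
  delta <- matrix(0, n_items, 1)
  if (!is.null(dif_item)) delta[dif_item, 1] <- dif_shift
  set.seed(seed + 1000L)
  theta <- rep(sort(stats::rnorm(n_per_group)), 2)
  kappa <- matrix(rep(c(0, 1), each = n_per_group), ncol = 1)
  simulate_gdif(sim_spec(theta, beta, alpha, delta, kappa), seed)
}
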