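#' Simulation specification for GPCM-DIF response data
#'
#' Bundles true generating parameters for [simulate_gdif()]: abilities,
#' per-item thresholds and discriminations, DIF offsets, and the group
#' membership matrix.  Group-specific thresholds are expressed through the
#' model's own parameterization (`beta` holds the reference-group
#' thresholds; members of focal group `f` see `beta_ij - delta_if`).
#'
#' @param theta numeric vector of true abilities (length N).
#' @param beta list of per-item threshold vectors.
#' @param alpha positive per-item discriminations.
#' @param delta items x covariates matrix of true DIF offsets.
#' @param kappa N x covariates binary membership matrix.
#' @param item_ids,subject_ids optional labels.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(theta, beta, alpha, delta, kappa,
                     item_ids = NULL, subject_ids = NULL) {
  params <- gdif_params(theta, beta, alpha, delta)
  kappa <- as.matrix(kappa)
  if (nrow(kappa) != length(params$theta))
    stop("`kappa` must have one row per subject", call. = FALSE)
  if (ncol(kappa) != ncol(params$delta))
    stop("`kappa` columns must match `delta` columns", call. = FALSE)
  P <- length(params$beta)
  structure(list(params = params, kappa = kappa,
                 item_ids = item_ids %||% paste0("item", seq_len(P)),
                 subject_ids = subject_ids %||%
                   paste0("S", seq_along(params$theta))),
            class = "sim_spec")
}

#' Benchmark two-group artificial design
#'
#' A 490-subject, 14-item, five-category design with two equal groups of
#' 245 sharing an ability grid `theta_n = 0.02 (n - 1) - 3`, `n = 1..245`.
#' Items 1-6 and 7-12 share thresholds
#' `beta_ij = (i - 1) - (1.3 + 0.8 (j - 1))` (`i = 1..6` within each block,
#' `j = 1..4`) but differ in discrimination: `alpha = 0.2` (hard to
#' predict) versus `alpha = 2` (easy to predict).  Two uniform-DIF items
#' complete the design: item 13 (`alpha = 0.8`, predictive) has group-1
#' thresholds `{-3.7, -2.9, -2.1, -1.3}` and group-2 thresholds
#' `{1.3, 2.1, 2.9, 3.7}` (a uniform shift of 5); item 14 (`alpha = 0.1`,
#' hard to predict) has `{-5.2, -4.4, -3.6, -2.8}` versus
#' `{2.8, 3.6, 4.4, 5.2}` (shift 8).  The single binary covariate marks
#' group 2, so the true DIF offsets are `delta_13 = -5` and
#' `delta_14 = -8` (effective threshold `beta - delta * kappa`).
#'
#' @return A [sim_spec] for the design.
#' @export
artificial_sim_spec <- function() {
  theta_grid <- 0.02 * (0:244) - 3
  theta <- rep(theta_grid, 2)
  kappa <- matrix(c(rep(0, 245), rep(1, 245)), ncol = 1,
                  dimnames = list(NULL, "group2"))
  block_beta <- lapply(1:6, function(i) (i - 1) - (1.3 + 0.8 * (0:3)))
  beta <- c(block_beta, block_beta,
            list(c(-3.7, -2.9, -2.1, -1.3)),
            list(c(-5.2, -4.4, -3.6, -2.8)))
  alpha <- c(rep(0.2, 6), rep(2, 6), 0.8, 0.1)
  delta <- matrix(0, 14, 1)
  delta[13, 1] <- -5
  delta[14, 1] <- -8
  sim_spec(theta, beta, alpha, delta, kappa)
}

#' Simulate ordinal responses from a GPCM-DIF specification
#'
#' Draws each response by inverse-CDF sampling from the model category
#' probabilities at the true parameters.  Deterministic given `seed`.
#'
#' @param spec a [sim_spec].
#' @param seed integer seed.
#' @return A list with `data` ([response_data]), `membership`
#'   ([dif_membership]), `truth` (the generating [gdif_params]), and
#'   `seed`.
#' @export
simulate_gdif <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(as.integer(seed))
  p <- spec$params
  N <- length(p$theta)
  P <- length(p$beta)
  X <- matrix(NA_integer_, N, P,
              dimnames = list(spec$subject_ids, spec$item_ids))
  for (i in seq_len(P)) {
    shift <- drop(spec$kappa %*% p$delta[i, ])
    pr <- exp(log_category_probabilities(p$theta, p$beta[[i]],
                                         p$alpha[i], shift))
    cum <- pr %*% upper.tri(diag(ncol(pr)), diag = TRUE)
    u <- stats::runif(N)
    X[, i] <- as.integer(rowSums(u > cum))
  }
  list(data = response_data(X, max_categories = lengths(p$beta),
                            subject_ids = spec$subject_ids,
                            item_ids = spec$item_ids),
       membership = dif_membership(spec$kappa),
       truth = p, seed = as.integer(seed))
}
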