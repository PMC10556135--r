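#' Item fit statistics (Infit and Outfit mean squares)
#'
#' Wright-Masters mean-square residual statistics, evaluated under the
#' fitted model including any DIF offsets.  With `E_ni` and `W_ni` the
#' conditional mean and variance of the response under the model, the
#' unweighted (Outfit) statistic is the mean of `(x - E)^2 / W` over
#' subjects, and the information-weighted (Infit) statistic is
#' `sum (x - E)^2 / sum W`.  Both have expectation 1 under the model;
#' values above 1 flag hard-to-predict (underfitting) items, values below
#' 1 overfitting items.  Missing cells are skipped; an item with no
#' observed responses gets `NA`.
#'
#' @param data a [response_data].
#' @param membership a [dif_membership].
#' @param fit a `gdif_fit` (or a list with `params` and `itemset`).
#' @param items items to evaluate (default: the fitted itemset).
#' @return A data frame with `item`, `infit`, `outfit` rows in `items`
#'   order, of class `item_fit`.
#' @export
item_fit <- function(data, membership, fit, items = fit$itemset) {
  ew <- fit_expected(data, membership, fit, items)
  X <- data$responses
  res <- data.frame(item = items, infit = NA_real_, outfit = NA_real_)
  for (k in seq_along(items)) {
    i <- items[k]
    obs <- which(!is.na(X[, i]))
    if (!length(obs)) next
    sq <- (X[obs, i] - ew$E[obs, i])^2
    w <- ew$W[obs, i]
    res$outfit[k] <- mean(sq / w)
    res$infit[k] <- sum(sq) / sum(w)
  }
  class(res) <- c("item_fit", "data.frame")
  res
}

fit_expected <- function(data, membership, fit, items) {
  params <- fit$params
  params$delta[is.na(params$delta)] <- 0
  if (any(is.na(params$alpha[items])))
    stop("`fit` does not cover all requested items", call. = FALSE)
  expected_scores(data, membership, params, items)
}

#' Standardized residuals and their mean inter-item correlation
#'
#' Standardized residuals `z = (x - E) / sqrt(W)` under the fitted model;
#' the summary is the signed mean of the upper triangle of their pairwise
#' (pairwise-complete) correlation matrix, a measure of local dependence
#' (near zero when item responses are conditionally independent given the
#' model).
#'
#' @inheritParams item_fit
#' @return The mean off-diagonal residual correlation (scalar).  The full
#'   residual matrix is available via `attr(, "residuals")`.
#' @export
residual_correlation <- function(data, membership, fit, items = fit$itemset) {
  if (length(items) < 2L)
    stop("residual correlation needs at least two items", call. = FALSE)
  ew <- fit_expected(data, membership, fit, items)
  Z <- (data$responses[, items, drop = FALSE] -
          ew$E[, items, drop = FALSE]) / sqrt(ew$W[, items, drop = FALSE])
  cm <- stats::cor(Z, use = "pairwise.complete.obs")
  out <- mean(cm[upper.tri(cm)])
  attr(out, "residuals") <- Z
  out
}

#' Person separation reliability
#'
#' Proportion of ability-estimate variance not attributable to estimation
#' error: `PSR = (var(theta) - mean(se^2)) / var(theta)`, with the squared
#' standard error of each ability taken from the inverse observed
#' likelihood information `1 / sum_i alpha_i^2 W_ni` at the fit.
#'
#' @inheritParams item_fit
#' @return The PSR (scalar, at most 1; `NA` when the abilities are
#'   constant).  Negative values are reported as computed but flagged with
#'   a warning.
#' @export
person_separation_reliability <- function(data, membership, fit,
                                          items = fit$itemset) {
  ew <- fit_expected(data, membership, fit, items)
  theta <- fit$params$theta
  v <- stats::var(theta)
  if (!is.finite(v) || v < 1e-12) {
    warning("constant ability estimates; PSR undefined", call. = FALSE)
    return(NA_real_)
  }
  a2 <- fit$params$alpha[items]^2
  Wobs <- ew$W[, items, drop = FALSE]
  Wobs[is.na(data$responses[, items, drop = FALSE])] <- NA
  info <- drop(ifelse(is.na(Wobs), 0, Wobs) %*% a2)
  se2 <- 1 / info
  psr <- (v - mean(se2)) / v
  if (is.finite(psr) && psr < 0)
    warning("PSR is negative (error variance exceeds ability variance)",
            call. = FALSE)
  psr
}

#' Cronbach's alpha
#'
#' Classical internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum var_i / var_total)` on complete-case raw
#' scores.
#'
#' @param x numeric matrix of item scores (subjects in rows) or a
#'   [response_data].
#' @param items columns to use (default all).
#' @return Cronbach's alpha (scalar).
#' @export
cronbach_alpha <- function(x, items = NULL) {
  if (inherits(x, "response_data")) x <- x$responses
  if (!is.null(items)) x <- x[, items, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2L) return(NA_real_)
  vt <- stats::var(rowSums(x))
  if (vt < 1e-12) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(x, 2L, stats::var)) / vt)
}

#' Cronbach-Mesbah curve
#'
#' Cronbach's alpha recomputed as items are removed one at a time in the
#' given order (typically the search's removal order), tracking how
#' internal consistency changes; the curve ends when two items remain.
#'
#' @param data a [response_data] (or numeric matrix).
#' @param removal_order a permutation of the item indices; item
#'   `removal_order[1]` is removed first.
#' @return A data frame `n_items`, `removed` (item removed to reach the
#'   row's set, `NA` for the full set), `alpha`, with the argmax stored in
#'   `attr(, "best")`.
#' @export
cronbach_mesbah_curve <- function(data, removal_order) {
  x <- if (inherits(data, "response_data")) data$responses else
    as.matrix(data)
  P <- ncol(x)
  removal_order <- as.integer(removal_order)
  if (!setequal(removal_order, seq_len(P)))
    stop("`removal_order` must be a permutation of the items", call. = FALSE)
  keep <- seq_len(P)
  steps <- data.frame(n_items = P, removed = NA_integer_,
                      alpha = cronbach_alpha(x))
  for (r in removal_order) {
    keep <- setdiff(keep, r)
    if (length(keep) < 2L) break
    steps <- rbind(steps,
                   data.frame(n_items = length(keep), removed = r,
                              alpha = cronbach_alpha(x, keep)))
  }
  attr(steps, "best") <- steps$n_items[which.max(steps$alpha)]
  steps
}

#' Random-instrument criterion baseline
#'
#' Distribution of the criterion over uniformly drawn k-item instruments:
#' the yardstick against which a searched instrument is compared.
#'
#' @inheritParams score_split
#' @param k instrument size (number of included items).
#' @param n_draws number of random instruments.
#' @param seed integer seed (draws are reproducible).
#' @return A list with `scores` (numeric vector of IPOQ-LL-DIF values),
#'   `draws` (list of itemsets), and `summary` (min/median/max).
#' @export
random_instrument_baseline <- function(data, membership, k, n_draws = 100L,
                                       seed = 1L,
                                       penalties = default_penalties(),
                                       constraint = model_constraint(),
                                       control = fit_control()) {
  P <- ncol(data$responses)
  stopifnot(k >= 1L, k <= P)
  set.seed(as.integer(seed))
  seen <- new.env(parent = emptyenv())
  draws <- vector("list", n_draws)
  scores <- numeric(n_draws)
  for (b in seq_len(n_draws)) {
    s <- sort(sample.int(P, k))
    draws[[b]] <- s
    key <- paste(s, collapse = ",")
    hit <- seen[[key]]
    if (is.null(hit)) {
      hit <- score_split(data, membership, item_split(s, P), penalties,
                         constraint, control)$ipoq_ll_dif
      seen[[key]] <- hit
    }
    scores[b] <- hit
  }
  list(scores = scores, draws = draws,
       summary = c(min = min(scores), median = stats::median(scores),
                   max = max(scores)))
}

#' Hypergeometric itemset-overlap probability
#'
#' Probability that a uniformly drawn `drawn_size`-item subset of
#' `total_items` shares at least `min_overlap` items with a fixed
#' `fixed_size`-item subset: the upper tail of the hypergeometric
#' distribution, computed from binomial coefficients.  Used to judge
#' whether the overlap between a searched instrument and a manually
#' constructed one could plausibly arise by chance.
#'
#' @param total_items,fixed_size,drawn_size,min_overlap integers with
#'   `0 <= min_overlap <= min(fixed_size, drawn_size) <= total_items`.
#' @return `P(X >= min_overlap)`.
#' @examples
#' overlap_probability(16, 8, 8, 6)   # about 0.066
#' @export
overlap_probability <- function(total_items, fixed_size, drawn_size,
                                min_overlap) {
  stopifnot(total_items >= 1, fixed_size <= total_items,
            drawn_size <= total_items, min_overlap >= 0,
            min_overlap <= min(fixed_size, drawn_size))
  lo <- max(min_overlap, fixed_size + drawn_size - total_items)
  hi <- min(fixed_size, drawn_size)
  if (lo > hi) return(0)
  k <- lo:hi
  sum(exp(lchoose(fixed_size, k) +
            lchoose(total_items - fixed_size, drawn_size - k) -
            lchoose(total_items, drawn_size)))
}

#' Correlation of ability estimates from two fits
#'
#' Pearson correlation of the ability vectors of two fits on the same
#' subjects — a summary of how interchangeable two instruments are for
#' ranking persons.
#'
#' @param fit_a,fit_b `gdif_fit` objects (or lists with `params$theta`).
#' @return Pearson correlation (scalar).
#' @export
ability_correlation <- function(fit_a, fit_b) {
  ta <- fit_a$params$theta
  tb <- fit_b$params$theta
  if (length(ta) != length(tb))
    stop("fits cover different numbers of subjects", call. = FALSE)
  if (stats::sd(ta) < 1e-12 || stats::sd(tb) < 1e-12) {
    warning("zero-variance abilities; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(ta, tb)
}

#' Instrument diagnostic summary
#'
#' Bundles the standard per-instrument statistics: mean Infit and Outfit,
#' mean residual correlation, person separation reliability, and
#' Cronbach's alpha.
#'
#' @inheritParams item_fit
#' @return A one-row data frame of class `instrument_summary`.
#' @export
instrument_summary <- function(data, membership, fit, items = fit$itemset) {
  fits <- item_fit(data, membership, fit, items)
  out <- data.frame(
    n_items = length(items),
    mean_infit = mean(fits$infit, na.rm = TRUE),
    mean_outfit = mean(fits$outfit, na.rm = TRUE),
    mean_residual_correlation = if (length(items) >= 2L)
      as.numeric(residual_correlation(data, membership, fit, items)) else NA_real_,
    person_separation_reliability =
      suppressWarnings(person_separation_reliability(data, membership, fit, items)),
    cronbach_alpha = cronbach_alpha(data, items))
  class(out) <- c("instrument_summary", "data.frame")
  out
}
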