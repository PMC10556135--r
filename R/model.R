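#' Category response probabilities under the GPCM-DIF
#'
#' Probability of each response category for one item, for one or more
#' subjects.  The model is the generalized partial credit model with
#' uniform DIF offsets: for response `x > 0`,
#' \deqn{P(X = x) \propto \exp\Big[\alpha_i \sum_{j \le x}
#'   \big(\theta_n - (\beta_{ij} - \sum_f \delta_{if}\kappa_{nf})\big)\Big],}
#' with the empty sum for `x = 0`.  The DIF offset enters only through the
#' effective threshold `beta_ij - sum_f delta_if kappa_nf`, so a member of
#' the focal group sees every threshold of a DIF item shifted by the same
#' amount (uniform DIF).
#'
#' @param theta ability value(s); vector of length N.
#' @param beta threshold vector for the item (length `m_i`).
#' @param alpha positive discrimination parameter (scalar).
#' @param delta DIF offset vector for the item (length `m_f`); use 0 for a
#'   DIF-free item.
#' @param kappa binary membership vector (length `m_f`) for a single
#'   subject, or an N x `m_f` matrix matching `theta`.
#' @return An N x (`m_i` + 1) matrix of probabilities; each row sums to 1.
#'   For scalar `theta` a 1-row matrix is returned.
#' @examples
#' category_probabilities(0, beta = 0, alpha = 1, delta = 0, kappa = 0)
#' @export
category_probabilities <- function(theta, beta, alpha, delta = 0, kappa = 0) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  theta <- as.numeric(theta)
  N <- length(theta)
  kappa <- if (is.matrix(kappa)) kappa else
    matrix(rep(as.numeric(kappa), N), nrow = N, byrow = TRUE)
  if (nrow(kappa) != N || ncol(kappa) != length(delta))
    stop("`kappa` dimensions must match `theta` and `delta`", call. = FALSE)
  exp(log_category_probabilities(theta, beta, alpha,
                                 drop(kappa %*% as.numeric(delta))))
}

# Log category probabilities with a log-sum-exp guard.
# `shift` is the per-subject DIF shift sum_f delta_if kappa_nf (length N).
# Returns an N x (m+1) matrix of log probabilities.
log_category_probabilities <- function(theta, beta, alpha, shift = 0) {
  m <- length(beta)
  u <- theta + shift                       # effective ability offset
  cb <- c(0, cumsum(beta))                 # cumulative thresholds, x = 0..m
  # C[n, x+1] = alpha * (x * u_n - cb_x): cumulative logits
  C <- alpha * (outer(u, 0:m) - matrix(cb, length(u), m + 1L, byrow = TRUE))
  mx <- C[cbind(seq_len(nrow(C)), max.col(C, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(C - mx)))
  C - lse
}

#' Log likelihood of GPCM-DIF parameters on an itemset
#'
#' Sum over items in `itemset` and subjects of the log probability of the
#' observed response; missing responses are skipped.  The empty itemset has
#' log likelihood 0.
#'
#' @param data a [response_data] object.
#' @param membership a [dif_membership] object.
#' @param params a [gdif_params] object (full-length `beta`/`alpha`/`delta`;
#'   entries outside `itemset` are ignored).
#' @param itemset integer vector of item indices (default: all items).
#' @return The log likelihood (a nonpositive scalar).
#' @export
loglik_gdif <- function(data, membership, params,
                        itemset = seq_along(data$item_ids)) {
  check_dims(data, membership)
  if (!length(itemset)) return(0)
  itemset <- as.integer(itemset)
  if (any(itemset < 1L | itemset > ncol(data$responses)))
    stop("`itemset` out of range", call. = FALSE)
  ll <- 0
  for (i in itemset) {
    shift <- drop(membership$kappa %*% params$delta[i, ])
    ll <- ll + item_loglik_cpp(data$responses[, i], params$theta,
                               params$beta[[i]], params$alpha[i], shift)
  }
  ll
}

#' Penalized log-likelihood objective
#'
#' The estimation objective: the log likelihood minus a ridge penalty on the
#' abilities, a ridge penalty on the log discriminations of the itemset, and
#' a lasso penalty on the DIF offsets of the itemset:
#' \deqn{F = L - \lambda_\theta \sum_n \theta_n^2
#'         - \lambda_\alpha \sum_{i \in S} (\ln\alpha_i)^2
#'         - \lambda_\delta \sum_{i \in S} \sum_f |\delta_{if}|.}
#'
#' @inheritParams loglik_gdif
#' @param penalties a [penalty_config] object.
#' @return The penalized objective value.
#' @export
penalized_objective <- function(data, membership, params, itemset,
                                penalties) {
  ll <- loglik_gdif(data, membership, params, itemset)
  ll - penalty_terms(params, itemset, penalties)
}

penalty_terms <- function(params, itemset, penalties) {
  pen <- penalties$lambda_theta * sum(params$theta^2)
  if (length(itemset)) {
    pen <- pen +
      penalties$lambda_alpha * sum(log(params$alpha[itemset])^2) +
      penalties$lambda_delta * sum(abs(params$delta[itemset, , drop = FALSE]))
  }
  pen
}

#' Model-expected scores and score variances
#'
#' Per-cell conditional expectation `E_ni` and variance `W_ni` of the
#' response under the fitted model, the building blocks of the Infit/Outfit
#' statistics and of the ability information.
#'
#' @inheritParams loglik_gdif
#' @return A list with N x P matrices `E` and `W` (`NA` outside `itemset`).
#' @keywords internal
expected_scores <- function(data, membership, params,
                            itemset = seq_along(data$item_ids)) {
  N <- nrow(data$responses)
  P <- ncol(data$responses)
  E <- W <- matrix(NA_real_, N, P)
  for (i in itemset) {
    shift <- drop(membership$kappa %*% params$delta[i, ])
    pr <- exp(log_category_probabilities(params$theta, params$beta[[i]],
                                         params$alpha[i], shift))
    cats <- 0:(length(params$beta[[i]]))
    E[, i] <- pr %*% cats
    W[, i] <- pr %*% cats^2 - E[, i]^2
  }
  list(E = E, W = W)
}
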