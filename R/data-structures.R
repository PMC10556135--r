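#' Ordinal response data
#'
#' Container for a subjects x items matrix of ordinal response codes.
#' Responses are 0-based: item `i` with `m_i` thresholds has `m_i + 1`
#' ordered categories coded `0, ..., m_i`.  `NA` marks a missing response;
#' missing cells are skipped in all likelihood sums and diagnostics.
#'
#' @param responses integer matrix (subjects in rows, items in columns);
#'   entries in `0:m_i` or `NA`.
#' @param max_categories optional integer vector of per-item threshold counts
#'   `m_i` (i.e. number of categories minus one).  Defaults to the maximum
#'   observed code per item.
#' @param subject_ids,item_ids optional label vectors; default to the
#'   dimnames of `responses` or generated labels.
#'
#' @details Items observed with an unused *middle* category (e.g. codes
#'   0, 1, 3 present but never 2) are rejected: collapsing disordered or
#'   empty categories is a substantive modelling decision left to the
#'   analyst.
#'
#' @return An object of class `response_data` with elements `responses`
#'   (integer matrix), `m` (thresholds per item), `subject_ids`, `item_ids`.
#' @export
response_data <- function(responses, max_categories = NULL,
                          subject_ids = NULL, item_ids = NULL) {
  responses <- as.matrix(responses)
  if (!is.numeric(responses))
    stop("`responses` must be a numeric/integer matrix", call. = FALSE)
  N <- nrow(responses)
  P <- ncol(responses)
  if (N < 1L || P < 1L)
    stop("need at least one subject and one item", call. = FALSE)
  storage.mode(responses) <- "integer"

  if (is.null(subject_ids))
    subject_ids <- rownames(responses) %||% paste0("S", seq_len(N))
  if (is.null(item_ids))
    item_ids <- colnames(responses) %||% paste0("item", seq_len(P))
  if (length(subject_ids) != N || length(item_ids) != P)
    stop("label lengths do not match matrix dimensions", call. = FALSE)

  obs_max <- apply(responses, 2L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_integer_)
    max(x)
  })
  if (is.null(max_categories)) {
    if (anyNA(obs_max))
      stop("item(s) with no observed responses need explicit `max_categories`",
           call. = FALSE)
    m <- as.integer(obs_max)
  } else {
    m <- as.integer(rep_len(max_categories, P))
  }
  if (any(m < 1L))
    stop("every item needs at least two categories (m_i >= 1)", call. = FALSE)

  declared <- !is.null(max_categories)
  for (i in seq_len(P)) {
    x <- responses[, i]
    x <- x[!is.na(x)]
    if (any(x < 0L | x > m[i]))
      stop(sprintf("item %d has responses outside 0..%d", i, m[i]),
           call. = FALSE)
    seen <- sort(unique(x))
    if (!declared && length(seen) > 1L) {
      # without a declared category count, a gap in the observed codes makes
      # the intended scale ambiguous; collapsing categories is the analyst's
      # decision, never done silently here
      gap <- setdiff(seq.int(min(seen), max(seen)), seen)
      if (length(gap))
        stop(sprintf(
          "item %d has unused middle categor%s (%s); declare `max_categories` or recode",
          i, if (length(gap) > 1L) "ies" else "y",
          paste(gap, collapse = ", ")), call. = FALSE)
    }
  }

  structure(
    list(responses = responses, m = m,
         subject_ids = as.character(subject_ids),
         item_ids = as.character(item_ids)),
    class = "response_data")
}

#' @export
print.response_data <- function(x, ...) {
  cat(sprintf("<response_data> %d subjects x %d items; categories per item: %s\n",
              nrow(x$responses), ncol(x$responses),
              paste(range(x$m + 1L), collapse = "-")))
  nm <- sum(is.na(x$responses))
  if (nm > 0) cat(sprintf("  %d missing responses\n", nm))
  invisible(x)
}

#' @export
dim.response_data <- function(x) dim(x$responses)

#' Group-membership (DIF covariate) matrix
#'
#' Binary subjects x covariates matrix; `kappa[n, f] = 1` marks subject `n`
#' as a member of focal group `f`, whose uniform DIF offsets apply.
#'
#' @param kappa binary matrix (or vector, treated as one covariate).
#' @param covariate_ids optional labels.
#' @return An object of class `dif_membership` with elements `kappa` and
#'   `covariate_ids`.
#' @export
dif_membership <- function(kappa, covariate_ids = NULL) {
  kappa <- as.matrix(kappa)
  if (anyNA(kappa) || !all(kappa %in% c(0, 1)))
    stop("`kappa` entries must be exactly 0 or 1", call. = FALSE)
  storage.mode(kappa) <- "double"
  if (is.null(covariate_ids))
    covariate_ids <- colnames(kappa) %||% paste0("group", seq_len(ncol(kappa)))
  structure(list(kappa = kappa, covariate_ids = as.character(covariate_ids)),
            class = "dif_membership")
}

#' @export
print.dif_membership <- function(x, ...) {
  cat(sprintf("<dif_membership> %d subjects x %d covariate(s): %s\n",
              nrow(x$kappa), ncol(x$kappa),
              paste(x$covariate_ids, collapse = ", ")))
  invisible(x)
}

#' GPCM-DIF parameter set
#'
#' @param theta numeric vector of person abilities (logits), length N.
#' @param beta list of per-item threshold vectors (item `i` has `m_i`
#'   thresholds).
#' @param alpha positive per-item discrimination parameters.
#' @param delta matrix of per-item DIF offsets (items x covariates); the
#'   effective threshold for subject `n` is `beta_ij - sum_f delta_if kappa_nf`.
#' @return An object of class `gdif_params`.
#' @export
gdif_params <- function(theta, beta, alpha, delta) {
  if (!is.list(beta)) beta <- list(beta)
  P <- length(beta)
  alpha <- rep_len(as.numeric(alpha), P)
  if (any(alpha <= 0))
    stop("discrimination parameters `alpha` must be positive", call. = FALSE)
  delta <- as.matrix(delta)
  if (nrow(delta) != P)
    stop("`delta` must have one row per item", call. = FALSE)
  structure(list(theta = as.numeric(theta),
                 beta = lapply(beta, as.numeric),
                 alpha = alpha, delta = delta),
            class = "gdif_params")
}

#' @export
print.gdif_params <- function(x, ...) {
  cat(sprintf("<gdif_params> %d persons, %d items, %d DIF covariate(s)\n",
              length(x$theta), length(x$beta), ncol(x$delta)))
  nz <- which(rowSums(abs(x$delta)) > 0)
  cat(if (length(nz)) sprintf("  nonzero DIF offsets on item(s): %s\n",
                              paste(nz, collapse = ", "))
      else "  all DIF offsets zero\n")
  invisible(x)
}

#' Penalty configuration for penalized joint maximum likelihood
#'
#' Ridge penalties anchor the abilities at zero (`lambda_theta`) and the
#' log-discriminations at zero, i.e. alpha at one (`lambda_alpha`); the
#' lasso coefficient `lambda_delta` shrinks irrelevant DIF offsets to
#' exactly zero.  The defaults are the package's standard operating point:
#' `lambda_theta = 0.05`, `lambda_delta = 10`, with `lambda_alpha = 50`
#' for included-itemset fits (`lambda_in`) and `1` for excluded-itemset
#' fits (`lambda_out`).
#'
#' @param lambda_theta,lambda_alpha,lambda_delta nonnegative reals.
#' @return A `penalty_config` object (a named list).
#' @export
penalty_config <- function(lambda_theta = 0.05, lambda_alpha = 50,
                           lambda_delta = 10) {
  stopifnot(lambda_theta >= 0, lambda_alpha >= 0, lambda_delta >= 0)
  structure(list(lambda_theta = lambda_theta, lambda_alpha = lambda_alpha,
                 lambda_delta = lambda_delta), class = "penalty_config")
}

#' Default penalty coefficients for itemset-split scoring
#'
#' @return A list with `lambda_theta = 0.05`, `lambda_in = 50`,
#'   `lambda_out = 1`, `lambda_delta = 10`.
#' @export
default_penalties <- function() {
  list(lambda_theta = 0.05, lambda_in = 50, lambda_out = 1, lambda_delta = 10)
}

#' Model constraint flags
#'
#' The GPCM-DIF nests the familiar Rasch-family models: fixing all
#' discriminations at one gives the PCM-DIF, fixing all DIF offsets at zero
#' gives the GPCM, and both give the PCM (the Rasch model for dichotomous
#' items).
#'
#' @param fix_alpha fix all discriminations at 1.
#' @param fix_delta fix all DIF offsets at 0.
#' @return A `model_constraint` object.
#' @export
model_constraint <- function(fix_alpha = FALSE, fix_delta = FALSE) {
  structure(list(fix_alpha = isTRUE(fix_alpha), fix_delta = isTRUE(fix_delta)),
            class = "model_constraint")
}

#' @rdname model_constraint
#' @param model one of `"gpcm_dif"`, `"pcm_dif"`, `"gpcm"`, `"pcm"`.
#' @export
constraint_for <- function(model = c("gpcm_dif", "pcm_dif", "gpcm", "pcm")) {
  model <- match.arg(model)
  switch(model,
         gpcm_dif = model_constraint(FALSE, FALSE),
         pcm_dif  = model_constraint(TRUE, FALSE),
         gpcm     = model_constraint(FALSE, TRUE),
         pcm      = model_constraint(TRUE, TRUE))
}

#' Apply constraint flags to a parameter set
#'
#' Forces `alpha = 1` and/or `delta = 0` according to the flags; during
#' estimation the same flags exclude the fixed parameters from updates.
#'
#' @param params a [gdif_params] object.
#' @param constraint a [model_constraint] object.
#' @return The constrained `gdif_params`.
#' @export
apply_constraint <- function(params, constraint) {
  if (constraint$fix_alpha) params$alpha[] <- 1
  if (constraint$fix_delta) params$delta[] <- 0
  params
}

#' Fit control settings
#'
#' @param max_outer maximum outer coordinate-descent iterations.
#' @param rel_tol relative objective-change convergence tolerance for the
#'   outer loop.
#' @param smooth_maxit iteration cap for the smooth-block (theta, beta,
#'   ln alpha) quasi-Newton solver per outer iteration.
#' @param smooth_tol gradient/objective tolerance passed to the smooth
#'   solver (`factr`-style relative tolerance).
#' @param delta_bound search bound for one-dimensional DIF updates
#'   (|delta| <= `delta_bound`).
#' @param delta_zero_threshold DIF offsets with absolute value below this
#'   at convergence are reported as exact zeros (followed by one
#'   smooth-block polish).  The default, 0.43 logits, is the conventional
#'   negligible-DIF bound (the ETS Mantel-Haenszel category-A cutoff);
#'   joint maximum likelihood at moderate sample sizes otherwise leaves
#'   noise-level offsets on DIF-free items.  Set to 0 to disable.
#' @return A `fit_control` object.
#' @export
fit_control <- function(max_outer = 200L, rel_tol = 1e-6,
                        smooth_maxit = 200L, smooth_tol = 1e-8,
                        delta_bound = 15, delta_zero_threshold = 0.43) {
  stopifnot(max_outer >= 1L, rel_tol > 0, smooth_maxit >= 1L,
            smooth_tol > 0, delta_bound > 0, delta_zero_threshold >= 0)
  structure(list(max_outer = as.integer(max_outer), rel_tol = rel_tol,
                 smooth_maxit = as.integer(smooth_maxit),
                 smooth_tol = smooth_tol, delta_bound = delta_bound,
                 delta_zero_threshold = delta_zero_threshold),
            class = "fit_control")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_dims <- function(data, membership) {
  if (nrow(membership$kappa) != nrow(data$responses))
    stop("membership rows must match response rows (one per subject)",
         call. = FALSE)
  invisible(TRUE)
}
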