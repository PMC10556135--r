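#' Itemset split
#'
#' Partition of the survey items into the included itemset (the candidate
#' instrument) and its complement, the excluded itemset.
#'
#' @param included item indices of the included itemset (nonempty).
#' @param n_items total number of items P; the excluded set is the
#'   complement.
#' @return An `item_split` object with `included` and `excluded`.
#' @export
item_split <- function(included, n_items) {
  included <- sort(unique(as.integer(included)))
  if (!length(included))
    stop("the included itemset must be nonempty", call. = FALSE)
  if (any(included < 1L | included > n_items))
    stop("`included` out of range", call. = FALSE)
  structure(list(included = included,
                 excluded = setdiff(seq_len(n_items), included)),
            class = "item_split")
}

#' Score an itemset split by the IPOQ-LL-DIF criterion
#'
#' Implements the two-stage evaluation of a split.  First all parameters
#' (abilities, thresholds, discriminations, DIF offsets) are fitted on the
#' included itemset by penalized joint maximum likelihood with
#' `lambda_alpha = lambda_in`; the in-questionnaire log likelihood with DIF
#' (IQ-LL-DIF) is the *unpenalized* log likelihood at those fitted values.
#' Then, holding the fitted abilities fixed, the thresholds,
#' discriminations and DIF offsets of each excluded item are fitted with
#' `lambda_alpha = lambda_out` (each excluded item separates, since the
#' abilities are fixed); OQ-LL-DIF is the unpenalized log likelihood of the
#' excluded itemset at those values.  The criterion is the sum:
#' IPOQ-LL-DIF = IQ-LL-DIF + OQ-LL-DIF.
#'
#' @inheritParams fit_gdif
#' @param split an [item_split].
#' @param penalties list with `lambda_theta`, `lambda_in`, `lambda_out`,
#'   `lambda_delta` (see [default_penalties()]).
#' @param constraint a [model_constraint]; the default (GPCM-DIF) is the
#'   standard scoring model.
#' @param init optional warm-start [gdif_params] (e.g. from a neighbouring
#'   split's score); results match a cold start to optimizer tolerance.
#' @return A `criterion_score` with `iq_ll_dif`, `oq_ll_dif`,
#'   `ipoq_ll_dif` (= their sum, exactly), `fit_in`, `fit_out` (list of
#'   per-item fits, possibly empty), `split`, and `warm` (merged
#'   parameters usable as a warm start for neighbouring splits).
#' @export
score_split <- function(data, membership, split,
                        penalties = default_penalties(),
                        constraint = model_constraint(),
                        control = fit_control(), init = NULL) {
  stopifnot(inherits(split, "item_split"))
  pen_in <- penalty_config(penalties$lambda_theta, penalties$lambda_in,
                           penalties$lambda_delta)
  pen_out <- penalty_config(penalties$lambda_theta, penalties$lambda_out,
                            penalties$lambda_delta)
  fit_in <- fit_gdif(data, membership, split$included, pen_in, constraint,
                     control, init = init)
  iq <- fit_in$loglik

  warm <- fit_in$params
  fit_out <- list()
  oq <- 0
  if (length(split$excluded)) {
    theta_init <- fit_in$params
    for (j in split$excluded) {
      init_j <- theta_init
      if (!is.null(init)) {       # carry the neighbour's excluded-item params
        init_j$beta[[j]] <- init$beta[[j]]
        init_j$alpha[j] <- init$alpha[j]
        init_j$delta[j, ] <- init$delta[j, ]
      }
      fj <- fit_gdif(data, membership, j, pen_out, constraint, control,
                     init = init_j, fix_theta = TRUE)
      fit_out[[as.character(j)]] <- fj
      oq <- oq + fj$loglik
      warm$beta[[j]] <- fj$params$beta[[j]]
      warm$alpha[j] <- fj$params$alpha[j]
      warm$delta[j, ] <- fj$params$delta[j, ]
    }
  }
  structure(list(iq_ll_dif = iq, oq_ll_dif = oq, ipoq_ll_dif = iq + oq,
                 fit_in = fit_in, fit_out = fit_out, split = split,
                 warm = warm),
            class = "criterion_score")
}

#' Score a split by the DIF-free IPOQ-LL criterion
#'
#' The predecessor criterion: identical to [score_split()] with all DIF
#' offsets constrained to zero in both fits (GPCM in place of GPCM-DIF).
#'
#' @inheritParams score_split
#' @return A `criterion_score`.
#' @export
score_split_no_dif <- function(data, membership, split,
                               penalties = default_penalties(),
                               constraint = model_constraint(),
                               control = fit_control(), init = NULL) {
  constraint$fix_delta <- TRUE
  score_split(data, membership, split, penalties, constraint, control, init)
}

#' @export
print.criterion_score <- function(x, ...) {
  cat(sprintf("<criterion_score> |S_in| = %d: IQ-LL-DIF = %.3f, OQ-LL-DIF = %.3f, IPOQ-LL-DIF = %.3f\n",
              length(x$split$included), x$iq_ll_dif, x$oq_ll_dif,
              x$ipoq_ll_dif))
  cat(sprintf("  included: %s\n", paste(x$split$included, collapse = ", ")))
  invisible(x)
}
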