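#' Stepwise itemset search maximizing the IPOQ-LL-DIF
#'
#' `backward_pass()` starts from the full itemset and repeatedly removes
#' the item whose removal gives the highest criterion, down to a single
#' item.  `forward_pass()` starts from the empty set and repeatedly adds
#' the item giving the highest criterion, up to the full set.
#' `stepwise_search()` alternates the two: after an initial backward and
#' forward pass, per-size best records are merged and refinement rounds
#' (removals from the best split one size up, additions from the best
#' split one size down) repeat until no per-size record improves.
#'
#' Ties resolve to the lowest item index; every scored split is cached by
#' its itemset, and candidate fits warm-start from the parent split's fit
#' (results match cold starts to optimizer tolerance).
#'
#' @inheritParams score_split
#' @param criterion `"ipoq-ll-dif"` (GPCM-DIF scoring) or `"ipoq-ll"`
#'   (DIF-free GPCM scoring).
#' @param constraint a [model_constraint] for the scoring fits (default
#'   GPCM-DIF; `"ipoq-ll"` additionally forces the DIF offsets to zero).
#' @param start_split optional [item_split] to start the backward pass
#'   from (default: all items).
#' @param max_rounds maximum alternation rounds for `stepwise_search`.
#' @param round_tol minimum per-size score improvement that counts as a
#'   change between rounds.
#' @param cold_start disable warm starts (full refits; for verification).
#' @param verbose print progress to stderr.
#' @return A `search_trace`: `per_size` (data frame with one row per
#'   included-set size: size, items, iq, oq, total, direction, round),
#'   `best_size`, `best_split`, `best_score` (the winning
#'   `criterion_score`), `candidates` (one data frame per accepted step
#'   with all scored neighbours), `n_scored` (distinct splits scored),
#'   `criterion`, `penalties`.
#' @export
stepwise_search <- function(data, membership, penalties = default_penalties(),
                            criterion = c("ipoq-ll-dif", "ipoq-ll"),
                            constraint = model_constraint(),
                            control = fit_control(), max_rounds = 5L,
                            round_tol = 1e-6, cold_start = FALSE,
                            verbose = FALSE) {
  criterion <- match.arg(criterion)
  st <- search_state(data, membership, penalties, criterion, constraint,
                     control, cold_start, verbose)
  run_backward(st)
  run_forward(st)
  P <- ncol(data$responses)
  for (round in seq_len(max_rounds - 1L) + 1L) {
    changed <- FALSE
    for (size in rev(seq_len(P - 1L)))          # backward refinement
      changed <- refine_step(st, size, size + 1L, "backward", round,
                             round_tol) || changed
    for (size in seq_len(P)[-1L])               # forward refinement
      changed <- refine_step(st, size, size - 1L, "forward", round,
                             round_tol) || changed
    if (!changed) break
  }
  finish_trace(st)
}

#' @rdname stepwise_search
#' @export
backward_pass <- function(data, membership, penalties = default_penalties(),
                          criterion = c("ipoq-ll-dif", "ipoq-ll"),
                          constraint = model_constraint(),
                          control = fit_control(), start_split = NULL,
                          cold_start = FALSE, verbose = FALSE) {
  criterion <- match.arg(criterion)
  st <- search_state(data, membership, penalties, criterion, constraint,
                     control, cold_start, verbose)
  run_backward(st, start_split)
  finish_trace(st)
}

#' @rdname stepwise_search
#' @export
forward_pass <- function(data, membership, penalties = default_penalties(),
                         criterion = c("ipoq-ll-dif", "ipoq-ll"),
                         constraint = model_constraint(),
                         control = fit_control(), cold_start = FALSE,
                         verbose = FALSE) {
  criterion <- match.arg(criterion)
  st <- search_state(data, membership, penalties, criterion, constraint,
                     control, cold_start, verbose)
  run_forward(st)
  finish_trace(st)
}

# --- internal search machinery ------------------------------------------

search_state <- function(data, membership, penalties, criterion, constraint,
                         control, cold_start, verbose) {
  st <- new.env(parent = emptyenv())
  st$data <- data
  st$membership <- membership
  st$penalties <- penalties
  st$criterion <- criterion
  st$constraint <- constraint
  st$control <- control
  st$cold_start <- isTRUE(cold_start)
  st$verbose <- isTRUE(verbose)
  st$P <- ncol(data$responses)
  st$cache <- new.env(parent = emptyenv())   # split key -> criterion_score
  st$n_scored <- 0L
  st$best <- vector("list", st$P)            # per-size best records
  st$candidates <- list()
  st
}

split_key <- function(included) paste(included, collapse = ",")

score_cached <- function(st, included, warm = NULL) {
  key <- split_key(included)
  hit <- st$cache[[key]]
  if (!is.null(hit)) return(hit)
  split <- item_split(included, st$P)
  scorer <- if (st$criterion == "ipoq-ll-dif") score_split else
    score_split_no_dif
  sc <- scorer(st$data, st$membership, split, st$penalties,
               constraint = st$constraint, control = st$control,
               init = if (st$cold_start) NULL else warm)
  st$cache[[key]] <- sc
  st$n_scored <- st$n_scored + 1L
  if (st$verbose)
    message(sprintf("  scored {%s}: %.3f", key, sc$ipoq_ll_dif))
  sc
}

# score all single-item removals from `included`; returns list(score, data)
score_neighbours <- function(st, included, candidates_add = NULL,
                             warm = NULL) {
  if (is.null(candidates_add)) {
    cand_sets <- lapply(included, function(j) setdiff(included, j))
    moved <- included
  } else {
    cand_sets <- lapply(candidates_add, function(j) sort(c(included, j)))
    moved <- candidates_add
  }
  scores <- lapply(cand_sets, function(s) score_cached(st, s, warm))
  totals <- vapply(scores, `[[`, 0, "ipoq_ll_dif")
  best <- which.max(totals)    # ties -> first, i.e. lowest item index
  list(best = scores[[best]], moved_item = moved[best],
       table = data.frame(item = moved,
                          total = totals,
                          iq = vapply(scores, `[[`, 0, "iq_ll_dif"),
                          oq = vapply(scores, `[[`, 0, "oq_ll_dif"),
                          accepted = seq_along(moved) == best))
}

record_best <- function(st, sc, direction, round, moved_item = NA_integer_) {
  size <- length(sc$split$included)
  old <- st$best[[size]]
  if (is.null(old) || sc$ipoq_ll_dif > old$score$ipoq_ll_dif) {
    st$best[[size]] <- list(score = sc, direction = direction,
                            round = round, moved_item = moved_item)
    return(TRUE)
  }
  FALSE
}

run_backward <- function(st, start_split = NULL) {
  included <- if (is.null(start_split)) seq_len(st$P) else
    start_split$included
  sc <- score_cached(st, included)
  record_best(st, sc, "backward", 1L)
  while (length(included) > 1L) {
    res <- score_neighbours(st, included, warm = sc$warm)
    st$candidates[[length(st$candidates) + 1L]] <-
      cbind(from_size = length(included), direction = "backward",
            res$table)
    sc <- res$best
    included <- sc$split$included
    record_best(st, sc, "backward", 1L, res$moved_item)
    if (st$verbose)
      message(sprintf("backward: removed %d -> size %d (%.3f)",
                      res$moved_item, length(included), sc$ipoq_ll_dif))
  }
  invisible(st)
}

run_forward <- function(st) {
  included <- integer(0)
  sc <- NULL
  while (length(included) < st$P) {
    res <- score_neighbours(st, included,
                            candidates_add = setdiff(seq_len(st$P), included),
                            warm = if (is.null(sc)) NULL else sc$warm)
    st$candidates[[length(st$candidates) + 1L]] <-
      cbind(from_size = length(included), direction = "forward", res$table)
    sc <- res$best
    included <- sc$split$included
    record_best(st, sc, "forward", 1L, res$moved_item)
    if (st$verbose)
      message(sprintf("forward: added %d -> size %d (%.3f)",
                      res$moved_item, length(included), sc$ipoq_ll_dif))
  }
  invisible(st)
}

refine_step <- function(st, size, from_size, direction, round, round_tol) {
  from <- st$best[[from_size]]
  cur <- st$best[[size]]
  if (is.null(from)) return(FALSE)
  inc <- from$score$split$included
  res <- if (direction == "backward")
    score_neighbours(st, inc, warm = from$score$warm)
  else
    score_neighbours(st, inc,
                     candidates_add = setdiff(seq_len(st$P), inc),
                     warm = from$score$warm)
  if (is.null(cur) ||
      res$best$ipoq_ll_dif > cur$score$ipoq_ll_dif + round_tol) {
    st$candidates[[length(st$candidates) + 1L]] <-
      cbind(from_size = from_size, direction = direction, res$table)
    st$best[[size]] <- list(score = res$best, direction = direction,
                            round = round, moved_item = res$moved_item)
    return(TRUE)
  }
  FALSE
}

finish_trace <- function(st) {
  sizes <- which(!vapply(st$best, is.null, TRUE))
  per_size <- do.call(rbind, lapply(sizes, function(s) {
    b <- st$best[[s]]
    data.frame(size = s,
               items = split_key(b$score$split$included),
               iq = b$score$iq_ll_dif, oq = b$score$oq_ll_dif,
               total = b$score$ipoq_ll_dif,
               direction = b$direction, round = b$round,
               moved_item = b$moved_item %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
  best_idx <- sizes[which.max(per_size$total)]
  best <- st$best[[best_idx]]
  structure(list(per_size = per_size,
                 best_size = best_idx,
                 best_split = best$score$split,
                 best_score = best$score,
                 candidates = st$candidates,
                 n_scored = st$n_scored,
                 criterion = st$criterion,
                 penalties = st$penalties),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("<search_trace> criterion %s; %d splits scored\n",
              x$criterion, x$n_scored))
  cat(sprintf("  best: |S_in| = %d {%s}, IPOQ = %.3f\n", x$best_size,
              paste(x$best_split$included, collapse = ", "),
              x$best_score$ipoq_ll_dif))
  invisible(x)
}

#' Plot the per-size criterion profile of a search
#'
#' Criterion value of the best split at each included-set size, mirroring
#' the score-versus-size profile used to locate the optimal instrument.
#'
#' @param x a `search_trace`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.search_trace <- function(x, ...) {
  graphics::plot(x$per_size$size, x$per_size$total, type = "b",
                 xlab = "number of included items",
                 ylab = toupper(x$criterion), ...)
  graphics::abline(v = x$best_size, lty = 2, col = "grey40")
  invisible(x)
}
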