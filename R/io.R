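#' Read ordinal responses from CSV
#'
#' Expected layout: header row of item ids, first column subject ids, one
#' row per subject, integer cells, empty cells for missing responses.
#'
#' @param path file path.
#' @param max_categories optional per-item threshold counts (recycled);
#'   default: maximum observed code per item.
#' @return A [response_data].
#' @export
read_responses <- function(path, max_categories = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  if (!nrow(df) || ncol(df) < 2L)
    stop(sprintf("'%s': need a subject-id column plus at least one item column",
                 path), call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, TRUE))[1L]
    stop(sprintf("'%s': column '%s' is not numeric", path,
                 names(df)[bad + 1L]), call. = FALSE)
  }
  response_data(m, max_categories = max_categories, subject_ids = ids,
                item_ids = colnames(m))
}

#' Read a binary group-membership matrix from CSV
#'
#' Same layout as [read_responses()]: subject ids first, then one binary
#' column per DIF covariate, in the same subject order as the responses.
#'
#' @param path file path.
#' @return A [dif_membership].
#' @export
read_membership <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  if (!nrow(df) || ncol(df) < 2L)
    stop(sprintf("'%s': need a subject-id column plus at least one covariate",
                 path), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  dif_membership(m, covariate_ids = colnames(m))
}

#' Write responses / membership to CSV
#'
#' Inverse of the readers; missing responses become empty cells.
#'
#' @param x a [response_data] or [dif_membership].
#' @param path file path.
#' @param header optional named list (e.g. seed, penalty settings) written
#'   as `# key: value` comment lines; the readers skip them.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "response_data"))
  df <- data.frame(subject = x$subject_ids, x$responses,
                   check.names = FALSE)
  colnames(df) <- c("subject", x$item_ids)
  write_csv_with_header(df, path, header, na = "")
}

#' @rdname write_responses
#' @export
write_membership <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "dif_membership"))
  df <- data.frame(subject = seq_len(nrow(x$kappa)), x$kappa,
                   check.names = FALSE)
  colnames(df) <- c("subject", x$covariate_ids)
  write_csv_with_header(df, path, header)
}

write_csv_with_header <- function(df, path, header, na = "NA") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header),
                       vapply(header, function(v) paste(format(v), collapse = " "), "")),
               con)
  utils::write.csv(df, con, row.names = FALSE, na = na)
  invisible(path)
}

#' Serialize / read a simulation specification as JSON
#'
#' @param spec a [sim_spec].
#' @param path file path.
#' @return `read_sim_spec_json` returns a [sim_spec]; the writer returns
#'   `path` invisibly.
#' @export
write_sim_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "sim_spec"))
  out <- list(theta = spec$params$theta, beta = spec$params$beta,
              alpha = spec$params$alpha,
              delta = as.data.frame(spec$params$delta),
              kappa = as.data.frame(spec$kappa),
              item_ids = spec$item_ids, subject_ids = spec$subject_ids)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_spec_json
#' @export
read_sim_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- if (is.list(x$beta)) lapply(x$beta, as.numeric) else
    as.list(as.data.frame(t(x$beta)))
  sim_spec(as.numeric(x$theta), beta, as.numeric(x$alpha),
           as.matrix(x$delta), as.matrix(x$kappa),
           item_ids = x$item_ids, subject_ids = x$subject_ids)
}

params_to_list <- function(p) {
  list(theta = p$theta, beta = p$beta, alpha = p$alpha,
       delta = as.data.frame(p$delta))
}

#' Serialize a fit to JSON
#'
#' Parameter arrays, objective and log-likelihood values, convergence
#' metadata, penalty settings and the itemset, written with full numeric
#' precision.
#'
#' @param fit a `gdif_fit`.
#' @param path output path.
#' @param seed optional seed to record alongside the configuration.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  out <- list(
    itemset = fit$itemset,
    params = params_to_list(fit$params),
    objective = fit$objective,
    log_likelihood = fit$loglik,
    converged = fit$converged,
    n_outer_iterations = fit$n_outer,
    constraint = unclass(fit$constraint),
    penalties = unclass(fit$penalties),
    fix_theta = fit$fix_theta,
    dif_items = which(rowSums(abs(fit$params$delta), na.rm = TRUE) > 0),
    seed = seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fit back from JSON
#'
#' @param path path written by [write_fit_json()].
#' @return A list mirroring the serialized fields, with `params` restored
#'   as a [gdif_params]-classed list.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$params
  beta <- if (is.list(p$beta)) lapply(p$beta, as.numeric) else
    as.list(as.data.frame(t(p$beta)))
  x$params <- structure(
    list(theta = as.numeric(p$theta), beta = beta,
         alpha = as.numeric(p$alpha),
         delta = as.matrix(p$delta)),
    class = "gdif_params")
  x
}

#' Write a search trace
#'
#' `write_trace_tsv` stores one row per scored candidate (size, direction,
#' moved item, IQ/OQ/total, accepted flag); `write_search_json` stores the
#' per-size bests and the overall optimum.
#'
#' @param trace a `search_trace`.
#' @param path output path.
#' @param seed,config optional metadata recorded in the JSON summary.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  tab <- do.call(rbind, trace$candidates)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
write_search_json <- function(trace, path, seed = NULL, config = NULL) {
  out <- list(criterion = trace$criterion,
              penalties = trace$penalties,
              per_size = trace$per_size,
              best_size = trace$best_size,
              best_items = trace$best_split$included,
              best_iq = trace$best_score$iq_ll_dif,
              best_oq = trace$best_score$oq_ll_dif,
              best_total = trace$best_score$ipoq_ll_dif,
              n_scored_splits = trace$n_scored,
              seed = seed, config = config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
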