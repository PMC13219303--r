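#' Response matrix container
#'
#' Holds one row per respondent and one integer column per presentation item
#' (including the instructed item). Simulated data may carry truth labels
#' ("attentive" or a careless archetype name) used to evaluate screening.
#'
#' Columns beyond the design's items (e.g. a criterion battery presented
#' after the focal scale) are allowed and kept after the design items in
#' their own order; only design columns are range-checked against the design
#' scale.
#'
#' @param values integer matrix, columns named by item id in presentation
#'   order.
#' @param respondent_ids character vector, one per row.
#' @param design a [survey_design()]; column order and value range are
#'   validated against it.
#' @param truth_labels optional character vector of per-respondent labels.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(values, respondent_ids, design,
                            truth_labels = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("values must have item ids as column names")
  missing_cols <- setdiff(design$item_ids, colnames(values))
  if (length(missing_cols))
    stop("missing item column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(colnames(values), design$item_ids)
  values <- values[, c(design$item_ids, extra), drop = FALSE]
  storage.mode(values) <- "integer"
  if (anyNA(values)) stop("response values contain missing entries")
  rng <- range(values[, design$item_ids])
  if (rng[1] < design$scale_min || rng[2] > design$scale_max)
    stop("response values outside [", design$scale_min, ", ",
         design$scale_max, "]")
  respondent_ids <- as.character(respondent_ids)
  if (length(respondent_ids) != nrow(values))
    stop("respondent_ids length does not match row count")
  if (!is.null(truth_labels) && length(truth_labels) != nrow(values))
    stop("truth_labels length does not match row count")
  structure(list(values = values,
                 respondent_ids = respondent_ids,
                 truth_labels = truth_labels),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$values), " respondents x ",
      ncol(x$values), " items\n", sep = "")
  if (!is.null(x$truth_labels)) {
    tab <- table(x$truth_labels)
    cat("  truth labels:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Subset a response matrix by respondent
#'
#' @param m a [response_matrix()].
#' @param keep logical or integer row index.
#' @return A `response_matrix` with the selected rows.
#' @export
subset_respondents <- function(m, keep) {
  structure(list(values = m$values[keep, , drop = FALSE],
                 respondent_ids = m$respondent_ids[keep],
                 truth_labels = if (!is.null(m$truth_labels))
                   m$truth_labels[keep]),
            class = "response_matrix")
}

#' Read Likert responses from CSV
#'
#' Expects a UTF-8 CSV with a header row, first column `respondent_id` and
#' one integer column per design item. Rows containing any missing,
#' non-integer or out-of-range cell are rejected under the complete-case
#' policy; rejected respondent ids are reported via a message and returned in
#' the `rejected` attribute.
#'
#' @param path CSV path.
#' @param design a [survey_design()].
#' @return A [response_matrix()] of the retained rows, with attribute
#'   `rejected` (character vector of dropped respondent ids).
#' @export
read_responses <- function(path, design) {
  if (!file.exists(path)) stop("response file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"respondent_id" %in% names(df))
    stop("response file lacks a 'respondent_id' column")
  missing_cols <- setdiff(design$item_ids, names(df))
  if (length(missing_cols))
    stop("missing item column(s): ", paste(missing_cols, collapse = ", "))
  ids <- as.character(df$respondent_id)
  item_cols <- setdiff(names(df), "respondent_id")
  raw <- as.matrix(df[, item_cols, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = dimnames(raw)))
  bad <- is.na(num) | num != round(num)
  in_design <- colnames(num) %in% design$item_ids
  bad[, in_design] <- bad[, in_design] |
    num[, in_design] < design$scale_min | num[, in_design] > design$scale_max
  bad_row <- rowSums(bad) > 0
  if (any(bad_row))
    message("read_responses: rejected ", sum(bad_row),
            " row(s) with missing/out-of-range cells: ",
            paste(utils::head(ids[bad_row], 10), collapse = ", "),
            if (sum(bad_row) > 10) ", ...")
  m <- response_matrix(num[!bad_row, , drop = FALSE], ids[!bad_row], design)
  attr(m, "rejected") <- ids[bad_row]
  m
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_responses()]; the round trip is bit-identical.
#'
#' @param m a [response_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(m, path) {
  df <- data.frame(respondent_id = m$respondent_ids, m$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Reflect reverse-coded items
#'
#' Applies the standard Likert reflection `x -> scale_min + scale_max - x`
#' to every reverse-coded column; all other columns are untouched. Applying
#' the recoding twice restores the original matrix.
#'
#' @param m a [response_matrix()] on the presentation metric.
#' @param design a [survey_design()].
#' @return A `response_matrix` on the analysis (recoded) metric.
#' @export
recode_reverse <- function(m, design) {
  v <- m$values
  rev <- design$reverse_items
  if (length(rev))
    v[, rev] <- design$scale_min + design$scale_max - v[, rev]
  structure(list(values = v, respondent_ids = m$respondent_ids,
                 truth_labels = m$truth_labels),
            class = "response_matrix")
}

#' Scale scores (sum convention)
#'
#' Totals are sums of recoded item values — not means — so that score
#' arithmetic stays exact in integers; the instructed item is always
#' excluded. Factor-level scores sum only that factor's items.
#'
#' @param m a [response_matrix()] that has already been reverse-recoded.
#' @param design a [survey_design()].
#' @param level `"total"` for the full scored item set, or a factor label.
#' @return Named numeric vector of per-respondent scores.
#' @export
scale_scores <- function(m, design, level = "total") {
  items <- if (identical(level, "total")) scored_items(design)
           else factor_items(design, level)
  s <- rowSums(m$values[, items, drop = FALSE])
  names(s) <- m$respondent_ids
  s
}
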