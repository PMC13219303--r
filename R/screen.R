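#' Instructed-response (attention-check) flag
#'
#' A respondent fails the check iff their answer to the instructed item
#' differs from the required category.
#'
#' @param m a [response_matrix()] on the presentation metric.
#' @param design a [survey_design()] with an instructed item.
#' @return Named logical vector, `TRUE` = failed the check.
#' @export
flag_instructed <- function(m, design) {
  if (is.null(design$instructed_item))
    stop("design has no instructed item")
  if (!design$instructed_item %in% colnames(m$values))
    stop("instructed item column '", design$instructed_item, "' absent")
  stats::setNames(m$values[, design$instructed_item] != design$required_category,
                  m$respondent_ids)
}

#' Longstring index
#'
#' Maximum run of consecutive identical responses in presentation order,
#' computed on the raw (non-recoded) values over the full battery — focal
#' items, the instructed item and any criterion columns.
#'
#' @param m a [response_matrix()] on the presentation metric.
#' @return Named integer vector of maximum run lengths.
#' @export
longstring_index <- function(m) {
  if (ncol(m$values) < 1) stop("need at least one item")
  out <- apply(m$values, 1, function(x) max(rle(x)$lengths))
  stats::setNames(as.integer(out), m$respondent_ids)
}

#' Even-odd consistency index
#'
#' Within each factor, the odd-position and even-position items (positions
#' within the factor's own presentation-ordered item list) are averaged into
#' half-scale means. Per respondent, the Pearson correlation `r` between the
#' odd and even half-means across factors is stepped up with the
#' Spearman-Brown formula `r_sb = 2r / (1 + r)` (with `r` floored at
#' `-0.999` to guard the pole at -1, and `r_sb` clipped to `[-1, 1]`), and
#' the index returned is
#' `1 - r_sb`, so higher values mean greater within-person inconsistency
#' (range 0..2). A respondent whose half-means have zero variance (e.g. a
#' pure straightliner) receives the maximal score 2: invariant responding
#' should not earn a missing value.
#'
#' @param m a [response_matrix()] already reverse-recoded.
#' @param design a [survey_design()] with at least 3 factors.
#' @return Named numeric vector in `[0, 2]`.
#' @export
evenodd_index <- function(m, design) {
  facs <- unique(design$factor_map)
  if (length(facs) < 3)
    stop("even-odd consistency needs at least 3 factors")
  halves <- lapply(facs, function(f) {
    ids <- factor_items(design, f)
    pos <- seq_along(ids)
    list(odd = ids[pos %% 2 == 1], even = ids[pos %% 2 == 0])
  })
  odd_means <- do.call(cbind, lapply(halves, function(h)
    rowMeans(m$values[, h$odd, drop = FALSE])))
  even_means <- do.call(cbind, lapply(halves, function(h)
    rowMeans(m$values[, h$even, drop = FALSE])))
  out <- vapply(seq_len(nrow(m$values)), function(i) {
    o <- odd_means[i, ]; e <- even_means[i, ]
    if (stats::sd(o) == 0 || stats::sd(e) == 0) return(2)
    r <- stats::cor(o, e)
    r <- max(r, -0.999)   # guard the Spearman-Brown pole at r = -1
    r_sb <- 2 * r / (1 + r)
    r_sb <- min(max(r_sb, -1), 1)
    1 - r_sb
  }, numeric(1))
  stats::setNames(out, m$respondent_ids)
}

#' Univariate outlier flag on total scores
#'
#' Flags respondents whose standardized total score exceeds `z_cut` in
#' absolute value (sample sd, denominator n - 1). Used as a pre-screen
#' before careless-responding detection.
#'
#' @param scores per-respondent total scores.
#' @param z_cut absolute z threshold (default 4).
#' @return Logical vector, `TRUE` = outlier.
#' @export
outlier_flag <- function(scores, z_cut = 4) {
  if (length(scores) < 2) stop("need at least 2 respondents")
  s <- stats::sd(scores)
  if (s == 0) stop("zero variance in total scores")
  abs((scores - mean(scores)) / s) > z_cut
}

#' Screen a sample with the primary and extended careless definitions
#'
#' Computes all indicators on the unscreened sample, sets the post-hoc cuts
#' at two standard deviations above the unscreened means (sd with
#' denominator n - 1), and returns per-respondent flags under both
#' definitions: primary = failed the instructed item; extended = failed the
#' instructed item OR longstring at/above its cut OR even-odd inconsistency
#' at/above its cut. The primary flag always implies the extended flag.
#'
#' @param m a [response_matrix()] on the presentation metric.
#' @param design a [survey_design()].
#' @return An object of class `screen_result`: a data frame with columns
#'   `respondent_id`, `instructed_fail`, `longstring`, `evenodd`,
#'   `outlier_z`, `flag_primary`, `flag_extended`, plus attributes
#'   `longstring_cut`, `evenodd_cut` and `z_cut`.
#' @export
screen_sample <- function(m, design) {
  instructed <- flag_instructed(m, design)
  ls <- longstring_index(m)
  eo <- evenodd_index(recode_reverse(m, design), design)
  totals <- scale_scores(recode_reverse(m, design), design)
  z <- (totals - mean(totals)) / stats::sd(totals)
  if (stats::sd(ls) == 0 || stats::sd(eo) == 0)
    stop("degenerate (zero-variance) index distribution")
  ls_cut <- mean(ls) + 2 * stats::sd(ls)
  eo_cut <- mean(eo) + 2 * stats::sd(eo)
  flag_ext <- instructed | ls >= ls_cut | eo >= eo_cut
  out <- data.frame(respondent_id = m$respondent_ids,
                    instructed_fail = unname(instructed),
                    longstring = unname(ls),
                    evenodd = unname(eo),
                    outlier_z = unname(z),
                    flag_primary = unname(instructed),
                    flag_extended = unname(flag_ext))
  attr(out, "longstring_cut") <- ls_cut
  attr(out, "evenodd_cut") <- eo_cut
  attr(out, "z_cut") <- 4
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Careless prevalence as a percentage
#'
#' @param n_flagged number of flagged respondents.
#' @param n_total sample size.
#' @param digits decimal places (default 2).
#' @return Percentage, rounded.
#' @export
careless_prevalence <- function(n_flagged, n_total, digits = 2) {
  round(100 * n_flagged / n_total, digits)
}

#' Partition a sample into unscreened / screened / careless
#'
#' @param m a [response_matrix()].
#' @param flags logical vector aligned with respondents (`TRUE` = careless).
#' @return A list of class `analysis_samples` with `unscreened`, `screened`
#'   and `careless` [response_matrix()] objects and a `counts` vector.
#' @export
split_samples <- function(m, flags) {
  if (length(flags) != nrow(m$values))
    stop("flags not aligned with respondents")
  screened <- subset_respondents(m, !flags)
  careless <- subset_respondents(m, flags)
  structure(list(unscreened = m, screened = screened, careless = careless,
                 counts = c(unscreened = nrow(m$values),
                            screened = sum(!flags),
                            careless = sum(flags)),
                 prevalence_pct = careless_prevalence(sum(flags),
                                                     nrow(m$values))),
            class = "analysis_samples")
}

#' @export
print.analysis_samples <- function(x, ...) {
  cat("<analysis_samples> unscreened n =", x$counts[["unscreened"]],
      "| screened n =", x$counts[["screened"]],
      "| careless n =", x$counts[["careless"]],
      sprintf("(%.2f%%)\n", x$prevalence_pct))
  invisible(x)
}
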