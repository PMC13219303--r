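#' Nested-sample permutation test of a mean difference
#'
#' The screened sample is a subset of the unscreened sample, so standard
#' independent-samples tests do not apply to their mean difference. Instead
#' the careless label is reassigned at random to the same number of
#' respondents drawn without replacement from the full sample, and the
#' difference between the full-sample mean and the resulting subsample mean
#' is recorded. The two-sided p-value is the plain proportion of permuted
#' absolute differences at least as large as the observed one (no +1
#' smoothing). When `choose(N, k)` does not exceed `exhaustive_cap`, all
#' reassignments are enumerated and the p-value is exact.
#'
#' @param scores per-respondent scores over the full (unscreened) sample.
#' @param flags logical careless labels aligned with `scores`.
#' @param B number of random reassignments (default 10000).
#' @param seed RNG seed (default 2025).
#' @param exhaustive_cap enumerate exhaustively when the number of distinct
#'   reassignments is at most this (default 50000).
#' @return List of class `permutation_result`: `observed_delta`
#'   (full-sample mean minus subsample mean), `p_two_sided`, `B`, `seed`,
#'   `exhaustive`.
#' @export
permutation_nested_mean_test <- function(scores, flags, B = 10000,
                                         seed = 2025,
                                         exhaustive_cap = 50000) {
  n <- length(scores)
  k <- sum(flags)
  if (k == 0 || k == n) stop("flags must mark a non-empty proper subset")
  full_mean <- mean(scores)
  total <- sum(scores)
  sub_mean <- function(flag_sum) (total - flag_sum) / (n - k)
  observed <- full_mean - sub_mean(sum(scores[flags]))
  n_comb <- choose(n, k)
  exhaustive <- is.finite(n_comb) && n_comb <= exhaustive_cap
  if (exhaustive) {
    sums <- utils::combn(scores, k, sum)
    deltas <- full_mean - sub_mean(sums)
    p <- mean(abs(deltas) >= abs(observed) - 1e-12)
    B_used <- length(deltas)
  } else {
    set.seed(seed)
    sums <- vapply(seq_len(B), function(b) sum(scores[sample.int(n, k)]),
                   numeric(1))
    deltas <- full_mean - sub_mean(sums)
    p <- mean(abs(deltas) >= abs(observed) - 1e-12)
    B_used <- B
  }
  structure(list(observed_delta = observed, p_two_sided = p, B = B_used,
                 seed = seed, exhaustive = exhaustive),
            class = "permutation_result")
}

#' Compare two correlations (Fisher z and Cohen's q)
#'
#' Independent-samples Fisher z test
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value, and Cohen's `q = |atanh(r1) - atanh(r2)|`
#' labelled negligible/small/medium/large at the 0.10/0.30/0.50 cutpoints
#' (boundaries assigned to the lower bin).
#'
#' Note: the unscreened and screened samples are nested, not independent;
#' this function applies the independent-samples formula exactly as the
#' comparative design uses it, so its p-values are approximate there.
#'
#' @param r1,r2 correlations (|r| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @return List of class `correlation_comparison`: `r1`, `r2`, `n1`, `n2`,
#'   `fisher_z`, `p`, `cohens_q`, `q_label`.
#' @export
fisher_q_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must satisfy |r| < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  dz <- atanh(r1) - atanh(r2)
  z <- dz / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  q <- abs(dz)
  structure(list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, fisher_z = z, p = p,
                 cohens_q = q, q_label = effect_label(q, c(0.10, 0.30, 0.50))),
            class = "correlation_comparison")
}

# Bin an absolute effect size; boundary values fall in the lower bin.
effect_label <- function(x, cuts) {
  labels <- c("negligible", "small", "medium", "large")
  labels[findInterval(abs(x), cuts, left.open = TRUE) + 1]
}

#' Cohen's d with confidence interval and Welch test
#'
#' `d = (m1 - m2) / s_pooled` with the pooled n-1 standard deviation, a
#' normal-approximation interval with
#' `se = sqrt(1/n1 + 1/n2 + d^2 / (2 (n1 + n2)))`, the magnitude label at
#' the 0.20/0.50/0.80 cutpoints, and the Welch t statistic with
#' Satterthwaite degrees of freedom.
#'
#' @param x,y numeric score vectors for the two groups.
#' @param level confidence level (default 0.95).
#' @return List of class `effect_size`: `cohens_d`, `ci`, `d_label`,
#'   `welch_t`, `welch_df`, `p`.
#' @export
cohens_d <- function(x, y, level = 0.95) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 observations")
  v1 <- stats::var(x); v2 <- stats::var(y)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  se <- sqrt(1 / n1 + 1 / n2 + d^2 / (2 * (n1 + n2)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  tt <- stats::t.test(x, y)   # Welch by default
  structure(list(cohens_d = d, ci = c(d - zq * se, d + zq * se),
                 d_label = effect_label(d, c(0.20, 0.50, 0.80)),
                 welch_t = unname(tt$statistic),
                 welch_df = unname(tt$parameter), p = tt$p.value),
            class = "effect_size")
}

#' Minimum detectable effect size for a two-sample t test
#'
#' Smallest standardized mean difference d for which a two-sided
#' independent-samples t test with the given group sizes reaches the stated
#' power, solved by root-finding on the noncentral-t power function with
#' noncentrality `d * sqrt(n1 n2 / (n1 + n2))`.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return Cohen's d.
#' @export
min_detectable_d <- function(n1, n2, alpha = 0.05, power = 0.80) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  df <- n1 + n2 - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  pw <- function(d) {
    ncp <- d * sqrt(n1 * n2 / (n1 + n2))
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp)
  }
  stats::uniroot(function(d) pw(d) - power, lower = 1e-6, upper = 10,
                 tol = 1e-9)$root
}

#' Per-item statistics entering the sensitivity index
#'
#' Item means on the recoded metric, corrected item-total correlations, and
#' standardized loadings from the design's factor model, for one analysis
#' sample.
#'
#' @param m a recoded [response_matrix()].
#' @param design a [survey_design()].
#' @param cfa optional pre-computed [fit_cfa()] result for this sample.
#' @param label sample label carried into the output.
#' @return Data frame of class `item_stats` with columns `item`, `factor`,
#'   `type` (standard/reverse), `position`, `mean`, `r_it`, `lambda`.
#' @export
item_stats <- function(m, design, cfa = NULL, label = "sample") {
  ids <- scored_items(design)
  x <- m$values[, ids, drop = FALSE]
  if (is.null(cfa)) cfa <- fit_cfa(m, design)
  out <- data.frame(
    item = ids,
    factor = unname(design$factor_map[ids]),
    type = ifelse(ids %in% design$reverse_items, "reverse", "standard"),
    position = match(ids, design$item_ids),
    mean = unname(colMeans(x)),
    r_it = unname(item_total_correlations(x)[ids]),
    lambda = unname(cfa$lambda_std[ids]))
  attr(out, "label") <- label
  class(out) <- c("item_stats", "data.frame")
  out
}

#' Composite Sensitivity Index between two parallel samples
#'
#' For each item, `CSI = |dM| + |dr| + |dlambda|`: the absolute differences
#' in item mean (recoded metric), corrected item-total correlation and
#' standardized loading between the two samples, summed without weights.
#' Ranks are assigned by descending CSI with ties broken by presentation
#' position (earlier first).
#'
#' @param stats_a,stats_b [item_stats()] for the two samples (same items).
#' @return Data frame of class `csi_table` with columns `item`, `factor`,
#'   `type`, `position`, `dM`, `dr`, `dlam`, `csi`, `rank`.
#' @export
csi_compute <- function(stats_a, stats_b) {
  if (!identical(stats_a$item, stats_b$item))
    stop("item sets differ between the two samples")
  out <- data.frame(item = stats_a$item, factor = stats_a$factor,
                    type = stats_a$type, position = stats_a$position,
                    dM = abs(stats_a$mean - stats_b$mean),
                    dr = abs(stats_a$r_it - stats_b$r_it),
                    dlam = abs(stats_a$lambda - stats_b$lambda))
  out$csi <- out$dM + out$dr + out$dlam
  out$rank <- rank_desc(out$csi, out$position)
  class(out) <- c("csi_table", "data.frame")
  out
}

# Descending rank with presentation-position tie-break.
rank_desc <- function(x, position) {
  ord <- order(-x, position)
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

#' Standardized Composite Sensitivity Index
#'
#' Adds `csi_z` — the sum of the three components after z-scoring each
#' across items (n-1 sd) — and its rank. Errors when any component is
#' constant across items.
#'
#' @param table a [csi_compute()] result with at least 3 items.
#' @return The table with `csi_z` and `rank_z` columns appended.
#' @export
csi_z <- function(table) {
  if (nrow(table) < 3) stop("need at least 3 items")
  comp <- table[, c("dM", "dr", "dlam")]
  sds <- vapply(comp, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("zero-variance component(s): ",
         paste(names(sds)[sds == 0], collapse = ", "))
  zs <- scale(as.matrix(comp))
  table$csi_z <- rowSums(zs)
  table$rank_z <- rank_desc(table$csi_z, table$position)
  table
}

#' Rank agreement between two orderings
#'
#' Spearman's rho (Pearson on mid-ranks) and Kendall's tau-b with tie
#' correction, with two-sided p-values.
#'
#' @param r1,r2 equal-length score or rank vectors (n >= 3).
#' @return List with `spearman_rho`, `spearman_p`, `kendall_tau_b`,
#'   `kendall_p`.
#' @export
rank_agreement <- function(r1, r2) {
  if (length(r1) != length(r2)) stop("vectors must have equal length")
  if (length(r1) < 3) stop("need at least 3 observations")
  if (stats::sd(r1) == 0 || stats::sd(r2) == 0)
    stop("constant input vector")
  sp <- suppressWarnings(stats::cor.test(r1, r2, method = "spearman"))
  kd <- suppressWarnings(stats::cor.test(r1, r2, method = "kendall"))
  list(spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       kendall_tau_b = unname(kd$estimate), kendall_p = kd$p.value)
}

#' Most-sensitive items report
#'
#' Items sorted by descending CSI (presentation-position tie-break), with
#' the count of reverse-coded items among the top k and the sensitivity of
#' the item immediately following the instructed item.
#'
#' @param table a [csi_compute()] result.
#' @param k how many items to report (default 10).
#' @param design optional [survey_design()]; enables the
#'   after-instructed-item annotation.
#' @return List with `top` (the first k rows in rank order),
#'   `n_reverse_top` and `after_instructed` (row for the item presented
#'   right after the instructed item, or `NULL`).
#' @export
top_k_report <- function(table, k = 10, design = NULL) {
  if (k > nrow(table)) stop("k exceeds the number of items")
  ord <- table[order(table$rank), ]
  top <- ord[seq_len(k), ]
  after <- NULL
  if (!is.null(design) && !is.null(design$instructed_item)) {
    pos_after <- match(design$instructed_item, design$item_ids) + 1
    if (pos_after <= length(design$item_ids)) {
      id_after <- design$item_ids[pos_after]
      after <- table[table$item == id_after, ]
      if (nrow(after) == 0) after <- NULL
    }
  }
  list(top = top, n_reverse_top = sum(top$type == "reverse"),
       after_instructed = after)
}
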