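#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))`, variances
#' with denominator n - 1.
#'
#' @param items numeric matrix of recoded item responses (rows =
#'   respondents).
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2) stop("need at least 2 items")
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero variance in the item sum")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Feldt confidence interval for alpha
#'
#' Inverts the F distribution of `(1 - alpha_hat)` with degrees of freedom
#' `n - 1` and `(n - 1)(k - 1)`.
#'
#' @param alpha estimated alpha (< 1).
#' @param n respondents.
#' @param k items.
#' @param level confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
alpha_ci <- function(alpha, n, k, level = 0.95) {
  if (n <= 1 || k <= 1) stop("invalid degrees of freedom")
  gamma <- 1 - level
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  low <- 1 - (1 - alpha) * stats::qf(1 - gamma / 2, df1, df2)
  high <- 1 - (1 - alpha) * stats::qf(gamma / 2, df1, df2)
  c(low = low, high = high)
}

#' Corrected item-total correlations
#'
#' Pearson correlation of each item with the sum of the remaining items.
#'
#' @param items numeric matrix of recoded item responses.
#' @return Named numeric vector, one per item.
#' @export
item_total_correlations <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 3) stop("need at least 3 items")
  total <- rowSums(items)
  out <- vapply(seq_len(ncol(items)), function(j) {
    rest <- total - items[, j]
    if (stats::sd(items[, j]) == 0 || stats::sd(rest) == 0)
      stop("zero variance in item or rest score (item ", j, ")")
    stats::cor(items[, j], rest)
  }, numeric(1))
  stats::setNames(out, colnames(items))
}

#' McDonald's omega (total and hierarchical)
#'
#' Fits the group-factor CFA implied by `design`, then a second-order
#' general factor over the group factors, and applies the Schmid-Leiman
#' transform: general loadings `g_j = lambda_j * gamma_f(j)` and residualized
#' group loadings `s_j = lambda_j * sqrt(1 - gamma_f^2)` (standardized
#' metric). Omegas follow
#' `omega_h = (sum g)^2 / V` and
#' `omega_t = ((sum g)^2 + sum_f (sum_{j in f} s_j)^2) / V` with
#' `V = (sum g)^2 + sum_f (sum s)^2 + sum psi`.
#'
#' With three group factors the second-order loadings have the closed form
#' `gamma_1 = sqrt(phi_12 * phi_13 / phi_23)` (and rotations thereof); they
#' are clipped to `[0, 0.999]`. For a single-factor design the general
#' factor is the factor itself and `omega_h = omega_t`.
#'
#' @param items numeric matrix of recoded scored-item responses.
#' @param design a [survey_design()] restricted to these items, or `NULL`
#'   for a one-factor model over all columns.
#' @return List with `omega_t`, `omega_h`, `ratio_h_t`, and the
#'   Schmid-Leiman loadings `general` and `group`.
#' @export
omega_coefficients <- function(items, design = NULL) {
  items <- as.matrix(items)
  if (is.null(design) || length(unique(design$factor_map)) == 1) {
    fit <- fit_cfa_matrix(items, rep("g", ncol(items)))
    lam <- abs(fit$lambda_std)
    psi <- 1 - lam^2
    v <- sum(lam)^2 + sum(psi)
    om <- sum(lam)^2 / v
    return(list(omega_t = om, omega_h = om, ratio_h_t = 1,
                general = lam, group = rep(0, length(lam))))
  }
  fmap <- design$factor_map[colnames(items)]
  fit <- fit_cfa_matrix(items, fmap)
  lam <- fit$lambda_std
  phi <- fit$phi_cor
  facs <- unique(fmap)
  if (length(facs) == 3) {
    g12 <- phi[facs[1], facs[2]]; g13 <- phi[facs[1], facs[3]]
    g23 <- phi[facs[2], facs[3]]
    if (any(c(g12, g13, g23) <= 0))
      stop("second-order structure requires positive factor correlations")
    gamma <- c(sqrt(g12 * g13 / g23), sqrt(g12 * g23 / g13),
               sqrt(g13 * g23 / g12))
  } else {
    # general-factor loadings from the average correlation structure:
    # least-squares fit of gamma_a * gamma_b to the off-diagonal of phi
    gamma <- rep(sqrt(mean(phi[upper.tri(phi)])), length(facs))
  }
  gamma <- pmin(pmax(gamma, 0), 0.999)
  names(gamma) <- facs
  g <- lam * gamma[fmap]
  s <- lam * sqrt(1 - gamma[fmap]^2)
  psi <- 1 - lam^2
  group_sums <- vapply(facs, function(f) sum(s[fmap == f])^2, numeric(1))
  v <- sum(g)^2 + sum(group_sums) + sum(psi)
  omega_h <- sum(g)^2 / v
  omega_t <- (sum(g)^2 + sum(group_sums)) / v
  list(omega_t = omega_t, omega_h = omega_h,
       ratio_h_t = omega_h / omega_t, general = g, group = s)
}

#' Reliability report for one sample
#'
#' Alpha with its Feldt interval for the total scale and each factor,
#' plus omega total/hierarchical for the total scale (hierarchical omega
#' requires the multi-factor structure) and omega total per factor.
#'
#' @param m a recoded [response_matrix()].
#' @param design a [survey_design()].
#' @param level confidence level for the alpha interval.
#' @return A data frame with one row per scale
#'   (`total` plus each factor): `scale`, `k`, `n`, `alpha`, `alpha_low`,
#'   `alpha_high`, `omega_t`, `omega_h`.
#' @export
reliability_report <- function(m, design, level = 0.95) {
  scales <- c("total", unique(design$factor_map))
  n <- nrow(m$values)
  rows <- lapply(scales, function(sc) {
    ids <- if (sc == "total") scored_items(design) else factor_items(design, sc)
    x <- m$values[, ids, drop = FALSE]
    a <- cronbach_alpha(x)
    ci <- alpha_ci(a, n, length(ids), level)
    om <- if (sc == "total") {
      omega_coefficients(x, design)
    } else {
      omega_coefficients(x, NULL)
    }
    data.frame(scale = sc, k = length(ids), n = n, alpha = a,
               alpha_low = unname(ci[1]), alpha_high = unname(ci[2]),
               omega_t = om$omega_t,
               omega_h = if (sc == "total") om$omega_h else NA_real_)
  })
  do.call(rbind, rows)
}
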