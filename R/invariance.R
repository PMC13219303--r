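# Multigroup ML CFA with mean structure, for measurement-invariance testing
# across two groups. Levels:
#   configural - all parameters free per group (factor means fixed at 0,
#                intercepts free, marker loadings fixed at 1)
#   metric     - factor loadings constrained equal across groups
#   scalar     - loadings and intercepts equal; the second group's factor
#                means are freed
# The discrepancy is sum_g (n_g - 1) * F_g (Wishart convention) with F_g the
# mean-and-covariance ML discrepancy; its minimum is the chi-square.

# Parameter packing for one invariance level. Layout:
#   shared lambda (metric/scalar) | per-group lambda (configural)
#   per-group Lchol | per-group psi
#   shared nu (scalar) | per-group nu (configural/metric)
#   alpha group 2 (scalar only)
mg_layout <- function(st, level, G = 2) {
  nl <- st$n_free_lambda; nL <- st$n_ltri; p <- st$p; nf <- st$nf
  share_lambda <- level %in% c("metric", "scalar")
  share_nu <- level == "scalar"
  free_alpha <- level == "scalar"
  n_lambda <- if (share_lambda) nl else G * nl
  n_nu <- if (share_nu) p else G * p
  n_alpha <- if (free_alpha) (G - 1) * nf else 0
  total <- n_lambda + G * nL + G * p + n_nu + n_alpha
  lam_idx <- function(g) if (share_lambda) seq_len(nl) else (g - 1) * nl + seq_len(nl)
  off_L <- n_lambda
  L_idx <- function(g) off_L + (g - 1) * nL + seq_len(nL)
  off_psi <- off_L + G * nL
  psi_idx <- function(g) off_psi + (g - 1) * p + seq_len(p)
  off_nu <- off_psi + G * p
  nu_idx <- function(g) if (share_nu) off_nu + seq_len(p)
                        else off_nu + (g - 1) * p + seq_len(p)
  off_alpha <- off_nu + n_nu
  alpha_idx <- function(g) {
    if (!free_alpha || g == 1) NULL else off_alpha + (g - 2) * nf + seq_len(nf)
  }
  list(total = total, share_lambda = share_lambda, share_nu = share_nu,
       free_alpha = free_alpha, lam_idx = lam_idx, L_idx = L_idx,
       psi_idx = psi_idx, nu_idx = nu_idx, alpha_idx = alpha_idx,
       diag_L = which(st$ltri %in% which(diag(st$nf) == 1)))
}

# Objective + gradient over the packed vector.
mg_objgrad <- function(th, st, lay, dat, want_grad = TRUE) {
  G_n <- length(dat)
  f <- 0
  grad <- if (want_grad) numeric(lay$total) else NULL
  for (g in seq_len(G_n)) {
    d <- dat[[g]]
    lam <- th[lay$lam_idx(g)]
    Lch <- ltri_matrix(st, th[lay$L_idx(g)])
    psi <- th[lay$psi_idx(g)]
    nu <- th[lay$nu_idx(g)]
    ai <- lay$alpha_idx(g)
    alpha <- if (is.null(ai)) rep(0, st$nf) else th[ai]
    r <- cfa_group_fg(st, lam, Lch, psi, d$S, d$logdetS,
                      sample_mean = d$m, nu = nu, alpha = alpha)
    w <- d$n - 1
    f <- f + w * r$F
    if (want_grad) {
      grad[lay$lam_idx(g)] <- grad[lay$lam_idx(g)] + w * r$g_lam
      grad[lay$L_idx(g)] <- grad[lay$L_idx(g)] + w * r$g_L
      grad[lay$psi_idx(g)] <- grad[lay$psi_idx(g)] + w * r$g_psi
      grad[lay$nu_idx(g)] <- grad[lay$nu_idx(g)] + w * r$g_nu
      if (!is.null(ai)) grad[ai] <- grad[ai] + w * r$g_alpha
    }
  }
  list(F = f, grad = grad)
}

# Fit one invariance level. start_from: optional parameter list from the
# previous level used to warm-start.
mg_fit_level <- function(st, dat, level, start_from = NULL) {
  lay <- mg_layout(st, level, length(dat))
  G_n <- length(dat)
  th0 <- numeric(lay$total)
  for (g in seq_len(G_n)) {
    s <- cfa_start(st, dat[[g]]$S)
    if (lay$share_lambda) {
      th0[lay$lam_idx(g)] <- if (g == 1) s$lam else
        (th0[lay$lam_idx(1)] + s$lam) / 2
    } else th0[lay$lam_idx(g)] <- s$lam
    th0[lay$L_idx(g)] <- s$L
    th0[lay$psi_idx(g)] <- s$psi
    th0[lay$nu_idx(g)] <- if (lay$share_nu && g == 2)
      (th0[lay$nu_idx(1)] + dat[[g]]$m) / 2 else dat[[g]]$m
  }
  if (!is.null(start_from)) {
    # carry over whatever the previous level estimated; a newly shared
    # parameter starts from the largest group's estimate (the small group's
    # free loadings can be wildly unstable when its factor variance is near
    # zero, so averaging them in would poison the start)
    ng <- vapply(dat, `[[`, 0, "n")
    g_big <- which.max(ng)
    w <- (ng - 1) / sum(ng - 1)
    for (g in seq_len(G_n)) {
      th0[lay$lam_idx(g)] <- if (lay$share_lambda)
        start_from$lambda[[min(g_big, length(start_from$lambda))]]
      else start_from$lambda[[min(g, length(start_from$lambda))]]
      th0[lay$L_idx(g)] <- start_from$L[[g]]
      th0[lay$psi_idx(g)] <- start_from$psi[[g]]
      th0[lay$nu_idx(g)] <- if (lay$share_nu)
        Reduce(`+`, Map(`*`, start_from$nu, w))
      else start_from$nu[[g]]
    }
  }
  lower <- rep(-Inf, lay$total)
  for (g in seq_len(G_n)) {
    lower[lay$psi_idx(g)] <- 0.001
    lower[lay$L_idx(g)[lay$diag_L]] <- 1e-4
  }
  # optimize on the per-observation scale so the convergence tolerance is
  # comparable to the single-group fit; chi-square = objective * (N - G)
  w_tot <- sum(vapply(dat, `[[`, 0, "n")) - length(dat)
  obj <- function(th) mg_objgrad(th, st, lay, dat, want_grad = FALSE)$F / w_tot
  gra <- function(th) mg_objgrad(th, st, lay, dat)$grad / w_tot
  best <- cfa_optimize(th0, obj, gra, lower, jitter_seed = 88007,
                       jitter_sd = 0.1)
  best$objective <- best$objective * w_tot
  th <- best$par
  n_free <- lay$total
  p_star <- G_n * (st$p * (st$p + 1) / 2 + st$p)   # cov + mean moments
  df <- p_star - n_free
  params <- list(
    lambda = if (lay$share_lambda) list(th[lay$lam_idx(1)])
             else lapply(seq_len(G_n), function(g) th[lay$lam_idx(g)]),
    L = lapply(seq_len(G_n), function(g) th[lay$L_idx(g)]),
    psi = lapply(seq_len(G_n), function(g) th[lay$psi_idx(g)]),
    nu = if (lay$share_nu) rep(list(th[lay$nu_idx(1)]), G_n)
         else lapply(seq_len(G_n), function(g) th[lay$nu_idx(g)]))
  list(chi2 = best$objective, df = df, converged = best$converged,
       iterations = best$iterations, gradient_norm = best$gradient_norm,
       params = params)
}

#' Invariance support decision rule
#'
#' A level is supported when the CFI drop from the previous level is no
#' worse than -0.010 and the RMSEA increase is at most 0.015.
#'
#' @param delta_cfi CFI(level) - CFI(previous level).
#' @param delta_rmsea RMSEA(level) - RMSEA(previous level).
#' @return Logical.
#' @export
invariance_decision <- function(delta_cfi, delta_rmsea) {
  delta_cfi >= -0.010 & delta_rmsea <= 0.015
}

#' Configural / metric / scalar invariance sequence
#'
#' Fits the three nested multigroup models to two groups measured with the
#' same design, and evaluates each constrained step with the
#' `delta CFI >= -0.010` and `delta RMSEA <= 0.015` rule plus the
#' chi-square difference test. CFI uses the multigroup independence
#' baseline (free variances and means per group); the RMSEA denominator is
#' `df * (N - #groups)`.
#'
#' @param group1,group2 recoded [response_matrix()] objects (or numeric
#'   matrices of the scored items).
#' @param design a [survey_design()].
#' @param min_n minimum per-group size (default 100).
#' @return An object of class `invariance_report`: data frame with one row
#'   per level (`chi2`, `df`, `cfi`, `rmsea`, `delta_cfi`, `delta_rmsea`,
#'   `delta_chi2`, `delta_df`, `p_delta`, `supported`) plus a `converged`
#'   attribute.
#' @export
invariance_sequence <- function(group1, group2, design, min_n = 100) {
  get_items <- function(m) {
    if (inherits(m, "response_matrix"))
      m$values[, scored_items(design), drop = FALSE]
    else as.matrix(m)[, scored_items(design), drop = FALSE]
  }
  g1 <- get_items(group1); g2 <- get_items(group2)
  if (nrow(g1) < min_n || nrow(g2) < min_n)
    stop("both groups must have at least ", min_n, " respondents")
  fmap <- design$factor_map[colnames(g1)]
  st <- cfa_structure(fmap)
  dat <- lapply(list(g1, g2), function(x) {
    S <- stats::cov(x)
    if (inherits(try(chol(S), silent = TRUE), "try-error"))
      stop("a group covariance matrix is not positive-definite")
    list(S = S, m = colMeans(x), n = nrow(x),
         logdetS = determinant(S, logarithm = TRUE)$modulus[1])
  })
  N <- sum(vapply(dat, `[[`, 0, "n"))
  G_n <- length(dat)
  chi2_b <- sum(vapply(dat, function(d)
    (d$n - 1) * (sum(log(diag(d$S))) - d$logdetS), numeric(1)))
  df_b <- G_n * st$p * (st$p - 1) / 2
  levels <- c("configural", "metric", "scalar")
  fits <- vector("list", 3)
  prev <- NULL
  for (i in seq_along(levels)) {
    fits[[i]] <- mg_fit_level(st, dat, levels[i], start_from = prev)
    prev <- fits[[i]]$params
  }
  # mean structure is saturated at configural/metric, so the baseline and
  # model chi-squares are covariance-moment quantities; indices use the
  # covariance-structure df for CFI/TLI consistency with the single-group
  # fits, and df * (N - G) for RMSEA.
  n_eff <- N - G_n + 1
  rows <- lapply(seq_along(levels), function(i) {
    f <- fits[[i]]
    idx <- fit_indices(f$chi2, f$df, chi2_b, df_b, n_eff)
    data.frame(level = levels[i], chi2 = f$chi2, df = f$df,
               cfi = idx$cfi, rmsea = idx$rmsea,
               converged = f$converged)
  })
  out <- do.call(rbind, rows)
  out$delta_cfi <- c(NA, diff(out$cfi))
  out$delta_rmsea <- c(NA, diff(out$rmsea))
  out$delta_chi2 <- c(NA, diff(out$chi2))
  out$delta_df <- c(NA, diff(out$df))
  out$p_delta <- ifelse(is.na(out$delta_chi2), NA,
                        stats::pchisq(out$delta_chi2, out$delta_df,
                                      lower.tail = FALSE))
  out$supported <- ifelse(is.na(out$delta_cfi), NA,
                          invariance_decision(out$delta_cfi, out$delta_rmsea))
  class(out) <- c("invariance_report", "data.frame")
  attr(out, "n_groups") <- c(nrow(g1), nrow(g2))
  out
}
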