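# Maximum-likelihood confirmatory factor analysis engine.
#
# Model: Sigma(theta) = Lambda Phi Lambda' + diag(psi), simple structure
# (each item loads on exactly one factor), identified by fixing the first
# indicator loading of each factor to 1. Phi is parameterized through its
# lower-triangular Cholesky factor so the implied covariance matrix is
# always positive-definite; residual variances are bounded below at 0.001
# (values at the bound are reported as Heywood warnings). The discrepancy
# function is
#   F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p
# with S the unbiased (n-1) sample covariance, minimized by nlminb with
# analytic gradients; chi-square = (n-1) * F_ML at the optimum.

# Model structure bookkeeping shared by single- and multigroup fits.
cfa_structure <- function(fmap) {
  items <- names(fmap)
  facs <- unique(fmap)
  p <- length(items)
  nf <- length(facs)
  fidx <- match(fmap, facs)                     # factor index per item
  marker <- match(facs, fmap)                   # first indicator per factor
  free_lambda <- setdiff(seq_len(p), marker)    # rows with free loadings
  ltri <- which(lower.tri(diag(nf), diag = TRUE))
  list(items = items, facs = facs, p = p, nf = nf, fidx = fidx,
       marker = marker, free_lambda = free_lambda, ltri = ltri,
       n_free_lambda = length(free_lambda), n_ltri = length(ltri))
}

# Lambda matrix (p x nf) from free-loading values.
cfa_lambda <- function(st, lam_free) {
  L <- matrix(0, st$p, st$nf)
  L[cbind(seq_len(st$p), st$fidx)] <- 1
  L[cbind(st$free_lambda, st$fidx[st$free_lambda])] <- lam_free
  L
}

# F_ML and gradient for one group (covariance structure only, or with mean
# structure when sample_mean/nu/alpha are supplied). Returns list(F, grad)
# where grad has components lam_free, Lchol (lower-tri vector), psi, and,
# with means, nu and alpha.
cfa_group_fg <- function(st, lam_free, Lchol, psi, S, logdetS,
                         sample_mean = NULL, nu = NULL, alpha = NULL) {
  Lam <- cfa_lambda(st, lam_free)
  Phi <- tcrossprod(Lchol)
  Sigma <- Lam %*% Phi %*% t(Lam)
  diag(Sigma) <- diag(Sigma) + psi
  ch <- chol(Sigma)
  Sinv <- chol2inv(ch)
  logdet <- 2 * sum(log(diag(ch)))
  f <- logdet + sum(Sinv * S) - logdetS - st$p
  Seff <- S
  mean_grad <- NULL
  if (!is.null(sample_mean)) {
    mu <- nu + as.numeric(Lam %*% alpha)
    d <- sample_mean - mu
    Sid <- as.numeric(Sinv %*% d)
    f <- f + sum(d * Sid)
    Seff <- S + tcrossprod(d)
    mean_grad <- list(dmu = -2 * Sid)
  }
  G <- Sinv %*% (Sigma - Seff) %*% Sinv
  GLP <- G %*% Lam %*% Phi
  g_lam <- 2 * GLP[cbind(st$free_lambda, st$fidx[st$free_lambda])]
  M <- t(Lam) %*% G %*% Lam                      # dF/dPhi (full symmetric)
  g_L <- (2 * M %*% Lchol)[st$ltri]
  g_psi <- diag(G)
  out <- list(F = f, g_lam = g_lam, g_L = g_L, g_psi = g_psi)
  if (!is.null(mean_grad)) {
    out$g_nu <- mean_grad$dmu
    out$g_alpha <- as.numeric(t(Lam) %*% mean_grad$dmu)
    # loadings also enter the mean structure through Lambda alpha
    out$g_lam <- out$g_lam +
      mean_grad$dmu[st$free_lambda] * alpha[st$fidx[st$free_lambda]]
  }
  out
}

# Start values per the package's fixed convention: free loadings from item /
# marker sd ratios, factor variance 0.49 * marker variance, factor
# correlations 0.3, psi = 0.5 * item variance.
cfa_start <- function(st, S) {
  sds <- sqrt(diag(S))
  lam0 <- sds[st$free_lambda] / sds[st$marker[st$fidx[st$free_lambda]]]
  Phi0 <- matrix(0.3, st$nf, st$nf)
  diag(Phi0) <- 1
  sf <- 0.7 * sds[st$marker]
  Phi0 <- Phi0 * tcrossprod(sf)
  L0 <- t(chol(Phi0))
  psi0 <- 0.5 * diag(S)
  list(lam = lam0, L = L0[st$ltri], psi = psi0)
}

# Generic bounded minimizer used by the single- and multigroup fits:
# quasi-Newton (nlminb) runs followed by L-BFGS-B polish cycles until the
# gradient norm drops below `gtol` (1e-5 on the per-observation F scale),
# with up to three jittered restarts from the supplied start values on
# non-convergence (fixed jitter seed). Returns the best solution found by
# objective value.
cfa_optimize <- function(th0, obj, gra, lower, gtol = 1e-5,
                         jitter_seed = 77003, jitter_sd = 0.2) {
  # projected gradient norm: at an active lower bound only a gradient
  # pushing further down is ignored
  pgn <- function(th) {
    g <- gra(th)
    at_bound <- is.finite(lower) & th <= lower + 1e-8
    g[at_bound & g > 0] <- 0
    sqrt(sum(g^2))
  }
  run_one <- function(th_try) {
    fit <- stats::nlminb(th_try, obj, gradient = gra, lower = lower,
                         control = list(iter.max = 2000, eval.max = 4000))
    th <- fit$par
    iters <- fit$iterations
    gn <- pgn(th)
    for (cycle in 1:4) {
      if (gn < gtol) break
      pol <- stats::optim(th, obj, gra, method = "L-BFGS-B", lower = lower,
                          control = list(maxit = 3000, factr = 10))
      fit <- stats::nlminb(pol$par, obj, gradient = gra, lower = lower,
                           control = list(iter.max = 2000, eval.max = 4000))
      th <- fit$par
      iters <- iters + fit$iterations
      gn <- pgn(th)
    }
    list(par = th, objective = obj(th), iterations = iters,
         gradient_norm = gn, converged = gn < gtol)
  }
  best <- NULL
  for (attempt in 0:3) {
    th_try <- th0
    if (attempt > 0) {
      set.seed(jitter_seed + attempt)
      th_try <- th0 * (1 + jitter_sd * stats::runif(length(th0), -1, 1))
      th_try <- pmax(th_try, lower + 1e-6)
    }
    cand <- run_one(th_try)
    if (is.null(best) || cand$objective < best$objective - 1e-9 ||
        (cand$objective < best$objective + 1e-9 && cand$converged &&
         !best$converged)) best <- cand
    if (best$converged && attempt >= 1) break
  }
  best
}

# Minimize F_ML for one group (covariance only).
cfa_minimize <- function(st, S) {
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  start <- cfa_start(st, S)
  i_lam <- seq_len(st$n_free_lambda)
  i_L <- st$n_free_lambda + seq_len(st$n_ltri)
  i_psi <- st$n_free_lambda + st$n_ltri + seq_len(st$p)
  diag_pos <- which(st$ltri %in% which(diag(st$nf) == 1))  # diagonal of L
  lower <- rep(-Inf, st$n_free_lambda + st$n_ltri + st$p)
  lower[i_psi] <- 0.001
  lower[i_L[diag_pos]] <- 1e-4
  obj <- function(th)
    cfa_group_fg(st, th[i_lam], ltri_matrix(st, th[i_L]), th[i_psi],
                 S, logdetS)$F
  gra <- function(th) {
    g <- cfa_group_fg(st, th[i_lam], ltri_matrix(st, th[i_L]), th[i_psi],
                      S, logdetS)
    c(g$g_lam, g$g_L, g$g_psi)
  }
  best <- cfa_optimize(c(start$lam, start$L, start$psi), obj, gra, lower)
  best$i_lam <- i_lam; best$i_L <- i_L; best$i_psi <- i_psi
  best
}

# Rebuild the lower-triangular Cholesky matrix from its packed vector.
ltri_matrix <- function(st, v) {
  L <- matrix(0, st$nf, st$nf)
  L[st$ltri] <- v
  L
}

# Core single-group fit on a raw data matrix + factor assignment.
# Exposed internally so reliability/omega can reuse it.
fit_cfa_matrix <- function(items, fmap) {
  items <- as.matrix(items)
  if (is.null(names(fmap))) names(fmap) <- colnames(items)
  st <- cfa_structure(fmap)
  n <- nrow(items)
  if (n <= st$p) stop("need more respondents than items (n > p)")
  S <- stats::cov(items)
  if (inherits(try(chol(S), silent = TRUE), "try-error"))
    stop("sample covariance matrix is not positive-definite")
  n_free <- st$n_free_lambda + st$n_ltri + st$p
  df <- st$p * (st$p + 1) / 2 - n_free
  if (df < 0) stop("model is underidentified (negative degrees of freedom)")
  opt <- cfa_minimize(st, S)
  lam_free <- opt$par[opt$i_lam]
  Lch <- ltri_matrix(st, opt$par[opt$i_L])
  psi <- opt$par[opt$i_psi]
  Lam <- cfa_lambda(st, lam_free)
  Phi <- tcrossprod(Lch)
  Sigma <- Lam %*% Phi %*% t(Lam); diag(Sigma) <- diag(Sigma) + psi
  heywood <- any(psi <= 0.001 + 1e-9)
  if (heywood)
    warning("Heywood case: residual variance(s) at the 0.001 bound")
  # standardized solution
  sd_items <- sqrt(diag(Sigma))
  sd_fac <- sqrt(diag(Phi))
  lambda_std <- (Lam %*% diag(sd_fac, st$nf))[cbind(seq_len(st$p), st$fidx)] /
    sd_items
  names(lambda_std) <- st$items
  phi_cor <- stats::cov2cor(Phi)
  dimnames(phi_cor) <- list(st$facs, st$facs)
  psi_std <- psi / sd_items^2
  names(psi_std) <- st$items
  chi2 <- (n - 1) * opt$objective
  # independence baseline (free variances and means)
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  chi2_b <- (n - 1) * (sum(log(diag(S))) - logdetS)
  df_b <- st$p * (st$p - 1) / 2
  idx <- fit_indices(chi2, df, chi2_b, df_b, n)
  # SRMR: standardized residuals, lower triangle including the diagonal
  Dinv <- 1 / sqrt(diag(S))
  res <- (S - Sigma) * tcrossprod(Dinv)
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  cr <- vapply(st$facs, function(f) {
    l <- abs(lambda_std[fmap == f])
    sum(l)^2 / (sum(l)^2 + sum(1 - l^2))
  }, numeric(1))
  ave <- vapply(st$facs, function(f) mean(lambda_std[fmap == f]^2), numeric(1))
  structure(list(chi2 = chi2, df = df, chi2_baseline = chi2_b,
                 df_baseline = df_b, n = n,
                 cfi = idx$cfi, tli = idx$tli, rmsea = idx$rmsea,
                 rmsea_ci = idx$rmsea_ci, srmr = srmr,
                 lambda_std = lambda_std, phi_cor = phi_cor,
                 psi_std = psi_std, cr = cr, ave = ave,
                 factor_map = fmap, heywood = heywood,
                 convergence = list(converged = opt$converged,
                                    iterations = opt$iterations,
                                    gradient_norm = opt$gradient_norm)),
            class = "cfa_fit")
}

#' Fit the design's confirmatory factor model
#'
#' Fits the simple-structure model implied by the design's factor map to a
#' reverse-recoded sample by plain maximum likelihood (marker-variable
#' identification) and reports the chi-square, fit indices with the RMSEA
#' 90% interval, SRMR, the standardized solution, and composite reliability
#' (CR) and average variance extracted (AVE) per factor.
#'
#' @param m a recoded [response_matrix()] (or plain numeric matrix whose
#'   columns are the scored items).
#' @param design a [survey_design()].
#' @return An object of class `cfa_fit`.
#' @export
fit_cfa <- function(m, design) {
  items <- if (inherits(m, "response_matrix"))
    m$values[, scored_items(design), drop = FALSE]
  else as.matrix(m)[, scored_items(design), drop = FALSE]
  fit_cfa_matrix(items, design$factor_map[colnames(items)])
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat("<cfa_fit> chi2(", x$df, ") = ", round(x$chi2, 2),
      ", n = ", x$n, "\n", sep = "")
  cat(sprintf("  CFI %.3f | TLI %.3f | RMSEA %.3f [%.3f, %.3f] | SRMR %.3f\n",
              x$cfi, x$tli, x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2], x$srmr))
  cat("  converged:", x$convergence$converged,
      "| mean |loading|:", round(mean(abs(x$lambda_std)), 3), "\n")
  invisible(x)
}

#' Goodness-of-fit indices from chi-square statistics
#'
#' CFI, TLI and RMSEA (point estimate and 90% interval from inverting the
#' noncentral chi-square distribution) for a fitted model against the
#' independence baseline. The RMSEA denominator is `df * (n - 1)`;
#' multigroup callers pass an effective `n` so that `n - 1` equals the total
#' N minus the number of groups.
#'
#' @param chi2_m,df_m model chi-square and degrees of freedom (`df_m > 0`).
#' @param chi2_b,df_b baseline chi-square and degrees of freedom.
#' @param n sample size.
#' @param ci_level confidence level of the RMSEA interval (default 0.90).
#' @return List with `cfi`, `tli`, `rmsea`, `rmsea_ci`.
#' @export
fit_indices <- function(chi2_m, df_m, chi2_b, df_b, n, ci_level = 0.90) {
  if (df_m <= 0) stop("df_m must be positive")
  if (df_b <= df_m) stop("baseline df must exceed model df")
  num <- max(chi2_m - df_m, 0)
  den <- max(chi2_b - df_b, chi2_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  tli <- ((chi2_b / df_b) - (chi2_m / df_m)) / ((chi2_b / df_b) - 1)
  tli <- min(max(tli, 0), 1)
  rmsea <- sqrt(num / (df_m * (n - 1)))
  a <- (1 - ci_level) / 2
  ncp_for <- function(target) {
    # ncp such that pchisq(chi2_m, df_m, ncp) == target
    if (stats::pchisq(chi2_m, df_m) < target) return(0)
    stats::uniroot(function(l) stats::pchisq(chi2_m, df_m, ncp = l) - target,
                   lower = 0, upper = max(chi2_m * 2, 100),
                   extendInt = "downX", tol = 1e-8)$root
  }
  lo <- ncp_for(1 - a)
  hi <- ncp_for(a)
  ci <- sqrt(c(lo, hi) / (df_m * (n - 1)))
  list(cfi = cfi, tli = tli, rmsea = rmsea, rmsea_ci = ci)
}
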