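#' Run the full screening-impact pipeline
#'
#' Orchestrates the comparative analysis: obtain data (simulate from a
#' [sim_config()] or read a response CSV), apply the |z| > 4 univariate
#' outlier pre-screen on total scores, flag careless respondents under the
#' chosen definition, partition into unscreened/screened/careless, run the
#' psychometric battery (reliability, CFA) in parallel on the unscreened
#' and screened samples, test configural/metric/scalar invariance across
#' the attentive-vs-careless pair, and quantify impact (nested permutation
#' tests of score means, CSI/CSI-z item ranking). Stage failures that the
#' design anticipates (careless group too small for invariance, zero
#' prevalence) are recorded as structured warnings in `$warnings`, not
#' errors.
#'
#' @param config list with either `sim` (a [sim_config()]) or `responses` +
#'   `design` (file paths); optional `definition` ("primary" or
#'   "extended", default primary), `permutations` (default 10000),
#'   `perm_seed` (default 2025), `outlier_z` (default 4), `invariance_min_n`
#'   (default 100).
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config) {
  def <- config$definition %||% "primary"
  if (!def %in% c("primary", "extended"))
    stop("definition must be 'primary' or 'extended'")
  B <- config$permutations %||% 10000
  perm_seed <- config$perm_seed %||% 2025
  z_cut <- config$outlier_z %||% 4
  min_n <- config$invariance_min_n %||% 100
  warnings <- list()
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(config$sim)) {
    study <- assemble_study(config$sim)
    design <- study$design
    m <- study$responses
    seed <- config$sim$seed
    say("simulated %d respondents (seed %d)", nrow(m$values), seed)
  } else {
    design <- read_design(config$design)
    m <- read_responses(config$responses, design)
    seed <- config$perm_seed %||% 2025
    say("read %d respondents (%d rejected)", nrow(m$values),
        length(attr(m, "rejected")))
  }

  # outlier pre-screen on recoded totals
  totals_all <- scale_scores(recode_reverse(m, design), design)
  out_flag <- outlier_flag(totals_all, z_cut)
  if (any(out_flag)) m <- subset_respondents(m, !out_flag)
  say("outlier pre-screen: removed %d of %d (|z| > %g), retained %d",
      sum(out_flag), length(out_flag), z_cut, nrow(m$values))

  screen <- screen_sample(m, design)
  flags <- if (def == "primary") screen$flag_primary else screen$flag_extended
  samples <- split_samples(m, flags)
  say("definition '%s': flagged %d of %d (%.2f%%), screened n = %d",
      def, samples$counts[["careless"]], samples$counts[["unscreened"]],
      samples$prevalence_pct, samples$counts[["screened"]])

  recoded <- lapply(samples[c("unscreened", "screened", "careless")],
                    recode_reverse, design = design)

  reliability <- list(
    unscreened = reliability_report(recoded$unscreened, design),
    screened = reliability_report(recoded$screened, design))

  cfa <- list(unscreened = fit_cfa(recoded$unscreened, design),
              screened = fit_cfa(recoded$screened, design))

  invariance <- NULL
  if (samples$counts[["careless"]] < min_n) {
    warnings$invariance <- sprintf(
      "invariance skipped: careless group n = %d below minimum %d",
      samples$counts[["careless"]], min_n)
    say(warnings$invariance)
  } else {
    invariance <- invariance_sequence(recoded$screened, recoded$careless,
                                      design, min_n = min_n)
  }

  impact <- NULL
  if (samples$counts[["careless"]] == 0) {
    warnings$impact <- "impact stage skipped: no careless respondents"
    say(warnings$impact)
  } else {
    perms <- lapply(c("total", unique(design$factor_map)), function(lv) {
      sc <- scale_scores(recoded$unscreened, design, lv)
      r <- permutation_nested_mean_test(sc, flags, B = B, seed = perm_seed)
      data.frame(scale = lv, observed_delta = r$observed_delta,
                 p = r$p_two_sided, B = r$B, exhaustive = r$exhaustive)
    })
    stats_uns <- item_stats(recoded$unscreened, design, cfa$unscreened,
                            "unscreened")
    stats_scr <- item_stats(recoded$screened, design, cfa$screened,
                            "screened")
    csi <- csi_z(csi_compute(stats_uns, stats_scr))
    agree <- rank_agreement(csi$csi, csi$csi_z)
    topk <- top_k_report(csi, k = min(10, nrow(csi)), design = design)
    impact <- list(permutation = do.call(rbind, perms), csi = csi,
                   rank_agreement = agree, top10 = topk)
  }

  structure(list(
    design = design,
    screen = screen,
    counts = samples$counts,
    prevalence_pct = samples$prevalence_pct,
    reliability = reliability,
    cfa = cfa,
    invariance = invariance,
    impact = impact,
    warnings = warnings,
    log = log,
    provenance = list(definition = def, permutations = B,
                      perm_seed = perm_seed, seed = seed,
                      version = as.character(utils::packageVersion("carescreen")))),
    class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strip non-serializable structure from a cfa_fit for the JSON report.
cfa_json <- function(f) {
  list(chi2 = f$chi2, df = f$df, n = f$n, cfi = f$cfi, tli = f$tli,
       rmsea = f$rmsea, rmsea_ci = f$rmsea_ci, srmr = f$srmr,
       lambda_std = as.list(f$lambda_std),
       factor_corr = f$phi_cor, cr = as.list(f$cr), ave = as.list(f$ave),
       converged = f$convergence$converged)
}

#' Write a run report to disk
#'
#' Writes `report.json` (full precision), `csi_table.csv`, `flags.csv` and
#' a human-readable `summary.md` (3 decimal places). Serialization is
#' deterministic: identical reports produce byte-identical files.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    counts = as.list(report$counts),
    prevalence_pct = report$prevalence_pct,
    reliability = lapply(report$reliability, function(x)
      as.list(as.data.frame(x))),
    cfa = lapply(report$cfa, cfa_json),
    invariance = if (!is.null(report$invariance))
      as.list(as.data.frame(report$invariance)),
    impact = if (!is.null(report$impact)) list(
      permutation = as.list(report$impact$permutation),
      rank_agreement = report$impact$rank_agreement,
      n_reverse_top10 = report$impact$top10$n_reverse_top),
    warnings = report$warnings,
    provenance = report$provenance)
  f_json <- file.path(dir, "report.json")
  jsonlite::write_json(json, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  f_csi <- file.path(dir, "csi_table.csv")
  if (!is.null(report$impact))
    utils::write.csv(report$impact$csi, f_csi, row.names = FALSE,
                     quote = FALSE)
  f_flags <- file.path(dir, "flags.csv")
  utils::write.csv(report$screen, f_flags, row.names = FALSE, quote = FALSE)
  f_md <- file.path(dir, "summary.md")
  md <- c("# Screening impact summary", "",
          sprintf("- unscreened n = %d, screened n = %d, careless n = %d (%.3f%%)",
                  report$counts[["unscreened"]], report$counts[["screened"]],
                  report$counts[["careless"]], report$prevalence_pct),
          "", "## Reliability (alpha, unscreened vs screened)", "")
  ru <- report$reliability$unscreened; rs <- report$reliability$screened
  md <- c(md, sprintf("- %s: %.3f vs %.3f (delta %+.3f)", ru$scale,
                      ru$alpha, rs$alpha, rs$alpha - ru$alpha))
  cu <- report$cfa$unscreened; cs <- report$cfa$screened
  md <- c(md, "", "## CFA fit", "",
          sprintf("- unscreened: chi2(%d) = %.3f, CFI %.3f, RMSEA %.3f, SRMR %.3f",
                  cu$df, cu$chi2, cu$cfi, cu$rmsea, cu$srmr),
          sprintf("- screened:   chi2(%d) = %.3f, CFI %.3f, RMSEA %.3f, SRMR %.3f",
                  cs$df, cs$chi2, cs$cfi, cs$rmsea, cs$srmr))
  if (!is.null(report$invariance)) {
    iv <- report$invariance
    md <- c(md, "", "## Invariance (attentive vs careless)", "",
            sprintf("- %s: chi2(%d) = %.3f, CFI %.3f, RMSEA %.3f%s",
                    iv$level, iv$df, iv$chi2, iv$cfi, iv$rmsea,
                    ifelse(is.na(iv$supported), "",
                           paste0(", supported: ", iv$supported))))
  }
  if (!is.null(report$impact)) {
    md <- c(md, "", "## Top-10 CSI items", "",
            sprintf("- %s (%s, %s): CSI %.3f",
                    report$impact$top10$top$item,
                    report$impact$top10$top$factor,
                    report$impact$top10$top$type,
                    report$impact$top10$top$csi),
            "",
            sprintf("Reverse-coded items in top 10: %d",
                    report$impact$top10$n_reverse_top))
  }
  if (length(report$warnings))
    md <- c(md, "", "## Warnings", "",
            paste0("- ", unlist(report$warnings)))
  writeLines(md, f_md)
  invisible(c(f_json, f_csi, f_flags, f_md))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
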