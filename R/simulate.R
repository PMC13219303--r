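#' Simulation configuration
#'
#' Parameterizes the synthetic-survey generator: a correlated-factor graded
#' Likert model for attentive respondents plus a mixture of careless
#' archetypes. Attentive responding draws factor scores from a zero-mean
#' multivariate normal, forms latent item responses
#' `y = lambda * theta + eps` with residual variance `1 - lambda^2`, and
#' discretizes them through fixed thresholds. Reverse-coded items are
#' generated with a sign-flipped loading on the presentation metric, so that
#' analytic recoding aligns them with their factor.
#'
#' @param design a [survey_design()].
#' @param n_respondents number of rows to simulate.
#' @param prevalence fraction of careless respondents in `[0, 1)`.
#' @param archetype_mix named probabilities over careless archetypes
#'   (`acquiescent`, `random_uniform`, `midpoint_straightliner`,
#'   `fixed_straightliner`, `late_onset`); must sum to 1.
#' @param loadings named vector of true standardized loadings per scored
#'   item (positive; the presentation-metric sign flip for reverse items is
#'   applied internally).
#' @param factor_corr factor correlation matrix (unit diagonal, symmetric
#'   positive-definite), dimnames = factor labels.
#' @param thresholds strictly increasing latent cut points on the
#'   construct-aligned metric; length must be `#categories - 1`. The default
#'   is agreement-skewed (cumulative category probabilities 0.05, 0.15,
#'   0.40, 0.75), emulating the agree-leaning response distributions of
#'   attitude scales; reverse-coded items apply the same thresholds on the
#'   aligned metric and are then reflected onto the presentation scale, so
#'   the skew follows item content.
#' @param acquiescent_probs probabilities of the top two categories for the
#'   acquiescent archetype.
#' @param onset_item presentation position at which late-onset carelessness
#'   begins.
#' @param late_onset_archetype archetype governing the post-onset segment.
#' @param criterion_block optional list of criterion-scale blocks, each a
#'   list with `name`, `n_items`, `scale_min`, `scale_max`, `loading`
#'   (per-item standardized loading on the block's own latent) and
#'   `latent_corr` (correlation between the block latent and the
#'   equally-weighted composite of the focal factors — the quantity
#'   criterion validity is about; the implied per-factor correlation is
#'   derived internally).
#' @param seed integer master seed; per-respondent substreams are derived
#'   from it so that changing the row count does not perturb other rows.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(design,
                       n_respondents = 1112L,
                       prevalence = 0.1133,
                       archetype_mix = c(acquiescent = 0.70,
                                         random_uniform = 0.15,
                                         fixed_straightliner = 0.10,
                                         late_onset = 0.05),
                       loadings = NULL,
                       factor_corr = NULL,
                       thresholds = stats::qnorm(c(0.05, 0.15, 0.40, 0.75)),
                       acquiescent_probs = c(0.52, 0.48),
                       onset_item = NULL,
                       late_onset_archetype = "acquiescent",
                       criterion_block = NULL,
                       seed = 2025L) {
  facs <- unique(design$factor_map)
  if (is.null(loadings)) {
    sc <- scored_items(design)
    loadings <- stats::setNames(rep(0.6, length(sc)), sc)
  }
  if (is.null(factor_corr)) {
    factor_corr <- matrix(0.5, length(facs), length(facs),
                          dimnames = list(facs, facs))
    diag(factor_corr) <- 1
  }
  if (is.null(onset_item))
    onset_item <- ceiling(length(design$item_ids) / 2)
  miss <- setdiff(scored_items(design), names(loadings))
  if (length(miss))
    stop("loadings missing for item(s): ", paste(miss, collapse = ", "))
  if (any(loadings <= 0) || any(loadings >= 1))
    stop("loadings must lie in (0, 1)")
  if (!isTRUE(all.equal(unname(diag(factor_corr)), rep(1, length(facs)))) ||
      !isSymmetric(unname(factor_corr)))
    stop("factor_corr must be symmetric with unit diagonal")
  ev <- eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("factor_corr is not positive-definite")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  n_cat <- design$scale_max - design$scale_min + 1L
  if (length(thresholds) != n_cat - 1L)
    stop("need ", n_cat - 1L, " thresholds for ", n_cat, " categories")
  if (abs(sum(archetype_mix) - 1) > 1e-9)
    stop("archetype_mix must sum to 1")
  known <- c("acquiescent", "random_uniform", "midpoint_straightliner",
             "fixed_straightliner", "late_onset")
  bad <- setdiff(names(archetype_mix), known)
  if (length(bad)) stop("unknown archetype(s): ", paste(bad, collapse = ", "))
  if (prevalence < 0 || prevalence >= 1) stop("prevalence must be in [0, 1)")
  structure(list(design = design, n_respondents = as.integer(n_respondents),
                 prevalence = prevalence, archetype_mix = archetype_mix,
                 loadings = loadings[scored_items(design)],
                 factor_corr = factor_corr, thresholds = thresholds,
                 acquiescent_probs = acquiescent_probs,
                 onset_item = as.integer(onset_item),
                 late_onset_archetype = late_onset_archetype,
                 criterion_block = criterion_block,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default configuration emulating the three-factor awareness instrument
#'
#' 37 presentation items (13/9/14 per factor plus the instructed item at
#' position 26), six reverse-coded items, five categories with agree-skewed
#' normal-quantile thresholds at cumulative (0.05, 0.15, 0.40, 0.75), factor
#' correlations 0.5, and fixed true loadings: standard items evenly spaced
#' over 0.52–0.72 and reverse items at 0.30, giving a grand mean loading of
#' about 0.57. The careless mixture defaults to an agree-skewed blend (70%
#' acquiescent, 15% uniform-random, 10% fixed straightliner, 5% late onset)
#' at 11.33% prevalence.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
default_sdas_config <- function(...) {
  design <- sdas_design()
  sc <- scored_items(design)
  std <- setdiff(sc, design$reverse_items)
  loadings <- stats::setNames(numeric(length(sc)), sc)
  loadings[std] <- seq(0.52, 0.72, length.out = length(std))
  loadings[design$reverse_items] <- 0.30
  sim_config(design, loadings = loadings, ...)
}

#' Standard criterion battery for the default configuration
#'
#' Two criterion blocks mirroring a typical follow-on battery: a 19-item
#' 0..10 scale and a 9-item 1..7 scale, each loading 0.65 on its own latent
#' that correlates 0.40 with every focal factor.
#'
#' @return A list usable as `criterion_block` in [sim_config()].
#' @export
default_criterion_blocks <- function() {
  list(
    list(name = "PSRS", n_items = 19L, scale_min = 0L, scale_max = 10L,
         loading = 0.65, latent_corr = 0.40),
    list(name = "OVC", n_items = 9L, scale_min = 1L, scale_max = 7L,
         loading = 0.65, latent_corr = 0.40))
}

# Deterministic per-respondent substream seed below 2^31.
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 104729) %%
               2147483647)
}

# Joint latent correlation matrix: focal factors then one latent per
# criterion block. `latent_corr` is the block latent's correlation with the
# equally-weighted focal composite; with equal per-factor correlations c,
# corr(block, sum theta) = c * nf / sqrt(sum(factor_corr)), so
# c = latent_corr * sqrt(sum(factor_corr)) / nf. Between-block correlations
# use the smaller of the two values; the full matrix is checked for
# positive-definiteness.
latent_corr_matrix <- function(cfg) {
  fc <- cfg$factor_corr
  blocks <- cfg$criterion_block
  if (is.null(blocks)) return(fc)
  nb <- length(blocks)
  nf <- nrow(fc)
  full <- diag(nf + nb)
  full[1:nf, 1:nf] <- fc
  for (b in seq_len(nb)) {
    cc <- blocks[[b]]$latent_corr * sqrt(sum(fc)) / nf
    full[nf + b, 1:nf] <- full[1:nf, nf + b] <- cc
  }
  if (nb > 1) {
    for (b1 in 1:(nb - 1)) for (b2 in (b1 + 1):nb) {
      r <- min(blocks[[b1]]$latent_corr, blocks[[b2]]$latent_corr)
      full[nf + b1, nf + b2] <- full[nf + b2, nf + b1] <- r
    }
  }
  ev <- eigen(full, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("joint latent correlation matrix is not positive-definite")
  rn <- c(rownames(fc), vapply(blocks, `[[`, "", "name"))
  dimnames(full) <- list(rn, rn)
  full
}

# Equally spaced cumulative-probability thresholds for a K-category block.
block_thresholds <- function(n_cat) stats::qnorm(seq_len(n_cat - 1) / n_cat)

# Column ids for a criterion block.
block_item_ids <- function(block)
  sprintf("%s_%02d", block$name, seq_len(block$n_items))

# One attentive row over the full battery, given pre-drawn latent scores.
# Draw order is fixed: focal items in presentation order, then blocks.
attentive_row <- function(cfg, theta) {
  design <- cfg$design
  facs <- unique(design$factor_map)
  out <- integer(0)
  for (id in design$item_ids) {
    if (!is.null(design$instructed_item) && id == design$instructed_item) {
      out[id] <- design$required_category
      next
    }
    lam <- cfg$loadings[[id]]
    y <- lam * theta[[design$factor_map[[id]]]] +
      sqrt(1 - lam^2) * stats::rnorm(1)
    v <- design$scale_min + sum(y > cfg$thresholds)
    # reverse items: same aligned process, reflected onto the presentation
    # scale (sign-flipped presentation loading, content-following skew)
    out[id] <- if (id %in% design$reverse_items)
      design$scale_min + design$scale_max - v else v
  }
  for (block in cfg$criterion_block) {
    thr <- block_thresholds(block$scale_max - block$scale_min + 1L)
    lam <- block$loading
    for (id in block_item_ids(block)) {
      y <- lam * theta[[block$name]] + sqrt(1 - lam^2) * stats::rnorm(1)
      out[id] <- block$scale_min + sum(y > thr)
    }
  }
  out
}

# One careless row over the full battery under the given archetype. The
# archetype process also answers the instructed item (content-blind
# responding governs the check too). For fixed_straightliner the category is
# drawn once on the focal scale and mapped proportionally onto each
# criterion block's scale.
careless_row <- function(cfg, archetype, theta = NULL) {
  design <- cfg$design
  n_cat <- design$scale_max - design$scale_min + 1L
  blocks <- cfg$criterion_block
  seg <- function(ids, smin, smax, kind, fixed_rel = NULL) {
    k <- length(ids)
    ncat <- smax - smin + 1L
    v <- switch(kind,
      acquiescent = sample(c(smax - 1L, smax), k, replace = TRUE,
                           prob = cfg$acquiescent_probs),
      random_uniform = sample(smin:smax, k, replace = TRUE),
      midpoint_straightliner = rep(as.integer(round((smin + smax) / 2)), k),
      fixed_straightliner = rep(as.integer(round(smin + fixed_rel *
                                                   (ncat - 1L))), k),
      stop("unknown archetype '", kind, "'"))
    stats::setNames(as.integer(v), ids)
  }
  if (archetype == "late_onset") {
    if (is.null(theta)) stop("late_onset needs latent scores")
    att <- attentive_row(cfg, theta)
    post <- careless_row(cfg, cfg$late_onset_archetype)
    ids <- names(att)
    onset <- cfg$onset_item
    out <- att
    if (onset <= length(ids)) out[onset:length(ids)] <- post[onset:length(ids)]
    return(out)
  }
  fixed_rel <- if (archetype == "fixed_straightliner")
    (sample(n_cat, 1) - 1) / (n_cat - 1) else NULL
  out <- seg(design$item_ids, design$scale_min, design$scale_max,
             archetype, fixed_rel)
  for (block in blocks)
    out <- c(out, seg(block_item_ids(block), block$scale_min,
                      block$scale_max, archetype, fixed_rel))
  out
}

#' Simulate attentive respondents
#'
#' @param cfg a [sim_config()].
#' @param n number of rows.
#' @param first_counter substream counter of the first row (rows `i` use
#'   substream `first_counter + i - 1`).
#' @return A [response_matrix()] with truth label `"attentive"` on all rows.
#' @export
simulate_attentive <- function(cfg, n, first_counter = 1L) {
  rows <- simulate_rows(cfg, rep("attentive", n), first_counter)
  response_matrix(rows, sprintf("R%05d", seq_len(n) + first_counter - 1L),
                  cfg$design, truth_labels = rep("attentive", n))
}

#' Simulate careless respondents of one archetype
#'
#' @param cfg a [sim_config()].
#' @param archetype one of `acquiescent`, `random_uniform`,
#'   `midpoint_straightliner`, `fixed_straightliner`, `late_onset`.
#' @param n number of rows.
#' @param first_counter substream counter of the first row.
#' @return A [response_matrix()] with the archetype as truth label.
#' @export
simulate_careless <- function(cfg, archetype, n, first_counter = 1L) {
  known <- c("acquiescent", "random_uniform", "midpoint_straightliner",
             "fixed_straightliner", "late_onset")
  if (!archetype %in% known) stop("unknown archetype '", archetype, "'")
  rows <- simulate_rows(cfg, rep(archetype, n), first_counter)
  response_matrix(rows, sprintf("R%05d", seq_len(n) + first_counter - 1L),
                  cfg$design, truth_labels = rep(archetype, n))
}

# Generate rows for the given per-row labels under counter-based substreams.
simulate_rows <- function(cfg, labels, first_counter = 1L) {
  corr <- latent_corr_matrix(cfg)
  ch <- chol(corr)
  n <- length(labels)
  need_theta <- labels %in% c("attentive", "late_onset")
  out <- NULL
  for (i in seq_len(n)) {
    set.seed(substream_seed(cfg$seed, first_counter + i - 1L))
    theta <- NULL
    if (need_theta[i]) {
      z <- stats::rnorm(nrow(corr))
      theta <- stats::setNames(as.numeric(crossprod(ch, z)), rownames(corr))
    }
    row <- if (labels[i] == "attentive") attentive_row(cfg, theta)
           else careless_row(cfg, labels[i], theta)
    if (is.null(out))
      out <- matrix(0L, n, length(row), dimnames = list(NULL, names(row)))
    out[i, ] <- row
  }
  out
}

#' Assemble a full simulated study
#'
#' Rounds `prevalence * n` to the careless count, samples archetype labels
#' from the mixture, scatters careless rows uniformly over row positions,
#' generates every row under its per-respondent substream and attaches truth
#' labels and the true generating parameters.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `simulated_study`: a list with `responses`
#'   (a [response_matrix()]), `design`, `params` (true loadings, factor
#'   correlations, thresholds) and `seed`.
#' @export
assemble_study <- function(cfg) {
  n <- cfg$n_respondents
  n_careless <- as.integer(round(cfg$prevalence * n))
  set.seed(substream_seed(cfg$seed, 0L))
  labels <- rep("attentive", n)
  if (n_careless > 0) {
    idx <- sample(n, n_careless)
    labels[idx] <- sample(names(cfg$archetype_mix), n_careless,
                          replace = TRUE, prob = cfg$archetype_mix)
  }
  rows <- simulate_rows(cfg, labels, first_counter = 1L)
  m <- response_matrix(rows, sprintf("R%05d", seq_len(n)), cfg$design,
                       truth_labels = labels)
  structure(list(responses = m, design = cfg$design,
                 params = list(loadings = cfg$loadings,
                               factor_corr = cfg$factor_corr,
                               thresholds = cfg$thresholds),
                 config = cfg, seed = cfg$seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  tab <- table(x$responses$truth_labels)
  cat("<simulated_study> n =", nrow(x$responses$values),
      "| careless:", sum(x$responses$truth_labels != "attentive"),
      sprintf("(%.2f%%)\n",
              100 * mean(x$responses$truth_labels != "attentive")))
  print(tab)
  invisible(x)
}
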