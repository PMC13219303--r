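# Shared fixtures and independent oracles for the test suite.

# A minimal legal blueprint: one factor, two items, no reverse items,
# no instructed item.
minimal_design <- function() {
  survey_design(item_ids = c("A1", "A2"),
                factor_map = c(A1 = "g", A2 = "g"),
                scale_min = 1, scale_max = 5)
}

# Small multi-factor design: 3 factors x k items, optional reverse item and
# instructed item appended at the end.
toy_design <- function(k = 3, reverse = character(), instructed = FALSE) {
  ids <- paste0("T", sprintf("%02d", seq_len(3 * k)))
  fmap <- stats::setNames(rep(c("f1", "f2", "f3"), each = k), ids)
  instructed_id <- NULL
  req <- NULL
  if (instructed) {
    instructed_id <- "T_CHK"
    req <- 3
    ids <- c(ids, instructed_id)
  }
  survey_design(item_ids = ids, factor_map = fmap, reverse_items = reverse,
                instructed_item = instructed_id, required_category = req,
                scale_min = 1, scale_max = 5)
}

# One-factor design with k items on a 1..5 scale.
one_factor_design <- function(k = 6) {
  ids <- sprintf("Q%02d", seq_len(k))
  survey_design(item_ids = ids, factor_map = stats::setNames(rep("g", k), ids),
                scale_min = 1, scale_max = 5)
}

# Brute-force longstring oracle: scan every run by hand.
longstring_oracle <- function(x) {
  best <- 1L
  run <- 1L
  for (i in seq_along(x)[-1]) {
    run <- if (x[i] == x[i - 1]) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

# Straight-line reimplementation of the even-odd inconsistency score for
# one respondent, independent of the vectorized package version.
evenodd_oracle_row <- function(values, design) {
  facs <- unique(design$factor_map)
  o <- e <- numeric(0)
  for (f in facs) {
    ids <- names(design$factor_map)[design$factor_map == f]
    odd <- ids[seq_along(ids) %% 2 == 1]
    even <- ids[seq_along(ids) %% 2 == 0]
    o <- c(o, mean(values[odd]))
    e <- c(e, mean(values[even]))
  }
  if (stats::sd(o) == 0 || stats::sd(e) == 0) return(2)
  r <- max(stats::cor(o, e), -0.999)
  1 - min(max(2 * r / (1 + r), -1), 1)
}

# Continuous data drawn exactly from a simple-structure factor model
# (used for CFA arithmetic checks without categorical attenuation).
continuous_factor_data <- function(n, lambda, fmap, phi, seed = 1) {
  set.seed(seed)
  facs <- unique(fmap)
  theta <- matrix(stats::rnorm(n * length(facs)), n) %*% chol(phi)
  colnames(theta) <- facs
  x <- sapply(seq_along(lambda), function(j)
    lambda[j] * theta[, fmap[j]] +
      sqrt(1 - lambda[j]^2) * stats::rnorm(n))
  colnames(x) <- names(fmap)
  x
}

# Fabricate an item_stats table from given components (used to feed printed
# component triples through csi_compute).
fake_item_stats <- function(items, means, r_its, lambdas,
                            types = rep("standard", length(items)),
                            factors = rep("f", length(items))) {
  out <- data.frame(item = items, factor = factors, type = types,
                    position = seq_along(items), mean = means,
                    r_it = r_its, lambda = lambdas)
  class(out) <- c("item_stats", "data.frame")
  out
}

# Published component triples for the ten most careless-sensitive items
# (|dM|, |dr|, |dlambda|, and the printed composite).
published_csi_rows <- function() {
  data.frame(
    item = c("SDAS_27", "SDAS_03", "SDAS_04", "SDAS_25", "SDAS_R_35",
             "SDAS_R_31", "SDAS_R_08", "SDAS_R_24", "SDAS_R_01", "SDAS_R_10"),
    type = c(rep("standard", 4), rep("reverse", 6)),
    dM = c(0.053, 0.052, 0.047, 0.071, 0.150, 0.146, 0.110, 0.131, 0.087, 0.083),
    dr = c(0.371, 0.259, 0.253, 0.150, 0.049, 0.023, 0.035, 0.008, 0.022, 0.019),
    dlam = c(0.379, 0.294, 0.304, 0.152, 0.084, 0.055, 0.058, 0.030, 0.049, 0.053),
    csi = c(0.803, 0.605, 0.604, 0.373, 0.283, 0.224, 0.203, 0.169, 0.158, 0.155))
}
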