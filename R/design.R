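#' Survey design blueprint
#'
#' A `survey_design` records everything the pipeline needs to know about a
#' Likert instrument before any data are seen: item identifiers in
#' presentation order, the factor each scored item measures, which items are
#' reverse-coded, the embedded instructed-response (attention-check) item and
#' the category it requires, and the response-scale bounds.
#'
#' The instructed item belongs to no factor and is excluded from every
#' psychometric computation; it is kept in the design (and in response
#' matrices) only so the attention check can be scored.
#'
#' @param item_ids character vector of item identifiers in presentation order.
#' @param factor_map named character vector mapping each scored item id to a
#'   factor label. The instructed item must not appear in it.
#' @param reverse_items character vector of reverse-coded item ids (may be
#'   empty).
#' @param instructed_item item id of the instructed-response item, or `NULL`
#'   if the instrument has none.
#' @param required_category integer category the instructed item demands.
#' @param scale_min,scale_max integer response-scale bounds (e.g. 1 and 5).
#'
#' @return An object of class `survey_design`.
#' @seealso [read_design()], [sdas_design()]
#' @export
survey_design <- function(item_ids, factor_map, reverse_items = character(),
                          instructed_item = NULL, required_category = NULL,
                          scale_min = 1L, scale_max = 5L) {
  item_ids <- as.character(item_ids)
  if (anyDuplicated(item_ids))
    stop("duplicate item ids: ",
         paste(unique(item_ids[duplicated(item_ids)]), collapse = ", "))
  if (!is.null(instructed_item)) {
    instructed_item <- as.character(instructed_item)
    if (!instructed_item %in% item_ids)
      stop("instructed_item '", instructed_item, "' is not among item_ids")
    if (instructed_item %in% names(factor_map))
      stop("instructed_item '", instructed_item,
           "' must not be assigned to a factor")
    if (instructed_item %in% reverse_items)
      stop("instructed_item '", instructed_item, "' cannot be reverse-coded")
    if (is.null(required_category))
      stop("required_category must be given when instructed_item is set")
    required_category <- as.integer(required_category)
  }
  scale_min <- as.integer(scale_min)
  scale_max <- as.integer(scale_max)
  if (scale_min >= scale_max)
    stop("scale_min (", scale_min, ") must be below scale_max (", scale_max, ")")
  if (!is.null(required_category) &&
      (required_category < scale_min || required_category > scale_max))
    stop("required_category ", required_category, " outside [",
         scale_min, ", ", scale_max, "]")
  scored <- setdiff(item_ids, instructed_item)
  missing_map <- setdiff(scored, names(factor_map))
  if (length(missing_map))
    stop("items without a factor assignment: ",
         paste(missing_map, collapse = ", "))
  stray <- setdiff(names(factor_map), scored)
  if (length(stray))
    stop("factor_map entries for unknown items: ", paste(stray, collapse = ", "))
  bad_rev <- setdiff(reverse_items, scored)
  if (length(bad_rev))
    stop("reverse_items not among scored items: ",
         paste(bad_rev, collapse = ", "))
  factor_map <- factor_map[scored]          # presentation order
  structure(
    list(item_ids = item_ids,
         factor_map = factor_map,
         reverse_items = as.character(reverse_items),
         instructed_item = instructed_item,
         required_category = required_category,
         scale_min = scale_min,
         scale_max = scale_max),
    class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("<survey_design> ", length(x$item_ids), " items (",
      length(scored_items(x)), " scored), ",
      length(unique(x$factor_map)), " factor(s), ",
      length(x$reverse_items), " reverse-coded\n", sep = "")
  for (f in unique(x$factor_map))
    cat("  ", f, ": ", sum(x$factor_map == f), " items\n", sep = "")
  if (!is.null(x$instructed_item))
    cat("  instructed item: ", x$instructed_item, " (requires ",
        x$required_category, ")\n", sep = "")
  cat("  scale: ", x$scale_min, "..", x$scale_max, "\n", sep = "")
  invisible(x)
}

#' Scored items of a design
#'
#' Item ids in presentation order with the instructed item removed.
#'
#' @param design a [survey_design()].
#' @return character vector of scored item ids.
#' @export
scored_items <- function(design) {
  setdiff(design$item_ids, design$instructed_item)
}

#' Items belonging to one factor
#'
#' @param design a [survey_design()].
#' @param factor factor label.
#' @return character vector of item ids, in presentation order.
#' @export
factor_items <- function(design, factor) {
  if (!factor %in% design$factor_map)
    stop("unknown factor label '", factor, "'")
  names(design$factor_map)[design$factor_map == factor]
}

#' Read a survey design key from YAML or JSON
#'
#' The key format has fields `items` (ordered ids), `factors` (factor label
#' to item-id list), `reverse_items`, optional `instructed_item`
#' (`id`, `required_category`) and `scale` (`min`, `max`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` key file.
#' @return A validated [survey_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design key not found: ", path)
  key <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  design_from_key(key)
}

# Build a survey_design from the parsed key list (shared by YAML/JSON).
design_from_key <- function(key) {
  for (field in c("items", "factors", "scale"))
    if (is.null(key[[field]])) stop("design key is missing field '", field, "'")
  fmap <- character()
  for (f in names(key$factors)) {
    ids <- as.character(unlist(key$factors[[f]]))
    fmap[ids] <- f
  }
  survey_design(
    item_ids = as.character(unlist(key$items)),
    factor_map = fmap,
    reverse_items = as.character(unlist(key$reverse_items)),
    instructed_item = key$instructed_item$id,
    required_category = key$instructed_item$required_category,
    scale_min = key$scale$min,
    scale_max = key$scale$max)
}

#' Write a survey design key
#'
#' @param design a [survey_design()].
#' @param path output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  key <- list(
    items = design$item_ids,
    factors = lapply(split(names(design$factor_map), design$factor_map),
                     as.list)[unique(design$factor_map)],
    reverse_items = design$reverse_items,
    scale = list(min = design$scale_min, max = design$scale_max))
  if (!is.null(design$instructed_item))
    key$instructed_item <- list(id = design$instructed_item,
                                required_category = design$required_category)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(key, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(key, path)
  }
  invisible(path)
}

#' The 37-item sustainable-development-awareness blueprint
#'
#' Built-in design for the instrument the pipeline emulates: 36 scored items
#' on three correlated factors — economy (13 items), society (9) and
#' environment (14) — on a 1..5 agreement scale, six reverse-coded items at
#' presentation positions 1, 8, 10, 24, 31 and 35, and an instructed-response
#' item at position 26 requiring the midpoint ("Neutral", category 3).
#'
#' Item ids follow the `SDAS_01` .. `SDAS_37` presentation numbering, with
#' reverse-coded items tagged `SDAS_R_*`; `SDAS_26` is the instructed item.
#'
#' @return A [survey_design()].
#' @export
sdas_design <- function() {
  pos <- 1:37
  rev_pos <- c(1, 8, 10, 24, 31, 35)
  ids <- sprintf("SDAS_%02d", pos)
  ids[rev_pos] <- sprintf("SDAS_R_%02d", rev_pos)
  instructed <- "SDAS_26"
  fmap <- character()
  fmap[ids[1:13]] <- "economy"
  fmap[ids[14:22]] <- "society"
  fmap[ids[setdiff(23:37, 26)]] <- "environment"
  survey_design(
    item_ids = ids,
    factor_map = fmap,
    reverse_items = ids[rev_pos],
    instructed_item = instructed,
    required_category = 3L,
    scale_min = 1L,
    scale_max = 5L)
}
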