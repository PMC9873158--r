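#' Aggregate prey categories to a coarser taxonomic level
#'
#' Counts of sibling family-level categories are summed into their
#' parent order; categories already at or above the requested level are
#' left as they are.  Per-fish total item counts are conserved exactly.
#'
#' @param ds a [diet_dataset()].
#' @param level target level; currently `"order"`.
#' @param taxonomy optional registry (as from [read_taxonomy()])
#'   overriding `ds$categories`.
#' @param other_label if non-`NULL`, categories without a parent at the
#'   requested level are pooled into this bin instead of erroring.
#' @return a [diet_dataset()] at the coarser level.
#' @export
aggregate_to_level <- function(ds, level = "order", taxonomy = NULL,
                               other_label = NULL) {
  stopifnot(inherits(ds, "diet_dataset"), identical(level, "order"))
  reg <- if (is.null(taxonomy)) ds$categories else
    .normalise_categories(taxonomy, colnames(ds$counts))
  target <- ifelse(reg$level == "family", reg$parent_order, reg$name)
  unmapped <- reg$level == "family" & is.na(reg$parent_order)
  if (any(unmapped)) {
    if (is.null(other_label)) {
      stop("mapping error: no order-level parent for ",
           paste(reg$name[unmapped], collapse = ", "),
           " and no 'other' bin configured", call. = FALSE)
    }
    target[unmapped] <- other_label
  }
  aggregate_categories(ds, stats::setNames(target, reg$name))
}

#' Pool prey categories by an explicit mapping
#'
#' General-purpose regrouping used both for order-level aggregation and
#' for report groupings such as "Diptera, Ephemeroptera, Trichoptera,
#' Oligochaeta, everything else pooled".
#'
#' @param ds a [diet_dataset()].
#' @param mapping named character vector: names are current categories,
#'   values the output bins.  Categories absent from `mapping` fall
#'   into `other_label` when given, otherwise raise a mapping error.
#' @param other_label pooled bin for unmapped categories.
#' @return a [diet_dataset()] with one column per distinct output bin,
#'   in order of first appearance.
#' @export
aggregate_categories <- function(ds, mapping, other_label = NULL) {
  stopifnot(inherits(ds, "diet_dataset"))
  cats <- colnames(ds$counts)
  target <- unname(mapping[cats])
  missing <- is.na(target)
  if (any(missing)) {
    if (is.null(other_label)) {
      stop("mapping error: unmapped categor",
           if (sum(missing) > 1) "ies: " else "y: ",
           paste(cats[missing], collapse = ", "), call. = FALSE)
    }
    target[missing] <- other_label
  }
  bins <- unique(target)
  counts <- vapply(bins, function(b)
    as.integer(rowSums(ds$counts[, target == b, drop = FALSE])),
    integer(nrow(ds$counts)))
  if (nrow(ds$counts) == 1L) counts <- matrix(counts, nrow = 1L,
                                              dimnames = list(NULL, bins))
  colnames(counts) <- bins
  # levels of pooled bins: an order keeps "order"; mixed bins become other
  lvl <- vapply(bins, function(b) {
    src <- ds$categories[target == b, , drop = FALSE]
    if (nrow(src) == 1L && src$level[1] != "family") src$level[1]
    else if (all(src$level == "family") &&
             length(unique(src$parent_order)) == 1L) "order"
    else if (nrow(src) == 1L && src$level[1] == "family") "order"
    else "other"
  }, character(1))
  categories <- data.frame(name = bins, level = unname(lvl),
                           parent_order = NA_character_,
                           stringsAsFactors = FALSE)
  diet_dataset(ds$fish[, c("fish_id", "species", "stream",
                           "total_length_mm")],
               counts, categories)
}
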