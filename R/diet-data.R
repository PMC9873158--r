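#' Construct a diet dataset
#'
#' A `diet_dataset` bundles per-fish prey counts with the fish metadata
#' (species, stream, total length) and a category registry.  It is the
#' common currency of the package: readers produce it, the simulator
#' produces it, and every statistic consumes it.
#'
#' Fish whose counts are all zero are retained but flagged as empty
#' stomachs; every summary statistic in the package excludes them (the
#' denominator of frequency of occurrence is the number of fish *with*
#' stomach contents).
#'
#' @param fish data.frame with columns `fish_id` (unique, non-empty
#'   strings), `species`, `stream`, and optionally `total_length_mm`
#'   (positive or `NA`).
#' @param counts integer matrix, one row per fish (same order as
#'   `fish`), one column per prey category; non-negative integers.
#'   Column names are the category labels.
#' @param categories optional data.frame with columns `name`, `level`
#'   (one of `"family"`, `"order"`, `"class"`, `"other"`) and
#'   `parent_order` (the order a family belongs to; `NA` otherwise).
#'   Defaults to level `"other"` for every count column.
#' @return An object of class `diet_dataset` with elements `fish`
#'   (metadata plus `total_items` and `empty` flag), `counts` (integer
#'   matrix) and `categories`.
#' @export
diet_dataset <- function(fish, counts, categories = NULL) {
  fish <- as.data.frame(fish, stringsAsFactors = FALSE)
  for (col in c("fish_id", "species", "stream")) {
    if (!col %in% names(fish)) {
      stop("fish table is missing mandatory column '", col, "'", call. = FALSE)
    }
    fish[[col]] <- as.character(fish[[col]])
  }
  if (!"total_length_mm" %in% names(fish)) fish$total_length_mm <- NA_real_
  fish$total_length_mm <- as.numeric(fish$total_length_mm)
  if (any(!is.na(fish$total_length_mm) & fish$total_length_mm <= 0)) {
    stop("total_length_mm must be positive where present", call. = FALSE)
  }
  if (anyDuplicated(fish$fish_id)) {
    stop("duplicated fish_id: ",
         paste(unique(fish$fish_id[duplicated(fish$fish_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(fish$fish_id))) stop("empty fish_id", call. = FALSE)

  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(fish)) {
    stop("counts has ", nrow(counts), " rows but fish table has ",
         nrow(fish), call. = FALSE)
  }
  if (is.null(colnames(counts)) || any(!nzchar(colnames(counts)))) {
    stop("count columns must be named by prey category", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated prey category: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  .check_counts(counts, fish$fish_id)
  storage.mode(counts) <- "integer"
  rownames(counts) <- fish$fish_id

  categories <- .normalise_categories(categories, colnames(counts))

  fish$total_items <- as.integer(rowSums(counts))
  fish$empty <- fish$total_items == 0L
  rownames(fish) <- NULL

  structure(list(fish = fish, counts = counts, categories = categories),
            class = "diet_dataset")
}

.check_counts <- function(counts, ids) {
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("invalid count (negative, missing or non-integer) at fish '",
         ids[i], "', category '", colnames(counts)[j], "': ",
         counts[i, j], call. = FALSE)
  }
  invisible(TRUE)
}

.normalise_categories <- function(categories, names) {
  if (is.null(categories)) {
    return(data.frame(name = names, level = "other",
                      parent_order = NA_character_,
                      stringsAsFactors = FALSE))
  }
  categories <- as.data.frame(categories, stringsAsFactors = FALSE)
  if (!all(c("name", "level") %in% names(categories))) {
    stop("categories needs columns 'name' and 'level'", call. = FALSE)
  }
  if (!"parent_order" %in% names(categories)) {
    categories$parent_order <- NA_character_
  }
  ok <- categories$level %in% c("family", "order", "class", "other")
  if (any(!ok)) {
    stop("unknown category level: ",
         paste(unique(categories$level[!ok]), collapse = ", "), call. = FALSE)
  }
  fam_no_parent <- categories$level == "family" & is.na(categories$parent_order)
  if (any(fam_no_parent)) {
    stop("family-level categories need a parent_order: ",
         paste(categories$name[fam_no_parent], collapse = ", "),
         call. = FALSE)
  }
  # registry entries for count columns missing from the table default to other
  missing <- setdiff(names, categories$name)
  if (length(missing)) {
    categories <- rbind(categories,
                        data.frame(name = missing, level = "other",
                                   parent_order = NA_character_,
                                   stringsAsFactors = FALSE))
  }
  categories <- categories[match(names, categories$name), , drop = FALSE]
  rownames(categories) <- NULL
  categories
}

#' @export
print.diet_dataset <- function(x, ...) {
  g <- dataset_groups(x)
  cat("diet_dataset:", nrow(x$fish), "fish,", ncol(x$counts),
      "prey categories,", sum(x$fish$empty), "empty stomachs\n")
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %s / %s: n = %d\n", g$species[i], g$stream[i], g$n[i]))
  }
  invisible(x)
}

#' Groups present in a dataset
#'
#' @param ds a `diet_dataset`.
#' @return data.frame with columns `species`, `stream`, `n` (all fish)
#'   and `n_nonempty`.
#' @export
dataset_groups <- function(ds) {
  stopifnot(inherits(ds, "diet_dataset"))
  key <- interaction(ds$fish$species, ds$fish$stream, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sel <- key == k
    data.frame(species = ds$fish$species[sel][1],
               stream = ds$fish$stream[sel][1],
               n = sum(sel),
               n_nonempty = sum(sel & !ds$fish$empty),
               stringsAsFactors = FALSE)
  }))
  out[order(out$species, out$stream), , drop = FALSE]
}

#' Subset a dataset to one species-by-stream group
#'
#' @param ds a `diet_dataset`.
#' @param species,stream group labels.
#' @param nonempty_only drop empty-stomach fish (default `TRUE`).
#' @return a `diet_dataset` restricted to the group.
#' @export
subset_group <- function(ds, species, stream, nonempty_only = FALSE) {
  stopifnot(inherits(ds, "diet_dataset"))
  sel <- ds$fish$species == species & ds$fish$stream == stream
  if (nonempty_only) sel <- sel & !ds$fish$empty
  if (!any(sel)) {
    stop("no ", if (nonempty_only) "non-empty " else "", "fish in group ",
         species, "/", stream, call. = FALSE)
  }
  diet_dataset(ds$fish[sel, c("fish_id", "species", "stream",
                              "total_length_mm")],
               ds$counts[sel, , drop = FALSE], ds$categories)
}

# canonical label normalisation: trim, first letter upper-cased
normalise_label <- function(x) {
  x <- trimws(x)
  ifelse(nchar(x) > 0,
         paste0(toupper(substring(x, 1, 1)), substring(x, 2)), x)
}
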