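#' Read a wide per-fish diet count CSV
#'
#' The wide dialect has one row per fish, identifier/metadata columns
#' named by `schema`, and one integer count column per prey category.
#' Category labels are normalised (whitespace trimmed, first letter
#' upper-cased); species and stream labels other than the expected
#' `MW`/`RB` and `Smith`/`Sheep` are passed through unchanged with a
#' warning.
#'
#' @param path path to a UTF-8 CSV with a header row.
#' @param schema named list mapping roles to column names; roles
#'   `fish_id`, `species`, `stream` are mandatory, `length` optional
#'   (set to `NULL` if the file has no length column).
#' @param categories optional category registry passed through to
#'   [diet_dataset()].
#' @return a [diet_dataset()].
#' @export
read_diet_csv <- function(path,
                          schema = list(fish_id = "fish_id",
                                        species = "species",
                                        stream = "stream",
                                        length = "total_length_mm"),
                          categories = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (role in c("fish_id", "species", "stream")) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("schema error: column '", if (is.null(col)) role else col,
           "' (role ", role, ") not found in ", path, call. = FALSE)
    }
  }
  meta_cols <- unlist(schema[!vapply(schema, is.null, logical(1))])
  len_col <- schema$length
  has_len <- !is.null(len_col) && len_col %in% names(raw)

  fish <- data.frame(
    fish_id = as.character(raw[[schema$fish_id]]),
    species = as.character(raw[[schema$species]]),
    stream = as.character(raw[[schema$stream]]),
    total_length_mm = if (has_len) as.numeric(raw[[len_col]]) else NA_real_,
    stringsAsFactors = FALSE)

  unknown_sp <- setdiff(unique(fish$species), c("MW", "RB"))
  if (length(unknown_sp)) {
    warning("unrecognised species label(s) passed through: ",
            paste(unknown_sp, collapse = ", "), call. = FALSE)
  }
  unknown_st <- setdiff(unique(fish$stream), c("Smith", "Sheep"))
  if (length(unknown_st)) {
    warning("unrecognised stream label(s) passed through: ",
            paste(unknown_st, collapse = ", "), call. = FALSE)
  }

  count_cols <- setdiff(names(raw), meta_cols)
  if (length(count_cols) == 0) {
    stop("no prey count columns found in ", path, call. = FALSE)
  }
  counts <- as.matrix(raw[, count_cols, drop = FALSE])
  if (!is.numeric(counts)) {
    j <- which(!vapply(raw[count_cols], is.numeric, logical(1)))[1]
    stop("validation error: non-numeric count column '",
         count_cols[j], "'", call. = FALSE)
  }
  colnames(counts) <- normalise_label(count_cols)
  diet_dataset(fish, counts, categories)
}

#' Read a long-format diet count table
#'
#' Long dialect: one row per (fish, category) pair with columns
#' `fish_id`, `species`, `stream`, optional `total_length_mm`,
#' `category`, `count`.  Missing pairs are zero.
#'
#' @inheritParams read_diet_csv
#' @return a [diet_dataset()].
#' @export
read_diet_long <- function(path, categories = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("fish_id", "species", "stream", "category", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw$category <- normalise_label(raw$category)
  ids <- unique(raw$fish_id)
  cats <- unique(raw$category)
  counts <- matrix(0L, length(ids), length(cats),
                   dimnames = list(ids, cats))
  counts[cbind(match(raw$fish_id, ids), match(raw$category, cats))] <-
    as.integer(raw$count)
  first <- raw[!duplicated(raw$fish_id), , drop = FALSE]
  fish <- data.frame(
    fish_id = as.character(first$fish_id),
    species = as.character(first$species),
    stream = as.character(first$stream),
    total_length_mm = if ("total_length_mm" %in% names(raw))
      as.numeric(first$total_length_mm) else NA_real_,
    stringsAsFactors = FALSE)
  diet_dataset(fish, counts, categories)
}

#' Write a diet dataset as a wide CSV
#'
#' Inverse of [read_diet_csv()] under the default schema:
#' `write_diet_csv()` then `read_diet_csv()` round-trips to an
#' identical dataset.
#'
#' @param ds a [diet_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diet_csv <- function(ds, path) {
  stopifnot(inherits(ds, "diet_dataset"))
  out <- cbind(ds$fish[, c("fish_id", "species", "stream",
                           "total_length_mm")],
               as.data.frame(ds$counts, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a prey-taxonomy mapping
#'
#' Accepts a 3-column CSV (`category`, `level`, `parent_order`) or a
#' YAML file whose top level maps category names to
#' `{level, parent_order}`.
#'
#' @param path path to the mapping file; format chosen by extension
#'   (`.yml`/`.yaml` vs anything else = CSV).
#' @return category registry data.frame (`name`, `level`,
#'   `parent_order`).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    out <- data.frame(
      name = normalise_label(names(y)),
      level = vapply(y, function(e) as.character(e$level), character(1)),
      parent_order = vapply(y, function(e)
        if (is.null(e$parent_order)) NA_character_
        else normalise_label(e$parent_order), character(1)),
      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("category", "level"), names(raw))
    if (length(miss)) {
      stop("taxonomy file missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (!"parent_order" %in% names(raw)) raw$parent_order <- NA_character_
    out <- data.frame(
      name = normalise_label(raw$category),
      level = raw$level,
      parent_order = ifelse(is.na(raw$parent_order) | raw$parent_order == "",
                            NA_character_, normalise_label(raw$parent_order)),
      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Quality-control summary of a dataset
#'
#' @param ds a [diet_dataset()].
#' @return data.frame with one row per group plus an `all` row: fish
#'   counts, empty stomachs, fish lacking a length measurement, and
#'   total items.
#' @export
qc_report <- function(ds) {
  stopifnot(inherits(ds, "diet_dataset"))
  g <- dataset_groups(ds)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    sel <- ds$fish$species == g$species[i] & ds$fish$stream == g$stream[i]
    data.frame(group = paste(g$species[i], g$stream[i], sep = ":"),
               n_fish = sum(sel),
               n_empty = sum(sel & ds$fish$empty),
               n_no_length = sum(sel & is.na(ds$fish$total_length_mm)),
               total_items = sum(ds$fish$total_items[sel]),
               stringsAsFactors = FALSE)
  })
  all_row <- data.frame(group = "all", n_fish = nrow(ds$fish),
                        n_empty = sum(ds$fish$empty),
                        n_no_length = sum(is.na(ds$fish$total_length_mm)),
                        total_items = sum(ds$fish$total_items),
                        stringsAsFactors = FALSE)
  rbind(do.call(rbind, rows), all_row)
}
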