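#' Pooled diet composition of one species-by-stream group
#'
#' The proportion of the group's diet in each prey category.  Two
#' conventions are supported: `"pooled"` (default) divides the summed
#' item counts across all non-empty fish in the group by the group's
#' total item count — the standard input to Pianka's index; `"mean"`
#' averages the per-fish proportion vectors, weighting every fish
#' equally regardless of how much it ate.
#'
#' Empty stomachs never contribute.
#'
#' @param ds a [diet_dataset()].
#' @param species,stream group labels.
#' @param mode `"pooled"` or `"mean"`.
#' @return object of class `group_composition`: a data.frame with
#'   columns `category` and `proportion` (summing to 1), with
#'   attributes `species`, `stream`, `n_fish` (non-empty fish) and
#'   `total_items`.
#' @export
group_composition <- function(ds, species, stream,
                              mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  grp <- subset_group(ds, species, stream, nonempty_only = TRUE)
  if (mode == "pooled") {
    totals <- colSums(grp$counts)
    prop <- totals / sum(totals)
  } else {
    per_fish <- grp$counts / grp$fish$total_items
    prop <- colMeans(per_fish)
  }
  out <- data.frame(category = colnames(grp$counts),
                    proportion = unname(prop),
                    stringsAsFactors = FALSE)
  structure(out, class = c("group_composition", "data.frame"),
            species = species, stream = stream,
            n_fish = nrow(grp$fish),
            total_items = sum(grp$fish$total_items),
            mode = mode)
}

#' Compositions of every group, side by side
#'
#' @param ds a [diet_dataset()].
#' @param mode proportion convention, see [group_composition()].
#' @return data.frame: `category` column plus one proportion column per
#'   group, named `species:stream`.
#' @export
composition_table <- function(ds, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  g <- dataset_groups(ds)
  out <- data.frame(category = colnames(ds$counts),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    comp <- group_composition(ds, g$species[i], g$stream[i], mode)
    out[[paste(g$species[i], g$stream[i], sep = ":")]] <- comp$proportion
  }
  out
}
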