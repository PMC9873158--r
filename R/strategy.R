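#' Feeding-strategy statistics (modified Costello method)
#'
#' For each prey category occurring in at least one stomach of the
#' group, computes frequency of occurrence
#' \eqn{F_i = N_i / N} — the fraction of fish with stomach contents
#' whose diet includes prey \eqn{i} — and prey-specific abundance
#' \eqn{P_i = \sum S_i / \sum S_{ti}}, prey \eqn{i}'s share of the
#' total items summed only over the fish that consumed it.  Plotting
#' \eqn{P_i} against \eqn{F_i} gives the Amundsen-Costello
#' feeding-strategy diagram: points near the top-left indicate
#' specialisation by a few individuals, near the top-right
#' specialisation by the whole population, and low \eqn{P_i} across
#' the board a generalist strategy.
#'
#' Categories no fish ate are omitted (their \eqn{P_i} would be 0/0).
#'
#' @param ds a [diet_dataset()].
#' @param species,stream group labels.
#' @return data.frame with one row per occurring category: `category`,
#'   `N_i` (fish containing it), `S_i` (items of it), `S_ti` (total
#'   items in those fish), `F_i`, `P_i`; attribute `N` is the group's
#'   non-empty-stomach count.
#' @export
feeding_strategy <- function(ds, species, stream) {
  grp <- subset_group(ds, species, stream, nonempty_only = TRUE)
  N <- nrow(grp$fish)
  present <- grp$counts > 0
  N_i <- colSums(present)
  S_i <- colSums(grp$counts)
  S_ti <- vapply(seq_len(ncol(grp$counts)), function(j)
    sum(grp$fish$total_items[present[, j]]), numeric(1))
  keep <- N_i > 0
  out <- data.frame(category = colnames(grp$counts)[keep],
                    N_i = as.integer(N_i[keep]),
                    S_i = as.integer(S_i[keep]),
                    S_ti = as.integer(S_ti[keep]),
                    F_i = unname(N_i[keep] / N),
                    P_i = unname(S_i[keep] / S_ti[keep]),
                    stringsAsFactors = FALSE)
  structure(out, N = N, species = species, stream = stream)
}

#' Prey-item richness summary
#'
#' Richness of a fish = the number of distinct prey categories with a
#' non-zero count in its stomach, at the dataset's recorded category
#' level.  Empty stomachs are excluded.
#'
#' @param ds a [diet_dataset()].
#' @param species,stream optional group labels; omit both to summarise
#'   all fish.
#' @return list with elements `scope`, `per_fish` (named integer
#'   vector), `median` (midpoint convention for even counts), `min`,
#'   `max`, `n_fish`.
#' @export
richness_summary <- function(ds, species = NULL, stream = NULL) {
  stopifnot(inherits(ds, "diet_dataset"))
  if (is.null(species) != is.null(stream)) {
    stop("give both species and stream, or neither", call. = FALSE)
  }
  if (is.null(species)) {
    scope <- "all"
    sel <- !ds$fish$empty
    if (!any(sel)) stop("no non-empty stomachs", call. = FALSE)
    counts <- ds$counts[sel, , drop = FALSE]
    ids <- ds$fish$fish_id[sel]
  } else {
    scope <- paste(species, stream, sep = ":")
    grp <- subset_group(ds, species, stream, nonempty_only = TRUE)
    counts <- grp$counts
    ids <- grp$fish$fish_id
  }
  rich <- as.integer(rowSums(counts > 0))
  names(rich) <- ids
  list(scope = scope, per_fish = rich,
       median = stats::median(rich),
       min = min(rich), max = max(rich), n_fish = length(rich))
}
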