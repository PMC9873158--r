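#' Pianka's index of niche overlap
#'
#' For resource-use proportion vectors \eqn{p} and \eqn{q} over a
#' common ordered category set,
#' \deqn{O = \frac{\sum_i p_i q_i}{\sqrt{\sum_i p_i^2 \sum_i q_i^2}},}
#' a symmetric measure in \[0, 1\]: 0 for disjoint resource use, 1 when
#' the two vectors are proportional.  The square root in the
#' denominator follows Pianka's (1973) definition; the variant without
#' it is available via `sqrt_denominator = FALSE` for diagnosis but is
#' not the index.
#'
#' @param p,q numeric vectors over the same category set, each summing
#'   to 1 (tolerance 1e-6).  When both are named, `q` is aligned to
#'   `p`'s names; mismatched name sets are an error.
#' @param sqrt_denominator use the square-rooted denominator (default
#'   `TRUE`).
#' @return the overlap index, a single number in \[0, 1\].
#' @export
pianka <- function(p, q, sqrt_denominator = TRUE) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q))) {
      stop("alignment error: category sets differ (",
           paste(c(setdiff(names(p), names(q)),
                   setdiff(names(q), names(p))), collapse = ", "), ")",
           call. = FALSE)
    }
    q <- q[names(p)]
  } else if (length(p) != length(q)) {
    stop("alignment error: vectors of length ", length(p), " and ",
         length(q), call. = FALSE)
  }
  if (any(p < 0) || any(q < 0)) {
    stop("proportions must be non-negative", call. = FALSE)
  }
  if (sum(p) == 0 || sum(q) == 0) {
    stop("degenerate input: zero composition vector", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("compositions must sum to 1 (got ", sum(p), " and ", sum(q), ")",
         call. = FALSE)
  }
  num <- sum(p * q)
  den <- if (sqrt_denominator) sqrt(sum(p^2) * sum(q^2)) else
    sum(p^2) * sum(q^2)
  min(1, num / den)
}

#' Niche-overlap matrix between species-by-stream groups
#'
#' Computes Pianka's index for each requested pair of groups over the
#' union of their categories (a category absent from a group takes
#' proportion 0) and classifies each value against the conventional
#' high-overlap threshold.
#'
#' @param ds a [diet_dataset()].
#' @param pairs list of pairs, each a list/vector of two group labels
#'   `"species:stream"`.  Default: the four study comparisons — the two
#'   species within each stream, and each species between streams.
#' @param mode proportion convention, see [group_composition()].
#' @param threshold classification cut-off, conventionally 0.60.
#' @return data.frame with columns `group_j`, `group_k`, `overlap`,
#'   `classification` (`"high"` / `"moderate/low"`), `n_categories`.
#' @export
overlap_matrix <- function(ds, pairs = NULL, mode = c("pooled", "mean"),
                           threshold = 0.60) {
  mode <- match.arg(mode)
  g <- dataset_groups(ds)
  labels <- paste(g$species, g$stream, sep = ":")
  if (is.null(pairs)) pairs <- default_overlap_pairs(ds)
  comps <- lapply(seq_len(nrow(g)), function(i)
    stats::setNames(group_composition(ds, g$species[i], g$stream[i],
                                      mode)$proportion,
                    colnames(ds$counts)))
  names(comps) <- labels
  rows <- lapply(pairs, function(pr) {
    pr <- as.character(unlist(pr))
    miss <- setdiff(pr, labels)
    if (length(miss)) stop("unknown group: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    o <- pianka(comps[[pr[1]]], comps[[pr[2]]])
    data.frame(group_j = pr[1], group_k = pr[2], overlap = o,
               classification = if (o >= threshold) "high"
                                else "moderate/low",
               n_categories = length(comps[[pr[1]]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The four standard group comparisons
#'
#' Within each stream, native vs introduced species; within each
#' species, mainstem vs tributary.
#'
#' @param ds a [diet_dataset()] with the 2 species x 2 stream design.
#' @return list of character pairs `"species:stream"`.
#' @export
default_overlap_pairs <- function(ds) {
  g <- dataset_groups(ds)
  pairs <- list()
  for (st in unique(g$stream)) {
    sp <- g$species[g$stream == st]
    if (length(sp) == 2) {
      pairs <- c(pairs, list(paste(sort(sp), st, sep = ":")))
    }
  }
  for (sp in unique(g$species)) {
    st <- g$stream[g$species == sp]
    if (length(st) == 2) {
      pairs <- c(pairs, list(paste(sp, sort(st), sep = ":")))
    }
  }
  pairs
}
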