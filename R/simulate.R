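#' Specification of one simulated species-by-stream group
#'
#' @param species,stream group labels (`"MW"`/`"RB"`,
#'   `"Smith"`/`"Sheep"` in the standard design).
#' @param n_fish number of fish to draw.
#' @param base_composition named probability vector over prey
#'   categories, summing to 1; the group's expected diet composition
#'   before any covariate effects.
#' @param mean_items,items_dispersion mean and negative-binomial size
#'   of the per-fish total item count; a drawn total of 0 yields an
#'   empty stomach.
#' @param theta Dirichlet concentration scalar controlling
#'   between-fish heterogeneity: a fish's own composition is drawn
#'   from Dirichlet(`theta` x composition), so smaller `theta` means
#'   more overdispersion; `Inf` means every fish shares the group
#'   composition exactly.
#' @param length_mean_mm,length_sd_mm total-length distribution
#'   (normal, truncated to `length_range`).
#' @param length_range lower/upper truncation for lengths; default
#'   keeps lengths positive.
#' @return a `group_spec` list.
#' @export
group_spec <- function(species, stream, n_fish, base_composition,
                       mean_items = 60, items_dispersion = 3,
                       theta = 8,
                       length_mean_mm = 300, length_sd_mm = 40,
                       length_range = c(1, Inf)) {
  if (is.null(names(base_composition)) ||
      any(!nzchar(names(base_composition)))) {
    stop("base_composition must be a named vector", call. = FALSE)
  }
  if (any(base_composition < 0) ||
      abs(sum(base_composition) - 1) > 1e-9) {
    stop("parameter error: base_composition must be non-negative and sum",
         " to 1 (got ", sum(base_composition), ")", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0) {
    stop("parameter error: theta must be a positive scalar", call. = FALSE)
  }
  if (n_fish < 1) stop("parameter error: n_fish >= 1 required",
                       call. = FALSE)
  structure(list(species = species, stream = stream,
                 n_fish = as.integer(n_fish),
                 base_composition = base_composition,
                 mean_items = mean_items,
                 items_dispersion = items_dispersion,
                 theta = theta,
                 length_mean_mm = length_mean_mm,
                 length_sd_mm = length_sd_mm,
                 length_range = length_range),
            class = "group_spec")
}

#' Covariate effect on one prey category's diet share
#'
#' Effects act on the log-odds of the category's share of the diet
#' (its proportion versus everything else), the same scale on which
#' the quasi-binomial consumption models are fit: a fish's expected
#' share of the category is
#' `plogis(qlogis(base) + species_logit * is_RB + stream_logit *
#' is_Smith + interaction_logit * is_RB * is_Smith +
#' length_logit_per_mm * (length - length_ref))`,
#' with the remaining categories rescaled to the leftover mass.
#'
#' @param category prey category the effect applies to.
#' @param species_logit log-odds shift for rainbow trout (`RB`) over
#'   the mountain whitefish baseline.
#' @param stream_logit log-odds shift for the Smith River over the
#'   Sheep Creek baseline.
#' @param interaction_logit additional shift for rainbow trout in the
#'   Smith River.
#' @param length_logit_per_mm log-odds shift per mm of total length.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(category, species_logit = 0, stream_logit = 0,
                        interaction_logit = 0, length_logit_per_mm = 0) {
  vals <- c(species_logit, stream_logit, interaction_logit,
            length_logit_per_mm)
  if (any(!is.finite(vals))) {
    stop("parameter error: effect logits must be finite", call. = FALSE)
  }
  structure(list(category = category, species_logit = species_logit,
                 stream_logit = stream_logit,
                 interaction_logit = interaction_logit,
                 length_logit_per_mm = length_logit_per_mm),
            class = "effect_spec")
}

# n draws from Dirichlet(alpha) rows; rows of alpha may differ
rdirichlet_rows <- function(alpha) {
  x <- matrix(0, nrow(alpha), ncol(alpha))
  pos <- alpha > 0
  x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
  tot <- rowSums(x)
  zero <- tot == 0
  if (any(zero)) {
    x[zero, ] <- alpha[zero, , drop = FALSE]
    tot[zero] <- rowSums(alpha[zero, , drop = FALSE])
  }
  x / tot
}

rtruncnorm <- function(n, mean, sd, range) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  for (i in 1:1000) {
    bad <- out < range[1] | out > range[2]
    if (!any(bad)) return(out)
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("length truncation region has negligible mass", call. = FALSE)
}

# expected compositions of a group's fish (one row each): shift each
# affected category's share on the logit scale, rescale the remaining
# categories onto the leftover mass.  When the shifted shares
# overshoot the simplex they are rescaled to fit; marginal effects are
# then no longer exact, which is why recovery experiments apply one
# category's effect at a time.
adjust_composition <- function(base, effects, is_rb, is_smith,
                               lengths, length_ref) {
  n <- length(lengths)
  comp <- matrix(base, n, length(base), byrow = TRUE,
                 dimnames = list(NULL, names(base)))
  if (length(effects) == 0) return(comp)
  affected <- vapply(effects, function(e) e$category, character(1))
  missing <- setdiff(affected, names(base))
  if (length(missing)) {
    stop("effect on unknown category: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  shares <- vapply(effects, function(e) {
    delta <- e$species_logit * is_rb + e$stream_logit * is_smith +
      e$interaction_logit * is_rb * is_smith +
      e$length_logit_per_mm * (lengths - length_ref)
    stats::plogis(stats::qlogis(base[[e$category]]) + delta)
  }, numeric(n))
  if (n == 1L) shares <- matrix(shares, nrow = 1L)
  tot <- rowSums(shares)
  over <- tot >= 0.999
  if (any(over)) {
    shares[over, ] <- shares[over, , drop = FALSE] * 0.999 / tot[over]
    tot[over] <- 0.999
  }
  rest <- setdiff(names(base), affected)
  comp[, affected] <- shares
  base_rest <- sum(base[rest])
  if (base_rest > 0) {
    comp[, rest] <- outer((1 - tot) / base_rest, base[rest])
  }
  comp
}

#' Simulate a diet dataset
#'
#' Draws a [diet_dataset()] with the statistical structure the
#' downstream analyses assume.  For every fish: a total length from a
#' truncated normal; the group composition adjusted for the fish's
#' covariates on the logit-share scale ([effect_spec()]); a
#' fish-specific composition from Dirichlet(`theta` x composition)
#' (between-fish overdispersion — the reason the consumption models
#' are quasi-binomial rather than binomial); a total item count from a
#' negative binomial (or `fixed_total`); and category counts from a
#' multinomial.  Identical seed and arguments give a bit-identical
#' dataset.
#'
#' @param specs list of [group_spec()]s sharing one category set.
#' @param effects list of [effect_spec()]s (may be empty).
#' @param seed non-negative integer seed; all draws flow from it.
#' @param length_ref_mm length at which effects vanish (centering of
#'   the length effect), default 306.
#' @param fixed_total if given, every fish eats exactly this many
#'   items (closed-form test mode).
#' @param categories optional category registry for the result.
#' @return a [diet_dataset()].
#' @export
generate_dataset <- function(specs, effects = list(), seed,
                             length_ref_mm = 306, fixed_total = NULL,
                             categories = NULL) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, logical(1),
                                           "group_spec")))
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  cats <- names(specs[[1]]$base_composition)
  for (s in specs) {
    if (!identical(names(s$base_composition), cats)) {
      stop("all group specs must share one ordered category list",
           call. = FALSE)
    }
  }
  if (missing(seed) || !is.numeric(seed) || seed < 0) {
    stop("parameter error: seed must be a non-negative integer",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  fish_blocks <- list()
  count_blocks <- list()
  for (b in seq_along(specs)) {
    s <- specs[[b]]
    n <- s$n_fish
    is_rb <- as.numeric(s$species == "RB")
    is_smith <- as.numeric(s$stream == "Smith")
    lens <- rtruncnorm(n, s$length_mean_mm, s$length_sd_mm,
                       s$length_range)
    comp <- adjust_composition(s$base_composition, effects, is_rb,
                               is_smith, lens, length_ref_mm)
    fish_comp <- if (is.infinite(s$theta)) comp else
      rdirichlet_rows(s$theta * comp)
    totals <- if (!is.null(fixed_total)) rep(as.integer(fixed_total), n)
      else stats::rnbinom(n, mu = s$mean_items,
                          size = s$items_dispersion)
    cnt <- matrix(0L, n, length(cats))
    for (i in which(totals > 0)) {
      cnt[i, ] <- as.integer(stats::rmultinom(1, totals[i],
                                              fish_comp[i, ]))
    }
    fish_blocks[[b]] <- data.frame(
      fish_id = sprintf("%s_%s_%03d", s$species, s$stream, seq_len(n)),
      species = s$species, stream = s$stream,
      total_length_mm = lens, stringsAsFactors = FALSE)
    count_blocks[[b]] <- cnt
  }
  counts <- do.call(rbind, count_blocks)
  colnames(counts) <- cats
  diet_dataset(do.call(rbind, fish_blocks), counts, categories)
}
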