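#' Simulation preset emulating the Smith River / Sheep Creek study
#' design
#'
#' Four species-by-stream groups — native mountain whitefish (`MW`)
#' and introduced rainbow trout (`RB`) in a mainstem (`Smith`) and a
#' tributary (`Sheep`) — with the sample sizes (11/6/20/20) and
#' total-length ranges of the field collection, group compositions
#' seeded from the model-estimated diet proportions of the eight most
#' consumed prey categories (everything else pooled as `Other`), and
#' covariate effects whose signs and magnitudes mirror the reported
#' log-odds coefficients (e.g. rainbow trout eat far more Oligochaeta
#' and fewer Brachycentridae than whitefish).
#'
#' Two generating modes are supported downstream:
#' \itemize{
#'   \item `$specs` carry per-group compositions and are used with
#'     `effects = list()` — simulation reproduces the four observed
#'     group compositions directly.
#'   \item [recovery_specs()] builds specs that all share
#'     `$baseline_composition`, to be used together with `$effects`;
#'     this is the generative form consistent with the consumption
#'     GLMs and is what parameter-recovery experiments use.
#' }
#'
#' @return list with `specs` (list of 4 [group_spec()]),
#'   `effects` (list of [effect_spec()]), `baseline_composition`
#'   (named vector, the whitefish/Sheep-Creek column at the reference
#'   length), `categories` (registry data.frame), `length_ref_mm`
#'   (306, the study's median length).
#' @export
smith_sheep_preset <- function() {
  cats <- c("Athericidae", "Baetidae", "Brachycentridae", "Chironomidae",
            "Ephemerellidae", "Heptageniidae", "Hydropsychidae",
            "Oligochaeta", "Other")
  comp <- function(x) {
    stopifnot(length(x) == 8, sum(x) < 1)
    stats::setNames(c(x, 1 - sum(x)), cats)
  }
  baseline <- comp(c(0.007, 0.205, 0.251, 0.214, 0.163, 0.026, 0.028,
                     0.007))
  group_comps <- list(
    MW_Smith = comp(c(0.026, 0.042, 0.125, 0.162, 0.259, 0.003, 0.246,
                      0.001)),
    MW_Sheep = baseline,
    RB_Smith = comp(c(0.015, 0.042, 0.023, 0.135, 0.259, 0.003, 0.246,
                      0.056)),
    RB_Sheep = comp(c(0.077, 0.205, 0.052, 0.015, 0.163, 0.026, 0.028,
                      0.332)))
  # n, length mean/sd chosen to respect the observed TL ranges
  design <- list(
    MW_Smith = list("MW", "Smith", 11L, 350, 25, c(306, 396)),
    MW_Sheep = list("MW", "Sheep", 20L, 326, 40, c(244, 408)),
    RB_Smith = list("RB", "Smith", 6L, 350, 35, c(285, 415)),
    RB_Sheep = list("RB", "Sheep", 20L, 266, 65, c(138, 395)))
  specs <- lapply(names(design), function(nm) {
    d <- design[[nm]]
    group_spec(species = d[[1]], stream = d[[2]], n_fish = d[[3]],
               base_composition = group_comps[[nm]],
               mean_items = 60, items_dispersion = 3, theta = 8,
               length_mean_mm = d[[4]], length_sd_mm = d[[5]],
               length_range = d[[6]])
  })
  names(specs) <- names(design)
  effects <- list(
    effect_spec("Athericidae", species_logit = 2.474,
                stream_logit = 1.354, interaction_logit = -3.053),
    effect_spec("Baetidae", stream_logit = -1.780),
    effect_spec("Brachycentridae", species_logit = -1.815,
                stream_logit = -0.855),
    effect_spec("Chironomidae", species_logit = -2.860,
                stream_logit = -0.346, interaction_logit = 2.645,
                length_logit_per_mm = -0.010),
    effect_spec("Ephemerellidae", stream_logit = 0.584),
    effect_spec("Heptageniidae", stream_logit = -2.254),
    effect_spec("Hydropsychidae", stream_logit = 2.413),
    effect_spec("Oligochaeta", species_logit = 4.267,
                stream_logit = -2.118, length_logit_per_mm = 0.015))
  list(specs = specs, effects = effects,
       baseline_composition = baseline,
       categories = smith_sheep_taxonomy(),
       length_ref_mm = 306)
}

#' Category registry for the study preset
#'
#' Aquatic insect families with their parent orders; Oligochaeta at
#' class level; a pooled `Other` bin.
#'
#' @return registry data.frame (`name`, `level`, `parent_order`).
#' @export
smith_sheep_taxonomy <- function() {
  data.frame(
    name = c("Athericidae", "Baetidae", "Brachycentridae",
             "Chironomidae", "Ephemerellidae", "Heptageniidae",
             "Hydropsychidae", "Oligochaeta", "Other"),
    level = c(rep("family", 7), "class", "other"),
    parent_order = c("Diptera", "Ephemeroptera", "Trichoptera",
                     "Diptera", "Ephemeroptera", "Ephemeroptera",
                     "Trichoptera", NA, NA),
    stringsAsFactors = FALSE)
}

#' Shared-baseline specs for parameter-recovery experiments
#'
#' Rebuilds the preset's four group specs with a common baseline
#' composition so that all between-group differences come from the
#' preset's [effect_spec()]s — the data-generating form the
#' quasi-binomial consumption models assume.
#'
#' @param preset a [smith_sheep_preset()].
#' @param n_fish fish per group (default: the study sizes).
#' @return list of 4 [group_spec()]s.
#' @export
recovery_specs <- function(preset = smith_sheep_preset(),
                           n_fish = NULL) {
  lapply(preset$specs, function(s) {
    group_spec(species = s$species, stream = s$stream,
               n_fish = if (is.null(n_fish)) s$n_fish else n_fish,
               base_composition = preset$baseline_composition,
               mean_items = s$mean_items,
               items_dispersion = s$items_dispersion,
               theta = s$theta,
               length_mean_mm = s$length_mean_mm,
               length_sd_mm = s$length_sd_mm,
               length_range = s$length_range)
  })
}

#' Reported log-odds coefficients of the study's final consumption
#' models
#'
#' The published coefficient table for the eight most consumed prey
#' categories (log-odds scale; baselines mountain whitefish and Sheep
#' Creek), shipped as package data so predicted consumption
#' proportions can be recomputed from the reported models without the
#' raw count data.
#'
#' @return data.frame with columns `category`, `term` (`intercept`,
#'   `stream`, `species`, `length`, `species:stream`), `estimate`,
#'   `t_value`.
#' @export
reference_coefficients <- function() {
  path <- system.file("extdata", "reference_coefficients.csv",
                      package = "dietoverlap", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Predicted proportion from a reported coefficient table
#'
#' Builds the linear predictor for a species-by-stream group from a
#' coefficient table in the shape of [reference_coefficients()] and
#' back-transforms it through the inverse logit.  Terms absent from
#' the table (not in that category's final model) contribute nothing.
#'
#' @param coefs coefficient table (`category`, `term`, `estimate`).
#' @param category prey category.
#' @param species `"MW"` (baseline) or `"RB"`.
#' @param stream `"Sheep"` (baseline) or `"Smith"`.
#' @param length_mm fish length; required iff the category's model has
#'   a length term.
#' @return the predicted consumption proportion (a single number).
#' @export
predict_from_coefficients <- function(coefs, category, species = "MW",
                                      stream = "Sheep",
                                      length_mm = NULL) {
  rows <- coefs[coefs$category == category, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("category '", category, "' not in coefficient table",
         call. = FALSE)
  }
  est <- stats::setNames(rows$estimate, rows$term)
  if (!"intercept" %in% names(est)) {
    stop("coefficient table has no intercept for '", category, "'",
         call. = FALSE)
  }
  lp <- est[["intercept"]]
  if (stream == "Smith" && "stream" %in% names(est)) {
    lp <- lp + est[["stream"]]
  }
  if (species == "RB" && "species" %in% names(est)) {
    lp <- lp + est[["species"]]
  }
  if (species == "RB" && stream == "Smith" &&
      "species:stream" %in% names(est)) {
    lp <- lp + est[["species:stream"]]
  }
  if ("length" %in% names(est)) {
    if (is.null(length_mm)) {
      stop("missing covariate: model for '", category,
           "' includes length; supply length_mm", call. = FALSE)
    }
    lp <- lp + est[["length"]] * length_mm
  }
  stats::plogis(lp)
}
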