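#' Run the full diet-analysis pipeline
#'
#' Sequences every stage of the analysis on either a count CSV or a
#' simulation specification: ingestion/QC, composition tables at the
#' recorded and order levels, the niche-overlap matrix,
#' feeding-strategy points, prey-item richness, and quasi-binomial
#' consumption models with QAICc selection and back-transformed
#' predictions.  The run is deterministic given the input (or
#' simulation seed) and configuration.
#'
#' @param input a [diet_dataset()] or path to a wide count CSV.
#'   Exactly one of `input` and `specs` must be given.
#' @param specs list of [group_spec()]s for a simulated run.
#' @param effects list of [effect_spec()]s for a simulated run.
#' @param seed simulation seed (required with `specs`).
#' @param taxonomy optional category registry for order-level
#'   aggregation.
#' @param proportion_mode `"pooled"` or `"mean"`; the alternative mode
#'   is also computed and stored for diagnosis.
#' @param overlap_pairs group pairs for [overlap_matrix()]; default
#'   the four standard comparisons.
#' @param candidates candidate model set, see [candidate_models()].
#' @param n_categories how many of the most consumed categories to
#'   model.
#' @param predict_length `"median"` (median total length of the fish
#'   used) or a number in mm.
#' @param overlap_threshold high-overlap classification cut-off.
#' @return object of class `report_bundle`: a list of tables
#'   (`qc`, `composition`, `composition_order`, `overlap`,
#'   `overlap_alt`, `strategy`, `richness`, `coefficients`,
#'   `selection`, `predictions`), `selections` (the fitted
#'   `prey_selection` objects), `consistency` (back-transform check),
#'   `warnings`, and `manifest`.
#' @export
run_pipeline <- function(input = NULL, specs = NULL, effects = list(),
                         seed = NULL, taxonomy = NULL,
                         proportion_mode = c("pooled", "mean"),
                         overlap_pairs = NULL,
                         candidates = candidate_models(),
                         n_categories = 8,
                         predict_length = "median",
                         overlap_threshold = 0.60) {
  proportion_mode <- match.arg(proportion_mode)
  if (is.null(input) == is.null(specs)) {
    stop("give exactly one of 'input' and 'specs'", call. = FALSE)
  }
  warn <- character(0)
  ds <- if (!is.null(specs)) {
    if (is.null(seed)) stop("simulated runs need a seed", call. = FALSE)
    generate_dataset(specs, effects, seed = seed,
                     categories = taxonomy)
  } else if (inherits(input, "diet_dataset")) {
    input
  } else {
    read_diet_csv(input, categories = taxonomy)
  }

  qc <- qc_report(ds)
  if (sum(ds$fish$empty) > 0) {
    warn <- c(warn, sprintf("%d empty stomach(s) excluded from statistics",
                            sum(ds$fish$empty)))
  }

  composition <- composition_table(ds, mode = proportion_mode)
  ds_order <- tryCatch(
    aggregate_to_level(ds, "order", taxonomy = taxonomy,
                       other_label = "Other"),
    error = function(e) NULL)
  composition_order <- if (is.null(ds_order)) NULL else
    composition_table(ds_order, mode = proportion_mode)

  if (is.null(overlap_pairs)) overlap_pairs <- default_overlap_pairs(ds)
  alt_mode <- if (proportion_mode == "pooled") "mean" else "pooled"
  overlap <- overlap_matrix(ds, overlap_pairs, mode = proportion_mode,
                            threshold = overlap_threshold)
  overlap_alt <- overlap_matrix(ds, overlap_pairs, mode = alt_mode,
                                threshold = overlap_threshold)

  g <- dataset_groups(ds)
  strategy <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    fs <- feeding_strategy(ds, g$species[i], g$stream[i])
    cbind(group = paste(g$species[i], g$stream[i], sep = ":"), fs)
  }))
  richness <- do.call(rbind, c(
    lapply(seq_len(nrow(g)), function(i) {
      r <- richness_summary(ds, g$species[i], g$stream[i])
      data.frame(scope = r$scope, n_fish = r$n_fish, median = r$median,
                 min = r$min, max = r$max, stringsAsFactors = FALSE)
    }),
    list({
      r <- richness_summary(ds)
      data.frame(scope = "all", n_fish = r$n_fish, median = r$median,
                 min = r$min, max = r$max, stringsAsFactors = FALSE)
    })))

  cats <- top_categories(ds, n = n_categories)
  selections <- list()
  for (cat in cats) {
    sel <- tryCatch(select_model(ds, cat, candidates = candidates),
                    error = function(e) e)
    if (inherits(sel, "error")) {
      warn <- c(warn, sprintf("model selection failed for %s: %s", cat,
                              conditionMessage(sel)))
    } else {
      selections[[cat]] <- sel
    }
  }

  len_at <- if (identical(predict_length, "median")) {
    stats::median(ds$fish$total_length_mm[!ds$fish$empty], na.rm = TRUE)
  } else {
    as.numeric(predict_length)
  }

  coefficients <- do.call(rbind, lapply(selections, function(sel)
    tidy_coefficients(sel$fits[[sel$selected]])))
  selection_tab <- do.call(rbind, lapply(selections, function(sel)
    cbind(category = sel$category, sel$table,
          selected = sel$table$model == sel$selected,
          stringsAsFactors = FALSE)))
  predictions <- do.call(rbind, lapply(selections, function(sel) {
    fit <- sel$fits[[sel$selected]]
    do.call(rbind, lapply(seq_len(nrow(g)), function(i)
      predict_proportion(fit, g$species[i], g$stream[i],
                         length_mm = if ("length" %in% fit$terms)
                           len_at else NULL)))
  }))
  rownames(coefficients) <- rownames(predictions) <- NULL
  if (!is.null(selection_tab)) rownames(selection_tab) <- NULL

  consistency <- check_consistency(selections, predictions, len_at)
  if (!all(consistency$ok)) {
    stop("internal inconsistency: predictions do not back-transform ",
         "from the selected coefficients", call. = FALSE)
  }

  manifest <- list(
    package = "dietoverlap",
    version = as.character(utils::packageVersion("dietoverlap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    input = if (is.null(specs)) "data" else "simulation",
    seed = seed,
    proportion_mode = proportion_mode,
    overlap_threshold = overlap_threshold,
    n_categories = n_categories,
    predict_length = predict_length,
    predict_length_mm = len_at,
    modeled_categories = cats,
    warnings = warn)

  structure(list(qc = qc, composition = composition,
                 composition_order = composition_order,
                 overlap = overlap, overlap_alt = overlap_alt,
                 strategy = strategy, richness = richness,
                 coefficients = coefficients,
                 selection = selection_tab,
                 predictions = predictions,
                 selections = selections,
                 consistency = consistency,
                 warnings = warn,
                 manifest = manifest),
            class = "report_bundle")
}

# coefficient rows of one fit in report shape
tidy_coefficients <- function(fit) {
  stopifnot(inherits(fit, "prey_glm"))
  tab <- fit$coefficients
  term_map <- c("(Intercept)" = "intercept", "streamSmith" = "stream",
                "speciesRB" = "species", "length" = "length",
                "speciesRB:streamSmith" = "species:stream")
  terms <- rownames(tab)
  data.frame(category = fit$category,
             term = unname(ifelse(terms %in% names(term_map),
                                  term_map[terms], terms)),
             estimate = tab[, 1], std_error = tab[, 2],
             t_value = tab[, 3], p_value = tab[, 4],
             stringsAsFactors = FALSE)
}

# every prediction must equal the inverse-logit of the selected
# model's linear predictor, recomputed here from the raw coefficients
check_consistency <- function(selections, predictions, len_at) {
  if (length(selections) == 0 || is.null(predictions)) {
    return(data.frame(category = character(0), ok = logical(0)))
  }
  rows <- lapply(seq_len(nrow(predictions)), function(i) {
    p <- predictions[i, ]
    sel <- selections[[p$category]]
    fit <- sel$fits[[sel$selected]]
    cf <- stats::coef(fit$glm)
    lp <- cf[["(Intercept)"]]
    if (p$stream == "Smith" && "streamSmith" %in% names(cf)) {
      lp <- lp + cf[["streamSmith"]]
    }
    if (p$species == "RB" && "speciesRB" %in% names(cf)) {
      lp <- lp + cf[["speciesRB"]]
    }
    if (p$species == "RB" && p$stream == "Smith" &&
        "speciesRB:streamSmith" %in% names(cf)) {
      lp <- lp + cf[["speciesRB:streamSmith"]]
    }
    if ("length" %in% names(cf)) lp <- lp + cf[["length"]] * len_at
    data.frame(category = p$category, species = p$species,
               stream = p$stream,
               ok = abs(stats::plogis(lp) - p$estimate) < 1e-8,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a report bundle to disk
#'
#' One TSV per table plus a YAML manifest.  Numbers are rounded only
#' at serialisation (3 decimals); identical bundle and directory give
#' byte-identical files.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @param digits rounding applied at serialisation.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir, digits = 3) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("qc", "composition", "composition_order", "overlap",
              "overlap_alt", "strategy", "richness", "coefficients",
              "selection", "predictions")
  for (nm in tables) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(x) round(x, digits))
    utils::write.table(tab, file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeLines(yaml::as.yaml(bundle$manifest),
             file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Compare a report bundle against expected values
#'
#' The reference lists rows `(table, cell, expected, tolerance)`;
#' supported tables are `overlap` (cell `"groupJ|groupK"`), `richness`
#' (cell `"median_all"` / `"max_all"` or `"median_<group>"` etc.),
#' `group_size` (cell `"species:stream"`), `coefficient`
#' (cell `"category|term"`) and `prediction`
#' (cell `"category|species:stream"`).
#'
#' @param bundle a `report_bundle`.
#' @param reference data.frame or CSV path with columns `table`,
#'   `cell`, `expected`, `tolerance`.
#' @return data.frame with the computed value, absolute difference and
#'   pass flag per row; attribute `ok` is `TRUE` when every row
#'   passes.
#' @export
compare_to_reference <- function(bundle, reference) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (is.character(reference)) {
    reference <- utils::read.csv(reference, stringsAsFactors = FALSE)
  }
  need <- c("table", "cell", "expected", "tolerance")
  miss <- setdiff(need, names(reference))
  if (length(miss)) {
    stop("malformed reference: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lookup <- function(table, cell) {
    parts <- strsplit(cell, "|", fixed = TRUE)[[1]]
    switch(table,
      overlap = {
        m <- bundle$overlap
        hit <- (m$group_j == parts[1] & m$group_k == parts[2]) |
          (m$group_j == parts[2] & m$group_k == parts[1])
        if (!any(hit)) NA_real_ else m$overlap[hit][1]
      },
      richness = {
        stat <- sub("_.*$", "", cell)
        scope <- sub("^[^_]*_", "", cell)
        r <- bundle$richness
        hit <- r$scope == scope
        if (!any(hit) || !stat %in% names(r)) NA_real_ else
          r[[stat]][hit][1]
      },
      group_size = {
        q <- bundle$qc
        hit <- q$group == cell
        if (!any(hit)) NA_real_ else q$n_fish[hit][1]
      },
      coefficient = {
        cf <- bundle$coefficients
        hit <- cf$category == parts[1] & cf$term == parts[2]
        if (!any(hit)) NA_real_ else cf$estimate[hit][1]
      },
      prediction = {
        pr <- bundle$predictions
        grp <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
        hit <- pr$category == parts[1] & pr$species == grp[1] &
          pr$stream == grp[2]
        if (!any(hit)) NA_real_ else pr$estimate[hit][1]
      },
      stop("malformed reference: unknown table '", table, "'",
           call. = FALSE))
  }
  computed <- mapply(lookup, reference$table, reference$cell)
  out <- data.frame(reference,
                    computed = as.numeric(computed),
                    stringsAsFactors = FALSE)
  out$difference <- abs(out$computed - out$expected)
  out$pass <- !is.na(out$difference) & out$difference <= out$tolerance
  structure(out, ok = all(out$pass))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle:", nrow(x$qc) - 1, "groups,",
      length(x$selections), "modeled categories\n")
  cat("overlap (", x$manifest$proportion_mode, " proportions):\n",
      sep = "")
  print(transform(x$overlap, overlap = round(overlap, 3)))
  invisible(x)
}
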