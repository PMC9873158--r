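#' Quasi-binomial logit model for one prey category
#'
#' Models the per-fish proportion of diet items in `category` with a
#' logit link, weighting each fish by its total item count, and
#' estimating a dispersion parameter \eqn{\hat c} from the Pearson
#' statistic (diet counts are overdispersed relative to the binomial
#' because fish differ in composition beyond sampling noise).  Point
#' estimates are identical to the ordinary binomial fit; standard
#' errors are inflated by \eqn{\sqrt{\hat c}} and tests use the t
#' distribution on \eqn{n - p} degrees of freedom.
#'
#' Baselines are mountain whitefish (`MW`) for species and Sheep Creek
#' (`Sheep`) for stream, so the intercept is the log-odds for a
#' whitefish in the tributary.
#'
#' @param ds a [diet_dataset()].
#' @param category prey category to model.
#' @param terms character vector, a subset of `"stream"`, `"species"`,
#'   `"length"`, `"species:stream"`; the intercept is always included
#'   and the interaction requires both main effects.
#' @param data optional pre-built model frame (used internally by
#'   [select_model()] so every candidate sees the same fish).
#' @return object of class `prey_glm`: list with the underlying `glm`
#'   fit, `category`, `terms`, `coefficients` table (estimate, SE, t,
#'   p), `dispersion`, `binomial_loglik`, `K` (regression coefficients
#'   + 1 for the dispersion parameter), `n`, `n_dropped_no_length`,
#'   `converged`.
#' @export
fit_prey_glm <- function(ds, category, terms = character(0), data = NULL) {
  valid <- c("stream", "species", "length", "species:stream")
  bad <- setdiff(terms, valid)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if ("species:stream" %in% terms &&
      !all(c("species", "stream") %in% terms)) {
    stop("species:stream interaction requires both main effects",
         call. = FALSE)
  }
  if (is.null(data)) data <- glm_frame(ds, category,
                                       need_length = "length" %in% terms)
  if (!category %in% names(data)) {
    # frame built for another category: recompute response
    stop("category '", category, "' not in model frame", call. = FALSE)
  }
  if (all(data[[category]] == 0)) {
    stop("degenerate fit: category '", category,
         "' absent from every stomach used", call. = FALSE)
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  data$.prop <- data[[category]] / data$total_items
  form <- stats::as.formula(paste(".prop ~", rhs))
  fit <- stats::glm(form, family = stats::quasibinomial(),
                    weights = total_items, data = data,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  if (!fit$converged) {
    stop("convergence error: quasi-binomial fit for '", category,
         "' did not converge", call. = FALSE)
  }
  p <- length(stats::coef(fit))
  n <- nrow(data)
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / (n - p)
  mu <- stats::fitted(fit)
  k <- data[[category]]
  ll <- sum(stats::dbinom(k, data$total_items, mu, log = TRUE))
  structure(list(
    glm = fit,
    category = category,
    terms = terms,
    coefficients = as.data.frame(summary(fit)$coefficients),
    dispersion = disp,
    binomial_loglik = ll,
    K = p + 1L,
    n = n,
    n_dropped_no_length = attr(data, "n_dropped_no_length") %||% 0L,
    converged = fit$converged
  ), class = "prey_glm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-fish model frame: one row per non-empty fish, counts of every
# category, totals, and baseline-coded factors
glm_frame <- function(ds, category = NULL, need_length = FALSE) {
  stopifnot(inherits(ds, "diet_dataset"))
  keep <- !ds$fish$empty
  dropped <- 0L
  if (need_length) {
    no_len <- keep & is.na(ds$fish$total_length_mm)
    dropped <- sum(no_len)
    keep <- keep & !is.na(ds$fish$total_length_mm)
  }
  if (!any(keep)) stop("no usable fish for model frame", call. = FALSE)
  df <- cbind(
    ds$fish[keep, c("fish_id", "total_items", "total_length_mm")],
    as.data.frame(ds$counts[keep, , drop = FALSE], check.names = FALSE))
  sp <- ds$fish$species[keep]
  st <- ds$fish$stream[keep]
  df$species <- factor(sp, levels = union("MW", sort(unique(sp))))
  df$stream <- factor(st, levels = union("Sheep", sort(unique(st))))
  df$length <- df$total_length_mm
  rownames(df) <- NULL
  attr(df, "n_dropped_no_length") <- dropped
  df
}

#' @export
print.prey_glm <- function(x, ...) {
  cat("prey_glm:", x$category, "~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      sprintf(" (n = %d, c-hat = %.3f)\n", x$n, x$dispersion))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Quasi-likelihood AICc
#'
#' \deqn{QAICc = -2 \log L / \hat c + 2K + \frac{2K(K+1)}{n - K - 1}}
#' where \eqn{\log L} is the binomial log-likelihood of the fit,
#' \eqn{\hat c} the overdispersion estimate, and \eqn{K} the number of
#' estimated parameters counting the dispersion parameter.  At
#' \eqn{\hat c = 1} this is the ordinary AICc of the binomial fit.
#'
#' @param fit a `prey_glm`.
#' @param c_hat overdispersion used for the quasi-likelihood; defaults
#'   to the fit's own estimate floored at 1.
#' @param n effective sample size; defaults to the fit's `n`.
#' @return the QAICc value.
#' @export
qaicc <- function(fit, c_hat = NULL, n = NULL) {
  stopifnot(inherits(fit, "prey_glm"))
  if (is.null(c_hat)) c_hat <- max(1, fit$dispersion)
  if (c_hat <= 0) stop("c_hat must be positive", call. = FALSE)
  if (is.null(n)) n <- fit$n
  K <- fit$K
  if (n <= K + 1) {
    stop("small-sample error: n = ", n, " <= K + 1 = ", K + 1,
         call. = FALSE)
  }
  -2 * fit$binomial_loglik / c_hat + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' The default candidate model set
#'
#' Nine models from the null (intercept only) to the global model with
#' species, stream, their interaction and fish length.  Every model a
#' final fit could plausibly select — stream only, stream + species,
#' stream + species + interaction, stream + species + length, and the
#' global — is in the set.
#'
#' @return named list of term vectors, in increasing complexity.
#' @export
candidate_models <- function() {
  list(
    null = character(0),
    length = "length",
    species = "species",
    stream = "stream",
    `species+stream` = c("species", "stream"),
    `stream+length` = c("stream", "length"),
    `species+stream+length` = c("species", "stream", "length"),
    `species*stream` = c("species", "stream", "species:stream"),
    global = c("species", "stream", "length", "species:stream")
  )
}

#' QAICc model selection for one prey category
#'
#' Fits every candidate on a common set of fish (fish lacking a length
#' measurement are dropped for all candidates whenever any candidate
#' uses length, so QAICc values are comparable), estimates the
#' overdispersion \eqn{\hat c} once from the global (most complex)
#' model, applies it to every candidate's QAICc, and selects by the
#' parsimony rule: among models within 2 QAICc units of the best, the
#' one with the fewest parameters (ties broken by lower QAICc, then by
#' candidate order).
#'
#' @param ds a [diet_dataset()].
#' @param category prey category to model.
#' @param candidates named list of term vectors, see
#'   [candidate_models()].
#' @param floor_c_hat treat estimated underdispersion
#'   (\eqn{\hat c < 1}) as binomial by flooring at 1 (default `TRUE`).
#' @return object of class `prey_selection`: list with `category`,
#'   `table` (model, K, QAICc, dQAICc, sorted by QAICc), `selected`
#'   (model name), `fits` (named list of `prey_glm`), `c_hat`,
#'   `c_hat_source`, `n`.
#' @export
select_model <- function(ds, category, candidates = candidate_models(),
                         floor_c_hat = TRUE) {
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    stop("candidates must be named", call. = FALSE)
  }
  need_length <- any(vapply(candidates, function(tm) "length" %in% tm,
                            logical(1)))
  frame <- glm_frame(ds, category, need_length = need_length)
  fits <- list()
  failed <- character(0)
  for (nm in names(candidates)) {
    f <- tryCatch(fit_prey_glm(ds, category, candidates[[nm]],
                               data = frame),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failed <- c(failed, nm)
    } else {
      fits[[nm]] <- f
    }
  }
  if (length(failed)) {
    warning("candidate(s) failed and were excluded for '", category,
            "': ", paste(failed, collapse = ", "), call. = FALSE)
  }
  if (length(fits) == 0) {
    stop("no candidate fitted for '", category, "'", call. = FALSE)
  }
  n_terms <- vapply(candidates, length, integer(1))
  global_name <- names(candidates)[which.max(n_terms)]
  if (!global_name %in% names(fits)) {
    stop("global model failed for '", category, "'; selection aborted",
         call. = FALSE)
  }
  c_hat <- fits[[global_name]]$dispersion
  if (floor_c_hat) c_hat <- max(1, c_hat)
  n <- fits[[1]]$n
  tab <- data.frame(
    model = names(fits),
    K = vapply(fits, function(f) f$K, integer(1)),
    QAICc = vapply(fits, function(f) qaicc(f, c_hat = c_hat), numeric(1)),
    stringsAsFactors = FALSE)
  tab$dQAICc <- tab$QAICc - min(tab$QAICc)
  # parsimony rule: Delta <= 2, fewest parameters, then lower QAICc,
  # then candidate order (row order in `tab` is candidate order)
  cand <- tab[tab$dQAICc <= 2, , drop = FALSE]
  cand <- cand[order(cand$K, cand$QAICc), , drop = FALSE]
  selected <- cand$model[1]
  tab <- tab[order(tab$QAICc), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(category = category, table = tab, selected = selected,
                 fits = fits, c_hat = c_hat,
                 c_hat_source = global_name, n = n),
            class = "prey_selection")
}

#' @export
print.prey_selection <- function(x, ...) {
  cat("prey_selection:", x$category,
      sprintf("(c-hat = %.3f from %s)\n", x$c_hat, x$c_hat_source))
  print(transform(x$table, QAICc = round(QAICc, 2),
                  dQAICc = round(dQAICc, 2)))
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' Predicted consumption proportion for a group
#'
#' Back-transforms the fitted log-odds for a species-by-stream group
#' (at a given fish length when the model uses length) and attaches a
#' 95% Wald interval computed on the linear-predictor scale with the
#' dispersion-scaled covariance, then mapped through the inverse
#' logit.
#'
#' @param fit a `prey_glm`.
#' @param species,stream group labels.
#' @param length_mm fish length in mm; required iff the model includes
#'   length.
#' @param z critical value for the interval (default 1.96, a 95%
#'   normal interval).
#' @return one-row data.frame: `category`, `species`, `stream`,
#'   `at_length_mm`, `estimate`, `ci_low`, `ci_high`.
#' @export
predict_proportion <- function(fit, species, stream, length_mm = NULL,
                               z = 1.96) {
  stopifnot(inherits(fit, "prey_glm"))
  uses_length <- "length" %in% fit$terms
  if (uses_length && is.null(length_mm)) {
    stop("missing covariate: model for '", fit$category,
         "' includes length; supply length_mm", call. = FALSE)
  }
  mf <- fit$glm$model
  nd <- data.frame(
    species = factor(species, levels = levels(mf$species) %||%
                       union("MW", species)),
    stream = factor(stream, levels = levels(mf$stream) %||%
                      union("Sheep", stream)))
  if (uses_length) nd$length <- length_mm
  pr <- stats::predict(fit$glm, newdata = nd, type = "link",
                       se.fit = TRUE)
  est <- stats::plogis(pr$fit)
  data.frame(category = fit$category, species = species, stream = stream,
             at_length_mm = if (uses_length) length_mm else NA_real_,
             estimate = unname(est),
             ci_low = unname(stats::plogis(pr$fit - z * pr$se.fit)),
             ci_high = unname(stats::plogis(pr$fit + z * pr$se.fit)),
             stringsAsFactors = FALSE)
}

#' Adjusted deviance explained
#'
#' \deqn{D^2_{adj} = 1 - \frac{n-1}{n-K_{reg}}
#'   \frac{\mathrm{residual\ deviance}}{\mathrm{null\ deviance}}}
#' with \eqn{K_{reg}} the number of regression coefficients — the
#' deviance analogue of adjusted \eqn{R^2}.  Zero for the
#' intercept-only model, approaching 1 as the model absorbs all
#' deviance.
#'
#' @param fit a `prey_glm`.
#' @param null_fit optional intercept-only `prey_glm` on the same
#'   fish; defaults to the null deviance recorded in `fit`.
#' @return the adjusted deviance explained.
#' @export
adjusted_deviance_explained <- function(fit, null_fit = NULL) {
  stopifnot(inherits(fit, "prey_glm"))
  null_dev <- if (is.null(null_fit)) fit$glm$null.deviance else
    null_fit$glm$deviance
  if (!is.finite(null_dev) || null_dev <= 0) {
    stop("degenerate error: null deviance is ", null_dev, call. = FALSE)
  }
  n <- fit$n
  k_reg <- fit$K - 1L
  1 - (n - 1) / (n - k_reg) * (fit$glm$deviance / null_dev)
}

#' Most commonly consumed prey categories
#'
#' Ranks categories by total item count across all non-empty fish.
#'
#' @param ds a [diet_dataset()].
#' @param n how many to return.
#' @param exclude labels to skip (pooled bins such as `"Other"` are
#'   not meaningful response categories).
#' @return character vector of category names, most consumed first.
#' @export
top_categories <- function(ds, n = 8, exclude = "Other") {
  stopifnot(inherits(ds, "diet_dataset"))
  totals <- colSums(ds$counts[!ds$fish$empty, , drop = FALSE])
  totals <- totals[setdiff(names(totals), exclude)]
  names(sort(totals, decreasing = TRUE))[seq_len(min(n, length(totals)))]
}
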