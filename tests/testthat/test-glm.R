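# a moderate simulated dataset reused across model tests
glm_test_ds <- function(seed = 21, n = 40) {
  p <- smith_sheep_preset()
  generate_dataset(recovery_specs(p, n_fish = n), p$effects,
                   seed = seed, categories = p$categories)
}

test_that("intercept-only fit equals the logit of the pooled proportion", {
  ds <- glm_test_ds()
  for (cat in c("Baetidae", "Oligochaeta", "Hydropsychidae")) {
    fit <- fit_prey_glm(ds, cat)
    keep <- !ds$fish$empty
    pooled <- sum(ds$counts[keep, cat]) / sum(ds$fish$total_items[keep])
    expect_equal(unname(coef(fit$glm)), qlogis(pooled),
                 tolerance = 1e-8)
  }
})

test_that("quasi-binomial point estimates equal the binomial fit", {
  ds <- glm_test_ds()
  frame <- dietoverlap:::glm_frame(ds, need_length = TRUE)
  frame$.prop <- frame$Baetidae / frame$total_items
  quasi <- fit_prey_glm(ds, "Baetidae", c("species", "stream", "length"))
  bin <- glm(.prop ~ species + stream + length, family = binomial(),
             weights = total_items, data = frame,
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(quasi$glm)), unname(coef(bin)),
               tolerance = 1e-6)
})

test_that("standard errors are the binomial SEs scaled by sqrt(c-hat)", {
  ds <- glm_test_ds()
  fit <- fit_prey_glm(ds, "Ephemerellidae", c("species", "stream"))
  frame <- dietoverlap:::glm_frame(ds)
  frame$.prop <- frame$Ephemerellidae / frame$total_items
  bin <- glm(.prop ~ species + stream, family = binomial(),
             weights = total_items, data = frame,
             control = glm.control(epsilon = 1e-12))
  se_bin <- summary(bin)$coefficients[, 2]
  expect_equal(unname(fit$coefficients[, 2]),
               unname(se_bin * sqrt(fit$dispersion)), tolerance = 1e-6)
  # quadrupling the dispersion doubles every interval half-width
  expect_equal(unname(se_bin * sqrt(4 * fit$dispersion)),
               unname(2 * fit$coefficients[, 2]), tolerance = 1e-6)
  # t statistics are estimate / SE
  expect_equal(fit$coefficients[, 3],
               fit$coefficients[, 1] / fit$coefficients[, 2],
               tolerance = 1e-8)
})

test_that("QAICc reduces to binomial AICc at c-hat 1 and orders by K", {
  ds <- glm_test_ds()
  fit <- fit_prey_glm(ds, "Baetidae", "stream")
  K <- fit$K
  n <- fit$n
  aicc <- -2 * fit$binomial_loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
  expect_equal(qaicc(fit, c_hat = 1), aicc, tolerance = 1e-12)
  # growing n shrinks the small-sample penalty monotonically
  qs <- vapply(c(20, 50, 200, 1e6), function(nn)
    qaicc(fit, c_hat = 1, n = nn), numeric(1))
  expect_true(all(diff(qs) < 0))
  # equal fit, more parameters -> larger QAICc
  fit2 <- fit_prey_glm(ds, "Baetidae", c("stream", "species"))
  penalty <- function(f) 2 * f$K + 2 * f$K * (f$K + 1) / (f$n - f$K - 1)
  expect_gt(penalty(fit2), penalty(fit))
  expect_error(qaicc(fit, n = fit$K + 1), "small-sample")
  expect_error(qaicc(fit, c_hat = 0), "positive")
})

test_that("a single candidate is selected with delta zero", {
  ds <- glm_test_ds()
  sel <- select_model(ds, "Baetidae", candidates = list(stream = "stream"))
  expect_equal(sel$selected, "stream")
  expect_equal(sel$table$dQAICc, 0)
})

test_that("selection applies the parsimony rule with a shared c-hat", {
  ds <- glm_test_ds(seed = 8, n = 60)
  sel <- select_model(ds, "Oligochaeta")
  expect_equal(sel$c_hat_source, "global")
  expect_gte(sel$c_hat, 1)
  expect_equal(min(sel$table$dQAICc), 0)
  expect_false(is.unsorted(sel$table$QAICc))
  # the selected model has the fewest parameters among Delta <= 2
  close <- sel$table[sel$table$dQAICc <= 2, ]
  expect_equal(sel$table$K[sel$table$model == sel$selected],
               min(close$K))
  # candidate order only matters through the documented tie-break
  sel_rev <- select_model(ds, "Oligochaeta",
                          candidates = rev(candidate_models()))
  expect_equal(sel_rev$selected, sel$selected)
})

test_that("degenerate responses are refused with a clear message", {
  counts <- rbind(c(0L, 5L), c(0L, 7L)) |> `colnames<-`(c("A", "B"))
  ds <- make_ds(counts)
  expect_error(fit_prey_glm(ds, "A"), "degenerate")
  expect_error(fit_prey_glm(ds, "B", "species:stream"), "main effects")
  expect_error(fit_prey_glm(ds, "B", "depth"), "unknown term")
})

test_that("predictions back-transform the linear predictor", {
  ds <- glm_test_ds()
  fit <- fit_prey_glm(ds, "Hydropsychidae", "stream")
  cf <- coef(fit$glm)
  pr <- predict_proportion(fit, "MW", "Smith")
  expect_equal(pr$estimate, plogis(cf[[1]] + cf[[2]]), tolerance = 1e-10)
  expect_true(pr$ci_low <= pr$estimate && pr$estimate <= pr$ci_high)
  pr0 <- predict_proportion(fit, "MW", "Sheep")
  expect_equal(pr0$estimate, plogis(cf[[1]]), tolerance = 1e-10)
  # length models demand a length
  fitl <- fit_prey_glm(ds, "Oligochaeta", c("species", "stream",
                                            "length"))
  expect_error(predict_proportion(fitl, "RB", "Sheep"),
               "missing covariate")
  prl <- predict_proportion(fitl, "RB", "Sheep", length_mm = 306)
  expect_equal(prl$estimate,
               plogis(sum(coef(fitl$glm) *
                            c(1, 1, 0, 306))), tolerance = 1e-10)
})

test_that("a zero linear predictor maps to one half", {
  expect_equal(plogis(0), 0.5)
  coefs <- data.frame(category = "X", term = "intercept", estimate = 0)
  expect_equal(predict_from_coefficients(coefs, "X"), 0.5)
})

test_that("adjusted deviance explained behaves at its boundaries", {
  ds <- glm_test_ds()
  null_fit <- fit_prey_glm(ds, "Baetidae")
  expect_equal(adjusted_deviance_explained(null_fit), 0)
  fit <- fit_prey_glm(ds, "Baetidae", "stream")
  d2 <- adjusted_deviance_explained(fit)
  expect_lte(d2, 1)
  expect_equal(d2, adjusted_deviance_explained(fit, null_fit),
               tolerance = 1e-10)
})

test_that("stronger generating effects explain more deviance", {
  base <- c(A = 0.3, B = 0.7)
  make <- function(effect) {
    specs <- list(group_spec("MW", "Sheep", 60, base, theta = 50),
                  group_spec("MW", "Smith", 60, base, theta = 50))
    generate_dataset(specs, effect_spec("A", stream_logit = effect),
                     seed = 11, fixed_total = 50)
  }
  d2 <- vapply(c(0, 2), function(e)
    adjusted_deviance_explained(fit_prey_glm(make(e), "A", "stream")),
    numeric(1))
  expect_gt(d2[2], d2[1])
})

test_that("fish lacking lengths are dropped only by length models", {
  counts <- matrix(c(3L, 4L, 5L, 2L, 1L, 6L), 3, 2,
                   dimnames = list(NULL, c("A", "B")))
  ds <- make_ds(counts, length_mm = c(300, NA, 250))
  fit0 <- fit_prey_glm(ds, "A")
  expect_equal(fit0$n, 3)
  expect_equal(fit0$n_dropped_no_length, 0L)
  fitl <- fit_prey_glm(ds, "A", "length")
  expect_equal(fitl$n, 2)
  expect_equal(fitl$n_dropped_no_length, 1L)
})
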