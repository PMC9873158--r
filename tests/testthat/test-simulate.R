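base_comp <- c(A = 0.5, B = 0.3, C = 0.2)

test_that("spec constructors validate their parameters", {
  expect_error(group_spec("MW", "Sheep", 5,
                          c(A = 0.5, B = 0.6)), "sum")
  expect_error(group_spec("MW", "Sheep", 5, base_comp, theta = 0),
               "theta")
  expect_error(group_spec("MW", "Sheep", 0, base_comp), "n_fish")
  expect_error(group_spec("MW", "Sheep", 5, unname(base_comp)),
               "named")
  expect_error(effect_spec("A", species_logit = Inf), "finite")
})

test_that("identical seeds give bit-identical datasets and CSV bytes", {
  spec <- group_spec("MW", "Sheep", 10, base_comp)
  d1 <- generate_dataset(spec, seed = 9)
  d2 <- generate_dataset(spec, seed = 9)
  expect_identical(d1, d2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_diet_csv(d1, f1); write_diet_csv(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  d3 <- generate_dataset(spec, seed = 10)
  expect_false(identical(d1$counts, d3$counts))
})

test_that("counts are multinomial-conserved", {
  p <- smith_sheep_preset()
  ds <- generate_dataset(p$specs, seed = 2, categories = p$categories)
  expect_identical(as.integer(rowSums(ds$counts)), ds$fish$total_items)
  expect_true(all(ds$counts >= 0))
})

test_that("exact-composition mode converges to the base composition", {
  spec <- group_spec("MW", "Sheep", 10, base_comp, theta = Inf)
  ds <- generate_dataset(spec, seed = 1, fixed_total = 10000)
  pooled <- colSums(ds$counts) / sum(ds$counts)
  expect_true(all(abs(pooled - base_comp) < 0.005))
})

test_that("identical generating compositions give overlap near 1", {
  specs <- list(group_spec("MW", "Sheep", 10, base_comp, theta = Inf),
                group_spec("RB", "Sheep", 10, base_comp, theta = Inf))
  ds <- generate_dataset(specs, seed = 1, fixed_total = 1000)
  om <- overlap_matrix(ds, pairs = list(c("MW:Sheep", "RB:Sheep")))
  expect_equal(om$overlap, 1.0, tolerance = 0.02)
})

test_that("the pooled composition estimator is unbiased without effects", {
  spec <- group_spec("MW", "Sheep", 5, base_comp, theta = Inf,
                     mean_items = 40, items_dispersion = 5)
  reps <- vapply(1:200, function(s) {
    ds <- generate_dataset(spec, seed = s)
    colSums(ds$counts) / sum(ds$counts)
  }, numeric(3))
  mc_se <- apply(reps, 1, sd) / sqrt(200)
  expect_true(all(abs(rowMeans(reps) - base_comp) < 3 * mc_se + 1e-12))
})

test_that("smaller theta gives more between-fish heterogeneity", {
  tv_dist <- function(theta) {
    spec <- group_spec("MW", "Sheep", 40, base_comp, theta = theta)
    ds <- generate_dataset(spec, seed = 77, fixed_total = 200)
    props <- ds$counts / rowSums(ds$counts)
    mean(apply(props, 1, function(p) sum(abs(p - base_comp)) / 2))
  }
  d <- vapply(c(1000, 10, 1), tv_dist, numeric(1))
  expect_true(d[1] < d[2] && d[2] < d[3])
})

test_that("covariate effects shift the affected share on the logit scale", {
  eff <- effect_spec("A", stream_logit = -1.5)
  specs <- list(group_spec("MW", "Sheep", 5, base_comp, theta = Inf),
                group_spec("MW", "Smith", 5, base_comp, theta = Inf))
  ds <- generate_dataset(specs, eff, seed = 4, fixed_total = 50000)
  sheep <- colSums(ds$counts[ds$fish$stream == "Sheep", ])
  smith <- colSums(ds$counts[ds$fish$stream == "Smith", ])
  expect_equal(unname(sheep["A"] / sum(sheep)), 0.5, tolerance = 0.01)
  expect_equal(unname(smith["A"] / sum(smith)),
               plogis(qlogis(0.5) - 1.5), tolerance = 0.01)
  # unaffected categories keep their relative proportions
  expect_equal(unname(smith["B"] / smith["C"]), 1.5, tolerance = 0.05)
})

test_that("the study preset encodes the field design", {
  p <- smith_sheep_preset()
  sizes <- vapply(p$specs, function(s) s$n_fish, integer(1))
  expect_equal(unname(sizes[c("MW_Smith", "RB_Smith", "MW_Sheep",
                              "RB_Sheep")]), c(11L, 6L, 20L, 20L))
  expect_equal(unname(p$specs$MW_Sheep$base_composition[
    "Brachycentridae"]), 0.251)
  expect_equal(unname(p$specs$RB_Sheep$base_composition[
    "Oligochaeta"]), 0.332)
  for (s in p$specs) {
    expect_lt(abs(sum(s$base_composition) - 1), 1e-9)
  }
  # effect signs: rainbow trout eat more Oligochaeta, fewer
  # Brachycentridae than whitefish
  eff <- p$effects
  names(eff) <- vapply(eff, function(e) e$category, character(1))
  expect_gt(eff$Oligochaeta$species_logit, 0)
  expect_lt(eff$Brachycentridae$species_logit, 0)
})
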