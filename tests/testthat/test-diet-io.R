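test_that("wide CSV reading builds a validated dataset", {
  path <- write_tiny_csv(withr::local_tempfile(fileext = ".csv"))
  ds <- read_diet_csv(path, schema = tiny_schema)
  expect_s3_class(ds, "diet_dataset")
  expect_equal(nrow(ds$fish), 3)
  expect_equal(colnames(ds$counts), c("Baetidae", "Oligochaeta"))
  expect_equal(ds$fish$total_items, c(4L, 2L, 2L))
  expect_false(any(ds$fish$empty))
  expect_equal(ds$fish$total_length_mm, c(310, 355, 290))
})

test_that("schema and validation errors name the offending column/cell", {
  path <- write_tiny_csv(withr::local_tempfile(fileext = ".csv"))
  expect_error(
    read_diet_csv(path, schema = list(fish_id = "nope",
                                      species = "species",
                                      stream = "stream")),
    "nope")
  bad <- write_tiny_csv(withr::local_tempfile(fileext = ".csv"),
                        baetidae = c(3L, -1L, 2L))
  expect_error(read_diet_csv(bad, schema = tiny_schema),
               "Baetidae")
  expect_error(read_diet_csv(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("unknown species/stream labels pass through with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(fish_id = "x", species = "Brown trout",
                   stream = "Smith", total_length_mm = 300, Baetidae = 2L)
  write.csv(df, path, row.names = FALSE)
  expect_warning(ds <- read_diet_csv(path), "Brown trout")
  expect_equal(ds$fish$species, "Brown trout")
})

test_that("empty stomachs are flagged and excluded from statistics", {
  ds <- make_ds(rbind(c(3L, 1L), c(0L, 0L), c(1L, 1L)) |>
                  `colnames<-`(c("A", "B")))
  expect_equal(sum(ds$fish$empty), 1)
  comp <- group_composition(ds, "MW", "Sheep")
  expect_equal(attr(comp, "n_fish"), 2)
  fs <- feeding_strategy(ds, "MW", "Sheep")
  expect_equal(attr(fs, "N"), 2)
  expect_equal(qc_report(ds)$n_empty[qc_report(ds)$group == "all"], 1)
})

test_that("write then read round-trips to an identical dataset", {
  p <- smith_sheep_preset()
  ds <- generate_dataset(p$specs, seed = 42, categories = p$categories)
  path <- withr::local_tempfile(fileext = ".csv")
  write_diet_csv(ds, path)
  back <- read_diet_csv(path, categories = p$categories)
  expect_equal(back$fish, ds$fish)
  expect_equal(back$counts, ds$counts)
  expect_equal(back$categories, ds$categories)
})

test_that("long-format reading matches the wide reader", {
  wide <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(wide)
  ds_wide <- read_diet_csv(wide, schema = tiny_schema)
  long <- withr::local_tempfile(fileext = ".csv")
  rows <- expand.grid(i = 1:3, cat = c("Baetidae", "Oligochaeta"),
                      stringsAsFactors = FALSE)
  df <- data.frame(fish_id = ds_wide$fish$fish_id[rows$i],
                   species = ds_wide$fish$species[rows$i],
                   stream = ds_wide$fish$stream[rows$i],
                   total_length_mm = ds_wide$fish$total_length_mm[rows$i],
                   category = rows$cat,
                   count = mapply(function(i, cc) ds_wide$counts[i, cc],
                                  rows$i, rows$cat))
  write.csv(df, long, row.names = FALSE)
  ds_long <- read_diet_long(long)
  expect_equal(ds_long$counts, ds_wide$counts)
  expect_equal(ds_long$fish, ds_wide$fish)
})

test_that("category labels are normalised, duplicates rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(fish_id = "x", species = "MW", stream = "Sheep",
                   check.names = FALSE)
  df[[" baetidae "]] <- 2L
  df[["oligochaeta"]] <- 1L
  write.csv(df, path, row.names = FALSE)
  ds <- read_diet_csv(path, schema = list(fish_id = "fish_id",
                                          species = "species",
                                          stream = "stream"))
  expect_setequal(colnames(ds$counts), c("Baetidae", "Oligochaeta"))
  expect_error(
    make_ds(matrix(1L, 1, 2, dimnames = list(NULL, c("A", "A")))),
    "duplicated")
})

test_that("taxonomy files read identically from CSV and YAML", {
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(category = c("Baetidae", "Oligochaeta"),
                       level = c("family", "class"),
                       parent_order = c("Ephemeroptera", NA)),
            csv, row.names = FALSE)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Baetidae:", "  level: family",
               "  parent_order: Ephemeroptera",
               "Oligochaeta:", "  level: class"), yml)
  expect_equal(read_taxonomy(csv), read_taxonomy(yml))
  expect_equal(read_taxonomy(csv)$parent_order, c("Ephemeroptera", NA))
})
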