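# quick dataset builder: counts is a matrix (fish x category), groups
# default to one MW/Sheep group
make_ds <- function(counts, species = NULL, stream = NULL,
                    length_mm = NULL, categories = NULL) {
  n <- nrow(counts)
  fish <- data.frame(
    fish_id = sprintf("f%02d", seq_len(n)),
    species = species %||% rep("MW", n),
    stream = stream %||% rep("Sheep", n),
    total_length_mm = length_mm %||% rep(NA_real_, n),
    stringsAsFactors = FALSE)
  diet_dataset(fish, counts, categories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# three-fish, two-category wide CSV fixture
write_tiny_csv <- function(path, baetidae = c(3L, 0L, 2L)) {
  df <- data.frame(id = c("a", "b", "c"),
                   species = c("MW", "MW", "RB"),
                   stream = c("Smith", "Smith", "Smith"),
                   TL_mm = c(310, 355, 290),
                   Baetidae = baetidae,
                   Oligochaeta = c(1L, 2L, 0L))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

tiny_schema <- list(fish_id = "id", species = "species",
                    stream = "stream", length = "TL_mm")

# random small dataset inside the oracle envelope:
# <= 5 fish x <= 4 categories, counts <= 3
random_small_ds <- function() {
  n <- sample(1:5, 1)
  k <- sample(2:4, 1)
  counts <- matrix(sample(0:3, n * k, replace = TRUE), n, k,
                   dimnames = list(NULL, paste0("C", seq_len(k))))
  # ensure at least one non-empty fish
  if (all(counts == 0)) counts[1, 1] <- 1L
  make_ds(counts)
}

# ---- independent naive-loop oracles -------------------------------

naive_pianka <- function(p, q) {
  num <- 0; sp <- 0; sq <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * q[i]
    sp <- sp + p[i]^2
    sq <- sq + q[i]^2
  }
  num / sqrt(sp * sq)
}

naive_feeding_strategy <- function(counts) {
  nonempty <- rowSums(counts) > 0
  counts <- counts[nonempty, , drop = FALSE]
  N <- nrow(counts)
  out <- list()
  for (j in seq_len(ncol(counts))) {
    Ni <- 0; Si <- 0; Sti <- 0
    for (f in seq_len(nrow(counts))) {
      if (counts[f, j] > 0) {
        Ni <- Ni + 1
        Si <- Si + counts[f, j]
        Sti <- Sti + sum(counts[f, ])
      }
    }
    if (Ni > 0) {
      out[[colnames(counts)[j]]] <-
        c(N_i = Ni, S_i = Si, S_ti = Sti, F_i = Ni / N, P_i = Si / Sti)
    }
  }
  out
}

naive_pooled_composition <- function(counts) {
  nonempty <- rowSums(counts) > 0
  tot <- colSums(counts[nonempty, , drop = FALSE])
  tot / sum(tot)
}
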