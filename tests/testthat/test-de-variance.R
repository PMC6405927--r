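make_partition_study <- function(n_tx, pop_shift = 0, geno_sd = 0,
                                 noise_sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    pops <- c("G", "J", "LC", "M")
    meta <- tidyr::expand_grid(population = pops, genotype_i = 1:4,
                               replicate = 1:3) |>
      dplyr::mutate(genotype = paste0(population, genotype_i),
                    sample = paste(population, genotype_i, replicate,
                                   sep = "_"))
    N <- nrow(meta)
    y <- matrix(rnorm(n_tx * N, 8, noise_sd), n_tx, N)
    if (pop_shift != 0) {
      y[, meta$population == "G"] <- y[, meta$population == "G"] + pop_shift
    }
    if (geno_sd > 0) {
      g_eff <- matrix(rnorm(n_tx * 16, 0, geno_sd), n_tx, 16)
      y <- y + g_eff[, match(meta$genotype, unique(meta$genotype))]
    }
    counts <- matrix(as.integer(round(2^y)), n_tx, N,
                     dimnames = list(sprintf("t%04d", seq_len(n_tx)),
                                     meta$sample))
    list(counts = counts, meta = meta)
  })
}

test_that("a pure population shift is attributed to the population factor", {
  st <- make_partition_study(150, pop_shift = 2, noise_sd = 0.8, seed = 2)
  vp <- partition_variance(st$counts, st$meta, normalized = TRUE)
  expect_gt(mean(vp$category %in% c("population-only", "both")), 0.9)
  expect_gt(mean(vp$category == "population-only"), 0.7)
})

test_that("pure genotype structure is attributed to the genotype factor", {
  st <- make_partition_study(150, geno_sd = 2, noise_sd = 0.3, seed = 3)
  vp <- partition_variance(st$counts, st$meta, normalized = TRUE)
  expect_gt(mean(vp$category %in% c("genotype-only", "both")), 0.9)
  expect_gt(mean(vp$category == "genotype-only"), 0.7)
})

test_that("pure noise lands almost entirely in 'neither'", {
  st <- make_partition_study(800, seed = 4)
  vp <- partition_variance(st$counts, st$meta, normalized = TRUE)
  expect_gt(mean(vp$category == "neither"), 0.9)
})

test_that("nested design prerequisites are enforced", {
  st <- make_partition_study(5, seed = 5)
  bad_meta <- st$meta
  bad_meta$genotype[1] <- bad_meta$genotype[40]   # genotype in two pops
  expect_error(partition_variance(st$counts, bad_meta, normalized = TRUE),
               "nested")
  single <- st$meta$replicate == 1
  expect_error(partition_variance(st$counts[, single],
                                  st$meta[single, ], normalized = TRUE),
               ">= 2 replicates")
})
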