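test_that("size factors follow the median-of-ratios contract", {
  m <- matrix(rep(c(10, 40, 100), 3), ncol = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  expect_equal(unname(compute_size_factors(m)), rep(1, 3))

  m2 <- cbind(s1 = c(10, 40, 100), s2 = c(20, 80, 200))
  expect_equal(unname(compute_size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # an all-zero transcript is excluded from the reference
  m3 <- rbind(m2, zero = c(0, 0))
  expect_equal(compute_size_factors(m3), compute_size_factors(m2))

  # equivariance: scaling one sample's column scales its factor by the
  # same constant, up to the global reference scale (ratios are exact)
  tc <- tiny_counts(n_tx = 30)
  sf <- compute_size_factors(tc$counts)
  scaled <- tc$counts
  scaled[, 3] <- scaled[, 3] * 4
  sf2 <- compute_size_factors(scaled)
  expect_equal(sf2[3] / sf2[1], 4 * sf[3] / sf[1], tolerance = 1e-12)
  expect_equal(sf2[-3] / sf2[1], sf[-3] / sf[1], tolerance = 1e-12)

  expect_error(compute_size_factors(matrix(c(0, 1, 1, 0), 2)),
               "all-positive")
})

test_that("size factors agree with the reference DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  tc <- tiny_counts(n_tx = 50, seed = 3)
  expect_equal(unname(compute_size_factors(tc$counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(tc$counts)),
               tolerance = 1e-8)
})

test_that("moment dispersion hits the floor for Poisson data and recovers
           a planted NB dispersion", {
  withr::with_seed(5, {
    groups <- rep(c("G", "J", "LC", "M"), each = 18)
    mu <- 200
    pois <- matrix(rpois(500 * 72, mu), nrow = 500)
    colnames(pois) <- paste0(groups, "_", seq_len(72))
    phi_p <- fit_dispersion(pois, groups, size_factors = rep(1, 72))
    expect_lt(median(phi_p$dispersion), 0.02)

    nb <- matrix(rnbinom(500 * 72, mu = mu, size = 1 / 0.5), nrow = 500)
    colnames(nb) <- colnames(pois)
    phi_nb <- fit_dispersion(nb, groups, size_factors = rep(1, 72))
    expect_gt(median(phi_nb$dispersion), 0.3)
    expect_lt(median(phi_nb$dispersion), 0.7)
  })

  zero <- rbind(matrix(5, 3, 8), 0)
  colnames(zero) <- paste0("s", 1:8)
  res <- fit_dispersion(zero, rep(c("A", "B"), each = 4),
                        size_factors = rep(1, 8))
  expect_true(res$all_zero[4])
  expect_true(is.na(res$dispersion[4]))
})

test_that("contrasts are null for identical groups and BH-consistent", {
  tc <- tiny_counts(n_tx = 40, seed = 7)
  # force two populations to share identical counts
  counts <- tc$counts
  counts[, tc$meta$population == "J"] <- counts[, tc$meta$population == "G"]
  ct <- pairwise_contrasts(counts, tc$meta, size_factors = rep(1, 16))
  gj <- dplyr::filter(ct, pair == "G_vs_J")
  expect_equal(gj$log2fc, rep(0, 40))
  expect_true(all(gj$p > 0.99))
  # adjusted p-values are the BH step-up of the raw ones within each pair
  for (pr in unique(ct$pair)) {
    sub <- dplyr::filter(ct, pair == pr)
    expect_equal(sub$p_adj, p.adjust(sub$p, "BH"))
  }
  expect_true(all(ct$p_adj >= ct$p - 1e-12, na.rm = TRUE))
})

test_that("log2FC is antisymmetric under relabelling of the pair", {
  tc <- tiny_counts(n_tx = 25, seed = 8)
  ct1 <- pairwise_contrasts(tc$counts, tc$meta)
  meta_swap <- tc$meta
  lv <- levels(meta_swap$population)
  # swap the G and J labels; the G_vs_J contrast must flip sign
  pop_chr <- as.character(meta_swap$population)
  pop_chr[pop_chr == "G"] <- "tmp"
  pop_chr[pop_chr == "J"] <- "G"
  pop_chr[pop_chr == "tmp"] <- "J"
  meta_swap$population <- factor(pop_chr, levels = lv)
  ct2 <- pairwise_contrasts(tc$counts, meta_swap)
  a <- dplyr::filter(ct1, pair == "G_vs_J") |> dplyr::arrange(transcript)
  b <- dplyr::filter(ct2, pair == "G_vs_J") |> dplyr::arrange(transcript)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("the population-exclusive sign rule assigns and partitions", {
  pairs <- c("G_vs_J", "G_vs_LC", "G_vs_M", "J_vs_LC", "J_vs_M", "LC_vs_M")
  mk_row <- function(tx, fc, padj) {
    tibble::tibble(transcript = tx, pair = pairs, log2fc = fc,
                   se = 0.1, stat = fc / 0.1, p = padj, p_adj = padj)
  }
  ct <- dplyr::bind_rows(
    # clean Pop.G pattern: up vs J, LC, M; other pairs null
    mk_row("tx_g", c(2, 2, 2, 0, 0, 0), c(0.01, 0.01, 0.01, 1, 1, 1)),
    # significant in only two of the three G comparisons
    mk_row("tx_partial", c(2, 2, 2, 0, 0, 0), c(0.01, 0.01, 0.2, 1, 1, 1)),
    # boundary: p_adj exactly 0.05 still counts
    mk_row("tx_edge", c(2, 2, 2, 0, 0, 0), c(0.05, 0.05, 0.05, 1, 1, 1)),
    # Pop.M pattern: M upregulated means negative FC in *_vs_M
    mk_row("tx_m", c(0, 0, -2, 0, -2, -2), c(1, 1, 0.01, 1, 0.01, 0.01))
  )
  det <- assign_population_dets(ct)
  expect_equal(det$det_population[det$transcript == "tx_g"], "G")
  expect_equal(det$det_population[det$transcript == "tx_partial"], "nonDET")
  expect_equal(det$det_population[det$transcript == "tx_edge"], "G")
  expect_equal(det$det_population[det$transcript == "tx_m"], "M")
})

test_that("DET sets partition the transcriptome on simulated data", {
  cfg <- sim_config(n_transcripts = 300, frac_de = 0.2, seed = 14)
  sim <- simulate_counts(cfg)
  det <- assign_population_dets(pairwise_contrasts(sim$counts, sim$meta))
  expect_equal(nrow(det), 300)
  expect_equal(sum(table(det$det_population)), 300)
  expect_false(any(duplicated(det$transcript)))
})
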