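test_that("genotype means average replicates and transform as documented", {
  tc <- tiny_counts(n_tx = 4, seed = 2)
  gm <- summarize_genotype_means(tc$counts, tc$meta,
                                 size_factors = rep(1, ncol(tc$counts)))
  # identical replicates: mean equals the replicate value
  counts <- tc$counts
  counts[, tc$meta$replicate == 2] <- counts[, tc$meta$replicate == 1]
  gm2 <- summarize_genotype_means(counts, tc$meta,
                                  size_factors = rep(1, ncol(counts)))
  first_rep <- counts[, tc$meta$replicate == 1]
  expect_equal(sort(gm2$mean), sort(as.numeric(first_rep)))
  expect_equal(gm$log2_mean, log2(gm$mean + 1))
  # order invariance of the input columns
  perm <- sample(ncol(tc$counts))
  gm3 <- summarize_genotype_means(tc$counts[, perm], tc$meta[perm, ],
                                  size_factors = rep(1, ncol(tc$counts)))
  expect_equal(dplyr::arrange(gm3, transcript, genotype),
               dplyr::arrange(gm, transcript, genotype))
})

test_that("H is approximately uniform under the drift null", {
  theta <- c(0.1, 0.2, 0.3, 0.4)
  sim <- simulate_genotype_means(theta, n_transcripts = 400, seed = 5)
  ht <- h_test(sim$genotype_means, diag(theta), seed = 6)
  expect_true(all(ht$h >= 0 & ht$h <= 1))
  expect_lt(abs(mean(ht$h) - 0.5), 0.05)
  expect_gt(mean(ht$h >= 0.95), 0.01)
  expect_lt(mean(ht$h >= 0.95), 0.10)
})

test_that("a strong single-population shift is flagged with high power and
           H grows monotonically with the shift", {
  theta <- c(0.1, 0.2, 0.3, 0.4)
  base_shift <- 5 * sqrt(2 * max(theta) * 0.04)
  sim <- simulate_genotype_means(theta, n_transcripts = 120,
                                 frac_shifted = 1, shift = base_shift,
                                 seed = 7)
  ht <- h_test(sim$genotype_means, diag(theta), seed = 8)
  expect_gt(mean(ht$selected), 0.9)

  mean_h <- vapply(c(0, 0.5, 1, 2) * base_shift, function(s) {
    simp <- simulate_genotype_means(theta, n_transcripts = 80,
                                    frac_shifted = 1, shift = s, seed = 9)
    mean(h_test(simp$genotype_means, diag(theta), seed = 10)$h)
  }, numeric(1))
  expect_true(all(diff(mean_h) > -0.02))   # non-decreasing up to MC noise
  expect_gt(mean_h[4] - mean_h[1], 0.3)
})

test_that("H test accepts a coancestry posterior and stays reproducible", {
  cfg <- sim_config(n_marker_loci = 20, seed = 33)
  post <- estimate_coancestry(simulate_markers(cfg)$markers,
                              n_iter = 2000, burn_in = 400, thin = 20,
                              seed = 3)
  sim <- simulate_genotype_means(colMeans(post$theta_draws),
                                 n_transcripts = 50, seed = 11)
  h1 <- h_test(sim$genotype_means, post, seed = 12)
  h2 <- h_test(sim$genotype_means, post, seed = 12)
  expect_equal(h1$h, h2$h)
  g <- glance(h1)
  expect_equal(g$n_transcripts, 50)
})

test_that("degenerate inputs are caught", {
  theta <- c(0.1, 0.2, 0.3, 0.4)
  sim <- simulate_genotype_means(theta, n_transcripts = 3, seed = 13)
  one_pop <- dplyr::filter(sim$genotype_means, population == "G")
  expect_error(h_test(one_pop, diag(1) * 0.1, seed = 1),
               "at least two populations")
  # zero-variance transcript is flagged, not scored
  flat <- sim$genotype_means
  flat$log2_mean[flat$transcript == "t00001"] <- 5
  ht <- h_test(flat, diag(theta), seed = 2)
  expect_true(is.na(ht$h[ht$transcript == "t00001"]))

  expect_identical(classify_selection(c(0.96, 0.95, 0.5)),
                   c(TRUE, TRUE, FALSE))
  expect_error(classify_selection(1.2))
})
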