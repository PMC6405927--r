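test_that("hard filters follow the QD/FS/cluster rules", {
  v <- tibble::tibble(
    transcript = "t1",
    pos = c(10L, 300L, 600L, 900L),
    qd = c(1.5, 2.0, 35, NA),
    fs = c(1, 30.0, 31.0, 2)
  )
  out <- filter_variants(v)
  expect_false(out$pass[out$pos == 10])     # QD 1.5 < 2 fails
  expect_true(out$pass[out$pos == 300])     # QD exactly 2, FS exactly 30 pass
  expect_false(out$pass[out$pos == 600])    # FS 31 > 30 fails
  expect_match(out$fail_reason[out$pos == 900], "missing-annotation")

  cl <- tibble::tibble(transcript = "t1", pos = c(100L, 110L, 130L),
                       qd = 10, fs = 1)
  expect_true(all(!filter_variants(cl)$pass))
  expect_true(all(grepl("snp-cluster",
                        filter_variants(cl)$fail_reason)))
  sp <- tibble::tibble(transcript = "t1", pos = c(100L, 150L, 200L),
                       qd = 10, fs = 1)
  expect_true(all(filter_variants(sp)$pass))
})

test_that("cluster flags match an exhaustive window scan and are
           order-independent", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      pos <- sort(sample.int(500, 25))
      v <- tibble::tibble(transcript = "tx", pos = pos, qd = 10, fs = 1)
      got <- filter_variants(v)
      expect_identical(!got$pass, oracle_snp_cluster(pos),
                       info = paste("rep", rep))
      # shuffled input gives identical flags after sorting
      shuf <- v[sample(nrow(v)), ]
      expect_identical(filter_variants(shuf), got)
      # idempotence
      expect_identical(filter_variants(got)[names(got)], got)
    }
  })
})

test_that("biallelic selection drops multiallelic sites and indels", {
  v <- tibble::tibble(
    transcript = "t", pos = 1:4,
    ref = c("A", "A", "A", "AT"),
    alt = c("T", "T,G", "AT", "A"),
    qd = 5, fs = 1
  )
  out <- select_biallelic(v)
  expect_equal(out$pos, 1L)
})

test_that("greedy LD pruning matches the exhaustive trace", {
  # constructed A-B r2 = 1 case: duplicate column dropped
  d <- cbind(a = c(0, 1, 2, 1, 0, 2), b = c(0, 1, 2, 1, 0, 2),
             c = c(1, 0, 1, 2, 1, 1))   # uncorrelated with a
  kept <- ld_prune(d, rep("t1", 3), 1:3, r2_max = 0.2)
  expect_equal(kept, c(1L, 3L))

  withr::with_seed(9, {
    for (rep in 1:8) {
      n <- 30
      base <- matrix(rbinom(n * 4, 2, 0.4), n, 4)
      # correlated companions plus noise columns
      d <- cbind(base,
                 base + matrix(rbinom(n * 4, 1, 0.2), n, 4),
                 matrix(rbinom(n * 4, 2, 0.5), n, 4))
      d <- pmin(d, 2)
      tx <- rep(c("t1", "t2"), each = 6)
      pos <- rep(1:6, 2)
      expect_identical(ld_prune(d, tx, pos, r2_max = 0.2),
                       oracle_ld_prune(d, tx, pos, r2_max = 0.2))
    }
  })

  # zero-variance SNP retained trivially
  dz <- cbind(rep(1, 6), c(0, 1, 2, 0, 1, 2))
  expect_equal(ld_prune(dz, c("t", "t"), 1:2), c(1L, 2L))
})

test_that("genotype PCA separates fixed populations on PC1", {
  n_snp <- 80
  pop1 <- matrix(0, 6, n_snp)
  pop2 <- matrix(2, 6, n_snp)
  d <- rbind(pop1, pop2)
  rownames(d) <- paste0("s", 1:12)
  res <- genotype_pca(d, n_pc = 3)
  expect_gt(res$var_explained[1], 0.99)
  pc1 <- res$scores$PC1
  expect_true(all(sign(pc1[1:6]) != sign(pc1[7:12])))
  # identical samples give zero eigenvalues
  same <- matrix(1, 5, 20)
  expect_lt(max(genotype_pca(same)$eigenvalues), 1e-12)
})

test_that("dosage extraction reads phased genotypes", {
  v <- tibble::tibble(transcript = "t", pos = 1:2, ref = "A", alt = "T",
                      qd = 5, fs = 1,
                      s1 = c("0|0", "1|1"), s2 = c("0|1", "1|0"))
  d <- popadapt:::dosage_matrix(v)
  expect_identical(d, matrix(c(0, 2, 1, 1), 2, 2, byrow = TRUE,
                             dimnames = list(c("s1", "s2"), NULL)))
})
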