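test_that("Weir-Cockerham FST hits its boundary cases", {
  # two populations fixed for alternative alleles
  fixed <- wc_fst(rbind(40, 0), rbind(40, 40))
  expect_equal(fixed$fst, 1)
  # identical frequencies: near zero, possibly slightly negative
  same <- wc_fst(rbind(20, 20), rbind(40, 40))
  expect_lt(abs(same$fst), 0.05)
  # monomorphic SNP excluded
  mono <- wc_fst(rbind(0, 0), rbind(40, 40))
  expect_true(is.na(mono$fst))
})

test_that("FST equals the independent ANOVA mean-square evaluation", {
  toy <- rbind(c(32, 10), c(8, 12))       # p = (0.8, 0.2) and (0.25, 0.3)
  n <- rbind(c(40, 40), c(40, 40))
  got <- wc_fst(toy, n)$fst
  want <- oracle_wc_fst_anova(toy, n)
  expect_equal(got, want, tolerance = 1e-12)

  withr::with_seed(21, {
    for (rep in 1:10) {
      r <- sample(2:5, 1)
      nc <- matrix(sample(20:60, r), r, 6)
      p <- matrix(runif(r * 6, 0.05, 0.95), r, 6)
      ac <- matrix(rbinom(r * 6, as.vector(nc), as.vector(p)), r, 6)
      keep <- colSums(ac) > 0 & colSums(ac) < colSums(nc)
      expect_equal(wc_fst(ac, nc)$fst[keep],
                   oracle_wc_fst_anova(ac, nc)[keep], tolerance = 1e-10)
    }
  })
})

test_that("FST never exceeds 1 and pooled identical populations sit at 0", {
  withr::with_seed(22, {
    ac <- replicate(300, popadapt:::sim_island_snp(4, 12, 2))
    res <- wc_fst(ac, 12)
    expect_true(all(res$fst <= 1 + 1e-12, na.rm = TRUE))
    # same draws assigned to both "populations": the estimator sits at its
    # known small negative value -1/(nc - 1), near zero from below
    p <- rbinom(200, 40, 0.5)
    same <- wc_fst(rbind(p, p), matrix(40, 2, 200))
    expect_lt(mean(same$fst, na.rm = TRUE), 0.01)
    expect_gt(mean(same$fst, na.rm = TRUE), -0.05)
  })
})

test_that("inbreeding coefficient follows its defining ratio", {
  # observed homozygosity equal to expected: F = 0
  d <- rbind(s1 = c(0, 2, 1, 1), s2 = c(1, 1, 0, 2))
  freqs <- colMeans(d) / 2
  n_chrom <- rep(4, 4)
  e_hom <- sum(1 - 2 * freqs * (1 - freqs) * n_chrom / (n_chrom - 1))
  res <- inbreeding_coefficient(d, freqs = freqs, n_chrom = n_chrom)
  expect_equal(res$f, (res$o_hom - e_hom) / (res$n_sites - e_hom))

  # fully homozygous sample at polymorphic sites: F = 1
  hom <- rbind(a = c(0, 2, 0, 2), b = c(1, 1, 1, 1))
  res2 <- inbreeding_coefficient(hom, freqs = rep(0.5, 4),
                                 n_chrom = rep(1000, 4))
  expect_equal(res2$f[1], 1, tolerance = 1e-3)

  # Hardy-Weinberg genotypes: mean F near zero
  withr::with_seed(23, {
    L <- 2000
    p <- runif(L, 0.1, 0.9)
    d_hw <- t(replicate(20, rbinom(L, 2, p)))
    rownames(d_hw) <- paste0("s", 1:20)
    res3 <- inbreeding_coefficient(d_hw)
    expect_lt(abs(mean(res3$f)), 0.05)
  })
})
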