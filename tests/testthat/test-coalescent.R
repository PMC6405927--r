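test_that("coalescent trees are well formed", {
  withr::with_seed(1, {
    tree <- sim_coal_tree(10)
    expect_equal(tree$n, 10)
    expect_equal(sum(tree$parent == 0), 1)       # single root
    has_parent <- tree$parent > 0
    expect_true(all(tree$time[tree$parent[has_parent]] >=
                      tree$time[has_parent]))
    expect_true(all(tree$time[seq_len(10)] == 0))
  })
})

test_that("segregating sites match the Watterson expectation under
           constant size", {
  withr::with_seed(2, {
    n <- 15
    theta_w <- 4
    s <- replicate(400, ncol(sim_locus(n, theta_w)))
    expect_equal(mean(s), theta_w * sum(1 / seq_len(n - 1)),
                 tolerance = 0.08)
  })
})

test_that("zero mutation rate yields monomorphic loci", {
  withr::with_seed(3, {
    hap <- sim_locus(8, 0)
    expect_equal(ncol(hap), 0)
    expect_true(tajimas_d(hap) |> dplyr::pull(d) |> is.na())
  })
})

test_that("demographic scenarios skew the site-frequency spectrum in the
           expected directions", {
  withr::with_seed(4, {
    d_const <- replicate(300, tajimas_d(sim_locus(20, 5, "constant"))$d)
    d_growth <- replicate(250,
                          tajimas_d(sim_locus(20, 5, "growth",
                                              growth_rate = 20))$d)
    d_struct <- replicate(250,
                          tajimas_d(sim_locus(20, 5, "structured",
                                              migration_rate = 0.05))$d)
    expect_lt(abs(mean(d_const, na.rm = TRUE)), 0.25)
    expect_lt(mean(d_growth, na.rm = TRUE), -0.3)
    expect_gt(mean(d_struct, na.rm = TRUE), 0.3)
  })
})

test_that("structured models require migration and growth a single deme", {
  expect_error(sim_coal_tree(c(5, 5), migration_rate = 0), "migration")
  expect_error(sim_coal_tree(c(5, 5), migration_rate = 1, growth_rate = 2),
               "single deme")
  expect_error(sim_locus(10, 1, "warp"), "unknown scenario")
})

test_that("haplotype simulation emits consistent VCF-ready variant records", {
  cfg <- sim_config(n_transcripts = 4, seed = 6)
  hs <- simulate_haplotypes(cfg)
  expect_equal(nrow(hs$haplotypes), 4 * 4)
  expect_identical(simulate_haplotypes(cfg), hs)   # deterministic
  v <- hs$variants
  expect_true(all(v$ref != v$alt))
  expect_true(all(v$qd > 0))
  # positions strictly increasing within transcript
  by_tx <- split(v$pos, v$transcript)
  expect_true(all(vapply(by_tx, function(p) all(diff(p) > 0), TRUE)))
  # phased diploid genotypes
  gt_cols <- setdiff(names(v), c("transcript", "pos", "ref", "alt",
                                 "qd", "fs"))
  expect_true(all(grepl("^[01]\\|[01]$", as.matrix(v[gt_cols]))))
})
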