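test_that("cluster co-occurrence categories follow the DET populations", {
  clusters <- tibble::tibble(
    cluster = c("C1", "C1", "C2", "C2", "C3"),
    transcript = c("t1", "t2", "t3", "t4", "t5")
  )
  dets <- tibble::tibble(
    transcript = c("t1", "t2", "t3", "t4", "t6"),
    det_population = c("G", "J", "G", "nonDET", "LC")
  )
  res <- categorize_det_clusters(clusters, dets)
  cat_of <- function(tx) {
    res$categories$category[res$categories$transcript == tx]
  }
  expect_equal(cat_of("t1"), "2Pop")
  expect_equal(cat_of("t2"), "2Pop")
  expect_equal(cat_of("t3"), "1Pop")     # partner is non-DET
  expect_equal(cat_of("t6"), "no-cluster")
  expect_equal(res$multi_pop_clusters, "C1")

  dup <- dplyr::bind_rows(clusters,
                          tibble::tibble(cluster = "C9", transcript = "t1"))
  expect_error(categorize_det_clusters(dup, dets), "partition")
})

test_that("protein-guided alignment handles identity, indels and rejects", {
  cds <- "ATGGCTGCTAAATTTGGTCAT"         # MAAKFGH
  aln <- align_pair_protein_guided(cds, cds)
  expect_identical(aln$status, "ok")
  expect_identical(aln$aln_a, cds)
  expect_identical(aln$aln_b, cds)

  # one inserted codon appears as a single in-frame 3-nt gap
  ins <- "ATGGCTGACGCTAAATTTGGTCAT"      # MADAKFGH
  aln2 <- align_pair_protein_guided(cds, ins)
  expect_identical(aln2$status, "ok")
  expect_equal(nchar(aln2$aln_a), nchar(ins))
  expect_match(aln2$aln_a, "---")
  expect_equal(gsub("-", "", aln2$aln_a), cds)

  expect_identical(
    align_pair_protein_guided(substr(cds, 1, 20), cds)$reason,
    "length-not-codon-multiple"
  )
  stop_cds <- "ATGGCTTAAAAATTTGGTCAT"    # internal TAA
  expect_identical(align_pair_protein_guided(stop_cds, cds)$reason,
                   "internal-stop")
})

test_that("K2P distances match the closed forms and their limits", {
  expect_equal(k2p_distance("ACGT", "ACGT")$d, 0)
  # 20 comparable sites, 2 transitions, 1 transversion: P = .1, Q = .05
  a <- "AAAAACCCCCGGGGGTTTTT"
  b <- "GAAAATCCCCGGGGGTTTTA"   # A>G transition, C>T transition, T>A transv.
  k <- k2p_distance(a, b)
  expect_equal(k$p, 0.1)
  expect_equal(k$q, 0.05)
  expect_equal(k$d, -0.5 * log(0.75) - 0.25 * log(0.90), tolerance = 1e-12)
  # gamma variant converges to the log form as alpha grows
  kg <- k2p_distance(a, b, alpha = 1e6)
  expect_equal(kg$d, k$d, tolerance = 1e-4)
  # symmetry
  expect_equal(k2p_distance(b, a)$d, k$d, tolerance = 1e-15)
  # saturation: 1 - 2P - Q <= 0 leaves d undefined
  sat <- k2p_distance("AAAA", "GGGG")
  expect_true(is.na(sat$d))
})

test_that("K2P agrees with the reference phylogenetics implementation", {
  skip_if_not_installed("ape")
  withr::with_seed(41, {
    for (rep in 1:10) {
      L <- 300
      a <- sample(c("a", "c", "g", "t"), L, replace = TRUE)
      b <- a
      mut <- runif(L) < 0.15
      b[mut] <- sample(c("a", "c", "g", "t"), sum(mut), replace = TRUE)
      m <- rbind(a, b)
      want <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
      got <- k2p_distance(paste(a, collapse = ""),
                          paste(b, collapse = ""))$d
      expect_equal(got, want, tolerance = 1e-10)
      want_g <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                                         gamma = 1))
      got_g <- k2p_distance(paste(a, collapse = ""),
                            paste(b, collapse = ""), alpha = 1)$d
      expect_equal(got_g, want_g, tolerance = 1e-10)
    }
  })
})

test_that("divergence classification applies the cutoff and propagates
           undefined", {
  expect_identical(classify_divergence(c(0.5, 3.0, NA)),
                   c("inparalog_or_isoform", "putative_misassembly",
                     "undefined"))
  expect_identical(classify_divergence(2), "putative_misassembly")
  expect_identical(classify_divergence(1.999), "inparalog_or_isoform")
})

test_that("the pairwise screen walks clusters and records skip reasons", {
  fasta <- c(t1 = "ATGGCTGCTAAATTTGGTCAT",
             t2 = "ATGGCTGCTAAATTTGGTCAC",
             t3 = "ATGGCTTAAAAATTTGGTCAT")
  clusters <- tibble::tibble(cluster = c("C1", "C1", "C1"),
                             transcript = c("t1", "t2", "t3"))
  dv <- pairwise_divergence(fasta, clusters)
  expect_equal(nrow(dv), 3)
  ok <- dv[dv$transcript_a == "t1" & dv$transcript_b == "t2", ]
  expect_equal(ok$class, "inparalog_or_isoform")
  bad <- dv[dv$transcript_b == "t3", ]
  expect_true(all(bad$class == "undefined"))
  expect_true(all(bad$reason == "internal-stop"))
})
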