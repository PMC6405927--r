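test_that("Tajima flow labels cover the node taxonomy", {
  sig_neg <- c(-2, -1.8, -2.1, -1.9)
  sig_p <- rep(0.01, 4)
  expect_equal(tajima_flow_label(sig_neg, sig_p), "AllNeg")
  expect_equal(tajima_flow_label(-sig_neg, sig_p), "AllPos")
  expect_equal(tajima_flow_label(c(1, 1, -1, -1), rep(0.5, 4)),
               "AllNonSig")
  expect_equal(tajima_flow_label(c(2, 2, 1, 1), c(0.01, 0.01, 0.5, 0.5)),
               "PosNonsig")
  expect_equal(tajima_flow_label(c(-2, -2, 1, 1), c(0.01, 0.01, 0.5, 0.5)),
               "NegNonsig")
  expect_equal(tajima_flow_label(c(-2, 2, 2, -2), rep(0.01, 4)), "PosNeg")
  expect_equal(tajima_flow_label(c(-2, 2, 2, 1), c(0.01, 0.01, 0.01, 0.5)),
               "PosNegNonsig")
  # undefined D counts as nonsignificant; all-undefined is the catch-all
  expect_equal(tajima_flow_label(c(NA, -2, -2, -2), c(NA, 0.01, 0.01, 0.01)),
               "NegNonsig")
  expect_equal(tajima_flow_label(rep(NA_real_, 4), rep(NA_real_, 4)),
               "Mixed-undefined")
  # significance switch: signs alone decide when disabled
  expect_equal(tajima_flow_label(c(-1, -1, -1, -1), rep(0.5, 4),
                                 require_significance = FALSE), "AllNeg")
  expect_error(tajima_flow_label(numeric(0), numeric(0)), "matched")
})

test_that("a hand-assembled three-transcript flow is reproduced exactly", {
  dets <- tibble::tibble(transcript = c("t1", "t2", "t3", "t4"),
                         det_population = c("G", "J", "M", "nonDET"))
  h <- tibble::tibble(transcript = c("t1", "t2", "t3"),
                      selected = c(TRUE, FALSE, TRUE))
  ol <- tibble::tibble(transcript = c("t1", "t2", "t3"),
                       outlier_label = c("Bal", "noOL", "BalDiv"))
  tj <- tibble::tibble(transcript = c("t1", "t2", "t3"),
                       tajima_label = c("AllNeg", "AllNonSig", "PosNeg"))
  fl <- build_flow(dets, h, ol, tj)
  expect_equal(nrow(fl$flow), 3)        # nonDET excluded
  expect_equal(fl$flow$step1, c("PopG", "PopJ", "PopM"))
  expect_equal(fl$flow$step2, c("H_ge", "H_lt", "H_ge"))
  expect_equal(fl$flow$step3, c("Bal", "noOL", "BalDiv"))
  expect_equal(fl$flow$step4, c("AllNeg", "AllNonSig", "PosNeg"))
  expect_equal(sum(fl$paths$n), 3)

  # missing step labels fall back with a warning, keeping the partition
  expect_warning(
    fl2 <- build_flow(dets, h[1:2, ], ol[1:2, ], tj[1:2, ]),
    "fallback"
  )
  expect_equal(nrow(fl2$flow), 3)
  expect_equal(fl2$flow$step3[3], "NC")
  expect_equal(fl2$flow$step4[3], "Mixed-undefined")
})

test_that("flow CSV export round-trips", {
  dets <- tibble::tibble(transcript = c("t1", "t2"),
                         det_population = c("G", "LC"))
  h <- tibble::tibble(transcript = c("t1", "t2"),
                      selected = c(TRUE, FALSE))
  ol <- tibble::tibble(transcript = c("t1", "t2"),
                       outlier_label = c("noOL", "Div"))
  tj <- tibble::tibble(transcript = c("t1", "t2"),
                       tajima_label = c("AllNonSig", "NegNonsig"))
  fl <- build_flow(dets, h, ol, tj)
  dir <- withr::local_tempdir()
  write_flow(fl, dir)
  back <- readr::read_csv(file.path(dir, "flow.csv"),
                          show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(fl$flow))
  smry <- jsonlite::read_json(file.path(dir, "flow_summary.json"))
  expect_equal(smry$step1$PopG, 1)
})
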