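#' Run the full multi-level pipeline on a synthetic study
#'
#' End-to-end driver: simulates a study from `config` (or accepts one), then
#' runs normalization and pairwise contrasts, the population-exclusive DET
#' assignment, coancestry estimation from the markers, the drift-null H test
#' on the DETs, variant filtering / biallelic selection / LD pruning,
#' per-transcript per-population Tajima's D, the FST outlier scan, the
#' cluster divergence screen, and the final flow cross-classification.
#' Every stage is seeded from the study's global seed, so rerunning with the
#' same configuration reproduces identical outputs (and manifest hashes).
#'
#' @param config A [sim_config()].
#' @param study Optional pre-simulated [simulate_study()] object.
#' @param out_dir Optional directory for TSV/CSV exports and the manifest.
#' @param alpha DET significance level.
#' @param h_threshold Selection threshold on H.
#' @param coancestry_iter,h_iter MCMC lengths (desk-scale defaults).
#' @param outlier_sims Simulated SNPs for the outlier envelope.
#' @param r2_max LD pruning threshold.
#' @return A list with every stage's result (`study`, `size_factors`,
#'   `contrasts`, `dets`, `coancestry`, `h`, `variants_filtered`,
#'   `pruned_idx`, `tajima`, `fst`, `outliers`, `outlier_labels`,
#'   `divergence`, `flow`, `manifest`).
#' @export
run_pipeline <- function(config, study = NULL, out_dir = NULL,
                         alpha = 0.05, h_threshold = 0.95,
                         coancestry_iter = 4000, h_iter = 600,
                         outlier_sims = 4000, r2_max = 0.2) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  study <- study %||% stage("simulate", simulate_study(config))

  sf <- stage("de", compute_size_factors(study$counts))
  contrasts <- stage("de", pairwise_contrasts(study$counts, study$meta, sf))
  dets <- stage("de", assign_population_dets(contrasts, alpha = alpha))

  post <- stage("drift-test", estimate_coancestry(
    study$markers, n_iter = coancestry_iter,
    burn_in = max(200, coancestry_iter %/% 10),
    thin = max(1, coancestry_iter %/% 200),
    seed = derive_seed(config$seed, "coancestry-mcmc")))
  gm <- stage("drift-test", summarize_genotype_means(study$counts,
                                                     study$meta, sf))
  det_tx <- dets$transcript[dets$det_population != "nonDET"]
  h_tx <- if (length(det_tx) > 0) det_tx else unique(gm$transcript)
  h_res <- stage("drift-test", h_test(
    filter(gm, .data$transcript %in% h_tx), post,
    n_iter = h_iter, burn_in = max(50, h_iter %/% 6),
    threshold = h_threshold,
    seed = derive_seed(config$seed, "h-test")))

  vflt <- stage("popgen", filter_variants(study$variants))
  vbi <- stage("popgen", select_biallelic(filter(vflt, .data$pass)))
  dose <- stage("popgen", dosage_matrix(vbi))
  kept <- stage("popgen", ld_prune(dose, vbi$transcript, vbi$pos,
                                   r2_max = r2_max))
  vpr <- vbi[kept, , drop = FALSE]
  dose_pr <- dose[, kept, drop = FALSE]

  tajima <- stage("popgen", study$haplotypes |>
                    mutate(res = purrr::map(.data$hap, tajimas_d)) |>
                    select("transcript", "population", "res") |>
                    tidyr::unnest("res"))

  pop_of_sample <- sub("_.*$", "", rownames(dose_pr))
  alt_counts <- rowsum(dose_pr, pop_of_sample, na.rm = TRUE)
  n_copies <- 2 * rowsum((!is.na(dose_pr)) + 0, pop_of_sample)
  fst <- stage("popgen", wc_fst(alt_counts, n_copies))
  fst$transcript <- vpr$transcript
  fst$snp <- paste0(vpr$transcript, ":", vpr$pos)
  outliers <- stage("popgen", fst_outlier_scan(
    fst, n_demes = config$n_pops,
    n_per_deme = config$coalescent$sample_size,
    n_sims = outlier_sims,
    seed = derive_seed(config$seed, "outlier-scan")))
  snp_classes <- tibble(transcript = fst$transcript,
                        class = outliers$class)
  ol_labels <- stage("popgen", transcript_outlier_labels(
    snp_classes, transcripts = rownames(study$counts)))

  cat_res <- stage("orthodiv", categorize_det_clusters(study$clusters, dets))
  diverg <- stage("orthodiv", pairwise_divergence(
    study$fasta, study$clusters,
    cluster_ids = if (length(cat_res$multi_pop_clusters) > 0) {
      cat_res$multi_pop_clusters
    } else {
      NULL
    }))

  taj_labels <- stage("flow", tajima |>
                        summarise(tajima_label = tajima_flow_label(.data$d,
                                                                   .data$p),
                                  .by = "transcript"))
  flow <- stage("flow", build_flow(dets, h_res, ol_labels, taj_labels))

  out_dir <- out_dir %||% tempfile("popadapt_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(contrasts, file.path(out_dir, "contrasts.tsv"))
  readr::write_tsv(dets, file.path(out_dir, "dets.tsv"))
  readr::write_tsv(as_tibble(h_res), file.path(out_dir, "h_test.tsv"))
  readr::write_tsv(tajima |> select(-dplyr::any_of("res")),
                   file.path(out_dir, "tajima.tsv"))
  readr::write_tsv(as_tibble(outliers), file.path(out_dir, "outliers.tsv"))
  readr::write_tsv(diverg, file.path(out_dir, "divergence.tsv"))
  write_flow(flow, out_dir)
  files <- c("contrasts.tsv", "dets.tsv", "h_test.tsv", "tajima.tsv",
             "outliers.tsv", "divergence.tsv", "flow.csv")
  hashes <- tools::md5sum(file.path(out_dir, files))
  names(hashes) <- files
  manifest <- list(
    package = "popadapt",
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_transcripts = config$n_transcripts,
    alpha = alpha, h_threshold = h_threshold,
    coancestry_iter = coancestry_iter, h_iter = h_iter,
    outlier_sims = outlier_sims, r2_max = r2_max,
    hashes = as.list(hashes)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  list(study = study, size_factors = sf, contrasts = contrasts, dets = dets,
       coancestry = post, h = h_res, variants_filtered = vflt,
       biallelic = vbi, pruned_idx = kept, tajima = tajima, fst = fst,
       outliers = outliers, outlier_labels = ol_labels,
       det_categories = cat_res$categories, divergence = diverg,
       flow = flow, manifest = manifest, out_dir = out_dir)
}
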