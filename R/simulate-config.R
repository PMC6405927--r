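#' Configuration for a synthetic local-adaptation study
#'
#' Bundles every parameter of the synthetic-study generator: the sampling
#' design (populations x genotypes x replicates), the F-model drift
#' coefficients used for the marker loci and the drift-null expression
#' covariance, negative-binomial count parameters, the coalescent settings for
#' per-transcript haplotypes, and the paralog/misassembly planting scheme.
#'
#' The generator is null by default: `frac_de` and `frac_selected_expression`
#' are 0, so every transcript drifts neutrally unless effects are explicitly
#' planted. `theta_true` are per-population coancestry (drift) coefficients in
#' (0, 1); population allele frequencies at the marker loci are
#' Dirichlet-dispersed around ancestral frequencies with concentration
#' `(1 - theta) / theta`, and neutral population expression effects have
#' covariance `2 * diag(theta) * sigma_a2` on the log2 scale.
#'
#' @param n_pops Number of populations (default 4, labelled G, J, LC, M).
#' @param genotypes_per_pop Clonal genotypes sampled per population.
#' @param reps_per_genotype Biological replicates per genotype.
#' @param n_transcripts Number of transcripts to simulate.
#' @param n_marker_loci Number of neutral marker loci (microsatellite-like).
#' @param alleles_per_locus Number of alleles segregating at each marker locus.
#' @param n_diploids_per_pop Diploid individuals genotyped per population at
#'   the marker loci.
#' @param theta_true Per-population drift coefficients in (0, 1); length
#'   `n_pops`.
#' @param sigma_a2 Additive population-effect variance on the log2-expression
#'   scale (scales the drift-null covariance).
#' @param sigma_g2 Genotype-effect variance (log2 scale).
#' @param nb_dispersion Negative-binomial dispersion phi (> 0); the count
#'   variance is `mu + phi * mu^2`.
#' @param frac_de Fraction of transcripts planted with population-exclusive
#'   upregulation of `de_log2fc` in exactly one population.
#' @param de_log2fc Planted log2 fold change for DE transcripts.
#' @param frac_selected_expression Fraction of transcripts planted with a
#'   single-population shift exceeding the drift null (for the H test).
#' @param selection_shift Magnitude of that shift (log2 scale); default
#'   `5 * sqrt(2 * max(theta_true) * sigma_a2)`, i.e. five drift-null standard
#'   deviations.
#' @param coalescent List with `sample_size` (haplotypes per population),
#'   `theta_w` (scaled mutation rate per transcript), `scenario` (one of
#'   `"constant"`, `"growth"`, `"structured"`), `growth_rate`, and
#'   `migration_rate` (scaled, for the structured scenario).
#' @param paralog_plant List with `n_inparalog_pairs`, `n_chimera_pairs`,
#'   `sub_rate_low`, `sub_rate_high`, and `cds_codons` (CDS length in codons).
#' @param seed Global integer seed; subsystem seeds derive from it via
#'   [derive_seed()].
#' @return An object of class `"sim_config"` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_transcripts = 50, seed = 1)
#' cfg$theta_true
sim_config <- function(n_pops = 4,
                       genotypes_per_pop = 6,
                       reps_per_genotype = 3,
                       n_transcripts = 1000,
                       n_marker_loci = 50,
                       alleles_per_locus = 5,
                       n_diploids_per_pop = 40,
                       theta_true = c(0.1, 0.2, 0.3, 0.4),
                       sigma_a2 = 0.04,
                       sigma_g2 = 0.04,
                       nb_dispersion = 0.2,
                       frac_de = 0,
                       de_log2fc = 2,
                       frac_selected_expression = 0,
                       selection_shift = NULL,
                       coalescent = list(),
                       paralog_plant = list(),
                       seed = 1L) {
  coalescent <- utils::modifyList(
    list(sample_size = 12L, theta_w = 5, scenario = "constant",
         growth_rate = 20, migration_rate = 0.1),
    coalescent
  )
  paralog_plant <- utils::modifyList(
    list(n_inparalog_pairs = 10L, n_chimera_pairs = 10L,
         sub_rate_low = 0.05, sub_rate_high = 1.5, cds_codons = 200L),
    paralog_plant
  )
  stopifnot(n_pops >= 2, genotypes_per_pop >= 1, reps_per_genotype >= 1,
            n_transcripts >= 1, n_marker_loci >= 1, alleles_per_locus >= 2)
  if (length(theta_true) != n_pops) {
    abort("`theta_true` must have one drift coefficient per population.")
  }
  if (any(theta_true <= 0) || any(theta_true >= 1)) {
    abort("`theta_true` entries must lie strictly in (0, 1).")
  }
  check_positive(sigma_a2, "sigma_a2", strict = FALSE)
  check_positive(sigma_g2, "sigma_g2", strict = FALSE)
  check_positive(nb_dispersion, "nb_dispersion")
  check_fraction(frac_de, "frac_de")
  check_fraction(frac_selected_expression, "frac_selected_expression")
  if (!coalescent$scenario %in% c("constant", "growth", "structured")) {
    abort('coalescent$scenario must be "constant", "growth" or "structured".')
  }
  if (coalescent$sample_size < 4) abort("coalescent sample_size must be >= 4.")
  if (is.null(selection_shift)) {
    selection_shift <- 5 * sqrt(2 * max(theta_true) * sigma_a2)
  }
  pops <- if (n_pops == 4) POP_LEVELS else paste0("P", seq_len(n_pops))
  structure(
    list(n_pops = as.integer(n_pops),
         pops = pops,
         genotypes_per_pop = as.integer(genotypes_per_pop),
         reps_per_genotype = as.integer(reps_per_genotype),
         n_transcripts = as.integer(n_transcripts),
         n_marker_loci = as.integer(n_marker_loci),
         alleles_per_locus = as.integer(alleles_per_locus),
         n_diploids_per_pop = as.integer(n_diploids_per_pop),
         theta_true = theta_true,
         sigma_a2 = sigma_a2, sigma_g2 = sigma_g2,
         nb_dispersion = nb_dispersion,
         frac_de = frac_de, de_log2fc = de_log2fc,
         frac_selected_expression = frac_selected_expression,
         selection_shift = selection_shift,
         coalescent = coalescent,
         paralog_plant = paralog_plant,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  design: %d pops x %d genotypes x %d reps; %d transcripts\n",
              x$n_pops, x$genotypes_per_pop, x$reps_per_genotype,
              x$n_transcripts))
  cat(sprintf("  theta_true: %s\n", paste(x$theta_true, collapse = ", ")))
  cat(sprintf("  markers: %d loci, %d alleles, %d diploids/pop\n",
              x$n_marker_loci, x$alleles_per_locus, x$n_diploids_per_pop))
  cat(sprintf("  counts: sigma_a2 %.3g, sigma_g2 %.3g, phi %.3g, frac_de %.3g\n",
              x$sigma_a2, x$sigma_g2, x$nb_dispersion, x$frac_de))
  cat(sprintf("  coalescent: %s, n = %d, theta_w = %.3g\n",
              x$coalescent$scenario, x$coalescent$sample_size,
              x$coalescent$theta_w))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
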