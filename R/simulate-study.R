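#' Simulate a complete synthetic study
#'
#' Runs the four generators — F-model marker drift, negative-binomial counts
#' under the drift null, per-transcript coalescent haplotypes, and planted
#' orthology clusters — with subsystem seeds derived from the single global
#' seed, and bundles their outputs with the ground truth.
#'
#' @param config A [sim_config()].
#' @return An object of class `"popadapt_study"`: a list with `config`,
#'   `markers`, `counts`, `meta`, `truth` (transcript-level),
#'   `haplotypes`, `variants`, `fasta`, `clusters`, `cluster_truth`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_transcripts = 30, seed = 11,
#'                                    paralog_plant = list(n_inparalog_pairs = 2,
#'                                                         n_chimera_pairs = 2)))
#' names(study)
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mk <- simulate_markers(config)
  cn <- simulate_counts(config)
  hp <- simulate_haplotypes(config)
  cl <- simulate_clusters(config, truth = cn$truth)
  structure(
    list(config = config,
         markers = mk$markers,
         marker_freqs = mk$freqs,
         counts = cn$counts,
         meta = cn$meta,
         truth = cn$truth,
         haplotypes = hp$haplotypes,
         variants = hp$variants,
         fasta = cl$fasta,
         clusters = cl$clusters,
         cluster_truth = cl$truth),
    class = "popadapt_study"
  )
}

#' @export
print.popadapt_study <- function(x, ...) {
  cat("<popadapt_study>\n")
  cat(sprintf("  %d transcripts x %d samples; %d marker loci; %d variants; %d clusters\n",
              nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(x$markers$locus),
              nrow(x$variants), dplyr::n_distinct(x$clusters$cluster)))
  invisible(x)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits the exchange formats consumed by the analysis stages: counts TSV
#' (transcripts x samples), sample metadata TSV, markers TSV (long), phased
#' VCF, CDS FASTA, cluster file, transcript/cluster truth TSVs, and a JSON
#' manifest recording the seed and design.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, overwrite = FALSE) {
  stopifnot(inherits(study, "popadapt_study"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(sprintf("directory '%s' is not empty; pass overwrite = TRUE.", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- as.data.frame(study$counts)
  cm <- cbind(transcript = rownames(study$counts), cm)
  readr::write_tsv(cm, file.path(dir, "counts.tsv"))
  readr::write_tsv(study$meta, file.path(dir, "samples.tsv"))
  readr::write_tsv(study$markers, file.path(dir, "markers.tsv"))
  write_variants_vcf(study$variants, file.path(dir, "variants.vcf"))
  write_fasta(study$fasta, file.path(dir, "cds.fasta"))
  write_clusters(study$clusters, file.path(dir, "clusters.txt"))
  readr::write_tsv(study$truth, file.path(dir, "truth_transcripts.tsv"))
  readr::write_tsv(study$cluster_truth, file.path(dir, "truth_clusters.tsv"))
  cfg <- study$config
  manifest <- list(
    generator = "popadapt",
    seed = cfg$seed,
    n_pops = cfg$n_pops,
    genotypes_per_pop = cfg$genotypes_per_pop,
    reps_per_genotype = cfg$reps_per_genotype,
    n_transcripts = cfg$n_transcripts,
    n_marker_loci = cfg$n_marker_loci,
    theta_true = cfg$theta_true,
    scenario = cfg$coalescent$scenario
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study directory back into memory
#'
#' Round-trips the files written by [write_study()]; the counts matrix,
#' metadata, markers, variants, FASTA and clusters are restored to the same
#' in-memory layout the simulator produces.
#'
#' @param dir Study directory.
#' @return A list with `counts`, `meta`, `markers`, `variants`, `fasta`,
#'   `clusters`, `truth`, `cluster_truth`, `manifest`.
#' @export
read_study <- function(dir) {
  cm <- readr::read_tsv(file.path(dir, "counts.tsv"),
                        show_col_types = FALSE)
  counts <- as.matrix(cm[, -1])
  rownames(counts) <- cm$transcript
  storage.mode(counts) <- "integer"
  meta <- readr::read_tsv(file.path(dir, "samples.tsv"),
                          show_col_types = FALSE)
  meta$population <- factor(meta$population,
                            levels = unique(meta$population))
  list(
    counts = counts,
    meta = meta,
    markers = readr::read_tsv(file.path(dir, "markers.tsv"),
                              show_col_types = FALSE),
    variants = read_variants_vcf(file.path(dir, "variants.vcf")),
    fasta = read_fasta(file.path(dir, "cds.fasta")),
    clusters = read_clusters(file.path(dir, "clusters.txt")),
    truth = readr::read_tsv(file.path(dir, "truth_transcripts.tsv"),
                            show_col_types = FALSE),
    cluster_truth = readr::read_tsv(file.path(dir, "truth_clusters.tsv"),
                                    show_col_types = FALSE),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"))
  )
}
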