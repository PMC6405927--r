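#' Simulate phased haplotypes per transcript and population
#'
#' For every transcript and population, draws a coalescent genealogy under
#' the configured scenario (`constant`, `growth`, or `structured`; in the
#' structured scenario the population's sample is split over two demes with
#' low migration and pooled, which inflates intermediate-frequency variants)
#' and places infinite-sites mutations at distinct positions along the
#' transcript. Variants are private to the population they arose in; the
#' joint variant table carries phased genotypes for all individuals, with
#' other populations homozygous reference.
#'
#' Site-level QD (quality by depth) and FS (Fisher strand) annotations are
#' drawn from pass/fail mixtures so that downstream hard filtering has
#' realistic work to do.
#'
#' @param config A [sim_config()]; the `coalescent` block sets sample size,
#'   mutation rate and scenario.
#' @param tx_len Transcript length in bp over which variant positions are
#'   placed.
#' @param qd_fail_frac,fs_fail_frac Fractions of sites drawn from the failing
#'   side of the QD/FS mixtures.
#' @return A list with
#'   \describe{
#'     \item{haplotypes}{tibble with `transcript`, `population`, `hap`
#'       (list-column of 0/1 haplotype matrices, haplotypes x sites), and
#'       `positions` (list-column), `monomorphic` flag.}
#'     \item{variants}{tibble of joint variant records: `transcript`, `pos`,
#'       `ref`, `alt`, `qd`, `fs`, plus one phased genotype column per
#'       individual (`G_1` ... `M_6`) in `"0|1"` notation.}
#'     \item{scenario}{the scenario label applied to every transcript.}
#'   }
#' @export
#' @examples
#' cfg <- sim_config(n_transcripts = 3, seed = 5)
#' hs <- simulate_haplotypes(cfg)
#' hs$haplotypes
simulate_haplotypes <- function(config, tx_len = 1000L,
                                qd_fail_frac = 0.05, fs_fail_frac = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  co <- config$coalescent
  if (co$sample_size < 4) abort("coalescent sample_size must be >= 4.")
  with_seed(derive_seed(config$seed, "haplotypes"), {
    T_ <- config$n_transcripts
    pops <- config$pops
    n_hap <- co$sample_size
    n_ind <- n_hap %/% 2L   # diploid individuals emitted in the VCF
    tx <- sprintf("t%05d", seq_len(T_))
    ind_names <- as.vector(t(outer(pops, seq_len(n_ind), paste, sep = "_")))

    hap_rows <- vector("list", T_ * length(pops))
    var_rows <- vector("list", T_)
    r <- 0L
    for (t in seq_len(T_)) {
      pop_sites <- list()
      for (p in seq_along(pops)) {
        hap <- sim_locus(n_hap, co$theta_w, co$scenario,
                         co$growth_rate, co$migration_rate)
        s <- ncol(hap)
        pos <- if (s > 0) sort(sample.int(tx_len, s)) else integer(0)
        r <- r + 1L
        hap_rows[[r]] <- tibble(
          transcript = tx[t], population = pops[p],
          hap = list(hap), positions = list(pos),
          monomorphic = s == 0L
        )
        pop_sites[[p]] <- list(hap = hap, pos = pos)
      }
      # joint variant table: union of per-population private sites.
      # colliding positions across populations are jittered to keep the
      # infinite-sites property transcript-wide.
      all_pos <- unlist(lapply(pop_sites, `[[`, "pos"))
      if (length(all_pos) > 0) {
        while (anyDuplicated(all_pos)) {
          dup <- which(duplicated(all_pos))
          all_pos[dup] <- (all_pos[dup] %% tx_len) + 1L
        }
        k <- 0L
        gt <- matrix("0|0", nrow = length(all_pos),
                     ncol = length(pops) * n_ind)
        pos_out <- integer(length(all_pos))
        pop_of <- integer(length(all_pos))
        for (p in seq_along(pops)) {
          hp <- pop_sites[[p]]$hap
          s <- ncol(hp)
          if (s == 0) next
          # haplotypes 2j-1, 2j form diploid individual j
          for (jj in seq_len(s)) {
            k <- k + 1L
            pos_out[k] <- all_pos[k]
            pop_of[k] <- p
            h1 <- hp[seq(1, 2 * n_ind, by = 2), jj]
            h2 <- hp[seq(2, 2 * n_ind, by = 2), jj]
            gt[k, (p - 1L) * n_ind + seq_len(n_ind)] <-
              paste0(h1, "|", h2)
          }
        }
        o <- order(pos_out)
        bases <- c("A", "C", "G", "T")
        ref <- sample(bases, length(all_pos), replace = TRUE)
        alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
        qd <- ifelse(runif(length(all_pos)) < qd_fail_frac,
                     runif(length(all_pos), 0.2, 2),
                     runif(length(all_pos), 2, 35))
        fs <- ifelse(runif(length(all_pos)) < fs_fail_frac,
                     runif(length(all_pos), 30, 60),
                     runif(length(all_pos), 0, 30))
        vt <- tibble(transcript = tx[t], pos = pos_out[o],
                     ref = ref[o], alt = unname(alt[o]),
                     qd = round(qd[o], 2), fs = round(fs[o], 2))
        gt <- gt[o, , drop = FALSE]
        colnames(gt) <- ind_names
        var_rows[[t]] <- bind_cols(vt, as_tibble(gt))
      }
    }
    list(haplotypes = bind_rows(hap_rows),
         variants = bind_rows(var_rows),
         scenario = co$scenario)
  })
}

#' Write a variant table as a VCF 4.2 file
#'
#' Emits the joint variant tibble produced by [simulate_haplotypes()] (or any
#' tibble with the same columns) as a minimal phased VCF with `QD` and `FS`
#' INFO fields.
#'
#' @param variants Variant tibble (`transcript`, `pos`, `ref`, `alt`, `qd`,
#'   `fs`, one phased-GT column per sample).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  meta_cols <- c("transcript", "pos", "ref", "alt", "qd", "fs")
  samples <- setdiff(names(variants), meta_cols)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popadapt",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- if (nrow(variants) > 0) {
    info <- sprintf("QD=%.2f;FS=%.2f", variants$qd, variants$fs)
    fixed <- paste(variants$transcript, variants$pos, ".", variants$ref,
                   variants$alt, ".", "PASS", info, "GT", sep = "\t")
    gts <- do.call(paste, c(unname(as.list(variants[samples])), sep = "\t"))
    paste(fixed, gts, sep = "\t")
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into the package's variant tibble
#'
#' Thin wrapper around `vcfR::read.vcfR()` that extracts positions, alleles,
#' the `QD`/`FS` INFO annotations and per-sample phased genotypes into the
#' same tabular layout the simulator produces.
#'
#' @param path VCF file path.
#' @return Variant tibble as in [simulate_haplotypes()].
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_num <- function(key) {
    x <- stringr::str_match(fix$INFO, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    as.numeric(x)
  }
  gt <- v@gt[, -1, drop = FALSE]
  out <- tibble(
    transcript = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qd = info_num("QD"),
    fs = info_num("FS")
  )
  bind_cols(out, as_tibble(gt))
}
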