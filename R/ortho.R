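#' Categorize DETs by orthology-cluster population co-occurrence
#'
#' For each differentially expressed transcript (DET), counts the distinct
#' populations represented by DETs in its orthology cluster: `1Pop` ...
#' `4Pop`, or `no-cluster` for DETs absent from the cluster map. Clusters
#' holding DETs from at least two populations are the candidates for the
#' divergence screen (`no-cluster` and `1Pop` DETs are excluded downstream).
#'
#' @param clusters Tibble `cluster`, `transcript` (a partition: a transcript
#'   may appear in at most one cluster).
#' @param dets DET assignment tibble from [assign_population_dets()].
#' @return List with `categories` (tibble `transcript`, `det_population`,
#'   `cluster`, `category`) and `multi_pop_clusters` (character vector of
#'   cluster ids with DETs from >= 2 populations).
#' @export
categorize_det_clusters <- function(clusters, dets) {
  if (anyDuplicated(clusters$transcript)) {
    abort("cluster map must partition transcripts (duplicate membership).")
  }
  det_only <- filter(dets, .data$det_population != "nonDET")
  joined <- det_only |>
    left_join(clusters, by = "transcript")
  pop_per_cluster <- joined |>
    filter(!is.na(.data$cluster)) |>
    summarise(n_pops = dplyr::n_distinct(.data$det_population),
              .by = "cluster")
  categories <- joined |>
    left_join(pop_per_cluster, by = "cluster") |>
    mutate(category = dplyr::case_when(
      is.na(.data$cluster) ~ "no-cluster",
      .default = paste0(.data$n_pops, "Pop")
    )) |>
    select("transcript", "det_population", "cluster", "category")
  multi <- pop_per_cluster$cluster[pop_per_cluster$n_pops >= 2]
  list(categories = categories, multi_pop_clusters = multi)
}

GENETIC_CODE_TABLE <- {
  b <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  ), "")[[1]]
  # standard table order: first base slowest, third base fastest
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  setNames(aas, codons)
}

# translate an in-frame CDS; returns NA if a non-ACGT codon is met
translate_cds <- function(cds) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- GENETIC_CODE_TABLE[codons]
  if (anyNA(aa)) return(NA_character_)
  paste(aa, collapse = "")
}

#' Protein-guided pairwise alignment of two CDS
#'
#' Translates both coding sequences in frame 1, aligns the proteins globally
#' (Needleman-Wunsch, BLOSUM62, affine gap open 10 / extend 1 via
#' `Biostrings::pairwiseAlignment`), and back-propagates every protein gap as
#' a codon triplet onto the nucleotide sequences, yielding a codon-aware
#' nucleotide alignment. Pairs whose length is not a multiple of 3 or whose
#' translation contains an internal stop are skipped with a reason — in a
#' transcriptome screen these are exactly the suspect (often misassembled)
#' sequences.
#'
#' @param cds_a,cds_b Uppercase nucleotide CDS strings.
#' @param gap_open,gap_extend Affine gap penalties for the protein
#'   alignment.
#' @return List with `status` (`"ok"`/`"skipped"`), `reason` (`NA` when ok),
#'   and aligned nucleotide strings `aln_a`, `aln_b` (with `-` gaps).
#' @export
align_pair_protein_guided <- function(cds_a, cds_b, gap_open = 10,
                                      gap_extend = 1) {
  skip <- function(reason) list(status = "skipped", reason = reason,
                                aln_a = NA_character_, aln_b = NA_character_)
  if (nchar(cds_a) %% 3 != 0 || nchar(cds_b) %% 3 != 0) {
    return(skip("length-not-codon-multiple"))
  }
  aa_a <- translate_cds(cds_a)
  aa_b <- translate_cds(cds_b)
  if (is.na(aa_a) || is.na(aa_b)) return(skip("untranslatable"))
  # trailing stop tolerated, internal stop rejected
  strip_stop <- function(aa, cds) {
    if (endsWith(aa, "*")) {
      list(aa = substr(aa, 1, nchar(aa) - 1),
           cds = substr(cds, 1, nchar(cds) - 3))
    } else {
      list(aa = aa, cds = cds)
    }
  }
  a <- strip_stop(aa_a, cds_a)
  b <- strip_stop(aa_b, cds_b)
  if (grepl("\\*", a$aa) || grepl("\\*", b$aa)) {
    return(skip("internal-stop"))
  }
  if (nchar(a$aa) == 0 || nchar(b$aa) == 0) return(skip("empty-translation"))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("protein-guided alignment requires the Biostrings package.")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$aa), Biostrings::AAString(b$aa),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  backprop <- function(aln_aa, cds) {
    out <- character(length(aln_aa))
    pos <- 0L
    for (i in seq_along(aln_aa)) {
      if (aln_aa[i] == "-") {
        out[i] <- "---"
      } else {
        out[i] <- substr(cds, pos * 3 + 1, pos * 3 + 3)
        pos <- pos + 1L
      }
    }
    paste(out, collapse = "")
  }
  list(status = "ok", reason = NA_character_,
       aln_a = backprop(pat, a$cds), aln_b = backprop(sub, b$cds))
}

#' Kimura two-parameter distance (optional gamma rate heterogeneity)
#'
#' From an aligned nucleotide pair, computes the proportions of transition
#' (`P`) and transversion (`Q`) differences over ungapped columns and the
#' K2P distance
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`; with a gamma shape `alpha`,
#' `d = alpha/2 ((1-2P-Q)^(-1/alpha) - 1) + alpha/4 ((1-2Q)^(-1/alpha) - 1)`.
#' The distance is undefined (saturated) when `1 - 2P - Q <= 0` or
#' `1 - 2Q <= 0`.
#'
#' @param aln_a,aln_b Aligned sequences of equal length (`-` gaps).
#' @param alpha Gamma shape, or `NULL` for the uncorrected distance.
#' @return One-row tibble: `sites` (ungapped columns), `p`, `q`, `alpha`,
#'   `d` (`NA` when undefined).
#' @export
#' @examples
#' k2p_distance("ACGTACGT", "ACGTACGA")
k2p_distance <- function(aln_a, aln_b, alpha = NULL) {
  a <- strsplit(toupper(aln_a), "")[[1]]
  b <- strsplit(toupper(aln_b), "")[[1]]
  if (length(a) != length(b)) abort("aligned sequences differ in length.")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) abort("no ungapped comparable column.")
  a <- a[ok]
  b <- b[ok]
  diff <- a != b
  purine <- c("A", "G")
  is_transition <- diff & ((a %in% purine) == (b %in% purine))
  n <- length(a)
  P <- sum(is_transition) / n
  Q <- sum(diff & !is_transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) {
    NA_real_
  } else if (is.null(alpha)) {
    -0.5 * log(w1) - 0.25 * log(w2)
  } else {
    alpha / 2 * (w1^(-1 / alpha) - 1) + alpha / 4 * (w2^(-1 / alpha) - 1)
  }
  tibble(sites = n, p = P, q = Q,
         alpha = if (is.null(alpha)) NA_real_ else alpha, d = d)
}

#' Classify a divergence value against the misassembly cutoff
#'
#' `d < cutoff` is an inparalog or isoform (highly similar duplicate);
#' `d >= cutoff` a putative misassembly; undefined (saturated or
#' unalignable) distances stay `undefined`.
#'
#' @param d Numeric vector of distances (`NA` = undefined).
#' @param cutoff Divergence cutoff (default 2).
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_divergence(c(0.5, 3, NA))
classify_divergence <- function(d, cutoff = 2) {
  dplyr::case_when(
    is.na(d) ~ "undefined",
    d < cutoff ~ "inparalog_or_isoform",
    .default = "putative_misassembly"
  )
}

#' Pairwise divergence screen over orthology clusters
#'
#' Runs the protein-guided alignment and K2P(+gamma) distance over every
#' within-cluster transcript pair of the requested clusters and classifies
#' each pair against the cutoff. Skipped pairs (untranslatable, internal
#' stop) are classed `undefined` with the skip reason recorded.
#'
#' @param fasta Named character vector of CDS.
#' @param clusters Tibble `cluster`, `transcript`.
#' @param cluster_ids Clusters to screen (default: all with >= 2 members).
#' @param alpha Gamma shape for the distance (default 1; `NULL` disables the
#'   correction).
#' @param cutoff Misassembly cutoff.
#' @return Tibble with `cluster`, `transcript_a`, `transcript_b`, `sites`,
#'   `p`, `q`, `d`, `class`, `reason`.
#' @export
pairwise_divergence <- function(fasta, clusters, cluster_ids = NULL,
                                alpha = 1, cutoff = 2) {
  sizes <- table(clusters$cluster)
  cluster_ids <- cluster_ids %||% names(sizes)[sizes >= 2]
  rows <- list()
  for (cl in cluster_ids) {
    members <- clusters$transcript[clusters$cluster == cl]
    if (length(members) < 2) next
    for (pr in utils::combn(members, 2, simplify = FALSE)) {
      sa <- fasta[[pr[1]]]
      sb <- fasta[[pr[2]]]
      if (is.null(sa) || is.null(sb) || is.na(sa) || is.na(sb)) {
        rows[[length(rows) + 1]] <- tibble(
          cluster = cl, transcript_a = pr[1], transcript_b = pr[2],
          sites = NA_integer_, p = NA_real_, q = NA_real_, d = NA_real_,
          class = "undefined", reason = "missing-sequence")
        next
      }
      aln <- align_pair_protein_guided(sa, sb)
      if (aln$status == "skipped") {
        rows[[length(rows) + 1]] <- tibble(
          cluster = cl, transcript_a = pr[1], transcript_b = pr[2],
          sites = NA_integer_, p = NA_real_, q = NA_real_, d = NA_real_,
          class = "undefined", reason = aln$reason)
        next
      }
      k <- k2p_distance(aln$aln_a, aln$aln_b, alpha = alpha)
      rows[[length(rows) + 1]] <- tibble(
        cluster = cl, transcript_a = pr[1], transcript_b = pr[2],
        sites = k$sites, p = k$p, q = k$q, d = k$d,
        class = classify_divergence(k$d, cutoff), reason = NA_character_)
    }
  }
  bind_rows(rows)
}
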