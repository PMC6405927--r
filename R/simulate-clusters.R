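CODONS <- {
  b <- c("T", "C", "A", "G")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# random CDS of n_codons sense codons (no internal stops)
random_cds <- function(n_codons) {
  paste(sample(CODONS, n_codons, replace = TRUE), collapse = "")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# point-mutate a CDS at per-site rate, 2:1 transition bias, never creating
# an internal stop codon (mutations that would are redrawn as silent skips)
mutate_cds <- function(cds, rate) {
  s <- strsplit(cds, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  for (i in hit) {
    old <- s[i]
    new <- if (runif(1) < 2 / 3) TRANSITION[[old]] else {
      sample(setdiff(c("A", "C", "G", "T"), c(old, TRANSITION[[old]])), 1L)
    }
    codon_i <- (i - 1L) %/% 3L
    codon <- s[codon_i * 3L + 1:3]
    codon[(i - 1L) %% 3L + 1L] <- new
    if (paste(codon, collapse = "") %in% c("TAA", "TAG", "TGA")) next
    s[i] <- new
  }
  paste(s, collapse = "")
}

#' Simulate orthology clusters with planted inparalogs and chimeras
#'
#' Builds a CDS pool and an orthology-cluster assignment with known truth:
#' \emph{inparalog pairs} are a parent CDS plus a copy point-mutated at
#' `sub_rate_low` (expected K2P divergence well below the misassembly
#' cutoff); \emph{chimera pairs} mimic transcriptome misassemblies — the
#' partner shares the parent's first half but continues with the second half
#' of an unrelated CDS spliced out of frame, so its translation almost surely
#' hits an internal stop and the pair is rejected (or saturates) in the
#' divergence screen. Remaining clustered transcripts get unrelated CDS in
#' single-member clusters.
#'
#' Pair members are drawn preferentially from transcripts planted as DETs in
#' different populations (when a truth table from [simulate_counts()] is
#' given), so planted clusters carry DETs from at least two populations and
#' survive the co-occurrence filter.
#'
#' @param config A [sim_config()]; the `paralog_plant` block sets pair counts,
#'   substitution rates and CDS length.
#' @param truth Optional truth tibble from [simulate_counts()].
#' @param n_background Number of additional single-member clusters.
#' @return A list with `fasta` (named character vector of CDS), `clusters`
#'   (tibble `cluster`, `transcript`), and `truth` (tibble `cluster`,
#'   `planted_relation` in inparalog/chimera/none).
#' @export
#' @examples
#' cl <- simulate_clusters(sim_config(n_transcripts = 50, seed = 2))
#' head(cl$clusters)
simulate_clusters <- function(config, truth = NULL, n_background = 5) {
  stopifnot(inherits(config, "sim_config"))
  pp <- config$paralog_plant
  with_seed(derive_seed(config$seed, "clusters"), {
    n_pairs <- pp$n_inparalog_pairs + pp$n_chimera_pairs
    tx_all <- sprintf("t%05d", seq_len(config$n_transcripts))
    if (2L * n_pairs > length(tx_all)) {
      abort("not enough transcripts to host the planted clusters.")
    }
    n_background <- min(n_background, length(tx_all) - 2L * n_pairs)
    need <- 2L * n_pairs + n_background
    # prefer DE transcripts from distinct populations as pair members
    pool <- tx_all
    if (!is.null(truth) && any(!is.na(truth$de_population))) {
      de <- truth$transcript[!is.na(truth$de_population)]
      pool <- c(sample(de), sample(setdiff(tx_all, de)))
    } else {
      pool <- sample(pool)
    }
    members <- pool[seq_len(need)]

    fasta <- character(0)
    clusters <- list()
    ctruth <- list()
    ci <- 0L
    take <- function(k) {
      out <- members[seq_len(k)]
      members <<- members[-seq_len(k)]
      out
    }
    n_cod <- pp$cds_codons
    half <- (n_cod %/% 2L) * 3L

    for (i in seq_len(pp$n_inparalog_pairs)) {
      ci <- ci + 1L
      ids <- take(2L)
      parent <- random_cds(n_cod)
      fasta[ids[1]] <- parent
      fasta[ids[2]] <- mutate_cds(parent, pp$sub_rate_low)
      clusters[[ci]] <- tibble(cluster = sprintf("C%04d", ci),
                               transcript = ids)
      ctruth[[ci]] <- tibble(cluster = sprintf("C%04d", ci),
                             planted_relation = "inparalog")
    }
    for (i in seq_len(pp$n_chimera_pairs)) {
      ci <- ci + 1L
      ids <- take(2L)
      parent <- random_cds(n_cod)
      donor <- random_cds(n_cod)
      # second half spliced with a +1 frameshift; pad to a codon multiple
      tail_part <- substr(donor, half + 2L, nchar(donor))
      chim <- paste0(substr(parent, 1L, half), tail_part)
      pad <- (3L - nchar(chim) %% 3L) %% 3L
      if (pad > 0) chim <- paste0(chim, paste(rep("A", pad), collapse = ""))
      fasta[ids[1]] <- parent
      fasta[ids[2]] <- chim
      clusters[[ci]] <- tibble(cluster = sprintf("C%04d", ci),
                               transcript = ids)
      ctruth[[ci]] <- tibble(cluster = sprintf("C%04d", ci),
                             planted_relation = "chimera")
    }
    for (i in seq_len(n_background)) {
      ci <- ci + 1L
      ids <- take(1L)
      fasta[ids] <- random_cds(n_cod)
      clusters[[ci]] <- tibble(cluster = sprintf("C%04d", ci),
                               transcript = ids)
      ctruth[[ci]] <- tibble(cluster = sprintf("C%04d", ci),
                             planted_relation = "none")
    }
    list(fasta = fasta,
         clusters = bind_rows(clusters),
         truth = bind_rows(ctruth))
  })
}

#' Write and read the one-line-per-cluster assignment format
#'
#' `clusterID: member1 member2 ...`, one cluster per line.
#'
#' @param clusters Tibble with `cluster` and `transcript`.
#' @param path File path.
#' @return `path` invisibly; `read_clusters()` returns the tibble.
#' @export
write_clusters <- function(clusters, path) {
  lines <- clusters |>
    summarise(line = paste0(.data$cluster[1], ": ",
                            paste(.data$transcript, collapse = " ")),
              .by = "cluster")
  writeLines(lines$line, path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(cluster = character(), transcript = character()))
  }
  parts <- stringr::str_split_fixed(lines, ":", 2)
  purrr::map2_dfr(parts[, 1], parts[, 2], function(cl, mem) {
    tibble(cluster = trimws(cl),
           transcript = strsplit(trimws(mem), "\\s+")[[1]])
  })
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return `path` invisibly; `read_fasta()` returns the named vector.
#' @export
write_fasta <- function(seqs, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  } else {
    writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    idx <- cumsum(hdr)
    seqs <- tapply(lines[!hdr], idx[!hdr], paste, collapse = "")
    setNames(as.character(seqs), sub("^>", "", lines[hdr]))
  }
}
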