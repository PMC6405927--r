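#' Hard-filter variant records
#'
#' Flags records failing any of: quality-by-depth `QD < 2.0`, Fisher strand
#' `FS > 30.0` (strict inequality), or membership in an SNP cluster of at
#' least `cluster_size` variants within any `window` bp on the same
#' transcript. Missing QD/FS annotations fail with reason
#' `"missing-annotation"`. Flags are idempotent and order-independent.
#'
#' @param variants Variant tibble with `transcript`, `pos`, `qd`, `fs`
#'   (extra columns pass through).
#' @param qd_min,fs_max,window,cluster_size Filter rules.
#' @return The input tibble with `pass` (logical) and `fail_reason`
#'   (comma-separated, `NA` when passing).
#' @export
#' @examples
#' v <- tibble::tibble(transcript = "t1", pos = c(100, 110, 130),
#'                     qd = c(5, 5, 5), fs = c(1, 1, 1))
#' filter_variants(v)$fail_reason
filter_variants <- function(variants, qd_min = 2.0, fs_max = 30.0,
                            window = 35L, cluster_size = 3L) {
  stopifnot(all(c("transcript", "pos", "qd", "fs") %in% names(variants)))
  v <- arrange(variants, .data$transcript, .data$pos)
  missing_ann <- is.na(v$qd) | is.na(v$fs)
  fail_qd <- !missing_ann & v$qd < qd_min
  fail_fs <- !missing_ann & v$fs > fs_max
  in_cluster <- logical(nrow(v))
  for (idx in split(seq_len(nrow(v)), v$transcript)) {
    pos <- v$pos[idx]
    for (i in seq_along(pos)) {
      lo <- pos[i] - window + 1L
      # any window of `window` bp containing >= cluster_size SNPs incl. i
      for (start in pos[pos >= lo & pos <= pos[i]]) {
        if (sum(pos >= start & pos <= start + window - 1L) >= cluster_size) {
          in_cluster[idx[i]] <- TRUE
          break
        }
      }
    }
  }
  reason <- rep(NA_character_, nrow(v))
  parts <- cbind(ifelse(missing_ann, "missing-annotation", NA),
                 ifelse(fail_qd, "low-QD", NA),
                 ifelse(fail_fs, "high-FS", NA),
                 ifelse(in_cluster, "snp-cluster", NA))
  any_fail <- missing_ann | fail_qd | fail_fs | in_cluster
  reason[any_fail] <- apply(parts[any_fail, , drop = FALSE], 1,
                            function(r) paste(na.omit(r), collapse = ","))
  v$pass <- !any_fail
  v$fail_reason <- reason
  v
}

#' Restrict a variant table to biallelic SNPs
#'
#' Drops records with more than one alternate allele or with
#' length-changing alleles (indels), keeping single-base
#' substitutions only.
#'
#' @param variants Variant tibble with `ref` and `alt`.
#' @return The biallelic subset.
#' @export
select_biallelic <- function(variants) {
  keep <- !grepl(",", variants$alt) &
    nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  variants[keep, , drop = FALSE]
}

# allele-dosage matrix (samples x variants) from phased GT columns
dosage_matrix <- function(variants, sample_cols = NULL) {
  meta_cols <- c("transcript", "pos", "ref", "alt", "qd", "fs", "pass",
                 "fail_reason")
  sample_cols <- sample_cols %||% setdiff(names(variants), meta_cols)
  gt <- as.matrix(variants[sample_cols])
  dose <- matrix(NA_real_, nrow = length(sample_cols), ncol = nrow(variants),
                 dimnames = list(sample_cols, NULL))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
  dose[] <- t(matrix(d, nrow = nrow(variants)))
  dose
}

#' Greedy within-transcript LD pruning
#'
#' Scans SNPs in position order within each transcript and drops a SNP if
#' its squared genotype correlation (on allele dosages, missing values
#' dropped pairwise) with any already-retained SNP of the same transcript
#' exceeds `r2_max`. Zero-variance SNPs are retained trivially (undefined
#' r-squared is treated as 0).
#'
#' @param dosages Samples x SNPs dosage matrix (0/1/2).
#' @param transcript Transcript id per SNP.
#' @param pos Position per SNP.
#' @param r2_max Pruning threshold (drop if `r^2 > r2_max`).
#' @return Integer indices (columns of `dosages`) of retained SNPs.
#' @export
ld_prune <- function(dosages, transcript, pos, r2_max = 0.2) {
  stopifnot(ncol(dosages) == length(transcript),
            length(pos) == length(transcript))
  keep <- logical(length(transcript))
  for (idx in split(seq_along(transcript), transcript)) {
    idx <- idx[order(pos[idx])]
    retained <- integer(0)
    for (i in idx) {
      ok <- TRUE
      for (j in retained) {
        r <- suppressWarnings(cor(dosages[, i], dosages[, j],
                                  use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_max) {
          ok <- FALSE
          break
        }
      }
      if (ok) retained <- c(retained, i)
    }
    keep[retained] <- TRUE
  }
  which(keep)
}

#' PCA of biallelic genotype dosages
#'
#' Centers each SNP's dosages (optionally scaling by the binomial standard
#' deviation `sqrt(2p(1-p))`) and eigendecomposes the sample covariance
#' matrix. All-missing or zero-variance-after-centering SNPs are excluded;
#' residual missing dosages are mean-imputed (i.e. set to 0 after centering).
#'
#' @param dosages Samples x SNPs matrix.
#' @param scale Divide by `sqrt(2p(1-p))` per SNP.
#' @param n_pc Number of components to return.
#' @return List with `scores` (tibble: `sample`, `PC1..`), `eigenvalues`,
#'   `var_explained`.
#' @export
genotype_pca <- function(dosages, scale = FALSE, n_pc = 10) {
  stopifnot(nrow(dosages) >= 2)
  keep <- colSums(!is.na(dosages)) > 0
  x <- dosages[, keep, drop = FALSE]
  p <- colMeans(x, na.rm = TRUE) / 2
  x <- sweep(x, 2, 2 * p)
  if (scale) {
    s <- sqrt(pmax(2 * p * (1 - p), 1e-12))
    x <- sweep(x, 2, s, "/")
  }
  x[is.na(x)] <- 0
  cv <- tcrossprod(x) / ncol(x)
  ei <- eigen(cv, symmetric = TRUE)
  n_pc <- min(n_pc, ncol(ei$vectors))
  ev <- pmax(ei$values, 0)
  scores <- ei$vectors[, seq_len(n_pc), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_pc)]), n_pc)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  list(
    scores = bind_cols(
      tibble(sample = rownames(dosages) %||%
               paste0("s", seq_len(nrow(dosages)))),
      as_tibble(as.data.frame(scores))
    ),
    eigenvalues = ev,
    var_explained = ev / sum(ev)
  )
}
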