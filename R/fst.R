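#' Weir-Cockerham FST per SNP
#'
#' Variance-components estimator of FST for biallelic SNPs from
#' per-population allele counts, with haploid-style components (appropriate
#' for phased haplotypes or when heterozygosity terms are unavailable):
#' `a = s2 - (pbar(1-pbar) - s2 (r-1)/r) / (nbar - 1)` among-population
#' component against `b = nbar/(nbar-1) * (pbar(1-pbar) - s2 (r-1)/r)`
#' within, using the sample-size-weighted frequency variance with the
#' standard `nc` correction for unequal sizes. Also returns the expected
#' heterozygosity from pooled frequencies. Monomorphic SNPs get `NA`.
#'
#' @param alt_counts Populations x SNPs matrix of alternate-allele copy
#'   counts.
#' @param n_copies Populations x SNPs matrix (or vector recycled per SNP) of
#'   total genotyped allele copies.
#' @return Tibble with `snp`, `he`, `fst`.
#' @export
#' @examples
#' ac <- rbind(c(32, 2), c(8, 2))
#' nc <- rbind(c(40, 40), c(40, 40))
#' wc_fst(ac, nc)
wc_fst <- function(alt_counts, n_copies) {
  alt_counts <- as.matrix(alt_counts)
  if (!is.matrix(n_copies)) {
    n_copies <- matrix(n_copies, nrow = nrow(alt_counts),
                       ncol = ncol(alt_counts))
  }
  r <- nrow(alt_counts)
  if (r < 2) abort("need at least two populations.")
  p <- alt_counts / n_copies
  nbar <- colMeans(n_copies)
  nc <- (colSums(n_copies) - colSums(n_copies^2) / colSums(n_copies)) /
    (r - 1)
  pbar <- colSums(n_copies * p) / colSums(n_copies)
  s2 <- colSums(n_copies * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  # haploid variance components (Weir & Cockerham without the h term)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  fst <- a / (a + b)
  mono <- pbar <= 0 | pbar >= 1
  fst[mono] <- NA_real_
  he <- 2 * pbar * (1 - pbar)
  tibble(snp = colnames(alt_counts) %||% paste0("snp", seq_along(fst)),
         he = as.numeric(he), fst = as.numeric(fst))
}

#' Per-sample inbreeding coefficient
#'
#' Method-of-moments F from observed vs expected homozygosity over the sites
#' genotyped in each sample:
#' `F = (O_hom - E_hom) / (L - E_hom)` with
#' `E_hom = sum_l 1 - 2 p_l (1 - p_l) * 2n/(2n - 1)`, the small-sample
#' corrected expectation (the convention of the standard VCF heterozygosity
#' tool). Allele frequencies are estimated from all samples jointly unless
#' supplied.
#'
#' @param dosages Samples x SNPs dosage matrix (0/1/2, `NA` missing).
#' @param freqs Optional per-SNP alternate-allele frequencies.
#' @param n_chrom Optional number of chromosomes behind `freqs` (defaults to
#'   twice the number of genotyped samples per site).
#' @return Tibble with `sample`, `n_sites`, `o_hom`, `e_hom`, `f`.
#' @export
inbreeding_coefficient <- function(dosages, freqs = NULL, n_chrom = NULL) {
  dosages <- as.matrix(dosages)
  n_geno <- colSums(!is.na(dosages))
  freqs <- freqs %||% (colSums(dosages, na.rm = TRUE) / (2 * n_geno))
  n_chrom <- n_chrom %||% (2 * n_geno)
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1 & n_chrom > 1
  d <- dosages[, poly, drop = FALSE]
  p <- freqs[poly]
  corr <- n_chrom[poly] / (n_chrom[poly] - 1)
  e_site <- 1 - 2 * p * (1 - p) * corr
  obs <- !is.na(d)
  o_hom <- rowSums(d != 1, na.rm = TRUE)
  e_hom <- obs %*% e_site
  n_sites <- rowSums(obs)
  f <- as.numeric((o_hom - e_hom) / (n_sites - e_hom))
  f[abs(n_sites - e_hom) < 1e-12] <- NA_real_
  tibble(sample = rownames(dosages) %||% paste0("s", seq_len(nrow(dosages))),
         n_sites = as.integer(n_sites), o_hom = as.integer(o_hom),
         e_hom = as.numeric(e_hom), f = f)
}
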