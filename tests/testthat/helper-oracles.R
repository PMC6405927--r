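# Independent brute-force oracles used across tests. These deliberately
# re-derive each quantity from its definition, without touching the package
# implementations they check.

# Tajima's D from first principles: pairwise differences summed over all
# C(n,2) pairs, segregating sites by column scan, constants from the
# closed forms.
oracle_tajima_d <- function(hap) {
  n <- nrow(hap)
  pairs <- utils::combn(n, 2)
  ndiff <- 0
  for (k in seq_len(ncol(pairs))) {
    ndiff <- ndiff + sum(hap[pairs[1, k], ] != hap[pairs[2, k], ])
  }
  pi_hat <- ndiff / ncol(pairs)
  s <- sum(apply(hap, 2, function(col) length(unique(col)) > 1))
  if (s == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

# exhaustive greedy LD pruning trace
oracle_ld_prune <- function(dosages, transcript, pos, r2_max) {
  keep <- integer(0)
  for (tr in unique(transcript)) {
    idx <- which(transcript == tr)
    idx <- idx[order(pos[idx])]
    retained <- integer(0)
    for (i in idx) {
      drop <- FALSE
      for (j in retained) {
        r <- suppressWarnings(stats::cor(dosages[, i], dosages[, j],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2_max) drop <- TRUE
      }
      if (!drop) retained <- c(retained, i)
    }
    keep <- c(keep, retained)
  }
  sort(keep)
}

# exhaustive window scan for the SNP-cluster rule
oracle_snp_cluster <- function(pos, window = 35, k = 3) {
  flagged <- logical(length(pos))
  for (start in pos) {
    inside <- which(pos >= start & pos <= start + window - 1)
    if (length(inside) >= k) flagged[inside] <- TRUE
  }
  flagged
}

# Weir-Cockerham theta via the ANOVA mean-square form (haploid data),
# algebraically independent of the variance-components coding
oracle_wc_fst_anova <- function(alt_counts, n_copies) {
  r <- nrow(alt_counts)
  p <- alt_counts / n_copies
  nvec <- n_copies[, 1]
  nbar <- mean(nvec)
  ntot <- sum(nvec)
  nc <- (ntot - sum(nvec^2) / ntot) / (r - 1)
  vapply(seq_len(ncol(alt_counts)), function(j) {
    pj <- p[, j]
    pbar <- sum(nvec * pj) / ntot
    msp <- sum(nvec * (pj - pbar)^2) / (r - 1)
    msg <- sum(nvec * pj * (1 - pj)) / sum(nvec - 1)
    (msp - msg) / (msp + (nc - 1) * msg)
  }, numeric(1))
}

# tiny balanced count study built directly (no generator), for DE unit tests
tiny_counts <- function(n_tx = 6, pops = c("G", "J", "LC", "M"),
                        n_geno = 2, n_rep = 2, base = 50, seed = 1) {
  withr::with_seed(seed, {
    meta <- expand.grid(replicate = seq_len(n_rep),
                        genotype_i = seq_len(n_geno),
                        population = pops,
                        stringsAsFactors = FALSE)
    meta <- tibble::tibble(
      sample = paste(meta$population, meta$genotype_i, meta$replicate,
                     sep = "_"),
      population = factor(meta$population, levels = pops),
      genotype = paste0(meta$population, meta$genotype_i),
      replicate = meta$replicate
    )
    counts <- matrix(rpois(n_tx * nrow(meta), base), nrow = n_tx,
                     dimnames = list(sprintf("t%03d", seq_len(n_tx)),
                                     meta$sample))
    list(counts = counts, meta = meta)
  })
}
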