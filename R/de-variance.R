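#' Partition expression variance between population and genotype
#'
#' Two-level nested ANOVA on `log2(normalized count + 1)` per transcript:
#' genotypes are nested within populations, the population effect is tested
#' against the genotype-within-population mean square and the genotype effect
#' against the residual mean square. P-values are Benjamini-Hochberg adjusted
#' across transcripts separately per factor, and each transcript is placed in
#' one of four categories by comparing both adjusted p-values to `alpha`.
#'
#' @param counts Count matrix, transcripts x samples (raw; normalized
#'   internally), or already-normalized values with `normalized = TRUE`.
#' @param meta Metadata tibble with `sample`, `population`, `genotype`.
#' @param alpha Significance level (inclusive).
#' @param normalized Set `TRUE` if `counts` are already normalized.
#' @return Tibble with `transcript`, `p_population`, `p_genotype`,
#'   `p_adj_population`, `p_adj_genotype`, `category` (one of
#'   `"population-only"`, `"genotype-only"`, `"both"`, `"neither"`).
#' @export
partition_variance <- function(counts, meta, alpha = 0.05,
                               normalized = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(meta$sample == colnames(counts)))
  geno <- as.factor(meta$genotype)
  pop <- as.factor(meta$population)
  pop_of_geno <- tapply(as.character(pop), geno, function(x) unique(x))
  if (any(lengths(pop_of_geno) > 1)) {
    abort("genotypes must be nested within populations.")
  }
  if (any(table(geno) < 2)) {
    abort("every genotype needs >= 2 replicates for the nested test.")
  }
  y <- if (normalized) counts else normalize_counts(counts)
  y <- log2(y + 1)

  N <- ncol(y)
  P <- nlevels(pop)
  Gt <- nlevels(geno)
  grand <- rowMeans(y)

  geno_idx <- split(seq_len(N), geno)
  pop_idx <- split(seq_len(N), pop)
  gm <- sapply(geno_idx, function(i) rowMeans(y[, i, drop = FALSE]))
  pm <- sapply(pop_idx, function(i) rowMeans(y[, i, drop = FALSE]))
  if (nrow(y) == 1) {
    gm <- matrix(gm, nrow = 1, dimnames = list(NULL, names(geno_idx)))
    pm <- matrix(pm, nrow = 1, dimnames = list(NULL, names(pop_idx)))
  }
  n_g <- lengths(geno_idx)
  n_p <- lengths(pop_idx)
  pop_of_g <- vapply(pop_of_geno[colnames(gm)], identity, "")

  ss_pop <- (pm - grand)^2 %*% n_p
  ss_geno <- (gm - pm[, match(pop_of_g, colnames(pm)), drop = FALSE])^2 %*% n_g
  resid <- y - gm[, match(as.character(geno), colnames(gm)), drop = FALSE]
  ss_res <- rowSums(resid^2)

  df_pop <- P - 1
  df_geno <- Gt - P
  df_res <- N - Gt
  f_pop <- (ss_pop / df_pop) / (ss_geno / df_geno)
  f_geno <- (ss_geno / df_geno) / (ss_res / df_res)
  p_pop <- pf(as.numeric(f_pop), df_pop, df_geno, lower.tail = FALSE)
  p_geno <- pf(as.numeric(f_geno), df_geno, df_res, lower.tail = FALSE)

  pa_pop <- p.adjust(p_pop, "BH")
  pa_geno <- p.adjust(p_geno, "BH")
  category <- dplyr::case_when(
    pa_pop <= alpha & pa_geno <= alpha ~ "both",
    pa_pop <= alpha ~ "population-only",
    pa_geno <= alpha ~ "genotype-only",
    .default = "neither"
  )
  tibble(
    transcript = rownames(counts) %||% paste0("t", seq_len(nrow(counts))),
    p_population = p_pop, p_genotype = p_geno,
    p_adj_population = pa_pop, p_adj_genotype = pa_geno,
    category = category
  )
}
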