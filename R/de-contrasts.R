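#' Pairwise negative-binomial Wald contrasts between populations
#'
#' For every ordered population pair `A_vs_B`, computes per transcript the
#' log2 fold change of normalized group means (with a +0.5 pseudocount on the
#' means), a Wald statistic `log2FC / SE` with the standard error from the
#' negative-binomial Fisher information under the two-group model
#' (`Var(log mu_g) ~ (1/mu_g + phi) / n_g`), a two-sided normal p-value, and
#' a Benjamini-Hochberg adjusted p-value computed within each pair across
#' transcripts. Transcripts flagged all-zero get missing results; a
#' degenerate (all-zero) group within a pair yields a missing p-value.
#'
#' @param counts Count matrix, transcripts x samples.
#' @param meta Sample metadata tibble with `sample` and `population` matching
#'   the columns of `counts`.
#' @param size_factors Optional size factors; computed if missing.
#' @param dispersions Optional [fit_dispersion()] result; computed if missing.
#' @return Tibble with `transcript`, `pair` (e.g. `"G_vs_J"`), `log2fc`,
#'   `se`, `stat`, `p`, `p_adj`.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_transcripts = 40, frac_de = 0.2, seed = 4))
#' ct <- pairwise_contrasts(sim$counts, sim$meta)
#' head(ct)
pairwise_contrasts <- function(counts, meta, size_factors = NULL,
                               dispersions = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(meta$sample == colnames(counts)))
  pops <- levels(as.factor(meta$population))
  if (any(table(meta$population) < 2)) {
    abort("each population needs >= 2 samples.")
  }
  size_factors <- size_factors %||% compute_size_factors(counts)
  dispersions <- dispersions %||%
    fit_dispersion(counts, meta$population, size_factors)
  norm <- normalize_counts(counts, size_factors)
  phi <- dispersions$dispersion
  tx <- dispersions$transcript
  all_zero <- dispersions$all_zero

  pair_tab <- utils::combn(pops, 2)
  out <- vector("list", ncol(pair_tab))
  for (k in seq_len(ncol(pair_tab))) {
    a <- pair_tab[1, k]
    b <- pair_tab[2, k]
    ia <- which(meta$population == a)
    ib <- which(meta$population == b)
    ma <- rowMeans(norm[, ia, drop = FALSE])
    mb <- rowMeans(norm[, ib, drop = FALSE])
    log2fc <- log2((ma + 0.5) / (mb + 0.5))
    va <- (1 / (ma + 0.5) + phi) / length(ia)
    vb <- (1 / (mb + 0.5) + phi) / length(ib)
    se <- sqrt(va + vb) / log(2)
    stat <- log2fc / se
    p <- 2 * stats::pnorm(-abs(stat))
    degenerate <- (ma == 0 & mb == 0) | all_zero
    p[degenerate] <- NA_real_
    stat[degenerate] <- NA_real_
    out[[k]] <- tibble(
      transcript = tx,
      pair = paste0(a, "_vs_", b),
      log2fc = as.numeric(log2fc),
      se = as.numeric(se),
      stat = as.numeric(stat),
      p = as.numeric(p),
      p_adj = as.numeric(p.adjust(p, method = "BH"))
    )
  }
  bind_rows(out)
}

#' Assign transcripts to the population where they are exclusively upregulated
#'
#' Applies the population-exclusive sign rule: a transcript is a DET of
#' population X if and only if, in all contrasts involving X, the adjusted
#' p-value is at or below `alpha` (ties count as significant) and the fold
#' change points to upregulation in X. The sign requirements of different
#' populations are mutually contradictory, so the resulting lists are
#' provably disjoint; everything else is `nonDET`.
#'
#' @param contrasts A [pairwise_contrasts()] tibble covering all pairs.
#' @param alpha Significance level on `p_adj` (default 0.05, inclusive).
#' @return Tibble with `transcript` and `det_population` (population label or
#'   `"nonDET"`).
#' @export
assign_population_dets <- function(contrasts, alpha = 0.05) {
  pairs <- unique(contrasts$pair)
  sides <- stringr::str_split_fixed(pairs, "_vs_", 2)
  pops <- sort(unique(as.vector(sides)))
  n_expected <- choose(length(pops), 2)
  if (length(pairs) != n_expected) {
    abort(sprintf("expected %d pairs for %d populations, got %d.",
                  n_expected, length(pops), length(pairs)))
  }
  tx <- unique(contrasts$transcript)
  wide_fc <- tidyr::pivot_wider(contrasts[c("transcript", "pair", "log2fc")],
                                names_from = "pair", values_from = "log2fc")
  wide_p <- tidyr::pivot_wider(contrasts[c("transcript", "pair", "p_adj")],
                               names_from = "pair", values_from = "p_adj")
  incomplete <- !stats::complete.cases(wide_p[pairs])
  if (any(incomplete)) {
    warn(sprintf("%d transcript(s) with missing contrasts set to nonDET.",
                 sum(incomplete)))
  }
  assign <- rep("nonDET", nrow(wide_fc))
  for (pop in pops) {
    ok <- rep(TRUE, nrow(wide_fc))
    for (k in seq_along(pairs)) {
      a <- sides[k, 1]
      b <- sides[k, 2]
      if (a != pop && b != pop) next
      fc <- wide_fc[[pairs[k]]]
      padj <- wide_p[[pairs[k]]]
      want_pos <- a == pop  # upregulated in pop means FC > 0 when pop is first
      sig <- !is.na(padj) & padj <= alpha &
        !is.na(fc) & (if (want_pos) fc > 0 else fc < 0)
      ok <- ok & sig
    }
    assign[ok] <- pop
  }
  tibble(transcript = wide_fc$transcript, det_population = assign)
}
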