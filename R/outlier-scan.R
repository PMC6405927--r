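# tips below one node, via parent-pointer climbing
tips_below <- function(tree, node) {
  if (node <= tree$n) return(node)
  out <- integer(0)
  for (tip in seq_len(tree$n)) {
    a <- tip
    while (a != 0L) {
      if (a == node) {
        out <- c(out, tip)
        break
      }
      a <- tree$parent[a]
    }
  }
  out
}

# one biallelic SNP under the island model: coalescent genealogy of
# n_per_deme samples in each of n_demes demes, a single mutation placed
# proportionally to branch length
sim_island_snp <- function(n_demes, n_per_deme, migration_rate) {
  tree <- sim_coal_tree(rep(n_per_deme, n_demes),
                        migration_rate = migration_rate)
  blen <- numeric(length(tree$parent))
  hp <- tree$parent > 0L
  blen[hp] <- tree$time[tree$parent[hp]] - tree$time[hp]
  node <- sample.int(length(blen), 1L, prob = blen)
  carriers <- tips_below(tree, node)
  counts <- tabulate(tree$deme[carriers], nbins = n_demes)
  counts
}

# mean WC FST over n_sims single-SNP island simulations
island_mean_fst <- function(n_sims, n_demes, n_per_deme, migration_rate) {
  ac <- replicate(n_sims,
                  sim_island_snp(n_demes, n_per_deme, migration_rate))
  res <- wc_fst(ac, n_per_deme)
  mean(res$fst, na.rm = TRUE)
}

#' FDist-style FST outlier scan
#'
#' Builds a neutral envelope for the joint distribution of expected
#' heterozygosity and FST by simulating biallelic SNPs under a symmetric
#' island model (single-mutation coalescent across `n_demes` demes), with the
#' migration rate tuned iteratively (bisection on the log scale, pilot
#' simulations) so the mean simulated FST matches the observed mean. The
#' simulated SNPs are binned by heterozygosity; per bin, empirical FST
#' quantiles at `(1 - ci)/2` and `1 - (1 - ci)/2` form the envelope.
#' Observed SNPs below the lower bound are candidate balancing outliers,
#' above the upper bound diversifying. Each SNP also gets an empirical
#' two-sided p-value from its bin's simulated FST distribution;
#' Benjamini-Hochberg at `fdr` demotes envelope outliers whose q-value is
#' too large back to neutral.
#'
#' @param observed Tibble with `snp`, `he`, `fst` (e.g. from [wc_fst()];
#'   monomorphic SNPs with `NA` FST are excluded from classification).
#' @param n_demes,n_per_deme Island-model sampling configuration (allele
#'   copies per deme).
#' @param ci Envelope confidence level.
#' @param fdr Benjamini-Hochberg false-discovery-rate level.
#' @param n_sims Number of simulated SNPs for the final envelope.
#' @param n_bins Number of heterozygosity bins.
#' @param seed Integer seed.
#' @param max_tune Maximum bisection iterations when matching the mean FST.
#' @param tune_sims Pilot simulations per bisection step.
#' @return An object of class `"outlier_scan"`: tibble with `snp`, `he`,
#'   `fst`, `p`, `q`, `class_envelope`, `class` (post-FDR, one of
#'   `balancing`, `diversifying`, `neutral`, `NA` for excluded SNPs);
#'   attributes carry the tuned migration rate, the envelope, and settings.
#' @export
fst_outlier_scan <- function(observed, n_demes = 4, n_per_deme = 12,
                             ci = 0.99, fdr = 0.1, n_sims = 20000,
                             n_bins = 12, seed = 1L, max_tune = 10,
                             tune_sims = 400) {
  stopifnot(all(c("he", "fst") %in% names(observed)))
  usable <- !is.na(observed$fst)
  if (sum(usable) < 1) abort("no scannable SNPs.")
  target <- mean(observed$fst[usable])
  target <- min(max(target, 0.005), 0.95)

  with_seed(seed, {
    # bisection on log migration rate; island-model FST falls with migration
    lo <- log(0.01)
    hi <- log(200)
    m <- exp((lo + hi) / 2)
    for (i in seq_len(max_tune)) {
      got <- island_mean_fst(tune_sims, n_demes, n_per_deme, m)
      if (abs(got - target) < 0.015) break
      if (got > target) lo <- log(m) else hi <- log(m)
      m <- exp((lo + hi) / 2)
    }
    got <- island_mean_fst(tune_sims, n_demes, n_per_deme, m)
    if (abs(got - target) > 0.05) {
      warn(sprintf(
        "mean simulated FST %.3f did not reach the observed %.3f; proceeding.",
        got, target))
    }

    ac <- replicate(n_sims, sim_island_snp(n_demes, n_per_deme, m))
    sim <- wc_fst(ac, n_per_deme)
    sim <- sim[!is.na(sim$fst), ]

    # heterozygosity bins with roughly equal occupancy
    brk <- unique(quantile(sim$he, probs = seq(0, 1, length.out = n_bins + 1)))
    brk[1] <- -Inf
    brk[length(brk)] <- Inf
    sim_bin <- cut(sim$he, brk)
    sim_by_bin <- split(sim$fst, sim_bin)
    qlo <- vapply(sim_by_bin, quantile, numeric(1), probs = (1 - ci) / 2,
                  na.rm = TRUE)
    qhi <- vapply(sim_by_bin, quantile, numeric(1), probs = 1 - (1 - ci) / 2,
                  na.rm = TRUE)

    obs_bin <- cut(observed$he, brk)
    p <- rep(NA_real_, nrow(observed))
    cls_env <- rep(NA_character_, nrow(observed))
    tail_p <- (1 - ci) / 2
    for (i in which(usable)) {
      b <- as.character(obs_bin[i])
      fst_sim <- sim_by_bin[[b]]
      if (is.null(fst_sim) || length(fst_sim) == 0) next
      n_s <- length(fst_sim)
      p_hi <- (sum(fst_sim >= observed$fst[i]) + 1) / (n_s + 1)
      p_lo <- (sum(fst_sim <= observed$fst[i]) + 1) / (n_s + 1)
      p[i] <- min(1, 2 * min(p_hi, p_lo))
      # envelope flag via the empirical tail probability (equivalent to the
      # quantile envelope but exact under ties/discreteness)
      cls_env[i] <- if (p_hi <= tail_p) {
        "diversifying"
      } else if (p_lo <= tail_p) {
        "balancing"
      } else {
        "neutral"
      }
    }
    q <- p.adjust(p, method = "BH")
    cls <- cls_env
    demote <- !is.na(cls) & cls != "neutral" & (is.na(q) | q > fdr)
    cls[demote] <- "neutral"
    out <- tibble(
      snp = observed$snp %||% paste0("snp", seq_len(nrow(observed))),
      he = observed$he, fst = observed$fst,
      p = p, q = q, class_envelope = cls_env, class = cls
    )
    attr(out, "migration_rate") <- m
    attr(out, "mean_sim_fst") <- got
    attr(out, "envelope") <- tibble(bin = names(qlo), lower = unname(qlo),
                                    upper = unname(qhi))
    attr(out, "settings") <- list(ci = ci, fdr = fdr, n_sims = n_sims,
                                  n_demes = n_demes,
                                  n_per_deme = n_per_deme, seed = seed)
    class(out) <- c("outlier_scan", class(out))
    out
  })
}

#' Transcript-level outlier labels
#'
#' Aggregates per-SNP outlier classes to the transcript level: `NC` when the
#' transcript had no scannable SNP, `noOL` when none was flagged, `Bal` /
#' `Div` when at least one balancing (resp. diversifying) SNP was found, and
#' `BalDiv` when both kinds occur in the same transcript.
#'
#' @param snp_classes Tibble with `transcript` and `class`
#'   (balancing/diversifying/neutral, `NA` = not scanned).
#' @param transcripts Optional vector of transcripts to label (those absent
#'   from `snp_classes` get `NC`).
#' @return Tibble with `transcript`, `outlier_label`.
#' @export
transcript_outlier_labels <- function(snp_classes, transcripts = NULL) {
  agg <- snp_classes |>
    summarise(
      any_scanned = any(!is.na(.data$class)),
      any_bal = any(.data$class == "balancing", na.rm = TRUE),
      any_div = any(.data$class == "diversifying", na.rm = TRUE),
      .by = "transcript"
    ) |>
    mutate(outlier_label = dplyr::case_when(
      !.data$any_scanned ~ "NC",
      .data$any_bal & .data$any_div ~ "BalDiv",
      .data$any_bal ~ "Bal",
      .data$any_div ~ "Div",
      .default = "noOL"
    )) |>
    select("transcript", "outlier_label")
  if (!is.null(transcripts)) {
    agg <- tibble(transcript = transcripts) |>
      left_join(agg, by = "transcript") |>
      mutate(outlier_label = tidyr::replace_na(.data$outlier_label, "NC"))
  }
  agg
}
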