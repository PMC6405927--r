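#' Median-of-ratios size factors
#'
#' Computes per-sample normalization factors against the geometric-mean
#' pseudo-reference: for each sample, the factor is the median across
#' transcripts of `count / geometric mean of the transcript's counts`, using
#' only transcripts with no zero count (so the geometric mean is positive).
#'
#' @param counts Non-negative integer matrix, transcripts x samples.
#' @return Named numeric vector of positive size factors (one per sample).
#' @export
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("t1", "t2"), c("a", "b")))
#' compute_size_factors(m)
compute_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(is.na(counts))) {
    abort("`counts` must be non-negative and complete.")
  }
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    abort("no transcript has all-positive counts; cannot form the reference.")
  }
  lc <- log(counts[all_pos, , drop = FALSE])
  log_ref <- rowMeans(lc)
  sf <- exp(apply(lc - log_ref, 2, median))
  setNames(as.numeric(sf), colnames(counts))
}

#' Divide counts by their size factors
#'
#' @param counts Count matrix.
#' @param size_factors From [compute_size_factors()]; computed if missing.
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  size_factors <- size_factors %||% compute_size_factors(counts)
  sweep(as.matrix(counts), 2, size_factors, "/")
}

#' Per-transcript negative-binomial dispersion by method of moments
#'
#' Estimates the NB dispersion phi (variance `mu + phi * mu^2`) from
#' normalized counts, pooling the within-group variance after removing group
#' means: `phi = max(floor, (s2 - m) / m^2)` with `s2` the pooled within-group
#' sample variance and `m` the overall mean. Transcripts with all-zero counts
#' are flagged and excluded from testing.
#'
#' @param counts Count matrix, transcripts x samples.
#' @param groups Factor of group labels (one per sample), typically the
#'   population.
#' @param size_factors Optional size factors; computed if missing.
#' @param floor Lower bound on the estimate.
#' @return Tibble with `transcript`, `dispersion`, `all_zero`.
#' @export
fit_dispersion <- function(counts, groups, size_factors = NULL,
                           floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) {
    abort("`groups` must have one label per sample.")
  }
  if (any(table(groups) < 2)) abort("every group needs >= 2 samples.")
  norm <- normalize_counts(counts, size_factors)
  g_idx <- split(seq_along(groups), groups)
  n <- ncol(norm)
  G <- length(g_idx)
  ss_within <- 0
  for (idx in g_idx) {
    gm <- rowMeans(norm[, idx, drop = FALSE])
    ss_within <- ss_within + rowSums((norm[, idx, drop = FALSE] - gm)^2)
  }
  s2 <- ss_within / (n - G)
  m <- rowMeans(norm)
  phi <- pmax(floor, (s2 - m) / m^2)
  all_zero <- rowSums(counts) == 0
  phi[all_zero] <- NA_real_
  tibble(transcript = rownames(counts) %||% paste0("t", seq_len(nrow(counts))),
         dispersion = as.numeric(phi),
         all_zero = unname(all_zero))
}
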