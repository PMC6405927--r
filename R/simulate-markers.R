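#' Simulate marker allele counts under the F model
#'
#' Generates per-population allele-count tables at neutral marker loci under
#' the admixture F model of drift from a shared ancestral pool: ancestral
#' frequencies at each locus are drawn from a symmetric Dirichlet(1), each
#' population's present-day frequencies from
#' `Dirichlet(pi * (1 - theta_p) / theta_p)`, and observed allele counts by
#' multinomial sampling of `2 * n_diploids_per_pop` allele copies. Larger
#' `theta_p` means stronger drift away from the ancestral frequencies.
#'
#' @param config A [sim_config()].
#' @return A list with
#'   \describe{
#'     \item{markers}{tibble in long format: `population`, `locus`, `allele`,
#'       `count` — the on-disk marker exchange format.}
#'     \item{freqs}{list of `n_pops x alleles` population frequency matrices,
#'       one per locus (handy for oracles).}
#'     \item{ancestral}{list of ancestral frequency vectors per locus.}
#'     \item{theta_true}{the drift coefficients used.}
#'   }
#' @export
#' @examples
#' mk <- simulate_markers(sim_config(n_marker_loci = 5, seed = 3))
#' head(mk$markers)
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "markers"), {
    P <- config$n_pops
    L <- config$n_marker_loci
    K <- config$alleles_per_locus
    n_copies <- 2L * config$n_diploids_per_pop
    theta <- config$theta_true

    ancestral <- vector("list", L)
    freqs <- vector("list", L)
    rows <- vector("list", L)
    for (l in seq_len(L)) {
      pi_l <- as.numeric(rdirichlet(1, rep(1, K)))
      p_pl <- matrix(NA_real_, P, K)
      counts <- matrix(0L, P, K)
      for (p in seq_len(P)) {
        conc <- pi_l * (1 - theta[p]) / theta[p]
        p_pl[p, ] <- as.numeric(rdirichlet(1, conc))
        counts[p, ] <- as.integer(rmultinom(1, n_copies, p_pl[p, ]))
      }
      ancestral[[l]] <- pi_l
      freqs[[l]] <- p_pl
      rows[[l]] <- tibble(
        population = rep(config$pops, each = K),
        locus = sprintf("L%03d", l),
        allele = rep(paste0("a", seq_len(K)), times = P),
        count = as.integer(t(counts))
      )
    }
    list(markers = bind_rows(rows),
         freqs = freqs,
         ancestral = ancestral,
         theta_true = theta)
  })
}

#' Multi-locus Weir-Cockerham FST from population allele frequencies
#'
#' Direct frequency-based estimator used as an oracle for the marker
#' generator: ratio of the among-population frequency variance to the pooled
#' heterozygosity, summed over loci and alleles. Under the F model its
#' expectation is close to the mean drift coefficient.
#'
#' @param freqs List of `P x K` population allele-frequency matrices.
#' @param n_per_pop Unused; retained so frequency- and count-based callers
#'   share a signature.
#' @return A single FST estimate.
#' @export
fst_from_freqs <- function(freqs, n_per_pop = NULL) {
  num <- 0
  den <- 0
  for (p_mat in freqs) {
    for (k in seq_len(ncol(p_mat))) {
      p <- p_mat[, k]
      pbar <- mean(p)
      num <- num + mean((p - pbar)^2)
      den <- den + pbar * (1 - pbar)
    }
  }
  num / den
}
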