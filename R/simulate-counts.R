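#' Simulate a transcript x sample count matrix under the drift null
#'
#' Draws negative-binomial read counts for a populations x genotypes x
#' replicates design. Per transcript, a baseline log2 mean is drawn, neutral
#' population effects come from the drift-null covariance
#' `MVN(0, 2 * diag(theta) * sigma_a2)`, genotype effects from
#' `N(0, sigma_g2)`, and counts from `NB(mu, size = 1/phi)` with
#' `mu = 2^(mu_t + a_p + g + planted effects)`.
#'
#' Planting is opt-in: a fraction `frac_de` of transcripts receives an extra
#' `de_log2fc` in exactly one population (population-exclusive upregulation),
#' and a disjoint fraction `frac_selected_expression` receives a
#' `selection_shift` in one population (divergence exceeding the drift null,
#' the target of the H test).
#'
#' @param config A [sim_config()].
#' @param theta_true Optional drift coefficients overriding
#'   `config$theta_true` (e.g. a posterior mean from markers).
#' @return A list with
#'   \describe{
#'     \item{counts}{integer matrix, transcripts x samples; columns named
#'       `POP_GENOTYPE_REP`.}
#'     \item{meta}{tibble with `sample`, `population`, `genotype`,
#'       `replicate`.}
#'     \item{truth}{tibble with `transcript`, `de_population` (`NA` if none),
#'       `expression_selected`, `pop_effect_1..P` (the realised log2
#'       population effects, planted shifts included).}
#'   }
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_transcripts = 20, seed = 7))
#' dim(sim$counts)
simulate_counts <- function(config, theta_true = NULL) {
  stopifnot(inherits(config, "sim_config"))
  theta <- theta_true %||% config$theta_true
  if (length(theta) != config$n_pops) {
    abort("`theta_true` must have one entry per population.")
  }
  check_positive(config$nb_dispersion, "nb_dispersion")
  with_seed(derive_seed(config$seed, "counts"), {
    P <- config$n_pops
    G <- config$genotypes_per_pop
    R <- config$reps_per_genotype
    T_ <- config$n_transcripts
    pops <- config$pops

    meta <- tidyr::expand_grid(
      population = factor(pops, levels = pops),
      genotype_i = seq_len(G),
      replicate = seq_len(R)
    ) |>
      mutate(genotype = paste0(.data$population, .data$genotype_i),
             sample = paste(.data$population, .data$genotype_i,
                            .data$replicate, sep = "_")) |>
      select("sample", "population", "genotype", "replicate")

    # baseline log2 abundance: wide dynamic range typical of bulk RNA-seq
    mu_t <- rnorm(T_, mean = 7, sd = 1.5)

    # neutral drift effects: independent across populations (diagonal theta)
    a <- matrix(rnorm(T_ * P, 0, rep(sqrt(2 * theta * config$sigma_a2),
                                     each = T_)),
                nrow = T_, ncol = P)

    # disjoint planted sets
    n_de <- round(config$frac_de * T_)
    n_sel <- round(config$frac_selected_expression * T_)
    idx <- sample.int(T_, n_de + n_sel)
    de_idx <- idx[seq_len(n_de)]
    sel_idx <- idx[n_de + seq_len(n_sel)]
    de_pop <- rep(NA_character_, T_)
    selected <- rep(FALSE, T_)
    if (n_de > 0) {
      de_pop[de_idx] <- sample(pops, n_de, replace = TRUE)
      a[cbind(de_idx, match(de_pop[de_idx], pops))] <-
        a[cbind(de_idx, match(de_pop[de_idx], pops))] + config$de_log2fc
    }
    if (n_sel > 0) {
      selected[sel_idx] <- TRUE
      sel_pop <- sample.int(P, n_sel, replace = TRUE)
      a[cbind(sel_idx, sel_pop)] <- a[cbind(sel_idx, sel_pop)] +
        config$selection_shift
    }

    g_eff <- matrix(rnorm(T_ * P * G, 0, sqrt(config$sigma_g2)),
                    nrow = T_, ncol = P * G)
    geno_levels <- unique(meta$genotype)

    log2mu <- mu_t +
      a[, match(meta$population, pops), drop = FALSE] +
      g_eff[, match(meta$genotype, geno_levels), drop = FALSE]
    mu <- 2^log2mu
    counts <- matrix(
      rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu),
      nrow = T_
    )
    storage.mode(counts) <- "integer"
    tx <- sprintf("t%05d", seq_len(T_))
    dimnames(counts) <- list(tx, meta$sample)

    truth <- tibble(transcript = tx,
                    de_population = de_pop,
                    expression_selected = selected)
    pe <- as_tibble(as.data.frame(a))
    names(pe) <- paste0("pop_effect_", pops)
    list(counts = counts, meta = meta, truth = bind_cols(truth, pe))
  })
}
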