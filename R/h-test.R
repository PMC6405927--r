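#' Per-genotype mean expression
#'
#' Averages normalized counts over the replicates of each genotype (one value
#' per genotype per transcript) and adds the `log2(x + 1)` transform used by
#' the drift-null model.
#'
#' @param counts Count matrix, transcripts x samples.
#' @param meta Metadata tibble with `sample`, `population`, `genotype`.
#' @param size_factors Optional size factors; computed if missing.
#' @return Tibble with `transcript`, `population`, `genotype`, `mean`,
#'   `log2_mean`.
#' @export
summarize_genotype_means <- function(counts, meta, size_factors = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(meta$sample == colnames(counts)))
  norm <- normalize_counts(counts, size_factors)
  geno <- factor(meta$genotype, levels = unique(meta$genotype))
  idx <- split(seq_len(ncol(norm)), geno)
  gm <- vapply(idx, function(i) rowMeans(norm[, i, drop = FALSE]),
               numeric(nrow(norm)))
  if (nrow(norm) == 1) gm <- matrix(gm, nrow = 1)
  pop_of <- vapply(idx, function(i) as.character(meta$population[i[1]]), "")
  tibble(
    transcript = rep(rownames(counts) %||% paste0("t", seq_len(nrow(norm))),
                     times = nlevels(geno)),
    population = rep(pop_of, each = nrow(norm)),
    genotype = rep(levels(geno), each = nrow(norm)),
    mean = as.numeric(gm),
    log2_mean = as.numeric(log2(gm + 1))
  ) |>
    arrange(.data$transcript, .data$population, .data$genotype)
}

#' Drift-null test of population expression divergence (H statistic)
#'
#' Fits, per transcript, the hierarchical model
#' `y_pg = mu + a_p + e_pg`, `e ~ N(0, sigma2)`, with the drift-null prior
#' `a ~ MVN(0, 2 * sigma2 * theta)` on the population effects, where the
#' coancestry matrix `theta` is redrawn each MCMC iteration from the supplied
#' posterior (propagating marker uncertainty). `sigma2` is the genetic
#' variance among clonal genotype means within populations; under neutral
#' drift the expected between-population covariance of trait means is
#' `2 theta` times that same variance, which is what makes the test a
#' quantitative-genetics drift null rather than a bare heterogeneity test.
#' Because `sigma2` is identified by the within-population degrees of
#' freedom, the between-population divergence is free to exceed it. Updates
#' are Gibbs for `mu` and `a` (conjugate normal, diagonalised in the
#' eigenbasis of `theta`) and random-walk Metropolis on `log sigma` with a
#' half-Cauchy prior scaled to the sample SD of `y`.
#'
#' H is the exceedance probability that the divergence of the observed
#' population means exceeds that of a drift-null replicate. Per retained
#' coancestry draw `theta^(s)`, the centred population means are reduced to
#' the Mahalanobis norm under the drift-null covariance `2 theta + I/G`
#' (pseudo-inverse on the centring null space), standardised by the
#' within-population variance estimator; under the null this ratio is
#' exactly F-distributed with `(P - 1, P(G - 1))` degrees of freedom given
#' `theta`, so the exceedance over null replicates integrates analytically
#' to the F cdf and H is averaged over the coancestry posterior:
#' `H = mean_s pf(F^(s), P - 1, P(G - 1))`. Under pure drift H is uniform
#' on (0, 1) up to coancestry uncertainty; H near 1 means the populations
#' have diverged more than drift can explain.
#'
#' @param genotype_means Long tibble from [summarize_genotype_means()] (or
#'   with columns `transcript`, `population`, `genotype`, `log2_mean`). A
#'   single transcript is simply a one-transcript tibble.
#' @param posterior A `coancestry_posterior`, a list of `P x P` PSD matrices,
#'   or a single fixed `P x P` matrix.
#' @param n_iter,burn_in,thin MCMC settings (desk-scale defaults; increase
#'   tenfold to match heavyweight runs).
#' @param threshold Selection threshold on H (inclusive).
#' @param seed Integer seed.
#' @return An object of class `"h_test"`: tibble with `transcript`, `h`,
#'   `selected`, `post_mu`, `post_sigma2`, plus one `effect_<pop>` column
#'   per population (posterior mean effects), and the run settings in
#'   attributes.
#' @export
#' @examples
#' cfg <- sim_config(n_transcripts = 5, seed = 8)
#' sim <- simulate_counts(cfg)
#' gm <- summarize_genotype_means(sim$counts, sim$meta)
#' ht <- h_test(gm, diag(cfg$theta_true), n_iter = 300, burn_in = 50, seed = 1)
#' ht
h_test <- function(genotype_means, posterior, n_iter = 600, burn_in = 100,
                   thin = 1, threshold = 0.95, seed = 1L) {
  need <- c("transcript", "population", "genotype", "log2_mean")
  stopifnot(all(need %in% names(genotype_means)))
  gm <- arrange(genotype_means, .data$transcript, .data$population,
                .data$genotype)
  pops <- sort(unique(gm$population))
  P <- length(pops)
  if (P < 2) abort("the H test needs at least two populations.")
  if (P < 3) warn("fewer than three populations: H is weakly identified.")

  theta_list <- if (inherits(posterior, "coancestry_posterior")) {
    theta_matrices(posterior)
  } else if (is.matrix(posterior)) {
    list(posterior)
  } else {
    posterior
  }
  if (any(vapply(theta_list, nrow, 1L) != P)) {
    abort("coancestry matrices must be P x P for the P populations present.")
  }

  # transcripts x populations x genotypes array of responses
  tx <- unique(gm$transcript)
  T_ <- length(tx)
  per_pg <- gm |>
    summarise(n = dplyr::n(), .by = c("transcript", "population"))
  G <- unique(per_pg$n)
  if (length(G) != 1) abort("the design must be balanced across populations.")
  if (G < 2) abort("need >= 2 genotypes per population.")
  y <- array(gm$log2_mean, dim = c(G, P, T_))   # genotype fastest
  ybar <- t(apply(y, c(2, 3), mean))            # T x P
  if (T_ == 1) ybar <- matrix(ybar, nrow = 1)
  ssw <- apply(y, 3, function(m) sum(sweep(m, 2, colMeans(m))^2))
  y_sd <- pmax(apply(y, 3, sd), 1e-8)
  flat <- apply(y, 3, function(m) var(as.numeric(m)) == 0)

  n_draws <- max(0L, (n_iter - burn_in) %/% thin)
  if (n_draws < 1) abort("chain settings leave no retained draws.")

  ybar_c <- ybar - rowMeans(ybar)     # centred population means
  s2_within <- ssw / (P * (G - 1))    # within-population variance estimate
  cmat <- diag(P) - 1 / P             # centring projector

  with_seed(seed, {
    mu <- rowMeans(ybar)
    sig <- pmax(sqrt(ssw / (P * (G - 1) + 1e-9)), 1e-4)
    b <- matrix(0, T_, P)
    s0 <- y_sd                                  # half-Cauchy scale
    h_acc <- numeric(T_)
    mu_acc <- numeric(T_)
    s2_acc <- numeric(T_)
    a_acc <- matrix(0, T_, P)
    kept <- 0L

    for (it in seq_len(n_iter)) {
      th <- theta_list[[sample.int(length(theta_list), 1L)]]
      ei <- eigen(2 * th, symmetric = TRUE)
      lam <- pmax(ei$values, 1e-12)             # pseudo-inverse guard
      U <- ei$vectors
      lam_m <- rep(lam, each = T_)

      ## population effects a (conjugate, in the eigenbasis of 2*theta);
      ## both prior and likelihood scale with sigma2, so the posterior mean
      ## of each component depends only on G and the eigenvalue
      z <- (ybar - mu) %*% U                    # T x P
      shrink <- lam_m / (G * lam_m + 1)
      v <- sig^2 * shrink
      mean_b <- G * shrink * z
      b <- mean_b + sqrt(v) * matrix(rnorm(T_ * P), T_, P)
      a <- b %*% t(U)

      ## grand mean mu (flat prior)
      mu <- rowMeans(ybar - a) + rnorm(T_, 0, sig / sqrt(P * G))

      ## shared variance: within-population residual + drift-null prior on a
      q <- rowSums(b^2 / lam_m)
      res2 <- ssw + G * rowSums((ybar - a - mu)^2) + q
      prop <- sig * exp(rnorm(T_, 0, 0.25))
      ll_old <- -(P * G + P) * log(sig) - res2 / (2 * sig^2) -
        log(1 + (sig / s0)^2) + log(sig)
      ll_new <- -(P * G + P) * log(prop) - res2 / (2 * prop^2) -
        log(1 + (prop / s0)^2) + log(prop)
      acc <- log(runif(T_)) < ll_new - ll_old
      sig[acc] <- prop[acc]

      if (it > burn_in && (it - burn_in) %% thin == 0) {
        kept <- kept + 1L
        ## pivotal drift-null exceedance given theta^(s): Mahalanobis norm
        ## of the centred means under 2*theta + I/G over the within-pop
        ## variance estimate is F(P-1, P(G-1)) under the null
        m_c <- cmat %*% (2 * th + diag(P) / G) %*% cmat
        em <- eigen(m_c, symmetric = TRUE)
        pos <- em$values > 1e-10 * max(em$values)
        proj <- ybar_c %*% em$vectors[, pos, drop = FALSE]
        w <- proj^2 %*% (1 / em$values[pos])
        f_stat <- (w / (P - 1)) / s2_within
        h_acc <- h_acc + pf(as.numeric(f_stat), P - 1, P * (G - 1))
        mu_acc <- mu_acc + mu
        s2_acc <- s2_acc + sig^2
        a_acc <- a_acc + a
      }
    }
    h <- h_acc / kept
    h[flat] <- NA_real_
    out <- tibble(
      transcript = tx,
      h = as.numeric(h),
      selected = !is.na(h) & h >= threshold,
      post_mu = mu_acc / kept,
      post_sigma2 = s2_acc / kept
    )
    eff <- as_tibble(as.data.frame(a_acc / kept))
    names(eff) <- paste0("effect_", pops)
    out <- bind_cols(out, eff)
    attr(out, "settings") <- list(n_iter = n_iter, burn_in = burn_in,
                                  thin = thin, threshold = threshold,
                                  seed = seed, n_draws = kept)
    class(out) <- c("h_test", class(out))
    out
  })
}

#' Simulate genotype means directly from the drift-null model
#'
#' Model-scale generator used to calibrate and power-check the H test
#' without going through read counts: per transcript,
#' `y_pg = mu + a_p + e_pg` with `e ~ N(0, sigma2)` and neutral effects
#' `a ~ MVN(0, 2 * sigma2 * theta)`. A fraction of transcripts instead
#' receives a fixed `shift` added to one population's effect.
#'
#' @param theta `P x P` PSD coancestry matrix (or vector of diagonal
#'   entries).
#' @param n_transcripts Number of transcripts.
#' @param n_genotypes Genotypes per population.
#' @param sigma2 Within-population variance of genotype means.
#' @param frac_shifted Fraction of transcripts with a planted shift.
#' @param shift Magnitude of the planted single-population shift.
#' @param pops Population labels.
#' @param seed Integer seed.
#' @return List with `genotype_means` (tibble as in
#'   [summarize_genotype_means()]) and `truth` (tibble `transcript`,
#'   `shifted`, `shift_population`).
#' @export
simulate_genotype_means <- function(theta, n_transcripts = 1000,
                                    n_genotypes = 6, sigma2 = 0.04,
                                    frac_shifted = 0, shift = 1,
                                    pops = NULL, seed = 1L) {
  if (!is.matrix(theta)) theta <- diag(theta)
  P <- nrow(theta)
  pops <- pops %||% (if (P == 4) POP_LEVELS else paste0("P", seq_len(P)))
  check_positive(sigma2, "sigma2")
  check_fraction(frac_shifted, "frac_shifted")
  with_seed(seed, {
    ei <- eigen(2 * sigma2 * theta, symmetric = TRUE)
    hl <- ei$vectors %*% diag(sqrt(pmax(ei$values, 0)), P)
    a <- matrix(rnorm(n_transcripts * P), n_transcripts) %*% t(hl)
    n_shift <- round(frac_shifted * n_transcripts)
    shifted <- seq_len(n_transcripts) %in% sample.int(n_transcripts, n_shift)
    shift_pop <- rep(NA_character_, n_transcripts)
    if (n_shift > 0) {
      which_pop <- sample.int(P, n_shift, replace = TRUE)
      shift_pop[shifted] <- pops[which_pop]
      a[cbind(which(shifted), which_pop)] <-
        a[cbind(which(shifted), which_pop)] + shift
    }
    mu <- rnorm(n_transcripts, 7, 1.5)
    tx <- sprintf("t%05d", seq_len(n_transcripts))
    out <- tidyr::expand_grid(transcript = tx, population = pops,
                              genotype_i = seq_len(n_genotypes)) |>
      mutate(
        genotype = paste0(.data$population, .data$genotype_i),
        log2_mean = mu[match(.data$transcript, tx)] +
          a[cbind(match(.data$transcript, tx),
                  match(.data$population, pops))] +
          rnorm(dplyr::n(), 0, sqrt(sigma2)),
        mean = 2^.data$log2_mean - 1
      ) |>
      select("transcript", "population", "genotype", "mean", "log2_mean")
    list(genotype_means = out,
         truth = tibble(transcript = tx, shifted = shifted,
                        shift_population = shift_pop))
  })
}

#' Flag transcripts whose divergence exceeds the drift null
#'
#' @param h Numeric vector of H statistics in `[0, 1]`.
#' @param threshold Inclusive threshold (default 0.95).
#' @return Logical vector (`NA` where H is undefined).
#' @export
#' @examples
#' classify_selection(c(0.96, 0.95, 0.5))
classify_selection <- function(h, threshold = 0.95) {
  stopifnot(is.numeric(h), all(is.na(h) | (h >= 0 & h <= 1)))
  h >= threshold
}

#' @method glance h_test
#' @export
glance.h_test <- function(x, ...) {
  s <- attr(x, "settings")
  tibble(n_transcripts = nrow(x),
         n_selected = sum(x$selected, na.rm = TRUE),
         frac_selected = mean(x$selected, na.rm = TRUE),
         n_draws = s$n_draws, threshold = s$threshold)
}
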