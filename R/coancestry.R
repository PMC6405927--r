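# internal: reshape the long marker tibble into count matrices
marker_arrays <- function(markers) {
  stopifnot(all(c("population", "locus", "allele", "count") %in%
                  names(markers)))
  markers <- arrange(markers, .data$locus, .data$allele, .data$population)
  pops <- sort(unique(markers$population))
  combos <- distinct(markers, .data$locus, .data$allele)
  J <- nrow(combos)
  key <- paste(combos$locus, combos$allele)
  counts <- matrix(0, nrow = length(pops), ncol = J,
                   dimnames = list(pops, key))
  idx <- cbind(match(markers$population, pops),
               match(paste(markers$locus, markers$allele), key))
  counts[idx] <- markers$count
  locus_of <- factor(combos$locus, levels = unique(combos$locus))
  list(counts = counts, locus_of = locus_of, pops = pops,
       loci = levels(locus_of))
}

# Dirichlet-multinomial log-likelihood, populations x loci, with
# concentration c_p = (1 - theta_p) / theta_p and ancestral weights pi
dm_loglik <- function(counts, locus_of, theta, pi_vec, n_pl) {
  cvec <- (1 - theta) / theta
  alpha <- outer(cvec, pi_vec)              # P x J
  term <- lgamma(alpha + counts) - lgamma(alpha)
  per_locus <- rowsum(t(term), locus_of)    # L x P
  t(per_locus) + lgamma(cvec) - lgamma(outer(cvec, rep(1, ncol(n_pl))) + n_pl)
}

#' Estimate population coancestry from marker allele counts (F model)
#'
#' Bayesian estimation of per-population drift (coancestry) coefficients
#' theta under the admixture F model: present-day population allele
#' frequencies at each locus are Dirichlet-distributed around ancestral
#' frequencies `pi_l` with concentration `pi_l * (1 - theta_p) / theta_p`,
#' and observed allele counts are multinomial. The population frequencies are
#' marginalized analytically (Dirichlet-multinomial likelihood), leaving a
#' componentwise Metropolis-Hastings sampler over `theta` (logit random walk,
#' uniform prior on (0.001, 0.999)) and `pi_l` (Dirichlet proposals, flat
#' symmetric Dirichlet(1) prior).
#'
#' The estimated coancestry matrix is diagonal (`diag(theta_p)`): populations
#' drift independently from the shared ancestor and no admixture component is
#' fitted. Downstream, [h_test()] accepts arbitrary PSD coancestry matrices.
#'
#' @param markers Long marker tibble: `population`, `locus`, `allele`,
#'   `count`.
#' @param n_iter Total MCMC iterations.
#' @param burn_in Iterations discarded before thinning.
#' @param thin Thinning interval; `floor((n_iter - burn_in)/thin)` draws are
#'   kept.
#' @param seed Integer seed for the chain.
#' @param proposal_sd Logit-scale random-walk standard deviation for theta.
#' @param pi_concentration Concentration of the Dirichlet proposal for pi.
#' @return An object of class `"coancestry_posterior"`: list with
#'   `theta_draws` (draws x populations matrix), `pi_draws` (draws x
#'   locus-allele matrix), `pops`, `accept` (acceptance rates), and the chain
#'   settings.
#' @export
#' @examples
#' mk <- simulate_markers(sim_config(n_marker_loci = 10, seed = 1))
#' post <- estimate_coancestry(mk$markers, n_iter = 2000, burn_in = 500,
#'                             thin = 10, seed = 1)
#' glance(post)
estimate_coancestry <- function(markers, n_iter = 20000, burn_in = 2000,
                                thin = 100, seed = 1L, proposal_sd = 0.3,
                                pi_concentration = 50) {
  arr <- marker_arrays(markers)
  P <- nrow(arr$counts)
  if (P < 2) abort("need at least two populations.")
  n_pl <- t(rowsum(t(arr$counts), arr$locus_of))   # P x L totals
  # polymorphism check: a locus where one allele carries all copies in every
  # population is uninformative; all-monomorphic data cannot be fit
  poly <- vapply(split(seq_along(arr$locus_of), arr$locus_of), function(j) {
    sub <- arr$counts[, j, drop = FALSE]
    any(colSums(sub) > 0 & colSums(sub) < sum(sub))
  }, TRUE)
  if (!any(poly)) abort("all marker loci are monomorphic.")

  lo <- 0.001
  hi <- 0.999
  n_draws <- max(0L, (n_iter - burn_in) %/% thin)
  if (n_draws < 1) abort("chain settings leave no retained draws.")

  with_seed(seed, {
    J <- ncol(arr$counts)
    locus_of <- arr$locus_of
    # initial values: moment-style start at moderate drift
    theta <- rep(0.1, P)
    pi_vec <- as.numeric(colSums(arr$counts))
    tot <- tapply(pi_vec, locus_of, sum)[locus_of]
    pi_vec <- (pi_vec + 1) / as.numeric(tot + nlevels(locus_of))
    # normalise within locus
    pi_vec <- pi_vec / as.numeric(tapply(pi_vec, locus_of, sum)[locus_of])

    ll <- dm_loglik(arr$counts, locus_of, theta, pi_vec, n_pl)   # P x L
    theta_draws <- matrix(NA_real_, n_draws, P,
                          dimnames = list(NULL, arr$pops))
    pi_draws <- matrix(NA_real_, n_draws, J,
                       dimnames = list(NULL, colnames(arr$counts)))
    acc_theta <- 0
    acc_pi <- 0
    d <- 0L
    L <- nlevels(locus_of)

    for (it in seq_len(n_iter)) {
      ## theta update (vectorised over populations; independent given pi)
      u <- stats::qlogis((theta - lo) / (hi - lo))
      u_new <- u + rnorm(P, 0, proposal_sd)
      theta_new <- lo + (hi - lo) * stats::plogis(u_new)
      ll_new <- dm_loglik(arr$counts, locus_of, theta_new, pi_vec, n_pl)
      # Jacobian of the logit reparameterisation (uniform prior on theta)
      jac <- log(theta_new - lo) + log(hi - theta_new) -
        log(theta - lo) - log(hi - theta)
      ratio <- rowSums(ll_new) - rowSums(ll) + jac
      acc <- log(runif(P)) < ratio
      theta[acc] <- theta_new[acc]
      ll[acc, ] <- ll_new[acc, , drop = FALSE]
      acc_theta <- acc_theta + mean(acc)

      ## pi update (vectorised over loci; independent given theta)
      alpha_prop <- pi_concentration * pi_vec + 0.05
      g <- rgamma(J, shape = alpha_prop)
      gs <- as.numeric(tapply(g, locus_of, sum)[locus_of])
      pi_new <- g / gs
      ll_new <- dm_loglik(arr$counts, locus_of, theta, pi_new, n_pl)
      alpha_back <- pi_concentration * pi_new + 0.05
      # Dirichlet proposal density terms, per locus
      fwd <- (alpha_prop - 1) * log(pi_new) - lgamma(alpha_prop)
      bwd <- (alpha_back - 1) * log(pi_vec) - lgamma(alpha_back)
      qdiff <- tapply(bwd - fwd, locus_of, sum) +
        lgamma(tapply(alpha_back, locus_of, sum)) -
        lgamma(tapply(alpha_prop, locus_of, sum))
      ratio_l <- colSums(ll_new) - colSums(ll) + as.numeric(qdiff)
      acc_l <- log(runif(L)) < ratio_l
      keep <- acc_l[as.integer(locus_of)]
      pi_vec[keep] <- pi_new[keep]
      ll[, acc_l] <- ll_new[, acc_l, drop = FALSE]
      acc_pi <- acc_pi + mean(acc_l)

      if (it > burn_in && (it - burn_in) %% thin == 0 && d < n_draws) {
        d <- d + 1L
        theta_draws[d, ] <- theta
        pi_draws[d, ] <- pi_vec
      }
    }
    acc_theta <- acc_theta / n_iter
    acc_pi <- acc_pi / n_iter
    if (acc_theta < 0.01 || acc_pi < 0.01) {
      warn(sprintf("poor MCMC mixing (acceptance theta %.3f, pi %.3f).",
                   acc_theta, acc_pi))
    }
    structure(
      list(theta_draws = theta_draws[seq_len(d), , drop = FALSE],
           pi_draws = pi_draws[seq_len(d), , drop = FALSE],
           pops = arr$pops,
           accept = c(theta = acc_theta, pi = acc_pi),
           n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed),
      class = "coancestry_posterior"
    )
  })
}

#' @export
print.coancestry_posterior <- function(x, ...) {
  cat("<coancestry_posterior>\n")
  cat(sprintf("  %d draws over %d populations (%d iterations, burn-in %d, thin %d)\n",
              nrow(x$theta_draws), length(x$pops), x$n_iter, x$burn_in,
              x$thin))
  cat("  posterior mean theta:",
      paste(sprintf("%s=%.3f", x$pops, colMeans(x$theta_draws)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Coancestry matrix draws from a posterior
#'
#' Returns the retained posterior draws as `P x P` (diagonal) coancestry
#' matrices, the form consumed by [h_test()].
#'
#' @param posterior A `coancestry_posterior`.
#' @return List of `P x P` matrices.
#' @export
theta_matrices <- function(posterior) {
  stopifnot(inherits(posterior, "coancestry_posterior"))
  lapply(seq_len(nrow(posterior$theta_draws)), function(i) {
    diag(posterior$theta_draws[i, ], nrow = length(posterior$pops))
  })
}

#' Tidy posterior draws of the coancestry coefficients
#' @param x A `coancestry_posterior`.
#' @param ... Unused.
#' @return Tibble with `draw`, `population`, `theta`.
#' @method tidy coancestry_posterior
#' @export
tidy.coancestry_posterior <- function(x, ...) {
  as_tibble(x$theta_draws) |>
    mutate(draw = dplyr::row_number()) |>
    tidyr::pivot_longer(-"draw", names_to = "population",
                        values_to = "theta")
}

#' One-row posterior summary
#' @param x A `coancestry_posterior`.
#' @param ... Unused.
#' @return Tibble with draw counts, acceptance rates and the posterior mean
#'   and sd of each population's theta (wide).
#' @method glance coancestry_posterior
#' @export
glance.coancestry_posterior <- function(x, ...) {
  pm <- colMeans(x$theta_draws)
  ps <- apply(x$theta_draws, 2, sd)
  out <- tibble(n_draws = nrow(x$theta_draws),
                accept_theta = unname(x$accept["theta"]),
                accept_pi = unname(x$accept["pi"]))
  bind_cols(out,
            as_tibble(as.list(setNames(pm, paste0("theta_", x$pops)))),
            as_tibble(as.list(setNames(ps, paste0("sd_", x$pops)))))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
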