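#' Simulate a coalescent genealogy
#'
#' Basic Hudson coalescent without recombination, in time units of 2N
#' generations. Three demographies are supported: a single constant-size
#' population, exponential growth (looking backwards the population shrinks,
#' so coalescence accelerates; sampled by inverting the cumulative hazard),
#' and an island model with `D` demes exchanging migrants at a scaled rate
#' (per-lineage migration intensity `migration_rate / 2`), where lineages
#' coalesce only within demes.
#'
#' @param n_per_deme Integer vector of sampled haplotypes per deme; a single
#'   number means one panmictic deme.
#' @param growth_rate Scaled exponential growth rate (0 = constant size).
#' @param migration_rate Scaled migration rate between demes; must be > 0
#'   when more than one deme holds more than one lineage.
#' @return A list with `n` (total tips), `parent` (parent index per node;
#'   node ids `1..n` are tips, the root has parent 0), `time` (node times,
#'   tips at 0), and `deme` (tip deme assignment).
#' @export
sim_coal_tree <- function(n_per_deme, growth_rate = 0, migration_rate = 0) {
  n_per_deme <- as.integer(n_per_deme)
  stopifnot(all(n_per_deme >= 0), sum(n_per_deme) >= 2)
  n <- sum(n_per_deme)
  D <- length(n_per_deme)
  if (D > 1 && migration_rate <= 0) {
    abort("migration_rate must be > 0 with more than one deme.")
  }
  if (D > 1 && growth_rate != 0) {
    abort("growth is only supported for a single deme.")
  }
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  tip_deme <- rep(seq_len(D), times = n_per_deme)

  active <- seq_len(n)           # node ids of live lineages
  deme <- tip_deme               # deme of each live lineage
  t_now <- 0
  next_node <- n + 1L

  while (length(active) > 1L) {
    k_d <- tabulate(deme, nbins = D)
    coal_rates <- k_d * (k_d - 1) / 2
    mig_rate <- if (D > 1) length(active) * migration_rate / 2 else 0
    tot <- sum(coal_rates) + mig_rate
    if (tot <= 0) abort("coalescent stalled: no feasible event.")
    if (growth_rate > 0) {
      # nonhomogeneous rate tot * exp(g t); invert the cumulative hazard
      e <- rexp(1)
      t_now <- log(exp(growth_rate * t_now) + growth_rate * e / tot) /
        growth_rate
    } else {
      t_now <- t_now + rexp(1, tot)
    }
    if (runif(1) < mig_rate / tot) {
      i <- sample.int(length(active), 1L)
      deme[i] <- if (D == 2) 3L - deme[i] else {
        sample(setdiff(seq_len(D), deme[i]), 1L)
      }
    } else {
      d <- sample.int(D, 1L, prob = coal_rates)
      in_d <- which(deme == d)
      pair <- in_d[sample.int(length(in_d), 2L)]
      node <- next_node
      next_node <- next_node + 1L
      parent[active[pair]] <- node
      time[node] <- t_now
      active <- c(active[-pair], node)
      deme <- c(deme[-pair], d)
    }
  }
  list(n = n, parent = parent, time = time, deme = tip_deme)
}

# leaves below every node, as a list of integer vectors
descendant_tips <- function(tree) {
  n_nodes <- length(tree$parent)
  desc <- vector("list", n_nodes)
  for (i in seq_len(tree$n)) desc[[i]] <- i
  # children lists; internal nodes are created in increasing time order,
  # so a forward pass over internal ids accumulates correctly
  for (node in (tree$n + 1L):n_nodes) {
    kids <- which(tree$parent == node)
    desc[[node]] <- sort(unlist(desc[kids]))
  }
  desc
}

#' Drop infinite-sites mutations on a coalescent tree
#'
#' Places `Poisson(theta_w / 2 * total branch length)` mutations uniformly on
#' the genealogy; each mutation creates one biallelic segregating site whose
#' derived allele is carried by the tips below the mutated branch. Under
#' constant size this gives `E[S] = theta_w * sum(1/i)`.
#'
#' @param tree A genealogy from [sim_coal_tree()].
#' @param theta_w Scaled mutation rate (4Nu per locus).
#' @return A 0/1 matrix of `n` haplotypes x `S` sites (0 columns if the locus
#'   is monomorphic).
#' @export
mutate_tree <- function(tree, theta_w) {
  check_positive(theta_w, "theta_w", strict = FALSE)
  n_nodes <- length(tree$parent)
  blen <- numeric(n_nodes)
  has_parent <- tree$parent > 0L
  blen[has_parent] <- tree$time[tree$parent[has_parent]] -
    tree$time[has_parent]
  total <- sum(blen)
  s <- rpois(1, theta_w / 2 * total)
  if (s == 0 || total == 0) {
    return(matrix(0L, nrow = tree$n, ncol = 0))
  }
  branch <- sample.int(n_nodes, s, replace = TRUE, prob = blen)
  desc <- descendant_tips(tree)
  hap <- matrix(0L, nrow = tree$n, ncol = s)
  for (j in seq_len(s)) hap[desc[[branch[j]]], j] <- 1L
  # drop sites fixed in the sample (mutation above the root never happens,
  # but a branch may subtend all tips when the final coalescence is pending)
  poly <- colSums(hap) > 0 & colSums(hap) < tree$n
  hap[, poly, drop = FALSE]
}

#' Simulate one locus under a named demographic scenario
#'
#' Convenience wrapper: draws a genealogy under `constant`, `growth`, or
#' `structured` (two demes, pooled sample) demography and drops
#' infinite-sites mutations on it.
#'
#' @param n Haplotypes sampled.
#' @param theta_w Scaled mutation rate.
#' @param scenario One of `"constant"`, `"growth"`, `"structured"`.
#' @param growth_rate,migration_rate Scenario parameters.
#' @return 0/1 haplotype matrix (`n` x segregating sites).
#' @export
#' @examples
#' dim(sim_locus(8, 3))
sim_locus <- function(n, theta_w, scenario = "constant", growth_rate = 20,
                      migration_rate = 0.1) {
  tree <- switch(
    scenario,
    constant = sim_coal_tree(n),
    growth = sim_coal_tree(n, growth_rate = growth_rate),
    structured = sim_coal_tree(c(ceiling(n / 2), floor(n / 2)),
                               migration_rate = migration_rate),
    abort(sprintf("unknown scenario '%s'", scenario))
  )
  mutate_tree(tree, theta_w)
}
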