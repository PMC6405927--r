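#' Derive a reproducible subsystem seed from a global seed and a label
#'
#' All stochastic stages of the pipeline draw their RNG state from one global
#' integer seed. Each subsystem (markers, counts, haplotypes, clusters, MCMC
#' chains, outlier envelopes) mixes the global seed with a short text label via
#' a deterministic string hash, so stages are reproducible independently of
#' the order in which they run.
#'
#' @param seed Global integer seed.
#' @param label Character label naming the subsystem.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1L, "markers")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(label)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# run code under a local RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(!is.na(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) abort(sprintf("`%s` must be %s.", name, if (strict) "> 0" else ">= 0"))
  invisible(x)
}

# draw from a Dirichlet(alpha) distribution, one row per draw
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# stable log of Dirichlet-multinomial pmf components (without the
# multinomial coefficient, which cancels in Metropolis-Hastings ratios)
ldirmult_kernel <- function(counts, alpha) {
  # counts, alpha: vectors of equal length
  sum(lgamma(alpha + counts) - lgamma(alpha)) +
    lgamma(sum(alpha)) - lgamma(sum(alpha) + sum(counts))
}
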