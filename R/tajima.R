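#' Tajima's D from a phased haplotype matrix
#'
#' Computes, for one locus and one population sample, the number of
#' segregating sites `S`, the mean number of pairwise differences `pi`, and
#' Tajima's D
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`
#' with the classical constants `a1, a2, b1, b2, c1, c2, e1, e2` derived from
#' the sample size. A two-sided p-value is obtained from the beta
#' approximation to D's null density over its theoretical support
#' `(Dmin, Dmax)`. With `S = 0` both D and p are undefined.
#'
#' @param hap 0/1 matrix, haplotypes x sites (column = segregating site), or
#'   a character matrix of aligned sequences (rows = haplotypes).
#' @return One-row tibble: `n`, `s`, `pi`, `theta_w`, `d`, `p`.
#' @export
#' @examples
#' hap <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 0, 0), c(0, 0, 0))
#' tajimas_d(hap)
tajimas_d <- function(hap) {
  if (is.character(hap)) {
    # aligned sequences: keep polymorphic columns as 0/1 vs the first allele
    hap <- apply(hap, 2, function(col) as.integer(col != col[1]))
  }
  hap <- as.matrix(hap)
  n <- nrow(hap)
  if (n < 4) abort("Tajima's D needs at least 4 haplotypes.")
  counts <- colSums(hap)
  seg <- counts > 0 & counts < n
  s <- sum(seg)
  k <- tajima_constants(n)
  if (s == 0) {
    return(tibble(n = n, s = 0L, pi = 0, theta_w = 0,
                  d = NA_real_, p = NA_real_))
  }
  j <- counts[seg]
  pi_hat <- sum(2 * j * (n - j)) / (n * (n - 1))
  theta_w <- s / k$a1
  d <- (pi_hat - theta_w) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
  tibble(n = n, s = as.integer(s), pi = pi_hat, theta_w = theta_w,
         d = d, p = tajima_p(d, n))
}

#' Tajima's constants for sample size n
#'
#' The closed-form coefficients entering D's variance normalisation.
#'
#' @param n Number of sampled haplotypes (>= 4).
#' @return Named list `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

# two-sided p-value from the beta approximation of D's null density,
# rescaled to the support (Dmin, Dmax)
tajima_p <- function(d, n) {
  k <- tajima_constants(n)
  dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  dmax <- ((n + 1) / (2 * n) - 1 / k$a1) / sqrt(k$e2)
  # Tajima's beta parameterisation: mean 0, variance 1 on (dmin, dmax)
  alpha <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
  beta <- (1 + dmin * dmax) * dmin / (dmax - dmin)
  x <- (d - dmin) / (dmax - dmin)
  x <- pmin(pmax(x, 0), 1)
  cdf <- pbeta(x, beta, alpha)
  2 * pmin(cdf, 1 - cdf)
}
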