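#' Halton quasi-random sequences
#'
#' Multidimensional Halton points: dimension `d` uses the van der Corput
#' sequence in the `d`-th prime base. An initial `burn` points can be
#' dropped (common practice, since the leading points of each base are
#' coarse and correlated across bases), and digits can optionally be
#' scrambled with a seeded random permutation per base (fixing digit 0) to
#' break the correlation between higher-prime dimensions.
#'
#' @param n Number of points.
#' @param dim Number of dimensions (at most 25).
#' @param burn Number of leading points to drop.
#' @param scramble Scramble digits with seeded permutations.
#' @param seed Seed for scrambling permutations (ignored otherwise).
#' @return An `n` x `dim` matrix of points in (0, 1).
#' @examples
#' halton(3, 1)  # 1/2, 1/4, 3/4
#' @export
halton <- function(n, dim = 1, burn = 0, scramble = FALSE, seed = 1L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97)
  if (dim > length(primes)) {
    stop("at most ", length(primes), " dimensions supported", call. = FALSE)
  }
  if (scramble) {
    set.seed(seed)
    perms <- lapply(primes[seq_len(dim)], function(b) {
      c(0L, sample.int(b - 1))  # digit 0 stays 0
    })
  }
  idx <- seq_len(n) + burn
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    x <- numeric(n)
    i <- idx
    f <- 1 / b
    while (any(i > 0)) {
      digit <- i %% b
      if (scramble) digit <- perms[[d]][digit + 1L]
      x <- x + digit * f
      i <- i %/% b
      f <- f / b
    }
    out[, d] <- x
  }
  out
}

## standard-normal Halton draws for simulated likelihood: an
## (n_resp x n_draws x n_rand) array; respondent i uses points
## ((i-1)*n_draws + 1):(i*n_draws) of the sequence in each dimension
draws_array <- function(n_resp, n_draws, n_rand, burn = 10, scramble = FALSE,
                        seed = 1L) {
  if (n_rand == 0) return(array(0, dim = c(n_resp, n_draws, 0)))
  h <- halton(n_resp * n_draws, n_rand, burn = burn, scramble = scramble,
              seed = seed)
  z <- stats::qnorm(h)
  out <- array(0, dim = c(n_resp, n_draws, n_rand))
  for (k in seq_len(n_rand)) {
    out[, , k] <- matrix(z[, k], n_resp, n_draws, byrow = TRUE)
  }
  out
}
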