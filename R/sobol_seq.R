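# Quasi-random Sobol' sequence generator (base-2 digital sequence).
#
# Direction numbers are built from primitive polynomials over GF(2), found by
# deterministic exhaustive search in increasing (degree, value) order, with
# initial direction integers drawn from a fixed internal linear-congruential
# stream (odd, m_i < 2^i), so the unscrambled sequence is a package constant.
# Randomization is a seeded digital shift (per-dimension XOR mask), which
# preserves the digital-net structure while giving an unbiased estimator.
# 31 bits of resolution are used so all integer work stays in R's int range.

.SOBOL_BITS <- 31L

# GF(2) polynomial arithmetic on bit-packed integers --------------------------

gf2_mulmod <- function(a, b, p, s) {
  # (a * b) mod p over GF(2); s = degree of p
  r <- 0L
  while (b > 0) {
    if (bitwAnd(b, 1L) == 1L) r <- bitwXor(r, a)
    b <- bitwShiftR(b, 1L)
    a <- bitwShiftL(a, 1L)
    if (bitwAnd(a, bitwShiftL(1L, s)) != 0L) a <- bitwXor(a, p)
  }
  r
}

gf2_powmod <- function(base, e, p, s) {
  r <- 1L
  while (e > 0) {
    if (e %% 2 == 1) r <- gf2_mulmod(r, base, p, s)
    base <- gf2_mulmod(base, base, p, s)
    e <- e %/% 2
  }
  r
}

prime_factors <- function(m) {
  f <- integer(0); d <- 2
  while (d * d <= m) {
    while (m %% d == 0) { f <- c(f, d); m <- m %/% d }
    d <- d + 1
  }
  if (m > 1) f <- c(f, m)
  unique(f)
}

is_primitive_poly <- function(p, s) {
  if (bitwAnd(p, 1L) != 1L) return(FALSE)      # constant term must be 1
  m <- 2^s - 1
  if (gf2_powmod(2L, m, p, s) != 1L) return(FALSE)    # x^(2^s-1) == 1
  for (q in prime_factors(m)) {
    if (gf2_powmod(2L, m %/% q, p, s) == 1L) return(FALSE)
  }
  TRUE
}

# first n primitive polynomials, ordered by degree then value
primitive_polys <- function(n) {
  out <- integer(0); deg <- integer(0); s <- 1L
  while (length(out) < n) {
    for (p in (2^s + 1):(2^(s + 1) - 1)) {
      if (is_primitive_poly(as.integer(p), s)) {
        out <- c(out, as.integer(p)); deg <- c(deg, s)
        if (length(out) >= n) break
      }
    }
    s <- s + 1L
  }
  list(poly = out, degree = deg)
}

# fixed internal LCG used only to fix the initial direction integers
.dn_lcg <- function(state) {
  (1103515245 * state + 12345) %% 2147483648
}

# direction integers V[k, j], k = 1..bits, j = 1..d
sobol_directions <- function(d, bits = .SOBOL_BITS) {
  V <- matrix(0L, bits, d)
  V[, 1] <- as.integer(2^(bits - seq_len(bits)))     # van der Corput
  if (d == 1) return(V)
  pp <- primitive_polys(d - 1)
  state <- 986543210
  for (j in 2:d) {
    p <- pp$poly[j - 1]; s <- pp$degree[j - 1]
    a <- integer(max(s - 1, 0))
    for (i in seq_len(max(s - 1, 0))) {
      a[i] <- bitwAnd(bitwShiftR(p, s - i), 1L)
    }
    m <- integer(bits)
    for (i in seq_len(min(s, bits))) {
      state <- .dn_lcg(state)
      u <- state / 2147483648
      m[i] <- as.integer(2 * floor(u * 2^(i - 1)) + 1)   # odd, < 2^i
    }
    if (bits > s) {
      for (k in (s + 1):bits) {
        acc <- bitwXor(m[k - s], as.integer(m[k - s] * 2^s))
        for (i in seq_len(s - 1)) {
          if (a[i] == 1L) acc <- bitwXor(acc, as.integer(m[k - i] * 2^i))
        }
        m[k] <- acc
      }
    }
    V[, j] <- as.integer(m[seq_len(bits)] * 2^(bits - seq_len(bits)))
  }
  V
}

count_trailing_zeros <- function(k) {
  z <- 0L
  while (k %% 2 == 0) { k <- k %/% 2; z <- z + 1L }
  z
}

#' Generate Sobol' quasi-random points in the unit hypercube
#'
#' Gray-code construction with 31-bit resolution. With `scramble = TRUE`
#' (default) a per-dimension random digital shift is applied, drawn from the
#' current RNG state (set a seed for reproducibility); otherwise the first
#' point is the origin.
#'
#' @param n Number of points (powers of two give the best uniformity).
#' @param d Dimension.
#' @param scramble Apply a random digital-shift scramble.
#' @return An `n x d` matrix in `[0, 1)`.
#' @export
sobol_points <- function(n, d, scramble = TRUE) {
  if (n < 1 || d < 1) abort_invalid("n and d must be positive")
  V <- sobol_directions(d)
  X <- matrix(0, n, d)
  state <- integer(d)
  X[1, ] <- 0
  if (n > 1) {
    for (k in 2:n) {
      v <- V[count_trailing_zeros(k - 1) + 1L, ]
      state <- bitwXor(state, v)
      X[k, ] <- state
    }
  }
  if (scramble) {
    shift <- as.integer(floor(stats::runif(d) * 2^.SOBOL_BITS))
    for (j in seq_len(d)) X[, j] <- bitwXor(as.integer(X[, j]), shift[j])
  }
  X / 2^.SOBOL_BITS
}
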