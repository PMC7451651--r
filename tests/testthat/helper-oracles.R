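# Independent brute-force routines used as oracles against the package's
# vectorized implementations. Deliberately written as explicit loops over
# the defining formulas.

# Ordinary-kriging prediction at a single location by assembling and
# solving the full bordered system entry by entry.
brute_force_ok <- function(x, y, z, model, x0, y0) {
  n <- length(x)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        h <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
        A[i, j] <- vgm_gamma(model, h)
      }
    }
    A[i, n + 1] <- 1
    A[n + 1, i] <- 1
  }
  b <- numeric(n + 1)
  for (i in seq_len(n)) {
    h <- sqrt((x[i] - x0)^2 + (y[i] - y0)^2)
    b[i] <- vgm_gamma(model, h)
  }
  b[n + 1] <- 1
  w <- solve(A, b)
  list(pred = sum(w[seq_len(n)] * z),
       variance = sum(w * b),
       weights = w[seq_len(n)])
}

# Moran's I by the double-sum definition with inverse-distance weights,
# row-standardized.
brute_force_moran <- function(x, y, z) {
  n <- length(z)
  zc <- z - mean(z)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) W[i, j] <- 1 / sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  }
  for (i in seq_len(n)) W[i, ] <- W[i, ] / sum(W[i, ])
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * zc[i] * zc[j]
  (n / sum(W)) * num / sum(zc^2)
}

# Inverse-distance-weighting interpolation (power 2), the comparison
# predictor for kriging accuracy checks.
idw_at <- function(x, y, z, xy0, power = 2) {
  apply(xy0, 1, function(p) {
    d2 <- (x - p[1])^2 + (y - p[2])^2
    if (any(d2 == 0)) return(z[which.min(d2)])
    w <- 1 / d2^(power / 2)
    sum(w * z) / sum(w)
  })
}

# tiny deterministic point set on [0, L]^2
toy_points <- function(n, L = 1000, seed = 1, sd = 10, base = 100) {
  withr::with_seed(seed, {
    price_points(stats::runif(n, 0, L), stats::runif(n, 0, L),
                 base + stats::rnorm(n, 0, sd))
  })
}
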