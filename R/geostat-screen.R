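#' Normality screening of price samples
#'
#' Shapiro-Wilk test; kriging does not strictly require normality but
#' variogram estimation and the kriging variance are best behaved for
#' near-normal data, so a failed test emits a log-transform recommendation
#' (not auto-applied).
#'
#' @param prices numeric vector of prices (n >= 3, non-constant).
#' @param alpha significance level (default 0.05); the sample passes when
#'   p >= alpha.
#' @return List with `statistic`, `p_value`, `pass` and `recommendation`
#'   (`NA` or `"log-transform"`).
#' @export
normality_test <- function(prices, alpha = 0.05) {
  if (length(prices) < 3) stop("need at least 3 prices, have ", length(prices))
  if (stats::sd(prices) == 0) stop("constant prices: normality test undefined")
  t <- stats::shapiro.test(prices)
  pass <- t$p.value >= alpha
  list(statistic = unname(t$statistic), p_value = t$p.value, pass = pass,
       recommendation = if (pass) NA_character_ else "log-transform")
}

#' Global Moran's I of point-referenced prices
#'
#' Inverse-distance weights w_ij = 1 / d_ij (zero diagonal),
#' row-standardized; significance by a one-sided (greater) permutation
#' test, the relevant alternative when screening for the positive spatial
#' correlation that justifies kriging.
#'
#' @param points a [price_points()] set, n >= 4.
#' @param n_perm number of seeded permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return List with `I`, `expected_I` = -1/(n-1), `p_value` (pseudo
#'   p-value `(1 + #(I_perm >= I)) / (n_perm + 1)`) and `n_perm`.
#' @export
morans_i <- function(points, n_perm = 999, seed = 1L) {
  n <- nrow(points)
  if (n < 4) stop("need at least 4 points, have ", n)
  z <- points$price - mean(points$price)
  if (sum(z^2) == 0) stop("zero-variance prices: Moran's I undefined")
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  W <- 1 / D
  diag(W) <- 0
  if (!any(is.finite(W) & W > 0)) stop("no neighbor pairs with positive weight")
  W <- W / rowSums(W)
  stat <- function(zz) sum(W * tcrossprod(zz)) / sum(zz^2)
  I <- stat(z)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(z)), numeric(1))
  })
  list(I = I, expected_I = -1 / (n - 1),
       p_value = (1 + sum(perm >= I)) / (n_perm + 1),
       n_perm = n_perm)
}
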