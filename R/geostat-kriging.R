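#' Epoch-tagged land-price point samples
#'
#' Points with identical coordinates are averaged on ingest (duplicate
#' sites make the kriging system singular), with a message.
#'
#' @param x,y coordinates in metres.
#' @param price prices in yuan/m2 (> 0).
#' @param epoch epoch label (e.g. `"2008"`).
#' @param landuse land-use type label (e.g. `"residential"`).
#' @return Data frame of class `price_points`.
#' @export
price_points <- function(x, y, price, epoch = "epoch", landuse = "residential") {
  stopifnot(length(x) == length(y), length(x) == length(price),
            all(is.finite(x)), all(is.finite(y)), all(is.finite(price)))
  if (any(price <= 0)) stop("prices must be positive")
  d <- data.frame(x = x, y = y, price = price,
                  epoch = rep_len(as.character(epoch), length(x)),
                  landuse = rep_len(as.character(landuse), length(x)),
                  stringsAsFactors = FALSE)
  key <- paste(d$x, d$y)
  if (anyDuplicated(key)) {
    message("averaging ", sum(duplicated(key)), " duplicate-coordinate point(s)")
    d <- do.call(rbind, lapply(split(d, key), function(s) {
      s$price[1] <- mean(s$price); s[1, ]
    }))
    rownames(d) <- NULL
  }
  structure(d, class = c("price_points", "data.frame"))
}

#' Read/write price points as CSV
#'
#' Columns: `x`, `y`, `price_yuan_m2`, `epoch`, `landuse`.
#'
#' @param path CSV path.
#' @return A [price_points()] set.
#' @export
read_price_points <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "price_yuan_m2") %in% names(d)))
  price_points(d$x, d$y, d$price_yuan_m2,
               epoch = if ("epoch" %in% names(d)) d$epoch else "epoch",
               landuse = if ("landuse" %in% names(d)) d$landuse else "unknown")
}

#' @rdname read_price_points
#' @param points a [price_points()] set.
#' @export
write_price_points <- function(points, path) {
  utils::write.csv(
    data.frame(x = points$x, y = points$y, price_yuan_m2 = points$price,
               epoch = points$epoch, landuse = points$landuse),
    path, row.names = FALSE)
  invisible(path)
}

#' Kriged price surface
#'
#' @param values matrix of predictions (yuan/m2), row 1 = north.
#' @param variance matrix of kriging variances (same shape) or `NULL`.
#' @param spec the [grid_spec()].
#' @param epoch epoch label.
#' @param mask logical matrix of valid cells (default: all finite values).
#' @return Object of class `price_surface`.
#' @export
price_surface <- function(values, variance = NULL, spec, epoch = "epoch",
                          mask = NULL) {
  stopifnot(is.matrix(values), nrow(values) == spec$nrow,
            ncol(values) == spec$ncol)
  if (is.null(mask)) mask <- is.finite(values)
  structure(list(values = values, variance = variance, spec = spec,
                 epoch = epoch, mask = mask),
            class = "price_surface")
}

#' @export
print.price_surface <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("price_surface [%s]: %d x %d @ %g m; price %.1f-%.1f (mean %.1f) yuan/m2\n",
              x$epoch, x$spec$nrow, x$spec$ncol, x$spec$cell_size,
              min(v), max(v), mean(v)))
  invisible(x)
}

# Bordered ordinary-kriging matrix for a point set under `model`:
# [ Gamma  1 ; 1' 0 ] with Gamma_ij = gamma(d_ij), gamma(0) = 0 on the
# diagonal (exact interpolation convention).
ok_matrix <- function(points, model) {
  n <- nrow(points)
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  A <- rbind(cbind(vgm_gamma(model, D), 1), c(rep(1, n), 0))
  diag(A)[seq_len(n)] <- 0
  A
}

# gamma between every target location (rows of `xy`) and every data point,
# with the unbiasedness column appended: the OK right-hand sides.
ok_rhs <- function(points, model, xy) {
  dx <- outer(xy[, 1], points$x, "-")
  dy <- outer(xy[, 2], points$y, "-")
  cbind(vgm_gamma(model, sqrt(dx * dx + dy * dy)), 1)
}

#' Ordinary kriging onto a regular grid
#'
#' Solves, per target cell, the ordinary-kriging system with Lagrange
#' multiplier from the fitted variogram; weights sum to 1 by the
#' unbiasedness constraint and the kriging variance
#' sigma^2 = sum w_i gamma(s_i, s0) + mu is returned alongside. With
#' `max_neighbors = Inf` (default) all samples inform every cell and the
#' whole grid is solved as one batched factorization; a finite value
#' restricts each cell to its nearest samples (an approximation useful for
#' large n).
#'
#' @param points a [price_points()] set (n >= 2).
#' @param model a [vgm_model()].
#' @param grid a [grid_spec()] (the study's analysis grid is 15 m).
#' @param max_neighbors number of nearest samples per cell; `Inf` = global.
#' @return A [price_surface()] with variances; attribute
#'   `max_weight_sum_err` records the largest deviation of any cell's
#'   weight sum from 1, and `n_masked` the number of cells masked because
#'   their local system was singular.
#' @export
ordinary_kriging <- function(points, model, grid, max_neighbors = Inf) {
  stopifnot(inherits(model, "variogram_model"), inherits(grid, "grid_spec"),
            nrow(points) >= 2, grid$cell_size > 0)
  n <- nrow(points)
  xy <- cell_centers(grid)
  z <- points$price
  if (!is.finite(max_neighbors) || max_neighbors >= n) {
    A <- ok_matrix(points, model)
    B <- ok_rhs(points, model, xy)          # ncell x (n+1)
    W <- solve(A, t(B))                      # (n+1) x ncell
    pred <- drop(crossprod(W[seq_len(n), , drop = FALSE], z))
    v <- colSums(W * t(B))
    wsum_err <- max(abs(colSums(W[seq_len(n), , drop = FALSE]) - 1))
    n_masked <- 0L
  } else {
    k <- as.integer(max_neighbors)
    dx <- outer(xy[, 1], points$x, "-")
    dy <- outer(xy[, 2], points$y, "-")
    D2 <- dx * dx + dy * dy
    pred <- v <- rep(NA_real_, nrow(xy))
    wsum_err <- 0
    n_masked <- 0L
    Dpt <- as.matrix(stats::dist(cbind(points$x, points$y)))
    for (i in seq_len(nrow(xy))) {
      nb <- order(D2[i, ])[seq_len(k)]
      A <- rbind(cbind(vgm_gamma(model, Dpt[nb, nb, drop = FALSE]), 1),
                 c(rep(1, k), 0))
      diag(A)[seq_len(k)] <- 0
      b <- c(vgm_gamma(model, sqrt(D2[i, nb])), 1)
      w <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(w)) { n_masked <- n_masked + 1L; next }
      pred[i] <- sum(w[seq_len(k)] * z[nb])
      v[i] <- sum(w * b)
      wsum_err <- max(wsum_err, abs(sum(w[seq_len(k)]) - 1))
    }
    if (n_masked > 0)
      warning(n_masked, " cell(s) masked: singular local kriging system")
  }
  vals <- matrix(pred, grid$nrow, grid$ncol)
  vars <- matrix(pmax(v, 0), grid$nrow, grid$ncol)
  out <- price_surface(vals, vars, grid, epoch = points$epoch[1])
  attr(out, "max_weight_sum_err") <- wsum_err
  attr(out, "n_masked") <- n_masked
  out
}

#' Kriging prediction at arbitrary locations
#'
#' Same estimator as [ordinary_kriging()] but for scattered target points.
#'
#' @inheritParams ordinary_kriging
#' @param xy two-column matrix of target coordinates.
#' @return List with `pred` and `variance` vectors.
#' @export
krige_at <- function(points, model, xy) {
  n <- nrow(points)
  A <- ok_matrix(points, model)
  B <- ok_rhs(points, model, xy)
  W <- solve(A, t(B))
  list(pred = drop(crossprod(W[seq_len(n), , drop = FALSE], points$price)),
       variance = pmax(colSums(W * t(B)), 0))
}

#' Leave-one-out cross-validation of candidate variogram models
#'
#' For each candidate, each sample is predicted by ordinary kriging from
#' all the others and the RMSE of those predictions ranks the candidates
#' (ascending). The LOO errors come from the bordered-matrix identity
#' e_i = (A^-1 z*)_i / (A^-1)_ii (z* = (z, 0)), which equals the explicit
#' refit leaving point i out; ties are broken by fewer parameters
#' (pure_nugget first), then by family order spherical < exponential <
#' gaussian.
#'
#' @param points a [price_points()] set, n >= 10.
#' @param candidates list of [vgm_model()]s.
#' @param max_skip_frac error out if more than this fraction of points is
#'   skipped for singularity (default 0.1).
#' @return The candidates, each with `$loo_rmse` filled, sorted by RMSE.
#' @export
loo_cross_validate <- function(points, candidates, max_skip_frac = 0.1) {
  stopifnot(nrow(points) >= 10, length(candidates) >= 1)
  n <- nrow(points)
  z <- points$price
  rmse <- vapply(candidates, function(m) {
    A <- ok_matrix(points, m)
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) return(Inf)
    w <- drop(Ainv %*% c(z, 0))
    dii <- diag(Ainv)[seq_len(n)]
    e <- w[seq_len(n)] / dii
    bad <- !is.finite(e)
    if (mean(bad) > max_skip_frac)
      stop("more than ", 100 * max_skip_frac,
           "% of points unskippable in cross-validation")
    if (any(bad)) warning(sum(bad), " point(s) skipped in LOO (singular system)")
    sqrt(mean(e[!bad]^2))
  }, numeric(1))
  npar <- vapply(candidates, function(m)
    if (m$family == "pure_nugget") 2L else 3L, integer(1))
  fam_rank <- vapply(candidates, function(m)
    match(m$family, c("spherical", "exponential", "gaussian", "pure_nugget")),
    integer(1))
  ord <- order(rmse, npar, fam_rank)
  out <- candidates[ord]
  for (i in seq_along(out)) out[[i]]$loo_rmse <- rmse[ord][i]
  out
}
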