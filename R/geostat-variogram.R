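#' Theoretical semivariogram model
#'
#' Families: spherical, exponential, gaussian, pure_nugget. `range` is the
#' model's distance parameter `a`: for the spherical family the true range
#' (the sill is reached at h = a); for the exponential and gaussian families
#' the correlation-length parameter of `1 - exp(-h/a)` and
#' `1 - exp(-(h/a)^2)` (effective ranges ~3a and ~sqrt(3)a). By convention
#' gamma(0) = 0 exactly; the nugget is the limit from above, so kriging with
#' this model is an exact interpolator at the data sites.
#'
#' @param family one of `"spherical"`, `"exponential"`, `"gaussian"`,
#'   `"pure_nugget"`.
#' @param nugget micro-scale variance at zero lag (>= 0).
#' @param psill partial sill (>= 0); sill = nugget + psill.
#' @param range distance parameter in metres (> 0; ignored for
#'   `pure_nugget`).
#' @param wsse,loo_rmse optional fit diagnostics carried along.
#' @return Object of class `variogram_model`.
#' @export
vgm_model <- function(family, nugget, psill, range = NA_real_,
                      wsse = NA_real_, loo_rmse = NA_real_) {
  family <- match.arg(family,
                      c("spherical", "exponential", "gaussian", "pure_nugget"))
  stopifnot(nugget >= 0, psill >= 0)
  if (family != "pure_nugget") stopifnot(is.finite(range), range > 0)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range, wsse = wsse, loo_rmse = loo_rmse),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s  nugget=%.4g  psill=%.4g  range=%.4g",
              x$family, x$nugget, x$psill, x$range))
  if (is.finite(x$loo_rmse)) cat(sprintf("  LOO-RMSE=%.4g", x$loo_rmse))
  cat("\n")
  invisible(x)
}

#' Evaluate a semivariogram model
#'
#' @param model a [vgm_model()].
#' @param h distances (m), vector; gamma(0) = 0.
#' @return Semivariances at `h`.
#' @export
vgm_gamma <- function(model, h) {
  g <- switch(model$family,
    spherical = {
      u <- pmin(h / model$range, 1)
      model$psill * (1.5 * u - 0.5 * u^3)
    },
    exponential = model$psill * (1 - exp(-h / model$range)),
    gaussian = model$psill * (1 - exp(-(h / model$range)^2)),
    pure_nugget = h * 0 + model$psill)   # keeps dim attributes
  out <- model$nugget + g
  out[h == 0] <- 0
  out
}

# covariance of the correlated (non-nugget) component
vgm_cov_smooth <- function(model, h) {
  if (model$family == "pure_nugget") return(ifelse(h == 0, model$psill, 0))
  m0 <- model; m0$nugget <- 0
  model$psill - vgm_gamma(m0, h)
}

#' Empirical semivariogram of point samples
#'
#' gamma_hat(h_k) = (1 / 2 N_k) * sum over pairs in lag bin k of
#' (z_i - z_j)^2, with equal-width bins up to `max_lag`; bins without pairs
#' are dropped.
#'
#' @param points a [price_points()] set (or any data frame with x, y and a
#'   value column named `price`), n >= 3.
#' @param n_bins number of lag bins (default 12).
#' @param max_lag maximum lag in metres; default half the maximum pairwise
#'   distance.
#' @return Data frame of class `empirical_variogram` with columns `lag`
#'   (bin centre), `gamma`, `npairs`, and attributes `max_lag`, `n_bins`,
#'   `n_points`.
#' @export
empirical_semivariogram <- function(points, n_bins = 12, max_lag = NULL) {
  stopifnot(nrow(points) >= 3, n_bins >= 1)
  d <- stats::dist(cbind(points$x, points$y))
  if (max(d) == 0) stop("all points coincident: no lags to bin")
  if (is.null(max_lag)) max_lag <- max(d) / 2
  stopifnot(max_lag > 0)
  dz2 <- stats::dist(points$price)^2
  keep <- d > 0 & d <= max_lag
  bin <- pmin(ceiling(as.numeric(d[keep]) / (max_lag / n_bins)), n_bins)
  npairs <- tabulate(bin, nbins = n_bins)
  ssq <- vapply(seq_len(n_bins),
                function(k) sum(dz2[keep][bin == k]), numeric(1))
  ok <- npairs > 0
  w <- max_lag / n_bins
  out <- data.frame(lag = (seq_len(n_bins)[ok] - 0.5) * w,
                    gamma = ssq[ok] / (2 * npairs[ok]),
                    npairs = npairs[ok])
  structure(out, max_lag = max_lag, n_bins = n_bins, n_points = nrow(points),
            class = c("empirical_variogram", "data.frame"))
}

#' Fit theoretical variogram models to an empirical semivariogram
#'
#' Per family, minimizes the pair-count-weighted squared error
#' sum_k N_k (gamma_hat_k - gamma(h_k))^2 by bounded quasi-Newton
#' (`optim` L-BFGS-B) from a multi-start grid over the range, with
#' nugget >= 0, partial sill >= 0 and range in (0, 2 max_lag]. The
#' `pure_nugget` family is the weighted-mean flat model.
#'
#' @param emp an [empirical_semivariogram()] with >= 3 retained bins.
#' @param families character vector of families to fit.
#' @return List of [vgm_model()]s (one per family, in `families` order)
#'   with the achieved weighted SSE in `$wsse`.
#' @export
fit_variogram <- function(emp,
                          families = c("spherical", "exponential", "gaussian")) {
  stopifnot(inherits(emp, "empirical_variogram"))
  if (nrow(emp) < 3) stop("need at least 3 variogram bins to fit, have ", nrow(emp))
  h <- emp$lag; g <- emp$gamma; w <- emp$npairs
  max_range <- 2 * attr(emp, "max_lag")
  sill0 <- max(mean(g[h > stats::median(h)]), max(g) * 0.5, 1e-12)

  fit_one <- function(family) {
    if (family == "pure_nugget") {
      # flat model: weighted mean level, split as pure nugget
      lev <- sum(w * g) / sum(w)
      m <- vgm_model("pure_nugget", nugget = lev, psill = 0)
      m$wsse <- sum(w * (g - lev)^2)
      return(m)
    }
    obj <- function(p) {
      m <- vgm_model(family, p[1], p[2], p[3])
      sum(w * (g - vgm_gamma(m, h))^2)
    }
    starts <- expand.grid(
      nugget = c(1e-8, 0.25 * sill0),
      psill = c(sill0, 0.75 * sill0),
      range = max(h) * c(0.25, 0.5, 1, 1.5))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                     lower = c(0, 0, max(h) * 1e-4),
                     upper = c(Inf, Inf, max_range)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best)) stop("variogram fit failed for family ", family)
    vgm_model(family, best$par[1], best$par[2], best$par[3],
              wsse = best$value)
  }
  lapply(stats::setNames(families, families), fit_one)
}
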