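#' Generate a land-cover grid with exact class areas
#'
#' Seeded multi-source region growth: each class gets a number of seed
#' cells proportional to its target area, regions grow one frontier layer
#' per round, and a class stops exactly at its cell quota, so
#' [tabulate_areas()] on the output reproduces the targets with zero error.
#' At 10-m cells one cell is 0.01 hm2, so any 2-decimal hm2 target vector
#' is representable.
#'
#' @param targets named numeric vector of class areas (hm2); every target
#'   must be an exact multiple of `cell_size^2 / 1e4`. Zero-area classes
#'   are allowed (they stay in the legend).
#' @param cell_size synthesis cell size in metres (default 10).
#' @param seed integer seed; the same seed gives an identical grid.
#' @param dims optional `c(nrow, ncol)`; default near-square. Cells beyond
#'   the total target count are nodata.
#' @param legend class -> code map; must cover `names(targets)`.
#' @param origin top-left corner (m).
#' @param region_cells target mean region size in cells (controls how many
#'   seeds each class gets; default 4000, i.e. ~40 hm2 patches at 10 m).
#' @return A [land_grid()].
#' @export
generate_landcover <- function(targets, cell_size = 10, seed = 1L,
                               dims = NULL, legend = landcover_classes(),
                               origin = c(0, 0), region_cells = 4000) {
  stopifnot(!is.null(names(targets)), all(names(targets) %in% names(legend)))
  cell_hm2 <- cell_size^2 / 1e4
  counts <- targets / cell_hm2
  bad <- abs(counts - round(counts)) > 1e-6
  if (any(bad))
    stop("target area not an exact cell multiple at ", cell_size,
         " m for class(es): ", paste(names(targets)[bad], collapse = ", "))
  counts <- as.integer(round(counts))
  total <- sum(counts)
  if (total < 1) stop("all targets are zero")
  if (is.null(dims)) {
    nc <- as.integer(ceiling(sqrt(total)))
    nr <- as.integer(ceiling(total / nc))
  } else {
    nr <- as.integer(dims[1]); nc <- as.integer(dims[2])
  }
  if (nr * nc < total) stop("dims too small for the target areas")

  codes <- legend[names(targets)]
  N <- nr * nc
  a <- integer(N)                       # 0 = unassigned, -1 = nodata
  if (N > total) a[(total + 1):N] <- -1L

  nbrs <- function(idx) {
    r <- (idx - 1L) %% nr + 1L
    c(idx[r > 1L] - 1L, idx[r < nr] + 1L,
      idx[idx > nr] - nr, idx[idx <= nr * (nc - 1L)] + nr)
  }

  withr::with_seed(seed, {
    active <- which(counts > 0L)
    remaining <- counts
    n_seeds <- pmax(1L, as.integer(round(counts / region_cells)))
    n_seeds <- pmin(n_seeds, counts)
    free <- which(a == 0L)
    pick <- free[sample.int(length(free), sum(n_seeds[active]))]
    frontiers <- vector("list", length(targets))
    off <- 0L
    for (ci in active) {
      s <- pick[(off + 1L):(off + n_seeds[ci])]
      off <- off + n_seeds[ci]
      a[s] <- codes[ci]
      remaining[ci] <- remaining[ci] - length(s)
      frontiers[[ci]] <- nbrs(s)
    }
    while (any(remaining > 0L)) {
      for (ci in active[sample.int(length(active))]) {
        if (remaining[ci] == 0L) next
        fr <- unique(frontiers[[ci]])
        fr <- fr[a[fr] == 0L]
        if (length(fr) == 0L) {
          # blocked region: reseed anywhere free
          free <- which(a == 0L)
          if (length(free) == 0L) break
          fr <- free[sample.int(length(free), 1L)]
        }
        k <- min(remaining[ci], length(fr))
        take <- if (k == length(fr)) fr else fr[sample.int(length(fr), k)]
        a[take] <- codes[ci]
        remaining[ci] <- remaining[ci] - k
        frontiers[[ci]] <- c(setdiff(fr, take), nbrs(take))
      }
    }
  })
  land_grid(matrix(a, nr, nc), cell_size, origin, legend = legend,
            nodata = -1L)
}
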