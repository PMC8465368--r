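#' Convert interaction frequencies to target distances
#'
#' Applies the inverse power law between contact frequency and spatial
#' distance, `D = IF^(-gamma)`: frequent contacts are near, rare contacts
#' far. `gamma` is stored as a positive magnitude (default 0.6) so that
#' restraint building and map extraction, `IF = D^(-1/gamma)`, are exact
#' inverses. Pairs with zero contact carry no restraint and are dropped;
#' the diagonal is never restrained. Returned distances are rescaled so
#' the maximum equals 1 (the scale factor is recorded as an attribute)
#' unless `rescale = FALSE`.
#'
#' @param map a [contact_map].
#' @param gamma positive exponent magnitude.
#' @param rescale rescale distances to unit maximum.
#' @return data.frame with columns `i`, `j` (1-based bin indices, `i < j`)
#'   and `target` (distance); attribute `scale` holds the applied factor
#'   such that `target * scale` restores the unscaled distances.
#' @export
contacts_to_distances <- function(map, gamma = 0.6, rescale = TRUE) {
  stopifnot(inherits(map, "contact_map"), gamma > 0)
  m <- map$matrix
  keep <- upper.tri(m) & m > 0
  if (!any(keep)) stop("contact map has no positive off-diagonal entries; no restraints can be derived")
  idx <- which(keep, arr.ind = TRUE)
  d <- m[keep]^(-gamma)
  sc <- if (rescale) max(d) else 1
  out <- data.frame(i = idx[, 1], j = idx[, 2], target = d / sc)
  attr(out, "scale") <- sc
  out
}

#' Build the discrete time grid of a 4D model
#'
#' The model tracks coordinates at `granularity` equally spaced times
#' spanning the observed interval. Each observed time is snapped to its
#' nearest grid time; a snap displacement above 25% of the grid spacing,
#' or two observed times landing on the same grid point, aborts with an
#' error (the granularity is too coarse to honour the observed design).
#'
#' @param observed_times strictly increasing numeric times.
#' @param granularity integer number of grid points (>= number of
#'   observed times, >= 2).
#' @return list with `grid` (numeric, length `granularity`),
#'   `observed_index` (grid position of each observed time), and
#'   `snap_displacement` (signed `grid - observed`, in time units).
#' @export
build_time_grid <- function(observed_times, granularity) {
  ot <- sort(unique(as.numeric(observed_times)))
  if (length(ot) != length(observed_times)) stop("observed times must be distinct")
  if (length(ot) < 2L) stop("need at least 2 observed times")
  granularity <- as.integer(granularity)
  if (granularity < max(2L, length(ot))) {
    stop("granularity (", granularity, ") must be at least the number of observed times (",
         length(ot), ")")
  }
  grid <- seq(ot[1], ot[length(ot)], length.out = granularity)
  spacing <- grid[2] - grid[1]
  idx <- vapply(ot, function(t) which.min(abs(grid - t)), 1L)
  disp <- grid[idx] - ot
  if (any(abs(disp) > 0.25 * spacing + 1e-12)) {
    worst <- which.max(abs(disp))
    stop("observed time ", ot[worst], " is ", signif(abs(disp[worst]), 3),
         " away from the nearest grid time (spacing ", signif(spacing, 3),
         "); increase the granularity")
  }
  if (anyDuplicated(idx)) {
    stop("granularity too coarse: two observed times snap to the same grid point")
  }
  list(grid = grid, observed_index = idx, snap_displacement = disp)
}

#' Derive a full restraint set from a Hi-C time series
#'
#' Converts every map of the series to target distances on a shared
#' discrete time grid. Bins with no data at any time (the common mask) are
#' excluded from every pair, and a single global factor rescales all
#' target distances so the largest is 1, commensurate with the unit-cube
#' initialization of the structure.
#'
#' @param series an [assemble_series()] result.
#' @param gamma positive exponent magnitude of the distance power law.
#' @param granularity number of grid time points; defaults to one grid
#'   point per observed time.
#' @param exclude_times observed times to withhold (used by interpolation
#'   experiments); their grid points keep no direct restraints.
#' @return an object of class `restraint_set`: list with `targets` (one
#'   data.frame `i`, `j`, `target` per restrained grid index), `grid`,
#'   `observed_index` (named by observed time), `n_bins`, `mask`,
#'   `bin_size`, `chrom`, `gamma` and `scale` (global distance rescaling
#'   factor).
#' @export
build_restraints <- function(series, gamma = 0.6, granularity = length(series$times),
                             exclude_times = numeric()) {
  stopifnot(inherits(series, "hic_series"))
  tg <- build_time_grid(series$times, granularity)
  use <- !(series$times %in% exclude_times)
  if (sum(use) < 2L) stop("need at least 2 retained time points")
  keep_bins <- !series$common_mask
  targets <- vector("list", length(tg$grid))
  raw <- list()
  for (k in which(use)) {
    tab <- contacts_to_distances(series$maps[[k]], gamma = gamma, rescale = FALSE)
    tab <- tab[keep_bins[tab$i] & keep_bins[tab$j], , drop = FALSE]
    if (nrow(tab) == 0L) {
      stop("no restraints at time ", series$times[k], " after masking")
    }
    raw[[as.character(tg$observed_index[k])]] <- tab
  }
  sc <- max(vapply(raw, function(tab) max(tab$target), 1))
  for (nm in names(raw)) {
    tab <- raw[[nm]]
    tab$target <- tab$target / sc
    targets[[as.integer(nm)]] <- tab
  }
  oi <- tg$observed_index[use]
  names(oi) <- series$times[use]
  structure(
    list(targets = targets, grid = tg$grid, observed_index = oi,
         n_bins = n_bins(series), mask = series$common_mask,
         bin_size = series$bin_size, chrom = series$chrom,
         gamma = gamma, scale = sc),
    class = "restraint_set"
  )
}

#' @export
print.restraint_set <- function(x, ...) {
  nr <- sum(vapply(x$targets, function(t) if (is.null(t)) 0L else nrow(t), 1L))
  cat(sprintf("<restraint_set> %s, %d bins, grid of %d times [%g, %g], %d observed, %d restraints\n",
              x$chrom, x$n_bins, length(x$grid), x$grid[1],
              x$grid[length(x$grid)], length(x$observed_index), nr))
  invisible(x)
}
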