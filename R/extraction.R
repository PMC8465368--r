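#' Extract a synthetic contact map from a fitted structure
#'
#' Converts the pairwise Euclidean distances of the frame at time `t`
#' back to interaction frequencies with `IF = d^(-1/gamma)`, the exact
#' inverse of the restraint conversion [contacts_to_distances()]. The
#' diagonal is zero and masked bins are zeroed (and flagged in the
#' returned mask). Values live on the model's internal distance scale;
#' downstream comparisons use rank or Pearson statistics, which are
#' insensitive to the global scale.
#'
#' @param structure a [structure_4d] (or a `hic4d_fit`, whose structure
#'   is used).
#' @param t real time; must coincide with a grid time within the snapping
#'   tolerance.
#' @param gamma positive exponent magnitude; defaults to the one the
#'   structure was fitted with.
#' @return a [contact_map] with attributes `provenance`
#'   (`"reconstructed"` if `t` was an observed fitting time, otherwise
#'   `"interpolated"`) and `grid_time`.
#' @export
extract_map <- function(structure, t, gamma = NULL) {
  if (inherits(structure, "hic4d_fit")) structure <- structure$structure
  stopifnot(inherits(structure, "structure_4d"))
  if (is.null(gamma)) gamma <- structure$gamma
  stopifnot(gamma > 0)
  if (t < structure$grid[1] - 1e-12 ||
      t > structure$grid[length(structure$grid)] + 1e-12) {
    stop("time ", t, " lies outside the model's grid [",
         structure$grid[1], ", ", structure$grid[length(structure$grid)], "]")
  }
  k <- .grid_index(structure$grid, t)
  X <- structure$coords[k, , ]
  d <- as.matrix(stats::dist(X))
  IF <- ifelse(d > 0, d^(-1 / gamma), 0)
  diag(IF) <- 0
  IF[structure$mask, ] <- 0
  IF[, structure$mask] <- 0
  out <- contact_map(IF, bin_size = structure$bin_size,
                     time = structure$grid[k], chrom = structure$chrom)
  out$mask <- out$mask | structure$mask
  attr(out, "provenance") <- "reconstructed"
  attr(out, "grid_time") <- structure$grid[k]
  out
}

#' Naive linear interpolation of two contact maps
#'
#' The baseline against which model-based interpolation is judged:
#' entrywise linear interpolation of the two flanking maps with the same
#' convex weights as [interpolation_weights()].
#'
#' @param map_a,map_b flanking [contact_map]s, `time(map_a) < time(map_b)`.
#' @param t target time, strictly between the two map times.
#' @return a [contact_map] at time `t` with `provenance = "baseline"`.
#' @export
naive_interpolation <- function(map_a, map_b, t) {
  stopifnot(inherits(map_a, "contact_map"), inherits(map_b, "contact_map"))
  if (!identical(dim(map_a$matrix), dim(map_b$matrix))) {
    stop("maps differ in shape: ", nrow(map_a$matrix), " vs ", nrow(map_b$matrix))
  }
  w <- interpolation_weights(t, map_a$time, map_b$time)
  m <- w[[1]] * map_a$matrix + w[[2]] * map_b$matrix
  out <- contact_map(m, bin_size = map_a$bin_size, time = t,
                     chrom = map_a$chrom)
  attr(out, "provenance") <- "baseline"
  out
}
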