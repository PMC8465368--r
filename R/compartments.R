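#' Observed-over-expected matrix
#'
#' Divides each entry by the mean interaction frequency at its genomic
#' separation (computed over unmasked bins), removing the dominant
#' distance decay so that compartment-scale structure becomes visible.
#' Entries on separations with zero expected value, and masked
#' rows/columns, are set to 0.
#'
#' @param map a [contact_map] with at least 3 unmasked bins.
#' @return n x n numeric matrix.
#' @export
oe_matrix <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  keep <- !map$mask
  if (sum(keep) < 3L) stop("need at least 3 unmasked bins")
  m <- map$matrix
  if (all(m == 0)) stop("all-zero contact map")
  n <- nrow(m)
  sep <- abs(row(m) - col(m))
  ok <- outer(keep, keep, `&`)
  expd <- vapply(0:(n - 1), function(s) {
    v <- m[sep == s & ok]
    if (length(v) == 0L) 0 else mean(v)
  }, 1)
  E <- matrix(expd[sep + 1L], n, n)
  oe <- ifelse(E > 0, m / E, 0)
  oe[!keep, ] <- 0
  oe[, !keep] <- 0
  oe
}

#' A/B compartment profile of one contact map
#'
#' The classical eigenvector analysis: Pearson correlation matrix of the
#' rows of the observed/expected matrix (unmasked bins only), PCA on the
#' correlation matrix, per-bin compartment assignment from the sign of
#' PC1. PCA sign is arbitrary, so the profile is oriented such that PC1
#' correlates positively with the per-bin total O/E row sum; the A
#' compartment is the positive sign after orientation.
#'
#' @param map a [contact_map].
#' @return an object of class `compartment_profile`: `pc1` (per-bin
#'   values, NA on masked bins), `signs` (factor `A`/`B`, NA on masked
#'   bins), `explained_variance` (fraction of variance on PC1), `mask`.
#' @export
ab_compartments <- function(map) {
  oe <- oe_matrix(map)
  keep <- !map$mask
  sub <- oe[keep, keep, drop = FALSE]
  if (any(apply(sub, 1, stats::sd) == 0)) {
    stop("degenerate O/E matrix: constant row(s); correlations undefined")
  }
  cm <- stats::cor(t(sub))
  pca <- stats::prcomp(cm, center = TRUE, scale. = FALSE)
  pc1 <- pca$x[, 1]
  # orientation: A (positive) should align with contact-rich bins
  orient <- stats::cor(pc1, rowSums(sub))
  if (is.finite(orient) && orient < 0) pc1 <- -pc1
  full <- rep(NA_real_, n_bins(map))
  full[keep] <- pc1
  signs <- factor(ifelse(full > 0, "A", "B"), levels = c("A", "B"))
  structure(
    list(pc1 = full, signs = signs,
         explained_variance = unname(pca$sdev[1]^2 / sum(pca$sdev^2)),
         mask = map$mask, time = map$time),
    class = "compartment_profile"
  )
}

#' @export
print.compartment_profile <- function(x, ...) {
  cat(sprintf("<compartment_profile> %d bins (%d A / %d B / %d masked), PC1 explains %.1f%%\n",
              length(x$pc1), sum(x$signs == "A", na.rm = TRUE),
              sum(x$signs == "B", na.rm = TRUE), sum(x$mask),
              100 * x$explained_variance))
  invisible(x)
}

#' Compartment trajectory across time points
#'
#' Stacks the A/B sign vectors of several profiles (A = +1, B = -1,
#' masked = 0) as observations and projects them on their first two
#' principal components, tracing how compartmentalization moves through
#' the process.
#'
#' @param profiles list of >= 3 [ab_compartments()] results with equal
#'   bin count.
#' @return data.frame with one row per profile: `time`, `pc1`, `pc2`.
#' @export
compartment_trajectory <- function(profiles) {
  stopifnot(is.list(profiles),
            all(vapply(profiles, inherits, TRUE, "compartment_profile")))
  if (length(profiles) < 3L) stop("need at least 3 profiles for a trajectory")
  nb <- unique(vapply(profiles, function(p) length(p$pc1), 1L))
  if (length(nb) != 1L) stop("profiles disagree on bin count")
  S <- t(vapply(profiles, function(p) {
    v <- ifelse(is.na(p$signs), 0, ifelse(p$signs == "A", 1, -1))
    as.numeric(v)
  }, numeric(nb)))
  pca <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pca$x))
  out <- data.frame(time = vapply(profiles, function(p) p$time %||% NA_real_, 1),
                    pc1 = pca$x[, 1],
                    pc2 = if (k == 2L) pca$x[, 2] else 0)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average a compartment vector into coarser bins
#'
#' Re-bins a per-bin PC1 vector by averaging `factor` consecutive bins
#' (e.g. 50 kb profiles to 100 kb with `factor = 2`); a trailing partial
#' group is averaged as-is. NA (masked) bins are dropped from each
#' group's mean.
#'
#' @param pc1 numeric per-bin vector.
#' @param factor integer >= 2.
#' @return shorter numeric vector.
#' @export
rebin_vector <- function(pc1, factor = 2) {
  stopifnot(factor >= 2, factor <= length(pc1))
  grp <- (seq_along(pc1) - 1L) %/% factor
  as.numeric(tapply(pc1, grp, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }))
}
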