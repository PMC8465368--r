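#' Compare two contact maps
#'
#' Spearman (SRC) and Pearson (PCC) correlation over the vectorized
#' upper triangle, excluding the diagonal and masked bins.
#'
#' @param map_a,map_b [contact_map]s of the same shape.
#' @param mask_policy which bins to exclude: `"union"` drops bins masked
#'   in either map, `"intersection"` only bins masked in both, `"none"`
#'   keeps everything.
#' @param log_scale correlate `log1p(IF)` instead of raw frequencies
#'   (affects PCC only; SRC is rank-based and invariant).
#' @return an object of class `comparison_report`: `src`, `pcc`,
#'   `n_pairs`.
#' @export
compare_maps <- function(map_a, map_b,
                         mask_policy = c("union", "intersection", "none"),
                         log_scale = FALSE) {
  stopifnot(inherits(map_a, "contact_map"), inherits(map_b, "contact_map"))
  mask_policy <- match.arg(mask_policy)
  if (!identical(dim(map_a$matrix), dim(map_b$matrix))) {
    stop("maps differ in shape")
  }
  drop <- switch(mask_policy,
                 union = map_a$mask | map_b$mask,
                 intersection = map_a$mask & map_b$mask,
                 none = rep(FALSE, n_bins(map_a)))
  keepm <- outer(!drop, !drop, `&`) & upper.tri(map_a$matrix)
  va <- map_a$matrix[keepm]
  vb <- map_b$matrix[keepm]
  if (length(va) < 2L) stop("fewer than 2 comparable entries")
  if (log_scale) {
    va <- log1p(va)
    vb <- log1p(vb)
  }
  structure(
    list(src = stats::cor(va, vb, method = "spearman"),
         pcc = stats::cor(va, vb, method = "pearson"),
         n_pairs = length(va)),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> SRC %.4f, PCC %.4f over %d pairs%s\n",
              x$src, x$pcc, x$n_pairs,
              if (!is.null(x$disparity)) sprintf(", M2 %.4g", x$disparity) else ""))
  invisible(x)
}

#' Procrustes disparity between two point sets
#'
#' Both configurations are centered at the origin and scaled to unit
#' Frobenius norm (`trace(A A^T) = 1`); the second is then optimally
#' rotated onto the first (reflections allowed, plus the optimal
#' further scaling), and the disparity `M^2` is the residual sum of
#' squared distances — 0 for configurations related by any similarity
#' transform.
#'
#' @param struct_a,struct_b `n x 3` coordinate matrices with equal `n`
#'   (>= 3) and non-zero spread.
#' @return scalar `M^2` in `[0, 1]`.
#' @export
procrustes_disparity <- function(struct_a, struct_b) {
  A <- as.matrix(struct_a)
  B <- as.matrix(struct_b)
  if (!identical(dim(A), dim(B))) stop("point sets differ in shape")
  if (nrow(A) < 3L) stop("need at least 3 points")
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  na <- sqrt(sum(A^2))
  nb <- sqrt(sum(B^2))
  if (na == 0 || nb == 0) stop("degenerate input: all points identical")
  A <- A / na
  B <- B / nb
  sv <- svd(crossprod(A, B))
  s <- sum(sv$d)                       # optimal scaling of the rotated B
  max(0, 1 - s^2)
}

#' Compare two 4D structures frame by frame
#'
#' Matches grid times shared by the two structures (within `tol`) and,
#' at each matched time, correlates the upper-triangle pairwise-distance
#' vectors (SRC/PCC) and computes the Procrustes disparity; averages
#' over matched times summarize the agreement.
#'
#' @param a,b [structure_4d]s with equal bin count.
#' @param tol time-matching tolerance.
#' @return an object of class `structure_comparison`: `per_time`
#'   (data.frame `time`, `src`, `pcc`, `m2`) and `average` (named list).
#' @export
compare_structures_4d <- function(a, b, tol = 1e-6) {
  if (inherits(a, "hic4d_fit")) a <- a$structure
  if (inherits(b, "hic4d_fit")) b <- b$structure
  stopifnot(inherits(a, "structure_4d"), inherits(b, "structure_4d"))
  if (dim(a$coords)[2] != dim(b$coords)[2]) stop("structures differ in bin count")
  pairs <- list()
  for (i in seq_along(a$grid)) {
    j <- which(abs(b$grid - a$grid[i]) <= tol)
    if (length(j) == 1L) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  if (length(pairs) == 0L) stop("structures share no grid times")
  ut <- upper.tri(diag(dim(a$coords)[2]))
  per <- do.call(rbind, lapply(pairs, function(p) {
    Xa <- a$coords[p[1], , ]
    Xb <- b$coords[p[2], , ]
    da <- as.matrix(stats::dist(Xa))[ut]
    db <- as.matrix(stats::dist(Xb))[ut]
    data.frame(time = a$grid[p[1]],
               src = stats::cor(da, db, method = "spearman"),
               pcc = stats::cor(da, db),
               m2 = procrustes_disparity(Xa, Xb))
  }))
  structure(
    list(per_time = per,
         average = list(src = mean(per$src), pcc = mean(per$pcc),
                        m2 = mean(per$m2))),
    class = "structure_comparison"
  )
}

#' @export
print.structure_comparison <- function(x, ...) {
  cat(sprintf("<structure_comparison> %d matched times: mean SRC %.4f, PCC %.4f, M2 %.4g\n",
              nrow(x$per_time), x$average$src, x$average$pcc, x$average$m2))
  invisible(x)
}

#' Coarsen a structure's spatial resolution
#'
#' Averages the coordinates of every `factor` consecutive bins within
#' each frame (e.g. 50 kb beads to 500 kb with `factor = 10`); a
#' trailing partial group is averaged as a final bin.
#'
#' @param structure a [structure_4d].
#' @param factor integer >= 2, at most the bin count.
#' @return a [structure_4d] with `ceiling(n / factor)` bins.
#' @export
reduce_resolution <- function(structure, factor) {
  stopifnot(inherits(structure, "structure_4d"), factor >= 2)
  n <- dim(structure$coords)[2]
  if (factor > n) stop("factor (", factor, ") exceeds bin count (", n, ")")
  grp <- (seq_len(n) - 1L) %/% as.integer(factor)
  g <- dim(structure$coords)[1]
  m <- length(unique(grp))
  out <- array(0, c(g, m, 3))
  for (t in seq_len(g)) {
    for (c in 1:3) out[t, , c] <- as.numeric(tapply(structure$coords[t, , c], grp, mean))
  }
  mask <- as.logical(tapply(structure$mask, grp, all))
  structure_4d(out, grid = structure$grid,
               bin_size = structure$bin_size * as.integer(factor),
               chrom = structure$chrom, mask = mask,
               scale = structure$scale, gamma = structure$gamma)
}

#' Holdout interpolation experiment
#'
#' Refits the model with one interior time point's contact map withheld,
#' extracts the interpolated map at that time, and scores it against the
#' held-out truth, the flanking real maps, and the naive linear
#' interpolation baseline. This is the central validation of the method:
#' can the 4D model predict a contact map it has never seen?
#'
#' @param series an [assemble_series()] result.
#' @param holdout_time an interior observed time (endpoints cannot be
#'   interpolated).
#' @param config a [fit_config()].
#' @param granularity grid size for the fit (defaults to one grid point
#'   per observed time).
#' @return an object of class `holdout_report`: `holdout_time`, per-map
#'   [compare_maps()] reports (`vs_truth`, `vs_baseline_truth`,
#'   `vs_previous`, `vs_next`), `beats_baseline` (model SRC strictly
#'   above baseline SRC), the fitted `fit`, and the `interpolated` and
#'   `baseline` maps.
#' @export
interpolation_experiment <- function(series, holdout_time,
                                     config = fit_config(),
                                     granularity = length(series$times)) {
  stopifnot(inherits(series, "hic_series"))
  ti <- match(holdout_time, series$times)
  if (is.na(ti)) stop("holdout_time ", holdout_time, " is not an observed time")
  if (ti == 1L || ti == length(series$times)) {
    stop("cannot hold out an endpoint: no flanking restraints on both sides")
  }
  res <- build_restraints(series, gamma = config$gamma,
                          granularity = granularity,
                          exclude_times = holdout_time)
  fit <- fit_structure(res, config)
  interp <- extract_map(fit$structure, holdout_time)
  attr(interp, "provenance") <- "interpolated"
  truth <- series$maps[[ti]]
  base <- naive_interpolation(series$maps[[ti - 1L]], series$maps[[ti + 1L]],
                              holdout_time)
  rep_truth <- compare_maps(interp, truth)
  rep_base <- compare_maps(base, truth)
  structure(
    list(holdout_time = holdout_time,
         vs_truth = rep_truth,
         vs_baseline_truth = rep_base,
         vs_previous = compare_maps(interp, series$maps[[ti - 1L]]),
         vs_next = compare_maps(interp, series$maps[[ti + 1L]]),
         beats_baseline = rep_truth$src > rep_base$src,
         fit = fit, interpolated = interp, baseline = base),
    class = "holdout_report"
  )
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf("<holdout_report> time %g held out\n", x$holdout_time))
  cat(sprintf("  model vs truth:    SRC %.4f  PCC %.4f\n",
              x$vs_truth$src, x$vs_truth$pcc))
  cat(sprintf("  baseline vs truth: SRC %.4f  PCC %.4f  (model %s)\n",
              x$vs_baseline_truth$src, x$vs_baseline_truth$pcc,
              if (x$beats_baseline) "wins" else "does not win"))
  invisible(x)
}
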