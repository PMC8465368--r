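# Toy looping chromosome: 11 beads on a unit-bond chain evolving over 6
# days from a closed loop (regular 11-gon, ends in contact) to a straight
# line. Frames are built from per-joint turning angles, so bond lengths
# are exactly constant across frames.
#
# unravel: the background curvature of the arms decays monotonically
#   while the apex angle at bin 5 first tightens into a hairpin (the loop
#   is pulled open from both ends, the shrinking loop tip keeps bins 4
#   and 6 in contact through the middle of the process) and finally
#   releases.
# swing: the curvature relaxes uniformly at every joint (the loop swings
#   open as one arc), so bins 4 and 6 separate from day 1.

.toy_schedules <- list(
  unravel = list(background = c(360 / 11, 20, 10, 4, 1.5, 0),
                 apex = c(360 / 11, 70, 100, 110, 100, 0)),
  swing = list(background = (360 / 11) * (1 - (0:5) / 5),
               apex = (360 / 11) * (1 - (0:5) / 5))
)

.build_chain <- function(turn_deg) {
  phi <- turn_deg * pi / 180
  nb <- length(phi) + 1L                 # bonds
  dirs <- cumsum(c(0, phi))
  xy <- rbind(c(0, 0), apply(cbind(cos(dirs), sin(dirs)), 2, cumsum))
  cbind(xy, 0)
}

#' Generate a toy 4D chromosome trajectory
#'
#' Two analytic trajectories of an 11-bin, 50 kb toy chromosome over a
#' 6-day process (days 0..5). Both start as a closed loop (bins 0 and 10
#' one bond length apart) and end as a fully elongated straight chain,
#' but take different paths: `"unravel"` keeps a tightening hairpin at
#' the chain's midpoint so that bins 4 and 6 stay proximal around day 3,
#' `"swing"` opens the loop uniformly so they separate early. Bond
#' lengths are exactly 1 in every frame.
#'
#' @param variant `"unravel"` or `"swing"`.
#' @return an object of class `toy_trajectory`: `coords` (6 x 11 x 3
#'   array), `times` (0..5), `bin_size` (50000), `variant`.
#' @export
make_toy_trajectory <- function(variant = c("unravel", "swing")) {
  variant <- match.arg(variant)
  sch <- .toy_schedules[[variant]]
  coords <- array(0, c(6, 11, 3))
  for (f in 1:6) {
    turns <- rep(sch$background[f], 9)
    turns[5] <- sch$apex[f]
    coords[f, , ] <- .build_chain(turns)
  }
  structure(
    list(coords = coords, times = 0:5, bin_size = 50000L, variant = variant),
    class = "toy_trajectory"
  )
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat(sprintf("<toy_trajectory> '%s': 11 bins x 6 days, 50 kb bins\n", x$variant))
  invisible(x)
}

#' Simulate a Hi-C time series from a trajectory
#'
#' Applies the inverse power law `IF = d^(-1/gamma)` to every frame's
#' pairwise distances (a noiseless synthetic Hi-C experiment). With
#' `noise = "poisson"` each upper-triangle entry is resampled as
#' `rpois(scale * IF) / scale`, emulating finite read coverage.
#'
#' @param trajectory a [make_toy_trajectory()] result (or any object
#'   with a `g x n x 3` `coords` array plus `times` and `bin_size`).
#' @param gamma positive exponent magnitude.
#' @param noise `"none"` or `"poisson"`.
#' @param scale Poisson expected-count multiplier (> 0).
#' @param seed seed for the noise draw.
#' @param chrom chromosome label for the simulated maps.
#' @return an [assemble_series()] result with one map per frame.
#' @export
simulate_hic <- function(trajectory, gamma = 0.6,
                         noise = c("none", "poisson"), scale = 100,
                         seed = 0, chrom = "toy") {
  noise <- match.arg(noise)
  if (noise == "poisson" && scale <= 0) stop("poisson scale must be positive")
  co <- trajectory$coords
  g <- dim(co)[1]
  set.seed(seed)
  maps <- lapply(seq_len(g), function(f) {
    d <- as.matrix(stats::dist(co[f, , ]))
    IF <- ifelse(d > 0, d^(-1 / gamma), 0)
    diag(IF) <- 0
    if (noise == "poisson") {
      ut <- upper.tri(IF)
      IF[ut] <- stats::rpois(sum(ut), scale * IF[ut]) / scale
      IF[lower.tri(IF)] <- t(IF)[lower.tri(IF)]
    }
    contact_map(IF, bin_size = trajectory$bin_size,
                time = trajectory$times[f], chrom = chrom)
  })
  assemble_series(maps)
}

# contact criterion used in variant discrimination: bins i and j are "in
# contact" in a frame when their distance is at most `thresh` times the
# mean consecutive-bin distance of that frame.
.contact_ratio <- function(X, i, j) {
  d <- as.matrix(stats::dist(X))
  n <- nrow(X)
  d[i, j] / mean(d[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)])
}

#' End-to-end recovery experiment on the toy trajectories
#'
#' The full validation loop on one toy variant: simulate a noiseless
#' Hi-C series, build restraints, fit the 4D model, extract maps at all
#' six days, and score them against the input maps (PCC); then repeat
#' with each interior day (1-4) held out and score the interpolated maps
#' against the withheld truth. Also evaluates the bin-4/bin-6 contact at
#' day 3 (distance relative to the mean bond length), the geometric
#' signature that separates the two variants.
#'
#' @param variant `"unravel"` or `"swing"`.
#' @param config a [fit_config()].
#' @return an object of class `recovery_report`: `variant`, `full_pcc`
#'   (per-day PCC of reconstructed vs input maps), `holdout_pcc` (named
#'   per held-out day), `contact_ratio_day3` (full fit),
#'   `holdout3_contact_ratio` (day-3 holdout fit), `fit`.
#' @export
end_to_end_recovery <- function(variant = c("unravel", "swing"),
                                config = fit_config()) {
  variant <- match.arg(variant)
  traj <- make_toy_trajectory(variant)
  series <- simulate_hic(traj, gamma = config$gamma)
  res <- build_restraints(series, gamma = config$gamma)
  fit <- fit_structure(res, config)
  full_pcc <- vapply(seq_along(series$times), function(k) {
    compare_maps(extract_map(fit$structure, series$times[k]),
                 series$maps[[k]])$pcc
  }, 1)
  names(full_pcc) <- series$times
  hold <- vapply(1:4, function(d) {
    interpolation_experiment(series, holdout_time = d, config = config)$vs_truth$pcc
  }, 1)
  names(hold) <- 1:4
  hd3 <- interpolation_experiment(series, holdout_time = 3, config = config)
  structure(
    list(variant = variant,
         full_pcc = full_pcc,
         holdout_pcc = hold,
         contact_ratio_day3 = .contact_ratio(frame_at(fit$structure, 3), 5L, 7L),
         holdout3_contact_ratio = .contact_ratio(frame_at(hd3$fit$structure, 3), 5L, 7L),
         fit = fit),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> '%s'\n", x$variant))
  cat("  reconstruction PCC by day: ",
      paste(sprintf("%.3f", x$full_pcc), collapse = " "), "\n", sep = "")
  cat("  holdout PCC (days 1-4):    ",
      paste(sprintf("%.3f", x$holdout_pcc), collapse = " "), "\n", sep = "")
  cat(sprintf("  day-3 bin4/bin6 distance / bond: %.2f (full), %.2f (day-3 holdout)\n",
              x$contact_ratio_day3, x$holdout3_contact_ratio))
  invisible(x)
}
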