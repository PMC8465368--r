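#' Fitting configuration for the 4D model
#'
#' Bundles the hyperparameters of the gradient-descent fit. The defaults
#' mirror the method's standard settings: learning rate `1e-4`,
#' smoothness weight `1000`, `400` epochs, distance exponent `0.6`.
#'
#' `sigma_floor` is a lower bound on the profiled Gaussian scale of the
#' restraint likelihood, expressed on the unit-max target-distance scale.
#' Without it the profiled likelihood is unbounded as the residuals of a
#' noiseless fit shrink, and a fixed-step descent ends up oscillating
#' around the degenerate optimum; the floor keeps the objective bounded
#' and the descent monotone. `restarts` independent random
#' initializations are fitted and the lowest final loss is kept, the
#' usual guard against tangled local optima of distance geometry.
#'
#' @param learning_rate positive gradient-descent step.
#' @param smoothness_weight non-negative weight of the inter-frame
#'   movement penalty (applied to the mean squared per-bin displacement).
#' @param epochs number of full-batch descent iterations.
#' @param seed integer seed controlling initialization.
#' @param gamma positive distance-exponent magnitude.
#' @param sigma_floor non-negative lower bound for the profiled Gaussian
#'   scale.
#' @param weight_by_n weight each time point's log-residual term by half
#'   its restraint count, i.e. use the exact profiled Gaussian
#'   log-likelihood rather than the constant-dropped form.
#' @param restarts number of random restarts.
#' @param per_frame_init draw an independent initialization per time frame
#'   instead of starting all frames identical.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(learning_rate = 1e-4, smoothness_weight = 1000,
                       epochs = 400, seed = 0, gamma = 0.6,
                       sigma_floor = 0.05, weight_by_n = TRUE,
                       restarts = 3, per_frame_init = FALSE) {
  stopifnot(learning_rate > 0, smoothness_weight >= 0, epochs >= 1,
            gamma > 0, sigma_floor >= 0, restarts >= 1)
  structure(
    list(learning_rate = learning_rate, smoothness_weight = smoothness_weight,
         epochs = as.integer(epochs), seed = as.integer(seed), gamma = gamma,
         sigma_floor = sigma_floor, weight_by_n = isTRUE(weight_by_n),
         restarts = as.integer(restarts), per_frame_init = isTRUE(per_frame_init)),
    class = "fit_config"
  )
}

#' Random initial structure
#'
#' Every coordinate is drawn i.i.d. uniform on (0, 1) — an unfolded
#' starting conformation commensurate with the unit-max restraint scale.
#' By default all frames start identical (zero initial inter-frame
#' movement); `per_frame` draws each frame independently.
#'
#' @param restraints a [build_restraints()] result.
#' @param seed integer seed.
#' @param per_frame independent draw per frame.
#' @return an object of class `structure_4d`: `coords` is a
#'   `g x n_bins x 3` array, plus the grid and map metadata.
#' @export
init_structure <- function(restraints, seed = 0, per_frame = FALSE) {
  stopifnot(inherits(restraints, "restraint_set"))
  g <- length(restraints$grid)
  n <- restraints$n_bins
  set.seed(seed)
  coords <- array(0, c(g, n, 3))
  if (per_frame) {
    for (t in seq_len(g)) coords[t, , ] <- stats::runif(n * 3)
  } else {
    x0 <- matrix(stats::runif(n * 3), n, 3)
    for (t in seq_len(g)) coords[t, , ] <- x0
  }
  structure_4d(coords, grid = restraints$grid, bin_size = restraints$bin_size,
               chrom = restraints$chrom, mask = restraints$mask,
               scale = restraints$scale, gamma = restraints$gamma)
}

#' Construct a 4D structure object
#'
#' @param coords `g x n x 3` numeric array of coordinates (grid time,
#'   bin, x/y/z).
#' @param grid strictly increasing grid times.
#' @param bin_size bin width in base pairs.
#' @param chrom chromosome label.
#' @param mask per-bin logical, TRUE where the bin had no data.
#' @param scale global factor mapping model distances back to the
#'   unscaled `IF^(-gamma)` scale.
#' @param gamma distance-exponent magnitude used to build the restraints.
#' @return an object of class `structure_4d`.
#' @export
structure_4d <- function(coords, grid, bin_size = NA_integer_, chrom = "chr",
                         mask = NULL, scale = 1, gamma = 0.6) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L,
            dim(coords)[1] == length(grid), all(is.finite(coords)),
            dim(coords)[1] >= 2L, dim(coords)[2] >= 1L)
  if (is.null(mask)) mask <- rep(FALSE, dim(coords)[2])
  structure(
    list(coords = coords, grid = as.numeric(grid),
         bin_size = bin_size, chrom = chrom, mask = mask,
         scale = scale, gamma = gamma),
    class = "structure_4d"
  )
}

#' @export
print.structure_4d <- function(x, ...) {
  cat(sprintf("<structure_4d> %s, %d bins x %d frames over [%g, %g]\n",
              x$chrom, dim(x$coords)[2], dim(x$coords)[1],
              x$grid[1], x$grid[length(x$grid)]))
  invisible(x)
}

#' Frame coordinates at a grid time
#' @param structure a [structure_4d].
#' @param t real time; must coincide with a grid time within 25% of the
#'   grid spacing.
#' @return `n x 3` coordinate matrix.
#' @export
frame_at <- function(structure, t) {
  structure$coords[.grid_index(structure$grid, t), , ]
}

.grid_index <- function(grid, t) {
  spacing <- if (length(grid) > 1) grid[2] - grid[1] else 1
  k <- which.min(abs(grid - t))
  if (abs(grid[k] - t) > 0.25 * spacing + 1e-12) {
    stop("time ", t, " does not coincide with any grid time (nearest: ",
         grid[k], ")")
  }
  k
}

#' Interpolation weights between flanking observed times
#'
#' For a grid time `t` strictly between the nearest earlier observed time
#' `a1` and the nearest later observed time `a2`, the model's likelihood
#' term at `t` is the convex combination `w1 * L(a1) + w2 * L(a2)` with
#' `w1 = (t - a2) / (a1 - a2)` and `w2 = 1 - w1`: the closer `t` lies to
#' an observed time, the more that time's restraints weigh.
#'
#' @param t grid time, strictly inside `(a1, a2)`.
#' @param a1,a2 flanking observed times, `a1 < a2`.
#' @return numeric `c(w1, w2)`, both in (0, 1), summing to 1.
#' @export
interpolation_weights <- function(t, a1, a2) {
  if (!(a1 < t && t < a2)) {
    stop("t = ", t, " must lie strictly inside (", a1, ", ", a2, ")")
  }
  w1 <- (t - a2) / (a1 - a2)
  c(w1 = w1, w2 = 1 - w1)
}

# per-grid-time term structure: list of (obs grid index, weight)
.time_terms <- function(restraints) {
  g <- length(restraints$grid)
  oi <- sort(unname(restraints$observed_index))
  lapply(seq_len(g), function(t) {
    if (t %in% oi) return(list(c(t, 1)))
    a1 <- max(oi[oi < t])
    a2 <- min(oi[oi > t])
    w <- interpolation_weights(restraints$grid[t], restraints$grid[a1],
                               restraints$grid[a2])
    list(c(a1, w[[1]]), c(a2, w[[2]]))
  })
}

#' Per-time data loss
#'
#' The restraint misfit of one grid time: `log(sum((H - D)^2) / n_t)`
#' where `H` are the target distances restrained at that time, `D` the
#' model's Euclidean distances and `n_t` the restraint count. At an
#' unobserved grid time the convex combination of the two flanking
#' observed-time losses (see [interpolation_weights()]) is returned.
#' `weight_by_n = TRUE` multiplies each term by `n_t / 2`, giving the
#' exact profiled Gaussian negative log-likelihood (the form minimized by
#' [fit_structure()]); `sigma_floor` bounds the profiled scale from
#' below.
#'
#' @param structure a [structure_4d].
#' @param restraints the matching [build_restraints()] result.
#' @param t_index grid index (1-based).
#' @param weight_by_n weight by half the restraint count.
#' @param sigma_floor lower bound for the profiled Gaussian scale.
#' @return scalar loss.
#' @export
data_loss <- function(structure, restraints, t_index,
                      weight_by_n = FALSE, sigma_floor = 0) {
  stopifnot(inherits(structure, "structure_4d"),
            inherits(restraints, "restraint_set"))
  g <- length(restraints$grid)
  if (t_index < 1 || t_index > g) stop("t_index out of range")
  terms <- .time_terms(restraints)[[t_index]]
  X <- structure$coords[t_index, , ]
  total <- 0
  for (tm in terms) {
    tab <- restraints$targets[[tm[1]]]
    if (is.null(tab) || nrow(tab) == 0L) {
      stop("no restraints applicable at grid index ", t_index)
    }
    dx <- X[tab$i, , drop = FALSE] - X[tab$j, , drop = FALSE]
    D <- sqrt(rowSums(dx^2))
    np <- nrow(tab)
    sse <- sum((D - tab$target)^2)
    cf <- if (weight_by_n) np / 2 else 1
    total <- total + tm[2] * cf * log((sse + np * sigma_floor^2) / np)
  }
  total
}

#' Inter-frame movement penalty
#'
#' Sum over consecutive frame pairs, bins and coordinates of the squared
#' displacement — the raw smoothness term discouraging uninformative
#' motion (e.g. arbitrary rotation between frames). The fit applies its
#' weight to this quantity divided by `(g - 1) * n_bins`, the mean
#' squared per-bin displacement, so that the default weight behaves
#' consistently across chromosome sizes and granularities.
#'
#' @param structure a [structure_4d].
#' @return scalar penalty (raw sum).
#' @export
smoothness_penalty <- function(structure) {
  stopifnot(inherits(structure, "structure_4d"))
  co <- structure$coords
  g <- dim(co)[1]
  sum((co[-1, , , drop = FALSE] - co[-g, , , drop = FALSE])^2)
}

# objective + gradient over the list-of-frames representation
.objective <- function(X, pre, cfg) {
  g <- length(X)
  n <- nrow(X[[1]])
  Ldata <- 0
  G <- lapply(seq_len(g), function(t) matrix(0, n, 3))
  for (t in seq_len(g)) {
    for (tm in pre$terms[[t]]) {
      a <- tm[1]; w <- tm[2]
      ii <- pre$ii[[a]]; jj <- pre$jj[[a]]; H <- pre$H[[a]]
      np <- length(H)
      dx <- X[[t]][ii, , drop = FALSE] - X[[t]][jj, , drop = FALSE]
      D <- pmax(sqrt(rowSums(dx^2)), 1e-12)
      r <- D - H
      sse <- sum(r^2)
      den <- sse + np * cfg$sigma_floor^2
      cf <- if (cfg$weight_by_n) np / 2 else 1
      Ldata <- Ldata + w * cf * log(den / np)
      gp <- dx * (w * cf * 2 / den * r / D)
      for (c in 1:3) {
        acc <- rowsum(c(gp[, c], -gp[, c]), c(ii, jj))
        G[[t]][as.integer(rownames(acc)), c] <-
          G[[t]][as.integer(rownames(acc)), c] + acc[, 1]
      }
    }
  }
  pen <- 0
  ec <- cfg$smoothness_weight / ((g - 1) * n)
  for (t in seq_len(g - 1)) {
    dlt <- X[[t]] - X[[t + 1]]
    pen <- pen + sum(dlt^2)
    G[[t]] <- G[[t]] + ec * 2 * dlt
    G[[t + 1]] <- G[[t + 1]] - ec * 2 * dlt
  }
  list(total = Ldata + ec * pen, data = Ldata,
       penalty = pen / ((g - 1) * n), G = G)
}

.precompute <- function(restraints) {
  obs <- sort(unname(restraints$observed_index))
  ii <- jj <- H <- vector("list", length(restraints$grid))
  for (a in obs) {
    tab <- restraints$targets[[a]]
    ii[[a]] <- tab$i; jj[[a]] <- tab$j; H[[a]] <- tab$target
  }
  list(terms = .time_terms(restraints), ii = ii, jj = jj, H = H)
}

#' Fit the 4D structure by gradient descent
#'
#' Minimizes the total objective — the profiled Gaussian restraint
#' negative log-likelihood summed over grid times (observed times use
#' their own restraints, unobserved times the convex combination of the
#' flanking observed sets) plus the weighted mean squared inter-frame
#' displacement — by full-batch fixed-step gradient descent. `restarts`
#' independent initializations are run and the lowest final objective is
#' kept; the whole procedure is deterministic given `config$seed`.
#'
#' @param restraints a [build_restraints()] result.
#' @param config a [fit_config()].
#' @return an object of class `hic4d_fit`: list with `structure` (the
#'   fitted [structure_4d]), `trace` (data.frame of per-epoch `total`,
#'   `data` and `penalty` values for the kept restart), `loss` (final
#'   total objective) and `restart` (index of the kept restart).
#' @export
fit_structure <- function(restraints, config = fit_config()) {
  stopifnot(inherits(restraints, "restraint_set"), inherits(config, "fit_config"))
  pre <- .precompute(restraints)
  g <- length(restraints$grid)
  n <- restraints$n_bins
  best <- NULL
  for (k in seq_len(config$restarts)) {
    s <- init_structure(restraints, seed = config$seed + (k - 1L) * 1009L,
                        per_frame = config$per_frame_init)
    X <- lapply(seq_len(g), function(t) s$coords[t, , ])
    trace <- data.frame(epoch = seq_len(config$epochs), total = NA_real_,
                        data = NA_real_, penalty = NA_real_)
    for (e in seq_len(config$epochs)) {
      ob <- .objective(X, pre, config)
      if (!is.finite(ob$total)) {
        stop("fit diverged at epoch ", e, " (non-finite loss); reduce the learning rate")
      }
      for (t in seq_len(g)) X[[t]] <- X[[t]] - config$learning_rate * ob$G[[t]]
      trace$total[e] <- ob$total
      trace$data[e] <- ob$data
      trace$penalty[e] <- ob$penalty
    }
    final <- .objective(X, pre, config)$total
    if (is.null(best) || final < best$loss) {
      best <- list(X = X, trace = trace, loss = final, restart = k)
    }
  }
  coords <- array(0, c(g, n, 3))
  for (t in seq_len(g)) coords[t, , ] <- best$X[[t]]
  out <- list(
    structure = structure_4d(coords, grid = restraints$grid,
                             bin_size = restraints$bin_size,
                             chrom = restraints$chrom, mask = restraints$mask,
                             scale = restraints$scale, gamma = restraints$gamma),
    trace = best$trace, loss = best$loss, restart = best$restart,
    config = config
  )
  class(out) <- "hic4d_fit"
  out
}

#' @export
print.hic4d_fit <- function(x, ...) {
  cat(sprintf("<hic4d_fit> %d epochs, final loss %.4f (restart %d of %d)\n",
              nrow(x$trace), x$loss, x$restart, x$config$restarts))
  print(x$structure)
  invisible(x)
}

#' Check the analytic gradient against finite differences
#'
#' Compares the analytic gradient of the total objective (data loss plus
#' weighted smoothness penalty, as minimized by [fit_structure()])
#' against central finite differences on every coordinate. Intended for
#' small instances.
#'
#' @param structure a [structure_4d] at which to evaluate.
#' @param restraints the matching restraint set.
#' @param config a [fit_config()] (supplies the weights entering the
#'   objective).
#' @param h finite-difference step.
#' @return maximum relative discrepancy over all coordinates.
#' @export
gradient_check <- function(structure, restraints, config = fit_config(),
                           h = 1e-6) {
  pre <- .precompute(restraints)
  g <- dim(structure$coords)[1]
  n <- dim(structure$coords)[2]
  X <- lapply(seq_len(g), function(t) structure$coords[t, , ])
  ob <- .objective(X, pre, config)
  worst <- 0
  for (t in seq_len(g)) {
    for (b in seq_len(n)) {
      for (c in 1:3) {
        Xp <- X; Xp[[t]][b, c] <- Xp[[t]][b, c] + h
        Xm <- X; Xm[[t]][b, c] <- Xm[[t]][b, c] - h
        fd <- (.objective(Xp, pre, config)$total -
               .objective(Xm, pre, config)$total) / (2 * h)
        ga <- ob$G[[t]][b, c]
        rel <- abs(ga - fd) / max(abs(ga) + abs(fd), 1e-6)
        worst <- max(worst, rel)
      }
    }
  }
  worst
}

#' Write a structure as multi-frame XYZ text
#'
#' One frame per grid time; each frame starts with the bin count and a
#' comment line carrying the time tag.
#'
#' @param structure a [structure_4d].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_xyz <- function(structure, path) {
  stopifnot(inherits(structure, "structure_4d"))
  co <- structure$coords
  n <- dim(co)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(dim(co)[1])) {
    writeLines(c(as.character(n), sprintf("time=%g", structure$grid[t])), con)
    writeLines(sprintf("BIN%d %.10g %.10g %.10g", seq_len(n) - 1L,
                       co[t, , 1], co[t, , 2], co[t, , 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ structure
#'
#' @param path file written by [write_structure_xyz()].
#' @param bin_size,chrom metadata to attach.
#' @return a [structure_4d].
#' @export
read_structure_xyz <- function(path, bin_size = NA_integer_, chrom = "chr") {
  lines <- readLines(path)
  frames <- list()
  times <- numeric()
  pos <- 1L
  while (pos <= length(lines)) {
    n <- as.integer(lines[pos])
    times <- c(times, as.numeric(sub("time=", "", lines[pos + 1L])))
    block <- lines[(pos + 2L):(pos + 1L + n)]
    xyz <- t(vapply(strsplit(block, "\\s+"),
                    function(f) as.numeric(f[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  coords <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (t in seq_along(frames)) coords[t, , ] <- frames[[t]]
  structure_4d(coords, grid = times, bin_size = bin_size, chrom = chrom)
}

#' Plot frames of a 4D structure
#'
#' Draws the bead chain of selected frames projected on two principal
#' axes of the first selected frame.
#'
#' @param x a [structure_4d].
#' @param frames grid indices to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.structure_4d <- function(x, frames = unique(round(seq(1, dim(x$coords)[1],
                                                           length.out = 4))), ...) {
  co <- x$coords
  base <- scale(co[frames[1], , ], scale = FALSE)
  pc <- svd(base)$v[, 1:2]
  cols <- grDevices::hcl.colors(length(frames), "Zissou 1")
  prj <- lapply(frames, function(t) scale(co[t, , ], scale = FALSE) %*% pc)
  rng <- apply(do.call(rbind, prj), 2, range)
  graphics::plot(NA, xlim = rng[, 1], ylim = rng[, 2], xlab = "PC1",
                 ylab = "PC2", main = x$chrom, asp = 1, ...)
  for (k in seq_along(frames)) {
    graphics::lines(prj[[k]], col = cols[k], lwd = 2)
    graphics::points(prj[[k]], col = cols[k], pch = 16, cex = 0.6)
  }
  graphics::legend("topright", legend = sprintf("t=%g", x$grid[frames]),
                   col = cols, lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}
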