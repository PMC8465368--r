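# shared fixture builders (all generated in code, no files)

rand_sym_map <- function(n = 11, seed = 1, bin_size = 50000, time = 0) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, 0.5, 10), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  contact_map(m, bin_size = bin_size, time = time)
}

# two-compartment checkerboard map: power-law distance decay modulated by
# a strong within-class / weak between-class factor over alternating A/B
# blocks — the plaid pattern O/E plus correlation PCA is designed to
# expose. Returns the map with the planted class labels attached.
block_map <- function(sizes = c(6, 6), hi = 10, lo = 1, bin_size = 50000) {
  lab <- rep(rep(c(1, 2), length.out = length(sizes)), sizes)
  n <- sum(sizes)
  decay <- (1 + abs(outer(seq_len(n), seq_len(n), `-`)))^-1
  m <- decay * ifelse(outer(lab, lab, `==`), hi, lo)
  diag(m) <- 0
  out <- contact_map(m, bin_size = bin_size, time = 0)
  attr(out, "planted") <- lab
  out
}

toy_series <- function(variant = "unravel", gamma = 0.6) {
  simulate_hic(make_toy_trajectory(variant), gamma = gamma)
}

# quick small fit used by several tests
quick_config <- function(...) {
  fit_config(restarts = 1, ...)
}

rigid_transform <- function(X, seed = 1, scale = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- stats::rnorm(3)
  sweep(scale * X %*% R, 2, shift, `+`)
}
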