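make_restraints <- function(n = 6, times = c(0, 1), seed = 4, granularity = length(times)) {
  maps <- lapply(times, function(t) rand_sym_map(n, seed = seed + round(100 * t), time = t))
  build_restraints(assemble_series(maps), granularity = granularity)
}

test_that("initialization is uniform on (0,1), reproducible, frames identical", {
  res <- make_restraints()
  s1 <- init_structure(res, seed = 7)
  s2 <- init_structure(res, seed = 7)
  s3 <- init_structure(res, seed = 8)
  expect_identical(s1$coords, s2$coords)
  expect_false(identical(s1$coords, s3$coords))
  expect_true(all(s1$coords > 0 & s1$coords < 1))
  expect_equal(s1$coords[1, , ], s1$coords[2, , ])
  s4 <- init_structure(res, seed = 7, per_frame = TRUE)
  expect_false(identical(s4$coords[1, , ], s4$coords[2, , ]))
})

test_that("interpolation weights are the convex pair of Eq-style time ratios", {
  expect_equal(unname(interpolation_weights(1, 0, 2)), c(0.5, 0.5))
  expect_equal(unname(interpolation_weights(0.5, 0, 2)), c(0.75, 0.25))
  for (t in c(0.1, 1.3, 1.9)) {
    w <- interpolation_weights(t, 0, 2)
    expect_equal(sum(w), 1)
    expect_true(all(w > 0 & w < 1))
  }
  # weight of the earlier time tends to 1 as t approaches it
  expect_gt(interpolation_weights(0.01, 0, 2)[[1]], 0.99)
  expect_error(interpolation_weights(2.5, 0, 2), "strictly inside")
  expect_error(interpolation_weights(0, 0, 2), "strictly inside")
})

test_that("data loss matches its closed forms and decreases with residuals", {
  # two bins, one restraint: engineer exact residuals
  m <- contact_map(matrix(c(0, 1, 1, 0), 2, 2), 1000, 0)
  series <- assemble_series(list(m, contact_map(m$matrix, 1000, 1)))
  res <- build_restraints(series, granularity = 2)    # one pair, target 1
  st <- init_structure(res, seed = 1)
  place <- function(d) {
    st$coords[1, , ] <- rbind(c(0, 0, 0), c(d, 0, 0))
    st
  }
  # residual r: loss = log(r^2 / 1) = 2 log |r|
  for (r in c(1, 0.5, 0.1)) {
    expect_equal(data_loss(place(1 + r), res, 1), 2 * log(r), tolerance = 1e-9)
  }
  # halving the residual strictly decreases the loss
  expect_lt(data_loss(place(1.25), res, 1), data_loss(place(1.5), res, 1))
  # n/2 weighting scales the loss by n_t/2 (= 1/2 here)
  expect_equal(data_loss(place(1.5), res, 1, weight_by_n = TRUE),
               0.5 * data_loss(place(1.5), res, 1))
})

test_that("data loss at an unobserved grid time blends the flanking terms", {
  n <- 5
  maps <- list(rand_sym_map(n, seed = 11, time = 0),
               rand_sym_map(n, seed = 12, time = 2))
  res <- build_restraints(assemble_series(maps), granularity = 5)
  st <- init_structure(res, seed = 3)
  set.seed(42)
  st$coords[2, , ] <- matrix(runif(n * 3), n, 3)
  # grid time 0.5 between observed 0 and 2: w1 = 0.75
  direct <- function(a) {
    tab <- res$targets[[a]]
    X <- st$coords[2, , ]
    D <- sqrt(rowSums((X[tab$i, ] - X[tab$j, ])^2))
    log(sum((D - tab$target)^2) / nrow(tab))
  }
  expect_equal(data_loss(st, res, 2), 0.75 * direct(1) + 0.25 * direct(5),
               tolerance = 1e-12)
})

test_that("smoothness penalty sums squared inter-frame displacements", {
  res <- make_restraints()
  st <- init_structure(res, seed = 1)
  expect_equal(smoothness_penalty(st), 0)                    # identical frames
  st$coords[2, 1, 1] <- st$coords[2, 1, 1] + 1
  expect_equal(smoothness_penalty(st), 1)                    # unit step
  # 3 frames, one bin at x = 0, 1, 3 -> 1 + 4
  res3 <- make_restraints(times = c(0, 1, 2))
  st3 <- init_structure(res3, seed = 1)
  st3$coords[, , ] <- 0
  st3$coords[1, 1, 1] <- 0; st3$coords[2, 1, 1] <- 1; st3$coords[3, 1, 1] <- 3
  expect_equal(smoothness_penalty(st3), 5)
})

test_that("analytic gradient agrees with central finite differences", {
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:8, 1)
    g <- sample(2:5, 1)
    times <- seq(0, g - 1)
    res <- make_restraints(n = n, times = times, seed = seed,
                           granularity = sample(c(g, 2 * g - 1), 1))
    st <- init_structure(res, seed = seed, per_frame = TRUE)
    worst <- max(worst, gradient_check(st, res, fit_config()))
  }
  expect_lt(worst, 1e-4)
})

test_that("gradient is near zero at a perfect fit and linear in eta", {
  # structure equal to the generating coordinates, eta = 0: stationary
  traj <- make_toy_trajectory("swing")
  series <- simulate_hic(traj)
  res <- build_restraints(series, granularity = 6)
  st <- init_structure(res, seed = 1)
  for (t in 1:6) st$coords[t, , ] <- traj$coords[t, , ] / res$scale
  cfg0 <- fit_config(smoothness_weight = 0, sigma_floor = 0.05)
  gr <- hic4d:::.objective(lapply(1:6, function(t) st$coords[t, , ]),
                           hic4d:::.precompute(res), cfg0)
  expect_lt(max(abs(unlist(gr$G))), 1e-8)

  # doubling eta doubles the penalty gradient component
  st$coords[3, , ] <- st$coords[3, , ] + 0.1
  X <- lapply(1:6, function(t) st$coords[t, , ])
  pre <- hic4d:::.precompute(res)
  g1 <- hic4d:::.objective(X, pre, fit_config(smoothness_weight = 500))$G
  g2 <- hic4d:::.objective(X, pre, fit_config(smoothness_weight = 1000))$G
  g0 <- hic4d:::.objective(X, pre, fit_config(smoothness_weight = 0))$G
  for (t in 1:6) {
    expect_equal(g2[[t]] - g0[[t]], 2 * (g1[[t]] - g0[[t]]), tolerance = 1e-9)
  }
})

test_that("the objective is invariant under global rigid motion of all frames", {
  res <- make_restraints(n = 7, times = c(0, 1, 2), seed = 6)
  st <- init_structure(res, seed = 2, per_frame = TRUE)
  X <- lapply(1:3, function(t) st$coords[t, , ])
  pre <- hic4d:::.precompute(res)
  cfg <- fit_config()
  L0 <- hic4d:::.objective(X, pre, cfg)
  Xr <- lapply(X, rigid_transform, seed = 99)        # same transform per frame
  L1 <- hic4d:::.objective(Xr, pre, cfg)
  expect_equal(L1$total, L0$total, tolerance = 1e-9)
  expect_equal(L1$penalty, L0$penalty, tolerance = 1e-9)
})

test_that("fitting recovers a static structure and the trace descends", {
  set.seed(10)
  X <- matrix(runif(33), 11, 3)
  d <- as.matrix(dist(X))
  IF <- ifelse(d > 0, d^(-1 / 0.6), 0)
  maps <- lapply(0:1, function(t) contact_map(IF, 50000, t))
  res <- build_restraints(assemble_series(maps), granularity = 2)
  fit <- fit_structure(res, fit_config(seed = 0))
  ut <- upper.tri(d)
  for (t in 1:2) {
    dm <- as.matrix(dist(fit$structure$coords[t, , ]))
    expect_gt(cor(dm[ut], d[ut], method = "spearman"), 0.95)
  }
  expect_lt(fit$trace$total[400], fit$trace$total[1])
  # determinism given the seed
  fit2 <- fit_structure(res, fit_config(seed = 0))
  expect_identical(fit$structure$coords, fit2$structure$coords)
})

test_that("without smoothness, frames with disjoint restraints decouple", {
  # two observed times; each frame's gradient then involves only its own data
  res <- make_restraints(n = 6, times = c(0, 1), seed = 21)
  cfg <- quick_config(smoothness_weight = 0, epochs = 30)
  fit <- fit_structure(res, cfg)
  # refit with a perturbed map at time 1 only: frame 0 must be bit-identical
  maps <- list(rand_sym_map(6, seed = 21, time = 0),
               rand_sym_map(6, seed = 999, time = 1))
  res2 <- build_restraints(assemble_series(maps), granularity = 2)
  # rescaling differs between restraint sets; align scales for the check
  res2$targets[[1]]$target <- res$targets[[1]]$target
  fit2 <- fit_structure(res2, cfg)
  expect_identical(fit$structure$coords[1, , ], fit2$structure$coords[1, , ])
  expect_false(identical(fit$structure$coords[2, , ], fit2$structure$coords[2, , ]))
})

test_that("structures round-trip through multi-frame XYZ text", {
  res <- make_restraints(n = 5, times = c(0, 1, 3), seed = 8, granularity = 4)
  st <- init_structure(res, seed = 3, per_frame = TRUE)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_structure_xyz(st, p)
  back <- read_structure_xyz(p)
  expect_equal(back$coords, st$coords, tolerance = 1e-9)
  expect_equal(back$grid, st$grid)
})
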