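test_that("O/E matrices normalize every diagonal to unit mean", {
  m <- rand_sym_map(12, seed = 31)
  oe <- oe_matrix(m)
  for (s in 1:11) {
    vals <- oe[abs(row(oe) - col(oe)) == s]
    expect_equal(mean(vals), 1, tolerance = 1e-9)
  }
  # constant off-diagonal map: O equals E everywhere
  cm <- contact_map(matrix(5, 8, 8) - diag(5, 8), 1000, 0)
  oec <- oe_matrix(cm)
  off <- abs(row(oec) - col(oec)) > 0
  expect_true(all(abs(oec[off] - 1) < 1e-12))
  # direct division oracle on one engineered diagonal
  mm <- matrix(1, 6, 6); diag(mm) <- 0
  mm[1, 2] <- mm[2, 1] <- 4; mm[2, 3] <- mm[3, 2] <- 0
  # separation-1 mean: (4 + 0 + 1 + 1 + 1)/5 = 1.4
  oe2 <- oe_matrix(contact_map(mm, 1000, 0))
  expect_equal(oe2[1, 2], 4 / 1.4, tolerance = 1e-12)
})

test_that("masked bins are excluded from O/E and compartment signs", {
  mm <- rand_sym_map(10, seed = 32)$matrix
  mm[4, ] <- mm[, 4] <- 0
  m <- contact_map(mm, 1000, 0)
  oe <- oe_matrix(m)
  expect_equal(oe[4, ], rep(0, 10))
  prof <- ab_compartments(m)
  expect_true(is.na(prof$pc1[4]))
  expect_true(is.na(prof$signs[4]))
  expect_error(oe_matrix(contact_map(matrix(0, 4, 4), 1000, 0)), "unmasked")
})

test_that("PC1 sign recovers a planted two-compartment partition", {
  for (sizes in list(c(6, 6), c(3, 3, 3, 3), c(4, 4, 4), c(5, 3, 4),
                     c(3, 4, 3, 4))) {
    m <- block_map(sizes)
    lab <- attr(m, "planted")
    prof <- ab_compartments(m)
    s <- as.character(prof$signs)
    # exact partition up to global flip
    expect_true(all(s[lab == 1] == s[lab == 1][1]))
    expect_true(all(s[lab == 2] == s[lab == 2][1]))
    expect_false(s[lab == 1][1] == s[lab == 2][1])
  }
  # flipping pc1 yields the complementary labelling with identical magnitudes
  prof <- ab_compartments(block_map(c(6, 6)))
  flipped <- ifelse(prof$pc1 > 0, "B", "A")
  expect_true(all(flipped != as.character(prof$signs)))
  expect_true(prof$explained_variance > 0.3)
})

test_that("compartment trajectories embed sign vectors in 2D", {
  mk_prof <- function(n_a) {
    # hand-build a profile flipping from all-A to all-B
    p <- list(pc1 = c(rep(1, n_a), rep(-1, 12 - n_a)),
              signs = factor(c(rep("A", n_a), rep("B", 12 - n_a)),
                             levels = c("A", "B")),
              explained_variance = 1, mask = rep(FALSE, 12), time = 12 - n_a)
    class(p) <- "compartment_profile"
    p
  }
  profs <- lapply(c(12, 9, 6, 3, 0), mk_prof)
  traj <- compartment_trajectory(profs)
  expect_equal(nrow(traj), 5L)
  expect_equal(ncol(traj), 3L)                     # time + exactly 2 PCs
  # monotone sweep: PC1 ordering follows the flip progression
  expect_true(all(diff(traj$pc1) > 0) || all(diff(traj$pc1) < 0))
  # identical profiles collapse to a single point
  same <- compartment_trajectory(lapply(c(6, 6, 6), mk_prof))
  expect_lt(max(dist(same[, c("pc1", "pc2")])), 1e-9)
  expect_error(compartment_trajectory(profs[1:2]), "at least 3")
})

test_that("directionality index matches Eq oracle and is antisymmetric", {
  # engineer a bin with upstream sum 20 and downstream sum 40
  m <- matrix(0, 3, 3)
  m[2, 1] <- m[1, 2] <- 20
  m[2, 3] <- m[3, 2] <- 40
  di <- directionality_index(contact_map(m, 1e6, 0), window_bp = 2e6)
  expect_equal(di$di[2], (100 / 30 + 100 / 30), tolerance = 1e-12)
  # swapped A and B negates DI
  msw <- matrix(0, 3, 3)
  msw[2, 1] <- msw[1, 2] <- 40
  msw[2, 3] <- msw[3, 2] <- 20
  disw <- directionality_index(contact_map(msw, 1e6, 0), window_bp = 2e6)
  expect_equal(disw$di[2], -di$di[2])
  # A = B gives 0 by convention
  meq <- matrix(0, 3, 3)
  meq[2, 1] <- meq[1, 2] <- 30
  meq[2, 3] <- meq[3, 2] <- 30
  expect_equal(directionality_index(contact_map(meq, 1e6, 0), 2e6)$di[2], 0)
})

test_that("DI windows truncate at chromosome ends and respect window size", {
  m <- rand_sym_map(20, seed = 41, bin_size = 50000)
  tr <- directionality_index(m, window_bp = 2e6)    # 40-bin window > n
  expect_equal(tr$A[1], 0)                          # nothing upstream of bin 1
  expect_equal(tr$B[20], 0)
  expect_equal(tr$A[5], sum(m$matrix[5, 1:4]))
  tr2 <- directionality_index(m, window_bp = 100000)  # 2-bin window
  expect_equal(tr2$A[5], sum(m$matrix[5, 3:4]))
  expect_equal(tr2$B[5], sum(m$matrix[5, 6:7]))
})

test_that("the HMM recovers planted TAD borders and is deterministic", {
  set.seed(7)
  truth_border <- 31L
  di_vals <- c(rep(8, 10), rep(-8, 20), rep(8, 20), rep(-8, 10)) +
    rnorm(60, sd = 0.5)
  track <- structure(list(di = di_vals, A = NULL, B = NULL, window = 2e6,
                          bin_size = 50000, mask = rep(FALSE, 60)),
                     class = "di_track")
  tads <- call_tads(track)
  # planted two-domain signal: the upstream->downstream flip at bin 31
  expect_true(any(abs(tads$borders - truth_border) <= 1))
  tads2 <- call_tads(track)
  expect_identical(tads$borders, tads2$borders)
  # featureless track yields no borders
  zero <- structure(list(di = rep(0, 40), A = NULL, B = NULL, window = 2e6,
                         bin_size = 50000, mask = rep(FALSE, 40)),
                    class = "tad_set")
  class(zero) <- "di_track"
  expect_length(call_tads(zero)$borders, 0L)
})

test_that("border overlap counts matches within tolerance, asymmetrically", {
  expect_equal(tad_border_overlap(c(10L, 50L), c(10L, 50L)), 100)
  expect_equal(tad_border_overlap(c(10L, 50L), c(12L, 100L), tol_bins = 3), 50)
  a <- c(10L, 50L, 90L)
  b <- c(11L, 49L)
  expect_equal(tad_border_overlap(a, b), 100 * 2 / 3)
  expect_equal(tad_border_overlap(b, a), 100)
  expect_error(tad_border_overlap(integer(), a), "undefined")
})

test_that("compartment vectors re-bin by consecutive averaging", {
  v <- c(1, 3, 5, 7, 9)
  expect_equal(rebin_vector(v, 2), c(2, 6, 9))
  expect_equal(rebin_vector(c(1, NA, 4, 4), 2), c(1, 4))
})
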