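test_that("init_binary_step counts and validates", {
  mask <- matrix(FALSE, 10, 10); mask[4:7, 4:7] <- TRUE
  phi <- init_binary_step(mask, 2)
  expect_identical(sum(phi$phi == -2), 16L)
  expect_identical(sum(phi$phi == 2), 84L)
  expect_error(init_binary_step(matrix(FALSE, 5, 5)), "empty")
  expect_error(init_binary_step(matrix(TRUE, 5, 5)), "full frame")
})

test_that("the initial zero contour traces the mask boundary", {
  mask <- box_mask(40, 40, 10)
  phi <- init_binary_step(mask, 2)
  cn <- extract_zero_contour(phi)
  # rectangle boundary through the pixel-midpoint lines at 10.5 / 30.5
  t_ <- seq(10.5, 30.5, by = 0.25)
  truth <- rbind(cbind(10.5, t_), cbind(30.5, t_), cbind(t_, 10.5),
                 cbind(t_, 30.5))
  expect_lt(hausdorff(cn, truth), 1)
})

test_that("signed_distance_disk is a discrete SDF", {
  phi <- signed_distance_disk(64, 64, c(32, 32), 10)
  expect_equal(phi$phi[32, 32], -10)
  expect_equal(phi$phi[32, 52], 10)  # at distance 2R from the center
  # per-pixel penalty density tiny away from the center kink
  r <- matrix(1:64, 64, 64); c_ <- t(r)
  d <- sqrt((r - 32)^2 + (c_ - 32)^2)
  m <- gradient_magnitude(phi$phi)
  dens <- 0.5 * (m - 1)^2
  expect_lt(max(dens[d > 2]), 1e-3)
})

test_that("dirac_reg matches its closed form and integrates to one", {
  expect_equal(dirac_reg(0, 1.5), 2 / 3, tolerance = 1e-12)
  expect_identical(dirac_reg(c(-1.5, 1.5, -9, 9), 1.5), rep(0, 4))
  x <- seq(-3, 3, by = 0.01)
  y <- dirac_reg(x, 1.5)
  integral <- sum((y[-1] + y[-length(y)]) / 2) * 0.01
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_true(all(y >= 0))
})

test_that("heaviside_reg saturates and differentiates to dirac_reg", {
  eps <- 1.5
  expect_equal(heaviside_reg(0, eps), 0.5)
  expect_identical(heaviside_reg(c(-10 * eps, 10 * eps), eps), c(0, 1))
  x <- 0.3 * eps; h <- 1e-6
  fd <- (heaviside_reg(x + h, eps) - heaviside_reg(x - h, eps)) / (2 * h)
  expect_equal(fd, dirac_reg(x, eps), tolerance = 1e-6)
  expect_true(all(heaviside_reg(seq(-3, 3, 0.1), eps) >= 0 &
                    heaviside_reg(seq(-3, 3, 0.1), eps) <= 1))
})

test_that("penalty_energy closed forms", {
  r <- matrix(1:12, 12, 12)
  expect_lt(penalty_energy(r - 5), 1e-12)      # unit-slope plane
  expect_equal(penalty_energy(matrix(7, 10, 10)), 50)  # N/2 for constants
})

test_that("length and area energies approximate circle geometry", {
  phi <- signed_distance_disk(128, 128, c(64.5, 64.5), 20)
  g1 <- matrix(1, 128, 128)
  expect_lt(abs(length_energy(phi, g1, 1.5) - 2 * pi * 20) / (2 * pi * 20),
            0.05)
  expect_lt(abs(area_energy(phi, g1, 1.5) - pi * 400) / (pi * 400), 0.03)

  expect_equal(length_energy(phi, matrix(0, 128, 128), 1.5), 0)
  # shifting a bounded field out of the Dirac band kills the length term
  ramp <- matrix(1:12, 12, 12) - 5  # values in [-4, 7]
  expect_gt(length_energy(ramp, matrix(1, 12, 12), 1.5), 0)
  expect_equal(length_energy(ramp + 15, matrix(1, 12, 12), 1.5), 0)
  # all inside / all outside area
  expect_equal(area_energy(matrix(-15, 64, 64), matrix(1, 64, 64), 1.5), 4096)
  expect_equal(area_energy(matrix(15, 64, 64), matrix(1, 64, 64), 1.5), 0)
  expect_error(length_energy(phi, matrix(1, 3, 3), 1.5), "shapes differ")
})

test_that("total_energy is the stated linear combination", {
  phi <- signed_distance_disk(48, 48, c(24, 24), 10)
  g <- edge_indicator_gaussian(
    make_disk_image(48, 48, c(24, 24), 10)$image)
  ep <- penalty_energy(phi)
  lg <- length_energy(phi, g, 1.5)
  ag <- area_energy(phi, g, 1.5)
  p <- evolve_params(mu = 0.04, lambda = 5, nu = 1.5, eps = 1.5)
  expect_equal(total_energy(phi, g, p), 0.04 * ep + 5 * lg + 1.5 * ag,
               tolerance = 1e-12)
  p2 <- evolve_params(mu = 0.08, lambda = 10, nu = 3, eps = 1.5, tau = 3)
  expect_equal(total_energy(phi, g, p2), 2 * total_energy(phi, g, p),
               tolerance = 1e-12)
  expect_equal(total_energy(phi, g, raw_params(mu = 0, lambda = 0, nu = 0)), 0)
})

test_that("evolve_params enforces its invariants", {
  expect_error(evolve_params(mu = 0), "mu")
  expect_error(evolve_params(mu = 0.1, tau = 5), "stability")
  expect_error(evolve_params(eps = 0), "eps")
  expect_error(evolve_params(n_iter = -1), "n_iter")
})

test_that("an exact SDF is a near-fixed point of the penalty flow", {
  phi <- signed_distance_disk(128, 128, c(64.5, 64.5), 30)
  g1 <- matrix(1, 128, 128)
  par <- raw_params(mu = 0.04, lambda = 0, nu = 0, tau = 5)
  out <- evolve_step(phi, g1, par)$phi
  upd <- abs(out - phi$phi) / par$tau
  r <- matrix(1:128, 128, 128); c_ <- t(r)
  d <- sqrt((r - 64.5)^2 + (c_ - 64.5)^2)
  interior <- r > 2 & r < 127 & c_ > 2 & c_ < 127  # replicate-border effects
  expect_lt(max(upd[d > 3 & interior]), 1e-3)
})

test_that("a flat field without zero set is untouched by the flow", {
  flat <- matrix(2, 16, 16)
  par <- raw_params(lambda = 0, nu = 0)
  expect_lt(max(abs(evolve_step(flat, matrix(1, 16, 16), par)$phi - 2)),
            1e-12)
})

test_that("evolve_step matches an independently coded stencil oracle", {
  g <- 1 / (1 + gradient_magnitude(seeded_matrix(8, 16, 16))^2)
  for (seed in c(1, 2)) {
    phi <- seeded_matrix(seed, 16, 16, -8, 8)
    par <- evolve_params(mu = 0.04, lambda = 5, nu = 1.5, eps = 1.5, tau = 5)
    mine <- evolve_step(phi, g, par)$phi
    brute <- evolve_step_brute(phi, g, 0.04, 5, 1.5, 1.5, 5)
    expect_lt(max(abs(mine - brute)), 1e-10)
  }
})

test_that("evolve with zero iterations is the identity with empty trace", {
  phi0 <- init_binary_step(box_mask(24, 24, 6), 2)
  res <- evolve(phi0, matrix(1, 24, 24), evolve_params(n_iter = 0))
  expect_identical(res$phi$phi, phi0$phi)
  expect_identical(nrow(res$trace), 0L)
  expect_length(res$snapshots, 0)
})

test_that("evolution recovers the disk and keeps phi near an SDF (scaled run)", {
  # scaled-down noisy fixture so the default test run stays fast; the full
  # 128x128 / 250-iteration protocol lives in test-acceptance.R
  fx <- noisy_disk_fixture(noise_sigma = 10, seed = 0, height = 80,
                           width = 80, radius = 18)
  g <- edge_indicator_gaussian(fx$noisy)
  phi0 <- init_binary_step(box_mask(80, 80, 5), 2)
  res <- evolve(phi0, g, evolve_params(n_iter = 150),
                snapshots = c(50L, 100L))
  tr <- res$trace
  expect_identical(nrow(tr), 150L)
  expect_lt(tr$total[150], tr$total[1])            # net energy descent
  expect_lt(tr$sdf_deviation[150], 0.3)            # SDF property held
  expect_named(res$snapshots, c("iter_50", "iter_100"))
  cn <- extract_zero_contour(res$phi)
  expect_lt(mean_contour_distance(cn, fx$truth$boundary), 1.5)
  expect_lt(hausdorff(cn, fx$truth$boundary), 3)
})

test_that("flipping nu's sign flips the direction of contour motion", {
  phi0 <- init_binary_step(box_mask(48, 48, 16), 2)
  g1 <- matrix(1, 48, 48)
  a0 <- sum(phi0$phi < 0)
  shrink <- evolve(phi0, g1, evolve_params(nu = 1.5, n_iter = 20),
                   trace_energy = FALSE)
  grow <- evolve(phi0, g1, evolve_params(nu = -1.5, n_iter = 20),
                 trace_energy = FALSE)
  expect_lt(sum(shrink$phi$phi < 0), a0)
  expect_gt(sum(grow$phi$phi < 0), a0)
})

test_that("reinitialize restores the SDF property without moving the contour", {
  r <- matrix(1:64, 64, 64); c_ <- t(r)
  mask <- (r - 32.5)^2 + (c_ - 32.5)^2 <= 20^2
  phi0 <- init_binary_step(mask, 2)
  out <- reinitialize(phi0, n_steps = 50, dt = 0.5)
  m <- gradient_magnitude(out$phi)
  off <- abs(out$phi) > 2  # exclude the 2-px interface band
  expect_gte(mean(m[off] >= 0.9 & m[off] <= 1.1), 0.9)
  expect_lt(hausdorff(extract_zero_contour(out), extract_zero_contour(phi0)),
            0.5)
  expect_error(reinitialize(phi0, 5, dt = 0.6), "stability")
})

test_that("a planar SDF is an exact fixed point of reinitialization", {
  pl <- matrix(rep(1:40 - 10.5, 40), 40, 40)
  out <- reinitialize(level_set(pl), n_steps = 10, dt = 0.5)
  expect_lt(max(abs(out$phi - pl)), 1e-6)
  # a disk SDF drifts O(h * curvature) off-interface but the contour is pinned
  sdf <- signed_distance_disk(64, 64, c(32.5, 32.5), 20)
  out2 <- reinitialize(sdf, n_steps = 10, dt = 0.5)
  expect_lt(hausdorff(extract_zero_contour(out2), extract_zero_contour(sdf)),
            0.05)
})

test_that("extract_zero_contour traces circles, planes and empty fields", {
  phi <- signed_distance_disk(64, 64, c(32.5, 32.5), 20)
  cn <- extract_zero_contour(phi)
  expect_length(cn, 1)
  expect_true(cn[[1]]$closed)
  radii <- sqrt((cn[[1]]$points[, 1] - 32.5)^2 + (cn[[1]]$points[, 2] - 32.5)^2)
  expect_lt(max(abs(radii - 20)), 0.2)

  expect_length(extract_zero_contour(matrix(1, 16, 16)), 0)

  plane <- matrix(rep(1:20 - 10.5, each = 16), 16, 20, byrow = FALSE)
  # phi = col - 10.5
  plane <- matrix(1:20, 16, 20, byrow = TRUE) - 10.5
  cp <- extract_zero_contour(plane)
  expect_length(cp, 1)
  expect_false(cp[[1]]$closed)
  expect_lt(max(abs(cp[[1]]$points[, 2] - 10.5)), 1e-9)

  # determinism
  expect_identical(extract_zero_contour(phi), extract_zero_contour(phi))
})
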