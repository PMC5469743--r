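test_that("volumetric source has the right signs in each regime", {
  g <- tiny_grid()
  gp <- growth_params()
  les <- disk_lesion(g, 80)
  sigma1 <- matrix(1, g$ny, g$nx)

  # untreated fully proliferating tissue grows
  lesP <- classify_tissue(sigma1, les, tissue_thresholds(0.5, 0.1))
  S <- proliferation_source(sigma1, lesP, gp)
  inside <- tumor_mask(les)
  expect_true(all(S[inside] > 0))
  expect_equal(unique(round(S[inside], 12)),
               round((gp$lambda_mit - gp$lambda_apop) * 0.8, 12))

  # all-necrotic tissue only loses volume through lysis
  lesN <- lesion_state(g, nec = matrix(0.6, g$ny, g$nx) * disk_mask_test(
    g, (g$nx - 1) * g$h / 2, (g$ny - 1) * g$h / 2, 80))
  lesN <- classify_tissue(matrix(0, g$ny, g$nx), lesN,
                          tissue_thresholds(0.5, 0.1))
  SN <- proliferation_source(matrix(0, g$ny, g$nx), lesN, gp)
  expect_true(all(SN[tumor_mask(lesN)] < 0))

  # a large kill rate makes treated viable regions net-negative
  kill <- matrix(10, g$ny, g$nx)
  SK <- proliferation_source(sigma1, lesP, gp, kill)
  expect_true(all(SK[inside] < 0))
})

test_that("pressure solve matches trivial and point-source behavior", {
  g <- sim_grid(81, 81, 10)
  gp <- growth_params(mobility = 1)
  expect_equal(max(abs(solve_pressure(zero_field(g), gp, g))), 0)

  # point source: log-profile of the 2D Green function away from boundaries
  S <- zero_field(g); S[41, 41] <- 1
  P <- solve_pressure(S, gp, g)
  expect_true(P[41, 41] == max(P))
  r1 <- P[41, 51] - P[41, 61] # distances 100 and 200 um
  expected <- (1 * g$h^2) / (2 * pi * gp$mobility) * log(200 / 100)
  expect_equal(r1, expected, tolerance = 0.05 * abs(expected) + 2e-3)

  # positive source region gives positive interior pressure
  les <- disk_lesion(g, 150, phi = 1)
  S2 <- 0.01 * tumor_mask(les)
  expect_gt(min(solve_pressure(S2, gp, g)[35:45, 35:45]), 0)
})

test_that("velocity field is consistent with the pressure gradient", {
  g <- sim_grid(41, 41, 10)
  gp <- growth_params(mobility = 1)
  u0 <- velocity_from_pressure(matrix(3, g$ny, g$nx), gp, g)
  expect_equal(max(abs(u0$ux)), 0); expect_equal(max(abs(u0$uy)), 0)

  # radial pressure peak pushes tissue outward
  S <- zero_field(g); S[19:23, 19:23] <- 0.05
  P <- solve_pressure(S, gp, g)
  u <- velocity_from_pressure(P, gp, g)
  expect_gt(u$ux[21, 31], 0) # east of the peak moves east
  expect_lt(u$ux[21, 11], 0)
  expect_gt(u$uy[31, 21], 0)

  # div(u) recovers S on smooth fields (model closure, interior nodes)
  div <- matrix(0, g$ny, g$nx)
  div[, 2:(g$nx - 1)] <- (u$ux[, 3:g$nx] - u$ux[, 1:(g$nx - 2)]) / (2 * g$h)
  div[2:(g$ny - 1), ] <- div[2:(g$ny - 1), ] +
    (u$uy[3:g$ny, ] - u$uy[1:(g$ny - 2), ]) / (2 * g$h)
  expect_lt(abs(div[21, 21] - S[21, 21]), 0.3 * S[21, 21])
})

test_that("advection translates the lesion and conserves the mass budget", {
  g <- sim_grid(64, 64, 10)
  les <- disk_lesion(g, 100, phi = 1)
  zero <- zero_field(g)

  # no velocity, no sources: unchanged
  still <- advect_update(les, list(ux = zero, uy = zero), zero, zero, dt = 1)
  expect_equal(still$phi, les$phi)

  # uniform velocity translates the mask by v dt within a node spacing
  v <- 10 # um/h
  u <- list(ux = matrix(v, g$ny, g$nx), uy = zero)
  moved <- les
  for (i in 1:10) moved <- advect_update(moved, u, zero, zero, dt = 1)
  # centroid moved by ~v * t = 100 um = 10 nodes
  cx0 <- mean(which(tumor_mask(les), arr.ind = TRUE)[, 2])
  cx1 <- mean(which(tumor_mask(moved), arr.ind = TRUE)[, 2])
  expect_equal((cx1 - cx0) * g$h, 100, tolerance = g$h)

  # mass change equals the integrated sources
  set.seed(9)
  les2 <- disk_lesion(g, 100, phi = 0.5)
  # sources supported on the lesion so clipping at 0 plays no role
  S_v <- matrix(runif(g$ny * g$nx, -0.01, 0.02), g$ny, g$nx) * tumor_mask(les2)
  S_n <- matrix(runif(g$ny * g$nx, 0, 0.01), g$ny, g$nx) * tumor_mask(les2)
  out <- advect_update(les2, u, S_v, S_n, dt = 0.5)
  expect_equal(sum(out$phi) - sum(les2$phi), sum(S_v) * 0.5, tolerance = 1e-8)
  expect_equal(sum(out$nec) - sum(les2$nec), sum(S_n) * 0.5, tolerance = 1e-8)

  # CFL violation is a loud error naming the admissible step
  fast <- list(ux = matrix(1000, g$ny, g$nx), uy = zero)
  expect_error(advect_update(les, fast, zero, zero, dt = 1), "CFL")
})

test_that("hypoxic necrosis converts and lyses with the right closed forms", {
  g <- tiny_grid()
  gp <- growth_params(lambda_nec = 0.5, lambda_lys = 0.05)
  thr <- tissue_thresholds(0.5, 0.3)
  les <- disk_lesion(g, 80, phi = 0.8)

  # well-oxygenated: phi untouched
  ok <- necrosis_transfer(les, matrix(0.9, g$ny, g$nx), thr, gp, dt = 1)
  expect_equal(ok$phi, les$phi)

  # anoxic with lambda_nec * dt >= 1: conversion capped at phi
  all_in <- necrosis_transfer(les, zero_field(g), thr,
                              growth_params(lambda_nec = 2, lambda_lys = 0),
                              dt = 1)
  expect_equal(max(all_in$phi), 0)

  # pure necrotic decay follows exp(-lambda_lys t) within 1%
  nec0 <- matrix(0.6, g$ny, g$nx) *
    disk_mask_test(g, (g$nx - 1) * g$h / 2, (g$ny - 1) * g$h / 2, 80)
  lesN <- lesion_state(g, nec = nec0)
  cur <- lesN
  for (i in 1:20) cur <- necrosis_transfer(cur, matrix(1, g$ny, g$nx), thr,
                                           gp, dt = 0.25)
  expect_equal(max(cur$nec), 0.6 * exp(-0.05 * 5), tolerance = 0.01 * 0.6)
})

test_that("fractions stay within bounds under randomized updates", {
  g <- tiny_grid(20)
  set.seed(11)
  les <- disk_lesion(g, 60, phi = 0.7)
  gp <- growth_params()
  thr <- tissue_thresholds()
  for (i in 1:300) {
    sigma <- matrix(runif(g$ny * g$nx), g$ny, g$nx)
    S <- matrix(runif(g$ny * g$nx, -0.05, 0.05), g$ny, g$nx)
    P <- solve_pressure(S, gp, g)
    u <- velocity_from_pressure(P, gp, g)
    dt <- min(1, 0.5 * g$h / max(abs(u$ux), abs(u$uy), 1e-9))
    les <- advect_update(les, u, S * 0.1, abs(S) * 0.05, dt)
    les <- necrosis_transfer(les, sigma, thr, gp, dt)
    expect_true(all(is.finite(les$phi)) && all(is.finite(les$nec)))
    expect_true(all(les$phi >= 0 & les$phi <= 1))
    expect_true(all(les$nec >= 0 & les$nec <= 1))
    expect_true(all(les$phi + les$nec <= 1 + 1e-9))
  }
})
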