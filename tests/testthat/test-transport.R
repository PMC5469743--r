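test_that("diffusivity derivation preserves the penetration-length scaling", {
  o2 <- species_params("O2", 1, 5, 1.0, 0.05)
  expect_equal(derive_diffusivity(o2), transport_reference()$D_ref)

  # L = sqrt(D / lambda) implies D scales with P_rel^2 at fixed uptake
  gem <- species_params("Gem", 0.2, 5, 1.0, 0)
  expect_equal(derive_diffusivity(gem), 0.04 * transport_reference()$D_ref)
  rf <- species_params("GemRF", 0.35, 5, 1.0, 0)
  expect_equal(derive_diffusivity(rf), 0.1225 * transport_reference()$D_ref)

  # uptake scaling cancels in the penetration length
  fast <- species_params("Gem", 0.2, 5, 5, 0)
  expect_equal(sqrt(derive_diffusivity(fast) / fast$lambda_u),
               sqrt(derive_diffusivity(gem) / gem$lambda_u))
  expect_error(derive_diffusivity(species_params("x", 0.2, 5, 0)),
               "penetration length undefined")
})

test_that("ECM hindrance reduces diffusivity monotonically", {
  g <- tiny_grid()
  E <- matrix(runif(g$ny * g$nx), g$ny, g$nx)
  expect_equal(ecm_hindered_diffusivity(100, E, ecm_params(alpha = 0)),
               matrix(100, g$ny, g$nx) * 0 + 100)
  half <- ecm_hindered_diffusivity(100, matrix(1, g$ny, g$nx),
                                   ecm_params(alpha = 1))
  expect_equal(unique(as.numeric(half)), 50)
  d <- ecm_hindered_diffusivity(100, E, ecm_params(alpha = 1))
  expect_equal(which.min(d), which.max(E))
})

test_that("quasi-steady solve obeys trivial limits and the maximum principle", {
  g <- tiny_grid(32)
  les <- disk_lesion(g, 100)
  E <- zero_field(g)
  gem <- species_params("Gem", 0.2, 5, 5, 0.2, TRUE)

  # no source anywhere: identically zero
  c0 <- solve_quasi_steady(gem, zero_field(g), les, E, vessel_level = 0)
  expect_equal(max(abs(c0)), 0)

  # strong ubiquitous delivery, no uptake: equilibrates to the vessel level
  free <- species_params("x", 1, 500, 1, 1e-3)
  host <- lesion_state(g)
  c1 <- solve_quasi_steady(free, matrix(1, g$ny, g$nx), host, E,
                           vessel_level = 0.7)
  expect_true(all(abs(c1[4:(g$ny - 3), 4:(g$nx - 3)] - 0.7) < 0.01))

  # discrete maximum principle: solution within [0, vessel_level]
  v <- matrix(rbinom(g$ny * g$nx, 1, 0.1), g$ny, g$nx)
  c2 <- solve_quasi_steady(gem, v, les, E, vessel_level = 1)
  expect_true(all(c2 >= 0 & c2 <= 1 + 1e-9))
})

test_that("1D penetration profile matches exp(-x/L) and the RF scaling", {
  o2 <- species_params("O2", 1, 5, 1.0, 0)
  gem <- species_params("Gem", 0.2, 5, 5, 0, TRUE)
  L_o2 <- penetration_length_1d(o2)
  L_gem <- penetration_length_1d(gem)
  expect_equal(L_gem / L_o2, 0.2, tolerance = 0.05)

  rf <- apply_rf(gem, dose_event(0, rf = TRUE), NULL, 1)
  expect_equal(penetration_length_1d(rf) / L_gem, 1.75, tolerance = 0.05)

  # profile itself matches the analytic exponential within 2% (L-inf)
  grid <- sim_grid(241, 16, 2.5)
  lesion <- lesion_state(grid, phi = matrix(1, grid$ny, grid$nx))
  fixed <- matrix(FALSE, grid$ny, grid$nx)
  fixed[, 1] <- TRUE; fixed[, grid$nx] <- TRUE
  val <- matrix(0, grid$ny, grid$nx); val[, 1] <- 1
  D0 <- derive_diffusivity(gem)
  op <- pdacRF:::assemble_operator(grid, matrix(D0, grid$ny, grid$nx),
                                   gem$lambda_u * lesion$phi, fixed,
                                   as.numeric(val))
  cf <- pdacRF:::solve_operator(op, matrix(0, grid$ny, grid$nx))
  x <- (seq_len(grid$nx) - 1) * 2.5
  L <- sqrt(D0 / gem$lambda_u)
  keep <- x <= 5 * L
  expect_lt(max(abs(cf[8, keep] - exp(-x[keep] / L))), 0.02)
})

test_that("explicit drug step matches the ODE limit and the steady state", {
  g <- tiny_grid(20, h = 10)
  les <- lesion_state(g, phi = matrix(0.5, g$ny, g$nx))
  E <- zero_field(g)
  sp <- species_params("Gem", 0.2, 5, 5, 0.2, TRUE)
  v <- matrix(1, g$ny, g$nx)

  # zero everywhere stays zero without a plasma source
  c0 <- step_drug(zero_field(g), sp, v, les, E, plasma_level = 0, dt = 0.01)
  expect_equal(max(abs(c0)), 0)

  # spatially uniform state follows the scalar ODE exactly
  r <- sp$TR * 1 + sp$lambda_u * 0.5 + sp$lambda_d
  ceq <- sp$TR * 1 * 0.8 / r
  c1 <- matrix(0.3, g$ny, g$nx)
  c2 <- step_drug(c1, sp, v, les, E, plasma_level = 0.8, dt = 0.01)
  expect_equal(c2[10, 10], ceq + (0.3 - ceq) * exp(-r * 0.01),
               tolerance = 1e-8)

  # stability contract names the admissible bound
  expect_error(step_drug(c1, sp, v, les, E, 0.8, dt = 1), "stability bound")

  # long-time stepping converges to the quasi-steady solution
  set.seed(1)
  vr <- matrix(rbinom(g$ny * g$nx, 1, 0.2), g$ny, g$nx)
  cs <- solve_quasi_steady(sp, vr, les, E, vessel_level = 0.8)
  cc <- zero_field(g)
  dt <- g$h^2 / (4 * derive_diffusivity(sp)) * 0.9
  for (i in seq_len(3000)) cc <- step_drug(cc, sp, vr, les, E, 0.8, dt)
  expect_lt(max(abs(cc - cs)), 1e-6)
})

test_that("drug mass balance holds over an explicit step", {
  g <- tiny_grid(20, h = 10)
  les <- lesion_state(g, phi = matrix(0.5, g$ny, g$nx))
  E <- zero_field(g)
  sp <- species_params("Gem", 0.2, 5, 5, 0.2, TRUE)
  set.seed(2)
  v <- matrix(rbinom(g$ny * g$nx, 1, 0.3), g$ny, g$nx)
  cc <- matrix(runif(g$ny * g$nx, 0, 0.5), g$ny, g$nx)
  # keep the clamped far boundary flux-free for the one-step budget
  ring <- c(1, 2, g$ny - 1, g$ny)
  cc[ring, ] <- 0; cc[, ring] <- 0
  v[ring, ] <- 0; v[, ring] <- 0
  dt <- 1e-4
  c2 <- step_drug(cc, sp, v, les, E, plasma_level = 1, dt = dt)
  r <- sp$TR * v + sp$lambda_u * les$phi + sp$lambda_d
  src <- sp$TR * v * 1
  expected_change <- sum((src - r * cc)) * dt # interior fluxes cancel
  expect_equal(sum(c2) - sum(cc), expected_change, tolerance = 1e-3)
})

test_that("TAF field respects sources, sinks and the maximum principle", {
  g <- tiny_grid(40)
  les <- disk_lesion(g, 120)
  les$labels[] <- region_labels()["host"]
  v <- zero_field(g)

  # no hypoxic nodes: no TAF
  expect_equal(max(update_taf(NULL, les, v)), 0)

  # a hypoxic disk produces TAF decreasing with distance from the disk
  inside <- tumor_mask(les)
  les$labels[inside] <- region_labels()["hypoxic"]
  taf <- update_taf(NULL, les, v)
  ctr <- taf[12, 12]
  expect_true(ctr > taf[2, 12] && ctr > taf[12, 2])
  expect_true(all(taf >= 0 & taf <= 1))

  # a vessel sink near the source lowers TAF at the vessel
  v2 <- zero_field(g); v2[12, 18] <- 1
  taf2 <- update_taf(NULL, les, v2)
  expect_lt(taf2[12, 18], taf[12, 18])
})

test_that("MDE production degrades ECM with the exponential closed form", {
  g <- tiny_grid()
  les <- disk_lesion(g, 80)
  E <- matrix(1, g$ny, g$nx)
  p <- ecm_params(lambda_deg = 0.1)

  # no viable tumor: M is zero and E is untouched
  none <- lesion_state(g)
  out0 <- update_mde_ecm(NULL, E, none, p, dt = 1)
  expect_equal(max(out0$M), 0)
  expect_equal(out0$E, E)

  # closed form at a node where M is known
  E2 <- matrix(0.5, g$ny, g$nx)
  M <- matrix(1, g$ny, g$nx)
  decayed <- E2 * exp(-p$lambda_deg * M * 1)
  expect_true(all(abs(decayed - 0.5 * exp(-0.1)) < 1e-12))

  # ECM never increases under the update
  out1 <- update_mde_ecm(NULL, E, les, p, dt = 5)
  expect_true(all(out1$E <= E + 1e-12))
})
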