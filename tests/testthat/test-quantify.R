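test_that("regression percent and minimal size follow their definitions", {
  traj <- structure(data.frame(t_h = c(0, 24, 48, 72),
                               radius_um = c(200, 180, 160.6, 170)),
                    class = c("trajectory", "data.frame"))
  attr(traj, "dose_times") <- 0
  expect_equal(regression_percent(traj, 48), 19.7)
  flat <- traj; flat$radius_um <- rep(100, 4)
  expect_equal(regression_percent(flat, 72, 0), 0)
  halved <- traj; halved$radius_um <- c(200, 150, 100, 100)
  expect_equal(regression_percent(halved, 48, 0), 50)
  expect_error(regression_percent(traj, -5, 0), "precede")

  ms <- minimal_size(traj)
  expect_equal(ms$fraction, 160.6 / 200)
  expect_equal(ms$t_h, 48)
  up <- traj; up$radius_um <- c(100, 110, 120, 130)
  expect_equal(minimal_size(up)$fraction, 1)
  expect_equal(minimal_size(up)$t_h, 0)
  tie <- traj; tie$radius_um <- c(100, 80, 80, 90)
  expect_equal(minimal_size(tie)$t_h, 24) # earliest of the tied minima
})

test_that("fraction of control interpolates and guards division", {
  tr <- function(r) structure(data.frame(t_h = c(0, 100), radius_um = r),
                              class = c("trajectory", "data.frame"))
  expect_equal(fraction_of_control(tr(c(100, 100)), tr(c(100, 100)), 50), 1)
  expect_equal(fraction_of_control(tr(c(80, 80)), tr(c(100, 100)), 100), 0.8)
  expect_error(fraction_of_control(tr(c(80, 80)), tr(c(100, 0)), 100), "zero")
})

test_that("radial profiles are boundary-normalized and scale invariant", {
  img <- matrix(5, 101, 101)
  roi <- roi_spec(c(51, 51), 40)
  expect_equal(roi$core, 20) # core radius is half the outer radius by spec
  pr <- radial_profile(img, roi, n_bins = 10)
  expect_true(all(abs(pr$intensity - 1) < 1e-12))
  # scaling the image leaves the normalized profile unchanged
  g <- gen_spheroid_image(list(noise_sd = 0), seed = 1)
  p1 <- radial_profile(g$image, g$truth$roi, 30, 2)
  p3 <- radial_profile(3 * g$image, g$truth$roi, 30, 2)
  expect_equal(p1$intensity, p3$intensity)
  expect_error(radial_profile(img, roi_spec(c(2, 2), 40), 10), "beyond")
})

test_that("penetration depth reads the 1/e crossing of a profile", {
  d <- seq(2, 100, by = 4)
  prof <- data.frame(depth_um = d, intensity = exp(-d / 20))
  prof$intensity <- prof$intensity / prof$intensity[1]
  depth <- penetration_depth(prof)
  expect_equal(depth + d[1], 20, tolerance = 1) # depth measured from bin 1
  flat <- data.frame(depth_um = d, intensity = rep(1, length(d)))
  expect_equal(penetration_depth(flat), Inf)
  prof35 <- data.frame(depth_um = d, intensity = exp(-d / 35))
  prof35$intensity <- prof35$intensity / prof35$intensity[1]
  expect_equal(penetration_depth(prof35) / depth, 1.75, tolerance = 0.09)
})

test_that("core and whole-spheroid intensity increases are exact on planted masks", {
  n <- 101
  roi <- roi_spec(c(51, 51), 40)
  untreated <- matrix(1, n, n)
  expect_equal(core_periphery_increase(untreated, untreated, roi),
               c(whole = 0, core = 0))
  # treated is 4x untreated inside the core only
  xs <- matrix(rep(1:n, each = n), n, n); ys <- matrix(rep(1:n, n), n, n)
  core <- (xs - 51)^2 + (ys - 51)^2 <= 20^2
  whole <- (xs - 51)^2 + (ys - 51)^2 <= 40^2
  treated <- untreated; treated[core] <- 4
  out <- core_periphery_increase(treated, untreated, roi)
  expect_equal(unname(out["core"]), 300)
  expected_whole <- 100 * (mean(treated[whole]) / mean(untreated[whole]) - 1)
  expect_equal(unname(out["whole"]), expected_whole)
})

test_that("blob segmentation applies intensity, area and edge gates", {
  expect_equal(nrow(draq7_segment(matrix(0, 50, 50), 0)), 0)

  # a 50 px^2 blob above threshold is rejected by the lower area gate
  img <- matrix(100, 80, 80)
  xs <- matrix(rep(1:80, each = 80), 80, 80); ys <- matrix(rep(1:80, 80), 80, 80)
  img[(xs - 40)^2 + (ys - 40)^2 <= (sqrt(50 / pi))^2] <- 100 + 800
  expect_equal(nrow(draq7_segment(img, 100)), 0)

  # boundary semantics: intensity gate is >= offset; area gates are strict
  img2 <- matrix(0, 60, 60); img2[20:29, 20:29] <- 750 # exactly at offset
  seg2 <- draq7_segment(img2, 0, segmentation_params(area_min = 99,
                                                     area_max = 101))
  expect_equal(nrow(seg2), 1) # area 100 < 101 and > 99; intensity == offset
  seg3 <- draq7_segment(img2, 0, segmentation_params(area_min = 100,
                                                     area_max = 1000))
  expect_equal(nrow(seg3), 0) # area 100 is not > 100 (strict)

  # diagonal connectivity merges pixels into one blob (8-connected)
  img4 <- matrix(0, 20, 20)
  img4[cbind(c(5, 6, 7), c(5, 6, 7))] <- 1000
  seg4 <- draq7_segment(img4, 0, segmentation_params(750, 1, 10, FALSE))
  expect_equal(nrow(seg4), 1)
  expect_equal(seg4$area, 3)

  # planted-blob round trip with one blob forced to the frame edge
  b <- gen_blob_image(list(n_blobs = 10, force_edge = 1), seed = 2)
  seg <- draq7_segment(b$image, 1000)
  expect_equal(nrow(seg), b$truth$n_gate_pass)
})

test_that("retraction flags implement the 33% area-decrease rule", {
  expect_equal(classify_retracted(c(100, 100, 100), c(66, 70, 67)),
               c(TRUE, FALSE, TRUE)) # 34%, 30%, exactly 33% ("at least")
  expect_error(classify_retracted(c(1, 2), c(1)), "pair")
  expect_error(classify_retracted(c(1, -2), c(1, 1)), "positive")
})

test_that("positive-area fraction is exact on planted masks", {
  img <- matrix(0, 10, 10); img[1:5, ] <- 2
  expect_equal(area_fraction_positive(img, 1), 50)
  expect_equal(area_fraction_positive(img, 5), 0)
  set.seed(21)
  m <- matrix(0, 40, 40)
  m[sample(1600, 480)] <- 10
  expect_equal(area_fraction_positive(m, 5), 30)
})

test_that("vessel distances equal brute force exactly on random masks", {
  set.seed(31)
  for (i in 1:5) {
    vm <- matrix(rbinom(64 * 64, 1, 0.03), 64, 64)
    if (sum(vm) == 0) vm[10, 10] <- 1
    pm <- matrix(rbinom(64 * 64, 1, 0.08), 64, 64)
    d <- distances_to_vessels(pm, vm, pixel_size_um = 1.5)
    vs <- which(vm > 0, arr.ind = TRUE)
    idx <- which(pm > 0, arr.ind = TRUE)
    bf <- apply(idx, 1, function(p)
      sqrt(min((p[1] - vs[, 1])^2 + (p[2] - vs[, 2])^2))) * 1.5
    expect_equal(d, unname(bf))
  }
  # adjacency and on-vessel special cases
  vm <- matrix(0, 5, 5); vm[3, 3] <- 1
  pm <- matrix(0, 5, 5); pm[3, 4] <- 1; pm[3, 3] <- 1
  expect_equal(sort(distances_to_vessels(pm, vm, 2)), c(0, 2))
  expect_error(distances_to_vessels(pm, matrix(0, 5, 5)), "empty")
})

test_that("cytostaticity measures growth suppression relative to control", {
  expect_equal(cytostaticity_percent(100, 240, 240), 0)
  expect_equal(cytostaticity_percent(100, 100, 240), 100)
  expect_equal(cytostaticity_percent(100, 160, 240), 100 * (1 - 60 / 140))
  expect_error(cytostaticity_percent(100, 160, 90), "control")
})

test_that("image metrics are invariant to transposition", {
  b <- gen_blob_image(list(n_blobs = 6), seed = 8)
  s1 <- draq7_segment(b$image, 1000)
  s2 <- draq7_segment(t(b$image), 1000)
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(sort(s1$area), sort(s2$area))
  img <- gen_spheroid_image(list(noise_sd = 0), seed = 3)$image
  expect_equal(area_fraction_positive(img, 0.3),
               area_fraction_positive(t(img), 0.3))
})
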