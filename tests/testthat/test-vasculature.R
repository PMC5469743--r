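test_that("capillary lattice geometry and perfusion flags", {
  g <- sim_grid(101, 101, 10)
  net <- build_capillary_grid(g, 10)
  # 11 horizontal + 11 vertical lines of 100 unit segments, minus overlaps
  expect_equal(nrow(net$segments), 2 * 11 * 100)
  expect_true(all(net$segments$perfused))
  # indicator is symmetric under transpose (lines at equal x and y offsets)
  v <- vessel_indicator(net)
  expect_equal(v, t(v))
  expect_error(build_capillary_grid(g, 150), "larger than the domain")
})

test_that("intratumoral pruning is probabilistic, seeded, and binomial", {
  g <- sim_grid(64, 64, 10)
  net <- build_capillary_grid(g, 8)
  les <- disk_lesion(g, 200, phi = 1)
  mask <- tumor_mask(les)
  mx <- floor((net$segments$x1 + net$segments$x2) / 2 + 0.5)
  my <- floor((net$segments$y1 + net$segments$y2) / 2 + 0.5)
  n_inside <- sum(mask[cbind(my, mx)])

  expect_equal(nrow(prune_intratumoral(net, les, 0, 1)$segments),
               nrow(net$segments))
  none_left <- prune_intratumoral(net, les, 1, 1)
  mx2 <- floor((none_left$segments$x1 + none_left$segments$x2) / 2 + 0.5)
  my2 <- floor((none_left$segments$y1 + none_left$segments$y2) / 2 + 0.5)
  expect_equal(sum(mask[cbind(my2, mx2)]), 0)

  # removed count over seeds matches the binomial mean within 3 sd
  removed <- vapply(1:200, function(s)
    nrow(net$segments) - nrow(prune_intratumoral(net, les, 0.8, s)$segments),
    numeric(1))
  expect_lt(abs(mean(removed) - 0.8 * n_inside),
            3 * sqrt(n_inside * 0.8 * 0.2) / sqrt(200) * 5)
  # identical seed gives identical network
  expect_identical(prune_intratumoral(net, les, 0.8, 42)$segments,
                   prune_intratumoral(net, les, 0.8, 42)$segments)
})

test_that("sprout spawning requires TAF and respects the per-call cap", {
  g <- sim_grid(41, 41, 10)
  net <- build_capillary_grid(g, 10)
  p <- angiogenesis_params(p_sprout = 1, taf_threshold = 0.3, max_tips = 1000)
  withr::with_seed(1, {
    n0 <- spawn_sprouts(net, matrix(0, g$ny, g$nx), p)
    expect_equal(nrow(n0$tips), 0)
    n1 <- spawn_sprouts(net, matrix(1, g$ny, g$nx), p)
    expect_lte(nrow(n1$tips), nrow(net$segments))
    expect_gt(nrow(n1$tips), 0)
  })
  a <- withr::with_seed(7, spawn_sprouts(net, matrix(1, g$ny, g$nx),
                                         angiogenesis_params(p_sprout = 0.1)))
  b <- withr::with_seed(7, spawn_sprouts(net, matrix(1, g$ny, g$nx),
                                         angiogenesis_params(p_sprout = 0.1)))
  expect_identical(a$tips, b$tips)
})

test_that("tip steps are uniform without bias and follow strong gradients", {
  g <- sim_grid(21, 21, 10)
  net <- new_test_net(g, 11, 11)
  E <- zero_field(g)

  # beta = 0, flat TAF: chi-squared uniformity over 1e4 draws
  p0 <- angiogenesis_params(beta = 0, p_branch = 0, max_age_h = 1e6)
  draws <- withr::with_seed(3, {
    counts <- c(E = 0, N = 0, W = 0, S = 0)
    for (i in 1:10000) {
      st <- sprout_step(net, matrix(0.5, g$ny, g$nx), E, p0, dt_h = 0)
      d <- c(st$tips$x[1] - 11, st$tips$y[1] - 11)
      dir <- if (d[1] == 1) "E" else if (d[1] == -1) "W"
             else if (d[2] == 1) "N" else "S"
      counts[dir] <- counts[dir] + 1
    }
    counts
  })
  expect_gt(stats::chisq.test(draws)$p.value, 0.01)

  # beta * dT = 5 toward +x: nearly all steps east
  taf <- matrix(rep(seq(0, 1, length.out = g$nx) * 0.5 / 0.05, each = g$ny),
                g$ny, g$nx) # gradient 0.5 per node in scaled units
  taf <- matrix(rep(seq_len(g$nx), each = g$ny), g$ny, g$nx) * 0.05
  p1 <- angiogenesis_params(beta = 100, p_branch = 0, max_age_h = 1e6)
  east <- withr::with_seed(4, {
    n_e <- 0
    for (i in 1:2000) {
      st <- sprout_step(net, taf, E, p1, dt_h = 0)
      if (st$tips$x[1] - 11 == 1) n_e <- n_e + 1
    }
    n_e
  })
  expect_gt(east / 2000, 0.95)
})

test_that("anastomosis fuses a sprout and perfusion follows connectivity", {
  g <- sim_grid(31, 31, 10)
  net <- build_capillary_grid(g, 30) # border lines only
  # plant a tip far from its spawn history, next to a capillary line
  net$tips <- data.frame(id = 99L, x = 2L, y = 15L, age_h = 0)
  net$lineage[["99"]] <- 99L
  net$visited[["99"]] <- c(7L * g$ny + 15L, 6L * g$ny + 15L, 5L * g$ny + 15L,
                           4L * g$ny + 15L, 3L * g$ny + 15L, 2L * g$ny + 15L,
                           (2L - 1L) * g$ny + 15L)
  taf <- matrix(rep(seq(g$nx, 1), each = g$ny), g$ny, g$nx) * 0.01 # pull west
  p <- angiogenesis_params(beta = 500, p_branch = 0)
  st <- withr::with_seed(5, sprout_step(net, taf, zero_field(g), p, dt_h = 1))
  expect_equal(nrow(st$tips), 0) # tip fused onto the x = 1 line
  expect_true(any(st$segments$sprout_id == 99L & st$segments$fused))
  # segment count never decreased
  expect_gte(nrow(st$segments), nrow(net$segments))
})

test_that("vessel indicator counts exactly the perfused-covered nodes", {
  g <- sim_grid(25, 25, 10)
  net <- build_capillary_grid(g, 12)
  # brute-force enumeration of covered nodes
  s <- net$segments[net$segments$perfused, ]
  nodes <- unique(c(paste(s$x1, s$y1), paste(s$x2, s$y2)))
  expect_equal(sum(vessel_indicator(net)), length(nodes))
  # a single horizontal line covers exactly one row
  one <- net
  one$segments <- data.frame(x1 = 1:24, y1 = 5, x2 = 2:25, y2 = 5,
                             perfused = TRUE, sprout_id = 0L,
                             engulf_checked = FALSE, fused = TRUE)
  v <- vessel_indicator(one)
  expect_equal(sum(v[5, ]), 25)
  expect_equal(sum(v), 25)
  # empty network gives a zero field
  none <- one; none$segments <- one$segments[0, ]
  expect_equal(sum(vessel_indicator(none)), 0)
})

test_that("capillary fragments disconnected from the host lose perfusion", {
  g <- sim_grid(31, 31, 10)
  net <- build_capillary_grid(g, 10)
  les <- disk_lesion(g, 120, phi = 1)
  pruned <- prune_intratumoral(net, les, 0.9, rng_seed = 2)
  marked <- mark_perfusion_connectivity(pruned, les)
  s <- marked$segments
  mx <- floor((s$x1 + s$x2) / 2 + 0.5); my <- floor((s$y1 + s$y2) / 2 + 0.5)
  inside <- tumor_mask(les)[cbind(my, mx)]
  # interior fragments (if any remain) are mostly unperfused now
  expect_lt(sum(s$perfused & inside), sum(inside))
  # everything outside the lesion stays perfused
  expect_true(all(s$perfused[!inside]))
})
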