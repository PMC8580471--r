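test_that("noise stream is reproducible per seed and distinct across seeds", {
  a1 <- draw_noise(100, bd_rng(42))
  a2 <- draw_noise(100, bd_rng(42))
  b <- draw_noise(100, bd_rng(43))
  expect_identical(a1, a2)
  expect_false(identical(a1, b))
})

test_that("Box-Muller noise has standard-normal moments and is white", {
  x <- as.vector(draw_noise(4e5, bd_rng(7)))   # 1.2e6 samples
  n <- length(x)
  expect_lt(abs(mean(x)), 5 / sqrt(n))             # ~5 sigma CLT bound
  expect_lt(abs(var(x) - 1), 5 * sqrt(2 / n))
  ac1 <- mean(x[-1] * x[-n])
  expect_lt(abs(ac1), 5 / sqrt(n))                 # lag-1 whiteness
  # tail mass sane for a Gaussian
  expect_equal(mean(abs(x) > 1.959964), 0.05, tolerance = 0.01)
})

test_that("a rest configuration without noise is a fixed point", {
  p <- fibrin_params(n_fibres = 1, nodes_per_fibre = 22, box = 1e-6)
  net <- toy_configurations(p)$rest_fibre
  out <- bd_step(net, p, n_steps = 100, noise = FALSE)
  expect_equal(out$positions, net$positions, tolerance = 1e-12)
  expect_equal(out$time, 100 * p$dt)
})

test_that("deterministic trajectories are identical for identical seeds", {
  p <- fibrin_params(n_fibres = 2, nodes_per_fibre = 6, box = 0.5e-6)
  net <- make_random_network(2, 6, box = 0.5e-6, seed = 3, params = p)
  o1 <- bd_step(net, p, rng = bd_rng(11), n_steps = 500)
  o2 <- bd_step(net, p, rng = bd_rng(11), n_steps = 500)
  o3 <- bd_step(net, p, rng = bd_rng(12), n_steps = 500)
  expect_identical(o1$positions, o2$positions)
  expect_false(identical(o1$positions, o3$positions))
})

test_that("a stretched bond relaxes monotonically without overshoot", {
  p <- fibrin_params(nodes_per_fibre = 4, n_fibres = 1, box = 1e-6)
  box <- 1e-6
  # straight 4-node fibre with every bond stretched 10%
  pos <- cbind(box / 2, box / 2, box / 2 + (0:3) * 1.1 * p$r0_S)
  net <- fibre_network(pos, box, 4L)
  lens <- c()
  for (i in 1:60) {
    net <- bd_step(net, p, n_steps = 5, noise = FALSE)
    lens <- c(lens, sqrt(sum((net$positions[2, ] - net$positions[1, ])^2)))
  }
  expect_true(all(diff(lens) < 1e-18))            # monotone decay
  expect_true(all(lens >= p$r0_S - 1e-12))        # no overshoot
  expect_equal(lens[length(lens)], p$r0_S, tolerance = 1e-3)
})

test_that("zero-noise dynamics descend the energy landscape", {
  # a bent, stretched single fibre: pure bonded-term descent
  p <- fibrin_params(n_fibres = 1, nodes_per_fibre = 8, box = 1e-6)
  net <- make_random_network(1, 8, box = 1e-6, jitter = 6e-9, seed = 5,
                             params = p)
  w <- energy_breakdown(net, p)$W_total
  for (i in 1:20) {
    net <- bd_step(net, p, n_steps = 10, noise = FALSE)
    w2 <- energy_breakdown(net, p)$W_total
    expect_lte(w2, w * (1 + 1e-9))
    w <- w2
  }
  # two fully bonded parallel fibres: the bond set is saturated, so the
  # potential is fixed and the relaxation monotone
  p2 <- fibrin_params(n_fibres = 2, nodes_per_fibre = 6, box = 1e-6)
  rod <- function(offset) {
    cbind(5e-7 + offset, 5e-7, 5e-7 + (0:5) * p2$r0_S)
  }
  net2 <- fibre_network(rbind(rod(0), rod(30e-9)), 1e-6, 6L)
  net2 <- bd_step(net2, p2, n_steps = 1, noise = FALSE)  # bonds form here
  w <- energy_breakdown(net2, p2)$W_total
  for (i in 1:20) {
    net2 <- bd_step(net2, p2, n_steps = 10, noise = FALSE)
    w2 <- energy_breakdown(net2, p2)$W_total
    expect_lte(w2, w * (1 + 1e-9))
    w <- w2
  }
})

test_that("two close parallel fibres relax towards the aggregation rest
           spacing without noise", {
  p <- fibrin_params(nodes_per_fibre = 6, n_fibres = 2, box = 1e-6)
  box <- 1e-6
  rod <- function(offset) {
    cbind(box / 2 + offset, box / 2, box / 2 + (0:5) * p$r0_S)
  }
  net <- fibre_network(rbind(rod(0), rod(30e-9)), box, 6L)
  gaps <- c()
  for (i in 1:40) {
    net <- bd_step(net, p, n_steps = 100, noise = FALSE)
    gaps <- c(gaps, net$positions[7, 1] - net$positions[1, 1])
  }
  expect_true(all(diff(gaps) < 1e-15))   # monotone approach
  expect_equal(gaps[length(gaps)], 16e-9, tolerance = 0.02)
})

test_that("aggregation log samples increase in time with non-negative
           energies", {
  p <- fibrin_params(n_fibres = 2, nodes_per_fibre = 6, box = 0.4e-6,
                     dt = 5e-9)
  run <- run_aggregation(p, t_end = 2e-5, steady_time = 1e-5,
                         sample_every = 1e-6, seed = 2)
  expect_true(all(diff(run$log$time) > 0))
  expect_true(all(run$log$W_S >= 0 & run$log$W_B >= 0 & run$log$W_T >= 0 &
                    run$log$W_A >= 0 & run$log$W_R >= 0))
  expect_false(is.null(run$steady_network$l0))
  expect_false(is.null(run$steady_network$ref_pairs))
  expect_equal(run$network$time, 2e-5, tolerance = 1e-9)
})

test_that("plateau detector finds the flattening time of a synthetic trace", {
  tt <- seq(0, 0.1, by = 1e-4)
  w <- 1e-15 * pmin(tt / 0.03, 1)          # ramps until 30 ms, then flat
  log <- tibble::tibble(time = tt, W_total = w)
  pt <- plateau_time(log, window = 0.01, tol = 0.01)
  expect_gte(pt, 0.03)
  expect_lte(pt, 0.05)
  # a steadily growing trace has no plateau
  log2 <- tibble::tibble(time = tt, W_total = 1e-15 * (1 + tt * 50))
  expect_true(is.na(plateau_time(log2, window = 0.01, tol = 0.001)))
})
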