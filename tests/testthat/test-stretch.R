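# helper: a network with steady-state references set, no dynamics needed
make_steady <- function(net, params) {
  fibrinbd:::declare_steady_state(net, params)
}

test_that("stretch factor follows xi = 1 + c_s dtau / L_z", {
  p <- fibrin_params(n_fibres = 1, nodes_per_fibre = 22, box = 3e-6)
  net <- toy_configurations(p)$rest_fibre
  # hand value: L_z = 3 um, c_s = 2.5 mm/s, dtau = 2 us -> xi = 1.0016667
  out <- stretch_increment(net, p, c_s = 2.5e-3, dtau = 2e-6, relax = FALSE)
  expect_equal(out$box[3] / net$box[3], 1.0016667, tolerance = 1e-6)
  expect_equal(out$box[3] / net$box[3] - 1,
               2.5e-3 * 2e-6 / 3e-6, tolerance = 1e-9)
  # x, y untouched
  expect_equal(out$box[1:2], net$box[1:2])
  expect_equal(out$positions[, 1:2], net$positions[, 1:2])
  # c_s = 0: identity
  out0 <- stretch_increment(net, p, c_s = 0, dtau = 2e-6, relax = FALSE)
  expect_equal(out0$positions, net$positions)
  expect_error(stretch_increment(net, p, c_s = -1, dtau = 2e-6,
                                 relax = FALSE), "xi")
})

test_that("a z-spanning fibre stores quadratic stretch energy under
           affine extension", {
  box <- 21 * 22.5e-9          # box exactly matches the fibre rest length
  p <- fibrin_params(n_fibres = 1, nodes_per_fibre = 22, box = box)
  pos <- cbind(box / 2, box / 2, (0:21) * 22.5e-9)
  net <- make_steady(fibre_network(pos, box, 22L), p)
  eps <- c(0.05, 0.1, 0.2)
  w <- vapply(eps, function(e) {
    n2 <- net
    n2$positions[, 3] <- (1 + e) * n2$positions[, 3]
    n2$box[3] <- (1 + e) * n2$box[3]
    energy_breakdown(n2, p)$W_S
  }, numeric(1))
  # W_S = 21 * 1/2 k_S (eps r0)^2 -> quadratic in eps
  expect_equal(w, 21 * 0.5 * p$k_S * (eps * p$r0_S)^2, tolerance = 1e-9)
  # a fibre lying in the x-y plane is untouched by the z-scaling
  posxy <- cbind((0:21) * 22.5e-9 + 1e-8, box / 2, box / 2)
  netxy <- make_steady(fibre_network(posxy, box, 22L), p)
  n2 <- netxy
  n2$positions[, 3] <- 1.2 * n2$positions[, 3]
  n2$box[3] <- 1.2 * n2$box[3]
  expect_equal(energy_breakdown(n2, p)$W_total,
               energy_breakdown(netxy, p)$W_total, tolerance = 1e-12)
})

test_that("run_stretch records a non-decreasing strain grid with
           engineering strain eps = xi - 1 after one increment", {
  p <- fibrin_params(n_fibres = 2, nodes_per_fibre = 6, box = 0.4e-6,
                     dt = 5e-9)
  box <- 0.4e-6
  rod <- function(offset) {
    cbind(box / 2 + offset, box / 2, box / 2 + (0:5) * p$r0_S)
  }
  net <- make_steady(fibre_network(rbind(rod(0), rod(20e-9)), box, 6L), p)
  rec <- run_stretch(net, p, eps_max = 0.05, dtau = 2e-7, seed = 1)
  expect_s3_class(rec, "stretch_record")
  expect_true(all(diff(rec$eps) > 0))
  expect_equal(rec$eps[1], 0)
  expect_equal(rec$eps[2], 2.5e-3 * 2e-7 / 0.4e-6, tolerance = 1e-9)
  expect_true(all(rec$survival >= 0 & rec$survival <= 1))
  expect_lte(max(rec$eps), 0.05 + 0.01)
})

test_that("stress from a synthetic quadratic energy matches the analytic
           derivative within 1%", {
  # W = 1/2 K (L_z - L_z0)^2 laid onto a stretch_record skeleton
  L_z0 <- 3e-6
  A <- 9e-12
  K <- 1e-3
  eps <- seq(0, 0.5, by = 0.005)
  rec <- tibble::tibble(eps = eps, L_z = (1 + eps) * L_z0,
                        W_total = 0.5 * K * (eps * L_z0)^2)
  attr(rec, "A") <- A
  attr(rec, "L_z0") <- L_z0
  class(rec) <- c("stretch_record", class(rec))
  out <- stress_curve(rec, window = 0.008)   # narrow window: no flattening
  sigma_expect <- K * eps * L_z0 / A
  interior <- seq(3, length(eps) - 2)
  expect_equal(out$stress[interior], sigma_expect[interior],
               tolerance = 0.01)
  # constant energy -> zero stress
  rec2 <- rec
  rec2$W_total <- rep(1e-15, length(eps))
  expect_true(all(abs(stress_curve(rec2, window = 0.04)$stress) < 1e-20))
  expect_error(stress_curve(rec, window = 0.001), "window")
})

test_that("moving-average windows 0.04 and 0.08 give near-identical stress
           on smooth data", {
  L_z0 <- 3e-6
  eps <- seq(0, 0.6, by = 0.005)
  set.seed(1)
  rec <- tibble::tibble(eps = eps, L_z = (1 + eps) * L_z0,
                        W_total = 1e-15 * (eps^2 + 0.3 * eps) +
                          rnorm(length(eps), sd = 2e-21))
  attr(rec, "A") <- 9e-12
  attr(rec, "L_z0") <- L_z0
  class(rec) <- c("stretch_record", class(rec))
  s4 <- stress_curve(rec, window = 0.04)$stress
  s8 <- stress_curve(rec, window = 0.08)$stress
  mid <- eps > 0.1 & eps < 0.5
  expect_equal(s4[mid], s8[mid], tolerance = 0.05)
})

test_that("modulus fit recovers exact and noisy synthetic lines", {
  d <- tibble::tibble(eps = seq(0, 0.3, by = 0.01),
                      stress = 100 * seq(0, 0.3, by = 0.01) + 5)
  fit <- fit_modulus(d)
  expect_equal(fit$E, 100, tolerance = 1e-9)
  expect_equal(fit$sigma0, 5, tolerance = 1e-9)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "E"], 100, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$r.squared, 1, tolerance = 1e-9)
  # noisy line: slope recovered within ~4 sigma of the OLS standard error
  set.seed(42)
  n <- 11
  dd <- tibble::tibble(eps = seq(0.05, 0.15, length.out = n))
  dd$stress <- 40 * dd$eps + 2 + rnorm(n, sd = 0.2)
  f2 <- fit_modulus(dd)
  se <- tidy(f2)$std.error[tidy(f2)$term == "E"]
  expect_lt(abs(f2$E - 40), 4 * se)
  # degenerate fits are rejected
  expect_error(fit_modulus(tibble::tibble(eps = c(0.1, 0.1, 0.1),
                                          stress = 1:3),
                           range = c(0.05, 0.15)), "degenerate")
})
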