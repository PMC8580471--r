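p0 <- fibrin_params()

rod_along <- function(dir, npf = 8, box = 2e-6) {
  dir <- dir / sqrt(sum(dir^2))
  pos <- sweep(outer(0:(npf - 1), dir) * 22.5e-9, 2, rep(box / 2, 3), `+`)
  fibre_network(pos, box, as.integer(npf))
}

test_that("axis angles fold into [0, pi/2] with the right limits", {
  expect_equal(segment_orientation(rod_along(c(0, 0, 1)))$mean_theta, 0,
               tolerance = 1e-12)
  expect_equal(segment_orientation(rod_along(c(0, 0, -1)))$mean_theta, 0,
               tolerance = 1e-12)
  expect_equal(segment_orientation(rod_along(c(1, 0, 0)))$mean_theta, pi / 2,
               tolerance = 1e-12)
  expect_equal(segment_orientation(rod_along(c(1, 0, 1)))$mean_theta, pi / 4,
               tolerance = 1e-12)
  th <- segment_orientation(make_random_network(4, 8, seed = 1))
  expect_true(all(th$segments$theta >= 0 & th$segments$theta <= pi / 2))
  # length weights sum to the fibre contour length
  expect_equal(th$fibres$contour,
               tortuosity(make_random_network(4, 8, seed = 1))$contour)
})

test_that("orientation probability is band-area normalised", {
  prob <- orientation_probability(rod_along(c(0, 0, 1)))
  expect_equal(prob$count[1], 1)
  expect_equal(sum(prob$count[-1]), 0)
  # the first-band factor is 1 - cos(pi/12)
  expect_equal(prob$density[1], 1 / (1 - cos(pi / 12)))
  # densities integrate to 1 against the band fractions
  rand <- make_random_network(30, 6, box = 2e-6, seed = 4)
  pr <- orientation_probability(rand)
  expect_equal(sum(pr$density * (cos(pr$lower) - cos(pr$upper))), 1,
               tolerance = 1e-12)
  expect_true(all(pr$density >= 0))
})

test_that("isotropic rods give uniform band densities", {
  p <- fibrin_params(n_fibres = 4000, nodes_per_fibre = 4, box = 20e-6)
  net <- random_straight_fibres(p, seed = 9)
  pr <- orientation_probability(net)
  # CLT: density estimate per band has sd ~ sqrt(p(1-p)/N)/frac
  for (b in seq_len(nrow(pr))) {
    frac <- cos(pr$lower[b]) - cos(pr$upper[b])
    se <- sqrt(frac * (1 - frac) / 4000) / frac
    expect_lt(abs(pr$density[b] - 1), 5 * se)
  }
})

test_that("z-rotation leaves the orientation distribution unchanged", {
  net <- make_compact_network(5, 6, seed = 2)
  a <- segment_orientation(net)$fibres$mean_theta
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  net$positions <- net$positions %*% t(R)
  b <- segment_orientation(net)$fibres$mean_theta
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("tortuosity is 1 for rods, sqrt(2) for a right angle, and
           rigid-motion/scale invariant", {
  expect_equal(tortuosity(rod_along(c(1, 2, 3)))$tortuosity, 1,
               tolerance = 1e-12)
  box <- 2e-6
  bentpos <- rbind(c(0, 0, 0), c(0, 0, 22.5e-9), c(22.5e-9, 0, 22.5e-9))
  bent <- fibre_network(sweep(bentpos, 2, rep(box / 2, 3), `+`), box, 3L)
  expect_equal(tortuosity(bent)$tortuosity, sqrt(2), tolerance = 1e-12)
  net <- make_compact_network(4, 8, seed = 6)
  t0 <- tortuosity(net)$tortuosity
  net2 <- net
  net2$positions <- sweep(net$positions * 0.5, 2, c(1e-7, 2e-7, -1e-7), `+`)
  expect_equal(tortuosity(net2)$tortuosity, t0, tolerance = 1e-12)
  # coincident endpoints flagged undefined
  loop <- rbind(c(0, 0, 0), c(22.5e-9, 0, 0), c(22.5e-9, 22.5e-9, 0),
                c(0, 0, 0))
  netl <- fibre_network(sweep(loop, 2, rep(box / 2, 3), `+`), box, 4L)
  expect_true(is.na(tortuosity(netl)$tortuosity))
})

test_that("fibre strain and the stretched fraction track the references", {
  net <- rod_along(c(0, 0, 1))
  expect_error(stretched_fraction(net), "steady state")
  net$l0 <- contour <- tortuosity(net)$contour
  expect_equal(stretched_fraction(net), 0)
  # uniform 10% extension: every fibre counted
  net$positions[, 3] <- net$positions[, 3] * 1.1
  expect_equal(stretched_fraction(net), 1)
  expect_equal(fibre_strain(net)$strain, 0.1, tolerance = 1e-9)
})

test_that("bond survival counts reference pairs still within threshold", {
  p <- fibrin_params(nodes_per_fibre = 4, n_fibres = 2, box = 1e-6)
  box <- 1e-6
  rod <- function(offset) {
    cbind(box / 2 + offset, box / 2, box / 2 + (0:3) * p$r0_S)
  }
  net <- fibre_network(rbind(rod(0), rod(20e-9)), box, 4L)
  net <- fibrinbd:::declare_steady_state(net, p)
  expect_equal(bond_survival(net, p, method = "count"), 1)
  expect_equal(bond_survival(net, p, method = "pairs"), 1)
  # drag the second fibre far away: all aggregation is lost
  net2 <- net
  net2$positions[5:8, 1] <- net2$positions[5:8, 1] + 200e-9
  expect_equal(bond_survival(net2, p, method = "count"), 0)
  expect_equal(bond_survival(net2, p, method = "pairs"), 0)
  # empty reference set is flagged
  net3 <- net
  net3$ref_pairs <- net$ref_pairs[0, , drop = FALSE]
  expect_warning(expect_true(is.na(bond_survival(net3, p))), "undefined")
})
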