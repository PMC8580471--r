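p_default <- fibrin_params()

test_that("hand-evaluated energies of the toy fixtures are reproduced", {
  toy <- toy_configurations(p_default)
  expect_equal(energy_breakdown(toy$rest_fibre, p_default)$W_total, 0,
               tolerance = 1e-30)
  # bond stretched 10%: W_S = 1/2 * 0.01 * (2.25 nm)^2
  expect_equal(stretch_term(toy$prestrained_bond, p_default)$energy$W_S,
               2.53125e-20, tolerance = 1e-9)
  # right angle: W_B = 1/2 * 1e-18 * (pi/2)^2
  expect_equal(bending_term(toy$right_angle_triple, p_default)$energy$W_B,
               0.5 * 1e-18 * (pi / 2)^2, tolerance = 1e-9)
  # 90 degree dihedral: W_T = 1/2 * 1e-23 * (pi/2)^2
  expect_equal(torsion_term(toy$dihedral_quadruple, p_default)$energy$W_T,
               0.5 * 1e-23 * (pi / 2)^2, tolerance = 1e-9)
})

test_that("aggregation pair energy and force follow the harmonic form", {
  box <- 1e-6
  p <- fibrin_params(nodes_per_fibre = 4, n_fibres = 2, box = box)
  base <- c(box / 2, box / 2, box / 2)
  f1 <- sweep(outer(0:3, c(0, 0, 1)) * p$r0_S, 2, base, `+`)
  f2 <- sweep(outer(0:3, c(0, 0, 1)) * p$r0_S, 2, base + c(20e-9, 0, 0), `+`)
  net <- fibre_network(rbind(f1, f2), box, 4L)
  # nearest partner of every node on the other fibre is its opposing node
  # at 20 nm: 4 mutual pairs, each W = 1/2 * 2e-3 * (4 nm)^2 = 1.6e-20 J
  ap <- aggregation_pairs(net, p)
  expect_equal(nrow(ap), 4)
  expect_equal(ap$distance, rep(20e-9, 4), tolerance = 1e-12)
  expect_true(all(ap$node_i == ap$node_j))
  agg <- aggregation_term(net, p)
  expect_equal(agg$energy$W_A, 4 * 1.6e-20, tolerance = 1e-9)
  # attractive: force on node 1 of fibre 1 points towards fibre 2 (+x)
  expect_gt(agg$forces[1, 1], 0)
  # equal and opposite across the two fibres
  expect_equal(colSums(agg$forces[1:4, ]), -colSums(agg$forces[5:8, ]),
               tolerance = 1e-12)
  # pairs exactly at rest separation 2a = 16 nm: zero energy and force
  f2b <- sweep(outer(0:3, c(0, 0, 1)) * p$r0_S, 2, base + c(16e-9, 0, 0), `+`)
  net_rest <- fibre_network(rbind(f1, f2b), box, 4L)
  agg2 <- aggregation_term(net_rest, p)
  expect_equal(agg2$energy$W_A, 0, tolerance = 1e-30)
  expect_equal(max(abs(agg2$forces)), 0)
})

test_that("repulsion activates only below the fibrinogen diameter", {
  box <- 1e-6
  p <- fibrin_params(nodes_per_fibre = 4, n_fibres = 2, box = box)
  base <- c(box / 2, box / 2, box / 2)
  make_sep <- function(sep) {
    f1 <- sweep(outer(0:3, c(0, 0, 1)) * p$r0_S, 2, base, `+`)
    f2 <- sweep(outer(0:3, c(0, 0, 1)) * p$r0_S, 2, base + c(sep, 0, 0), `+`)
    fibre_network(rbind(f1, f2), box, 4L)
  }
  expect_equal(repulsive_term(make_sep(16e-9), p)$energy$W_R, 0)
  rep10 <- repulsive_term(make_sep(10e-9), p)
  expect_equal(rep10$energy$W_R, 4 * 0.5 * p$k_R * (6e-9)^2,
               tolerance = 1e-9)
  # pushes the overlapping fibres apart: force on fibre 1 along -x
  expect_lt(rep10$forces[1, 1], 0)
})

test_that("analytic forces match central finite differences on random bent
           configurations", {
  p <- fibrin_params(n_fibres = 3, nodes_per_fibre = 8, box = 0.4e-6)
  terms <- list(stretch = stretch_term, bend = bending_term,
                torsion = torsion_term, aggregation = aggregation_term,
                repulsion = repulsive_term, total = total_field)
  for (s in 1:12) {
    net <- make_random_network(3, 8, box = 0.4e-6, jitter = 6e-9, seed = s,
                               params = p)
    for (nm in names(terms)) {
      expect_lt(max_fd_error(net, p, terms[[nm]], n_coords = 4), 1e-6)
    }
  }
})

test_that("internal forces sum to zero (translation invariance)", {
  p <- fibrin_params(n_fibres = 4, nodes_per_fibre = 7, box = 0.4e-6)
  for (s in 1:10) {
    net <- make_random_network(4, 7, box = 0.4e-6, jitter = 10e-9, seed = s,
                               params = p)
    f <- total_field(net, p)
    scale <- max(abs(f$forces))
    expect_lt(max(abs(colSums(f$forces))), 1e-12 * max(scale, 1e-15))
  }
})

test_that("energies are invariant under rigid translation and rotation", {
  p <- fibrin_params(n_fibres = 3, nodes_per_fibre = 6, box = 2e-6)
  for (s in 1:5) {
    net <- make_compact_network(3, 6, seed = s)
    e0 <- energy_breakdown(net, p)
    # translation (staying inside the box)
    nt <- net
    nt$positions <- sweep(net$positions, 2, c(3e-7, -2e-7, 1e-7), `+`)
    et <- energy_breakdown(nt, p)
    expect_equal(unlist(et[1, 1:6]), unlist(e0[1, 1:6]), tolerance = 1e-10)
    # rotation about the cluster centroid
    set.seed(s + 100)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); ang <- runif(1, 0, pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    ctr <- colMeans(net$positions)
    nr <- net
    nr$positions <- sweep(sweep(net$positions, 2, ctr) %*% t(R), 2, ctr, `+`)
    er <- energy_breakdown(nr, p)
    expect_equal(unlist(er[1, 1:6]), unlist(e0[1, 1:6]), tolerance = 1e-9)
  }
})

test_that("torsion angle is signed and mirror-antisymmetric", {
  toy <- toy_configurations(p_default)
  phi <- torsion_angles(toy$dihedral_quadruple)$phi
  mirror <- toy$dihedral_quadruple
  mirror$positions[, 2] <- 2 * mean(mirror$positions[, 2]) -
    mirror$positions[, 2]
  phi_m <- torsion_angles(mirror)$phi
  expect_equal(abs(phi), pi / 2, tolerance = 1e-9)
  expect_equal(phi_m, -phi, tolerance = 1e-9)
  # planar trans configuration: phi = 0, zero torsion energy
  box <- 1e-6
  zig <- fibre_network(
    rbind(c(0, 0, 0), c(22e-9, 22e-9, 0), c(44e-9, 0, 0),
          c(66e-9, 22e-9, 0)) + box / 2,
    box, 4L)
  expect_equal(torsion_angles(zig)$phi, 0, tolerance = 1e-9)
  expect_equal(torsion_term(zig, p_default)$energy$W_T, 0, tolerance = 1e-30)
})

test_that("coincident bonded nodes are rejected", {
  box <- 1e-6
  net <- fibre_network(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 22.5e-9),
                             c(0, 0, 45e-9)) + box / 2, box, 4L)
  expect_error(stretch_term(net, p_default), "coincident")
})

test_that("straight-chain bending has zero force (collinear limit)", {
  toy <- toy_configurations(p_default)
  b <- bending_term(toy$rest_fibre, p_default)
  expect_equal(b$energy$W_B, 0, tolerance = 1e-30)
  expect_equal(max(abs(b$forces)), 0)
})
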