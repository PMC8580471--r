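# Random thermally-bent test networks: straight rods jittered with R's RNG
# (independent of the package generator under test).
make_random_network <- function(n_fibres = 3, npf = 8, box = 1e-6,
                                jitter = 3e-9, seed = 1,
                                params = fibrin_params(box = box,
                                                       n_fibres = n_fibres,
                                                       nodes_per_fibre = npf)) {
  set.seed(seed)
  net <- random_straight_fibres(params, seed = seed)
  net$positions <- net$positions +
    matrix(rnorm(length(net$positions), sd = jitter), ncol = 3)
  net
}

# compact cluster well away from the periodic boundary (no wrapped pairs),
# for rigid-motion invariance checks
make_compact_network <- function(n_fibres = 3, npf = 6, seed = 1,
                                 box = 2e-6) {
  set.seed(seed)
  p <- fibrin_params(box = box, n_fibres = n_fibres, nodes_per_fibre = npf)
  centre <- box / 2
  pos <- NULL
  for (f in seq_len(n_fibres)) {
    orig <- centre + rnorm(3, sd = 20e-9)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    rod <- outer(seq_len(npf) - 1, dir) * p$r0_S
    rod <- sweep(rod, 2, orig, `+`)
    pos <- rbind(pos, rod + matrix(rnorm(npf * 3, sd = 2e-9), ncol = 3))
  }
  fibre_network(pos, box, npf)
}

# central finite-difference force for one coordinate of one term; h is a
# compromise between O(h^2) truncation against the stiff stretch curvature
# and subtractive cancellation in the per-term energies
fd_force <- function(net, params, term_fn, i, k, h = 3e-13) {
  n1 <- net; n1$positions[i, k] <- n1$positions[i, k] + h
  n2 <- net; n2$positions[i, k] <- n2$positions[i, k] - h
  w1 <- sum(term_fn(n1, params)$energy[1, 1:5])
  w2 <- sum(term_fn(n2, params)$energy[1, 1:5])
  -(w1 - w2) / (2 * h)
}

# relative force error against the finite-difference oracle over a sample
# of coordinates; scale-aware (absolute floor avoids 0/0 on zero forces)
max_fd_error <- function(net, params, term_fn, n_coords = 8, floor = 1e-18) {
  f <- term_fn(net, params)$forces
  idx <- cbind(sample(nrow(net$positions), n_coords, replace = TRUE),
               sample(3, n_coords, replace = TRUE))
  errs <- vapply(seq_len(n_coords), function(q) {
    fd <- fd_force(net, params, term_fn, idx[q, 1], idx[q, 2])
    abs(f[idx[q, 1], idx[q, 2]] - fd) / max(abs(fd), floor)
  }, numeric(1))
  max(errs)
}
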