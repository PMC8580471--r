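#' Number of protofibrils at a given fibrinogen concentration
#'
#' The reference condition -- 1215 protofibrils of 22 nodes in a 3 um cube
#' at 0.5 mg/ml -- fixes the mass of one model protofibril
#' (1.111e-20 kg, about 20 fibrinogen molecules of 340 kDa, consistent with
#' a 21-segment fibre at two half-molecules per segment). The count for any
#' other box or concentration scales with box volume and concentration
#' around that calibration.
#'
#' @param concentration fibrinogen concentration (mg/ml), positive.
#' @param box box edge lengths (m), length 1 or 3.
#' @param fibre_mass mass of one protofibril (kg). The default is the
#'   calibration above.
#' @return integer fibre count (rounded, at least 1).
#' @examples
#' fibre_count_from_concentration(0.5, 3e-6)    # 1215
#' fibre_count_from_concentration(0.5, 1.5e-6)  # 152
#' @export
fibre_count_from_concentration <- function(concentration, box,
                                           fibre_mass = 1.1111111e-20) {
  if (length(box) == 1) box <- rep(box, 3)
  if (any(box <= 0)) stop("box volume must be positive")
  if (concentration <= 0) stop("concentration must be positive")
  if (fibre_mass <= 0) stop("fibre_mass must be positive")
  vol <- prod(box)                      # m^3
  mass <- concentration * vol           # mg/ml == kg/m^3, so mass in kg
  max(1L, as.integer(round(mass / fibre_mass)))
}

#' Random straight-rod initial condition
#'
#' Places `n_fibres` straight protofibrils (contour length
#' `(nodes_per_fibre - 1) * r0_S`, 472.5 nm for defaults) at uniformly
#' random positions and orientations (uniform on the sphere) in the periodic
#' box. Rods may overlap; the repulsive potential resolves overlaps
#' dynamically. Reproducible for a given seed.
#'
#' @param params a [fibrin_params()] object supplying the box, fibre count
#'   and geometry.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return A [fibre_network()] at `time = 0`.
#' @export
random_straight_fibres <- function(params, seed = params$seed) {
  rng <- bd_rng(seed)
  nf <- params$n_fibres
  npf <- params$nodes_per_fibre
  centre <- matrix(rng_uniform_cpp(rng, 3L * nf), ncol = 3)
  centre <- sweep(centre, 2, params$box, `*`)
  dir <- rng_normal_cpp(rng, nf, 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  offs <- (seq_len(npf) - (npf + 1) / 2) * params$r0_S
  pos <- matrix(0, nf * npf, 3)
  for (k in 1:3) {
    pos[, k] <- rep(centre[, k], each = npf) +
      rep(dir[, k], each = npf) * rep(offs, times = nf)
  }
  fibre_network(pos, params$box, npf, time = 0)
}

#' Deterministic toy configurations
#'
#' Small hand-checkable fixtures: a fibre at its rest geometry, a
#' three-node right-angle bend, a four-node dihedral, two parallel fibres at
#' the aggregation rest spacing, and a single pre-strained bond. Their
#' energies follow directly from the harmonic forms of the potentials.
#'
#' @param params a [fibrin_params()] object (geometry constants only).
#' @return Named list of [fibre_network()] objects:
#' \describe{
#'   \item{rest_fibre}{straight 22-node fibre at rest bond length: all
#'     energies zero.}
#'   \item{right_angle_triple}{three nodes with a 90 degree angle at the
#'     middle: `W_B = k_B/2 (pi/2)^2`.}
#'   \item{dihedral_quadruple}{four nodes with a 90 degree torsion angle:
#'     `W_T = k_T/2 (pi/2)^2` (plus the bending energy of its two joints).}
#'   \item{parallel_pair_16nm}{two parallel 22-node fibres at the 2a = 16 nm
#'     aggregation rest spacing: the aggregation set is exactly the 22
#'     opposing pairs and `W_A = 0`.}
#'   \item{prestrained_bond}{one bond stretched 10 percent beyond rest:
#'     `W_S = k_S/2 (0.1 r0_S)^2`.}
#' }
#' @export
toy_configurations <- function(params = fibrin_params()) {
  r0 <- params$r0_S
  box <- params$box
  mid <- box / 2
  npf <- params$nodes_per_fibre

  straight <- function(n, origin, dir) {
    sweep(outer(seq_len(n) - 1, dir) * r0, 2, origin, `+`)
  }

  rest_fibre <- fibre_network(
    straight(npf, mid - c(0, 0, (npf - 1) * r0 / 2), c(0, 0, 1)),
    box, npf)

  right_angle_triple <- fibre_network(
    rbind(mid + c(r0, 0, 0), mid, mid + c(0, r0, 0)),
    box, 3L)

  # nodes a,b,c straight along x, d lifted so the m/n plane normals are
  # orthogonal: a zig in y then a zag in z gives |phi| = pi/2
  dihedral_quadruple <- fibre_network(
    rbind(mid,
          mid + c(r0, r0, 0),
          mid + c(2 * r0, 0, 0),
          mid + c(3 * r0, 0, r0)),
    box, 4L)

  two <- rbind(
    straight(npf, mid - c(0, 0, (npf - 1) * r0 / 2), c(0, 0, 1)),
    straight(npf, mid - c(0, 0, (npf - 1) * r0 / 2) + c(params$r0_A, 0, 0),
             c(0, 0, 1)))
  parallel_pair_16nm <- fibre_network(two, box, npf)

  prestrained_bond <- fibre_network(
    rbind(mid, mid + c(0, 0, 1.1 * r0)),
    box, 2L)

  list(rest_fibre = rest_fibre,
       right_angle_triple = right_angle_triple,
       dihedral_quadruple = dihedral_quadruple,
       parallel_pair_16nm = parallel_pair_16nm,
       prestrained_bond = prestrained_bond)
}
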