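#' Model parameters for the protofibril simulation
#'
#' Builds the full parameter set in SI units: the geometry of the
#' coarse-grained fibre (fibrinogen radius `a`, segment rest length `r0_S`),
#' the five energy constants, solvent properties, the thermal scale and
#' the numerical settings. Derived quantities are filled in automatically:
#' the aggregation threshold `a_th = 2 r0_S` (one fibrinogen length), the
#' aggregation/repulsion rest lengths `r0_A = r0_R = 2 a` (one fibrinogen
#' diameter) and the Stokes friction coefficient `c = 6 pi mu a`.
#'
#' @param a fibrinogen radius (m). Default 8 nm.
#' @param r0_S segment (stretch) rest length (m). Default 22.5 nm, half the
#'   45 nm fibrinogen molecule.
#' @param k_S stretch constant (N/m). Default 0.01.
#' @param k_B bending constant (J/rad^2). Default 1e-18; the interesting
#'   physiological sweep is 0.1e-18 to 10e-18.
#' @param k_T torsion constant (J/rad^2). Default 1e-23.
#' @param k_A aggregation constant (N/m). Default 2e-3; sweep 0.2e-3 to 20e-3.
#' @param k_R repulsive constant (N/m). Default 1e-3.
#' @param mu solvent (plasma) viscosity (Pa s). Default 1.2e-3.
#' @param temperature absolute temperature (K). Default 300.
#' @param k_b Boltzmann constant (J/K).
#' @param theta0 reference bending angle (rad). Default pi (straight chain).
#' @param phi0 reference torsion angle (rad). Default 0.
#' @param dt integration time step (s). Default 2e-9. Validated against the
#'   stiffest relaxation times (see Details).
#' @param seed default RNG seed for runs that do not pass one explicitly.
#' @param nodes_per_fibre nodes per protofibril. Default 22 (torsion needs
#'   at least 4).
#' @param box initial box edge lengths (m), length-1 or length-3.
#'   Default 3 um cube.
#' @param aggregation_pairing how aggregation bonds between nodes of
#'   different protofibrils are assigned. `"persistent"` (default): each
#'   node carries at most one bond; free nodes bind greedily (closest
#'   candidate pair first) within `a_th`, and an existing bond breaks only
#'   when its length reaches `a_th` -- so bonds are identifiable objects
#'   that can dissociate under load. `"nearest"`: stateless variant
#'   re-selecting each node's nearest partner every step. `"all"`: every
#'   inter-fibre pair within `a_th` interacts (unbounded per-node
#'   attraction; collapses the network -- kept for ablation). See the
#'   methods vignette.
#' @param concentration fibrinogen concentration (mg/ml). Default 0.5.
#' @param n_fibres number of protofibrils. Default `NULL`: derived from the
#'   concentration and box volume via [fibre_count_from_concentration()]
#'   (1215 for the default 3 um box at 0.5 mg/ml).
#' @param verlet_skin neighbour-list skin (m) used by the integrator.
#'
#' @details The time step must satisfy two stability constraints: the
#' stretch term is advanced by classical RK4, stable for
#' `k_S dt / c < 2.785` (enforced with a safety factor of 2), while the
#' remaining terms use the Euler method, for which `dt <= 0.5 c / k_max`
#' over the Euler-integrated spring constants (aggregation, repulsion and
#' the effective bending stiffness `k_B / r0_S^2`) is required. Tight
#' thermal-equilibrium statistics (equipartition to a few percent) need a
#' step about five times smaller than these bounds.
#'
#' @return A list of class `fibrin_params`.
#' @examples
#' p <- fibrin_params()
#' p$c               # 6 pi mu a = 1.81e-10 kg/s
#' p$n_fibres        # 1215
#' @export
fibrin_params <- function(a = 8e-9,
                          r0_S = 22.5e-9,
                          k_S = 0.01,
                          k_B = 1e-18,
                          k_T = 1e-23,
                          k_A = 2e-3,
                          k_R = 1e-3,
                          mu = 1.2e-3,
                          temperature = 300,
                          k_b = 1.38e-23,
                          theta0 = pi,
                          phi0 = 0,
                          dt = 2e-9,
                          seed = 1L,
                          nodes_per_fibre = 22L,
                          box = 3e-6,
                          aggregation_pairing = c("persistent", "nearest",
                                                  "all"),
                          concentration = 0.5,
                          n_fibres = NULL,
                          verlet_skin = 1e-8) {
  aggregation_pairing <- match.arg(aggregation_pairing)
  if (length(box) == 1) box <- rep(box, 3)
  p <- list(
    a = a, r0_S = r0_S,
    a_th = 2 * r0_S, r0_A = 2 * a, r0_R = 2 * a,
    theta0 = theta0, phi0 = phi0,
    k_S = k_S, k_B = k_B, k_T = k_T, k_A = k_A, k_R = k_R,
    mu = mu, temperature = temperature, k_b = k_b,
    c = friction_coefficient(mu, a),
    dt = dt, seed = as.integer(seed),
    nodes_per_fibre = as.integer(nodes_per_fibre),
    box = box, concentration = concentration,
    aggregation_pairing = aggregation_pairing,
    verlet_skin = verlet_skin
  )
  p$n_fibres <- if (is.null(n_fibres)) {
    fibre_count_from_concentration(concentration, box)
  } else {
    as.integer(n_fibres)
  }
  class(p) <- "fibrin_params"
  validate_params(p)
  p
}

#' Stokes-law friction coefficient
#'
#' `c = 6 pi mu a` for a sphere of radius `a` in a solvent of viscosity
#' `mu`.
#'
#' @param mu solvent viscosity (Pa s), positive.
#' @param a bead radius (m), positive.
#' @return friction coefficient (kg/s).
#' @examples
#' friction_coefficient(1.2e-3, 8e-9)  # ~1.81e-10
#' @export
friction_coefficient <- function(mu, a) {
  stopifnot(is.numeric(mu), is.numeric(a), is.finite(mu), is.finite(a))
  if (any(mu <= 0)) stop("`mu` must be strictly positive")
  if (any(a <= 0)) stop("`a` must be strictly positive")
  6 * pi * mu * a
}

validate_params <- function(p) {
  pos_fields <- c("a", "r0_S", "a_th", "r0_A", "r0_R", "k_S", "k_B", "k_T",
                  "k_A", "k_R", "mu", "temperature", "k_b", "c", "dt",
                  "verlet_skin")
  for (f in pos_fields) {
    if (!is.numeric(p[[f]]) || any(!is.finite(p[[f]])) || any(p[[f]] <= 0)) {
      stop("parameter `", f, "` must be a strictly positive finite number")
    }
  }
  if (abs(p$a_th - 2 * p$r0_S) > 1e-12 * p$a_th)
    stop("invariant violated: a_th must equal 2 * r0_S")
  if (abs(p$c - 6 * pi * p$mu * p$a) > 1e-12 * p$c)
    stop("invariant violated: c must equal 6 * pi * mu * a")
  if (p$nodes_per_fibre < 4)
    stop("nodes_per_fibre must be >= 4 (torsion needs four nodes)")
  if (length(p$box) != 3 || any(p$box <= 0))
    stop("box must be three positive edge lengths")
  if (p$n_fibres < 1) stop("n_fibres must be >= 1")
  # time-step stability: RK4 bound for the stretch term, Euler bound for
  # the soft terms (with safety factors; see ?fibrin_params Details)
  if (p$dt > 1.4 * p$c / p$k_S)
    stop("dt = ", p$dt, " s exceeds the RK4 stability bound for the ",
         "stretch term (", signif(1.4 * p$c / p$k_S, 3), " s)")
  k_euler <- max(p$k_A, p$k_R, p$k_B / p$r0_S^2, p$k_T / p$r0_S^2)
  if (p$dt > 0.5 * p$c / k_euler)
    stop("dt = ", p$dt, " s exceeds the Euler stability bound for the ",
         "non-stretch terms (", signif(0.5 * p$c / k_euler, 3), " s)")
  invisible(p)
}

#' @export
print.fibrin_params <- function(x, ...) {
  cat("<fibrin_params>\n")
  cat(sprintf("  fibre: %d nodes, segment %.3g nm, %d fibres in %s nm box\n",
              x$nodes_per_fibre, x$r0_S * 1e9, x$n_fibres,
              paste(signif(x$box * 1e9, 4), collapse = " x ")))
  cat(sprintf("  k_S %.3g N/m  k_B %.3g J/rad2  k_T %.3g J/rad2  k_A %.3g N/m  k_R %.3g N/m\n",
              x$k_S, x$k_B, x$k_T, x$k_A, x$k_R))
  cat(sprintf("  T %.4g K  mu %.3g Pa s  c %.4g kg/s  dt %.3g s  seed %d\n",
              x$temperature, x$mu, x$c, x$dt, x$seed))
  invisible(x)
}

# internal: parameter list consumed by the C++ kernels
par_for_cpp <- function(p) {
  out <- p[c("k_S", "k_B", "k_T", "k_A", "k_R", "r0_S", "r0_A", "r0_R",
             "a_th", "theta0", "c", "dt", "k_b", "temperature",
             "verlet_skin")]
  out$pairing_mode <- match(p$aggregation_pairing %||% "persistent",
                            c("persistent", "nearest", "all")) - 1L
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a simulation configuration file
#'
#' Reads a YAML (or JSON) key-value configuration using the field naming and
#' units conventional for this model -- lengths in nm, viscosity in mPa s,
#' time step in ns -- and converts to the SI [fibrin_params()] object.
#' Recognised keys: `a`, `r0S` (nm), `kS`, `kA`, `kR` (N/m), `kB`, `kT`
#' (J/rad^2), `mu` (mPa s), `T` (K), `dt` (ns), `seed`, `n_fibres`,
#' `box_nm` (scalar or 3), `concentration_mg_ml`. Missing keys keep the
#' defaults.
#'
#' @param path path to a YAML/JSON file.
#' @return A `fibrin_params` object.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg),
                     c("a", "r0S", "kS", "kB", "kT", "kA", "kR", "mu", "T",
                       "dt", "seed", "n_fibres", "box_nm",
                       "concentration_mg_ml"))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  args <- list()
  if (!is.null(cfg$a)) args$a <- cfg$a * 1e-9
  if (!is.null(cfg$r0S)) args$r0_S <- cfg$r0S * 1e-9
  for (k in c("kS", "kB", "kT", "kA", "kR")) {
    if (!is.null(cfg[[k]])) args[[sub("k", "k_", k)]] <- cfg[[k]]
  }
  if (!is.null(cfg$mu)) args$mu <- cfg$mu * 1e-3
  if (!is.null(cfg$T)) args$temperature <- cfg$T
  if (!is.null(cfg$dt)) args$dt <- cfg$dt * 1e-9
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  if (!is.null(cfg$n_fibres)) args$n_fibres <- cfg$n_fibres
  if (!is.null(cfg$box_nm)) args$box <- cfg$box_nm * 1e-9
  if (!is.null(cfg$concentration_mg_ml))
    args$concentration <- cfg$concentration_mg_ml
  do.call(fibrin_params, args)
}
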