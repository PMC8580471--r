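#' Apply one stretch increment
#'
#' Uniaxial extension is an affine scaling of the z coordinates and the z
#' box length by `xi = 1 + c_s dtau / L_z` (stretching speed `c_s`,
#' relaxation period `dtau`), followed by `dtau` of Brownian relaxation.
#' The x and y coordinates and box edges are untouched, so the nominal
#' cross-section is constant.
#'
#' @param net a [fibre_network()].
#' @param params a [fibrin_params()].
#' @param c_s stretching speed (m/s). Default 2.5e-3 (2.5 mm/s).
#' @param dtau relaxation period (s). Default 2e-6.
#' @param rng a [bd_rng()] generator (required unless `relax = FALSE`).
#' @param relax logical; apply the Brownian relaxation after scaling.
#' @param noise passed to the relaxation steps.
#' @return The scaled (and relaxed) network.
#' @export
stretch_increment <- function(net, params, c_s = 2.5e-3, dtau = 2e-6,
                              rng = NULL, relax = TRUE, noise = TRUE) {
  xi <- 1 + c_s * dtau / net$box[3]
  if (xi < 1) stop("stretch factor xi must be >= 1 (c_s and dtau >= 0)")
  net$positions[, 3] <- xi * net$positions[, 3]
  net$box[3] <- xi * net$box[3]
  if (relax && dtau > 0) {
    if (is.null(rng)) rng <- bd_rng(params$seed)
    net <- bd_step(net, params, rng = rng,
                   n_steps = max(1L, round(dtau / params$dt)), noise = noise)
  }
  net
}

#' Virtual tensile test
#'
#' Alternates affine z-extension increments with Brownian relaxation until
#' the engineering strain `eps_z = L_z / L_z0 - 1` reaches `eps_max`,
#' recording the energy breakdown and the conformation observables
#' (stretched-fibre fraction, bond survival, orientation statistics) after
#' each relaxation. Start from the steady-state network of
#' [run_aggregation()] so the fibre-strain references `l0` and the
#' reference pair set are in place.
#'
#' @param net a steady-state [fibre_network()] (with `l0`, `ref_pairs`).
#' @param params a [fibrin_params()].
#' @param eps_max maximum engineering strain. Default 1.5.
#' @param c_s stretching speed (m/s). Default 2.5e-3.
#' @param dtau relaxation period (s). Default 2e-6.
#' @param seed RNG seed; defaults to `params$seed`.
#' @param rng optional [bd_rng()] generator (overrides `seed`).
#' @param noise logical.
#' @return A tibble of class `stretch_record`, one row per increment:
#'   `eps` (engineering strain), `L_z`, `time`, the five energies and
#'   `W_total` (J), `n_agg`, `survival` (aggregated-point ratio),
#'   `survival_pairs` (reference-pair fraction), `frac_stretched`
#'   (`epsilon >= 0.05`), `mean_theta` (rad), `frac_theta_le_45`
#'   (head-count fraction of fibres with `<theta_i> <= pi/4`),
#'   `aligned_45` (the same limit on the band-density scale, see
#'   [aligned_fraction()]; 0.5 for an isotropic network),
#'   `prob_first_band` (band-area-normalised probability of `<theta_i>`
#'   in `[0, pi/12]`) and the raw per-band fibre counts `band1..band6`
#'   (pi/12 bands), which allow pooling the orientation distribution over
#'   replicas before normalising.
#'   Attributes: `A` (cross-section, m^2), `L_z0`, `params`.
#' @export
run_stretch <- function(net, params, eps_max = 1.5, c_s = 2.5e-3,
                        dtau = 2e-6, seed = params$seed, rng = NULL,
                        noise = TRUE) {
  validate_params(params)
  if (is.null(net$l0) || is.null(net$ref_pairs))
    stop("stretch requires a steady-state network (l0 and ref_pairs set)")
  if (is.null(rng)) rng <- bd_rng(seed)
  L_z0 <- net$box[3]
  A <- net$box[1] * net$box[2]
  rows <- list(stretch_row(net, params, L_z0))
  while (net$box[3] / L_z0 - 1 < eps_max - 1e-12) {
    net <- stretch_increment(net, params, c_s = c_s, dtau = dtau,
                             rng = rng, noise = noise)
    rows[[length(rows) + 1]] <- stretch_row(net, params, L_z0)
  }
  rec <- dplyr::bind_rows(rows)
  attr(rec, "A") <- A
  attr(rec, "L_z0") <- L_z0
  attr(rec, "params") <- params
  attr(rec, "final_network") <- net
  class(rec) <- c("stretch_record", class(rec))
  rec
}

stretch_row <- function(net, params, L_z0) {
  e <- energy_breakdown(net, params)
  ori <- segment_orientation(net)
  pb <- orientation_probability(ori)
  bands <- stats::setNames(as.list(pb$count),
                           paste0("band", seq_len(nrow(pb))))
  tibble::tibble(
    eps = net$box[3] / L_z0 - 1,
    L_z = net$box[3],
    time = net$time,
    W_S = e$W_S, W_B = e$W_B, W_T = e$W_T, W_A = e$W_A, W_R = e$W_R,
    W_total = e$W_total, n_agg = e$n_agg,
    survival = bond_survival(net, params, method = "count"),
    survival_pairs = bond_survival(net, params, method = "pairs"),
    frac_stretched = stretched_fraction(net),
    mean_theta = ori$mean_theta,
    frac_theta_le_45 = mean(ori$fibres$mean_theta <= pi / 4),
    aligned_45 = sum(pb$density[pb$upper <= pi / 4 + 1e-12]) /
      sum(pb$density),
    prob_first_band = pb$density[1],
    !!!bands
  )
}

#' Engineering stress from the smoothed energy
#'
#' The total energy is moving-averaged over a strain window (default
#' `eps = 0.08`), then the engineering stress
#' `sigma_z = (1/A) dW/dL_z` is obtained by central differences on the
#' strain grid (one-sided at the ends). The nominal cross-section `A` is
#' the initial x-y box area, held fixed during extension.
#'
#' @param record a [run_stretch()] record (needs at least 3 strain rows).
#' @param window moving-average window in strain units. Default 0.08. Must
#'   be at least the grid spacing.
#' @return The record with columns `W_smooth` (J) and `stress` (Pa) added.
#' @export
stress_curve <- function(record, window = 0.08) {
  if (nrow(record) < 3) stop("need at least 3 strain samples")
  eps <- record$eps
  spacing <- stats::median(diff(eps))
  if (window < spacing)
    stop("smoothing window smaller than the strain grid spacing")
  A <- attr(record, "A")
  L_z0 <- attr(record, "L_z0")
  w <- record$W_total
  # small tolerance keeps window membership stable against floating-point
  # jitter of regular strain grids (else the point count alternates and
  # the differentiated stress picks up a sawtooth)
  tol <- 1e-6 * window
  W_smooth <- vapply(eps, function(e) {
    mean(w[eps >= e - window / 2 - tol & eps <= e + window / 2 + tol])
  }, numeric(1))
  n <- length(eps)
  dW <- numeric(n)
  dW[1] <- (W_smooth[2] - W_smooth[1]) / (eps[2] - eps[1])
  dW[n] <- (W_smooth[n] - W_smooth[n - 1]) / (eps[n] - eps[n - 1])
  if (n > 2) {
    dW[2:(n - 1)] <- (W_smooth[3:n] - W_smooth[1:(n - 2)]) /
      (eps[3:n] - eps[1:(n - 2)])
  }
  record$W_smooth <- W_smooth
  record$stress <- dW / L_z0 / A    # dW/dL_z = (dW/deps) / L_z0
  record
}

#' Elastic modulus by least squares
#'
#' Ordinary least squares of the engineering stress on the engineering
#' strain over a strain range (default 0.05 to 0.15, where the response is
#' close to linear): `sigma_z = E eps_z + sigma_0`, returning the elastic
#' coefficient `E` (slope) and residual stress `sigma_0` (intercept).
#'
#' @param record a [stress_curve()] output, or a data frame with `eps` and
#'   `stress` columns, or a [run_stretch()] record (stress is computed with
#'   the given `window`).
#' @param range strain range used for the fit.
#' @param window smoothing window used if stress must be computed.
#' @return An object of class `modulus_fit` with elements `E`, `sigma0`,
#'   `fit` (the `lm`), `n` and `range`. `tidy()` and `glance()` methods
#'   are provided.
#' @examples
#' d <- tibble::tibble(eps = seq(0, 0.3, 0.01), stress = 100 * eps + 5)
#' fit <- fit_modulus(d)
#' fit$E        # 100
#' fit$sigma0   # 5
#' @export
fit_modulus <- function(record, range = c(0.05, 0.15), window = 0.08) {
  if (!"stress" %in% names(record)) record <- stress_curve(record, window)
  d <- record[record$eps >= range[1] & record$eps <= range[2], ]
  if (nrow(d) < 3) stop("need at least 3 points in the fit range")
  if (diff(range(d$eps)) < 1e-12) stop("degenerate fit: constant strain")
  fit <- stats::lm(stress ~ eps, data = d)
  structure(list(E = unname(coef(fit)["eps"]),
                 sigma0 = unname(coef(fit)["(Intercept)"]),
                 fit = fit, n = nrow(d), range = range),
            class = "modulus_fit")
}

#' @export
print.modulus_fit <- function(x, ...) {
  cat(sprintf("<modulus_fit> E = %.4g Pa, sigma0 = %.4g Pa (n = %d, eps in [%g, %g])\n",
              x$E, x$sigma0, x$n, x$range[1], x$range[2]))
  invisible(x)
}

#' @rdname fit_modulus
#' @param x a `modulus_fit`.
#' @param ... unused.
#' @export
tidy.modulus_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("sigma0", "E"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname fit_modulus
#' @export
glance.modulus_fit <- function(x, ...) {
  tibble::tibble(E = x$E, sigma0 = x$sigma0,
                 r.squared = suppressWarnings(summary(x$fit))$r.squared,
                 n = x$n, eps_min = x$range[1], eps_max = x$range[2])
}
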