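#' Seedable noise generator
#'
#' Creates the thermal-noise generator used by the integrator: a xorwow
#' uniform stream transformed to standard normals by the Box-Muller method.
#' The stream is bit-reproducible for a given seed.
#'
#' @param seed integer seed.
#' @return An external pointer of class `bd_rng`.
#' @export
bd_rng <- function(seed) {
  rng_create_cpp(as.numeric(seed))
}

#' Draw per-node random force directions
#'
#' Returns `n` i.i.d. standard-normal 3-vectors from the generator; these
#' are the unit-variance kicks scaled by `sigma = sqrt(2 c k_b T)` in the
#' Langevin update.
#'
#' @param n number of nodes.
#' @param rng a [bd_rng()] generator (advanced in place).
#' @return An `n` x 3 numeric matrix.
#' @export
draw_noise <- function(n, rng) {
  rng_normal_cpp(rng, as.integer(n), 3L)
}

#' Advance the network by Brownian-dynamics steps
#'
#' One step of the overdamped equation `c dr/dt = -dW/dr + F_rand` is an
#' operator split: (1) an Euler displacement `dt/c * F` from the bend,
#' torsion, aggregation and repulsion forces, (2) a thermal displacement
#' `sqrt(2 k_b T dt / c)` per coordinate, (3) one classical fourth-order
#' Runge-Kutta step of `dr/dt = f_S(r)/c` for the stiff stretch term with
#' the other contributions frozen.
#'
#' @param net a [fibre_network()].
#' @param params a [fibrin_params()] (validated, including dt stability).
#' @param rng a [bd_rng()] generator; if `NULL`, seeded from `seed`.
#' @param n_steps number of steps.
#' @param noise logical; `FALSE` gives the deterministic (zero-temperature)
#'   descent.
#' @param seed seed used when `rng` is `NULL`.
#' @return The updated `fibre_network` (time advanced by `n_steps * dt`).
#' @export
bd_step <- function(net, params, rng = NULL, n_steps = 1, noise = TRUE,
                    seed = params$seed) {
  validate_params(params)
  if (is.null(rng)) rng <- bd_rng(seed)
  out <- bd_run_cpp(net$positions, net$nodes_per_fibre, net$box,
                    par_for_cpp(params), n_steps, 0L, rng, noise, net$time,
                    net$partner %||% integer(0))
  net$positions <- out$positions
  net$time <- out$time
  net$partner <- out$partner
  net
}

log_tibble <- function(mat) {
  colnames(mat) <- c("time", "W_S", "W_B", "W_T", "W_A", "W_R",
                     "W_total", "n_agg")
  tb <- tibble::as_tibble(as.data.frame(mat))
  class(tb) <- c("bd_log", class(tb))
  tb
}

#' Run the aggregation phase
#'
#' Integrates a network of initially straight, randomly placed protofibrils
#' under thermal noise until `t_end`, sampling the energy breakdown and
#' aggregation pair count at a fixed cadence. At `steady_time` the run
#' declares a steady state: the per-fibre reference contour lengths `l0`
#' (used for fibre strain) and the reference aggregation pair set (used for
#' bond survival) are frozen from the configuration at that time.
#'
#' @param params a [fibrin_params()].
#' @param init optional initial [fibre_network()]; default
#'   [random_straight_fibres()] drawn with `seed`.
#' @param t_end simulated end time (s). Default 0.2 (200 ms).
#' @param steady_time time at which the steady state is declared and the
#'   references frozen (s). Default 0.05. `NULL` disables freezing.
#' @param sample_every sampling cadence for the log (s). Default 1e-4.
#' @param seed RNG seed. Defaults to `params$seed`.
#' @param noise logical; `FALSE` runs the zero-temperature descent.
#' @return A list of class `aggregation_run`:
#'   \item{network}{state at `t_end`, with `l0`/`ref_pairs` frozen at
#'     `steady_time`;}
#'   \item{steady_network}{snapshot at `steady_time` (with references),
#'     the standard starting point for [run_stretch()];}
#'   \item{log}{tibble of sampled times, energies and pair counts.}
#' @export
run_aggregation <- function(params, init = NULL, t_end = 0.2,
                            steady_time = 0.05, sample_every = 1e-4,
                            seed = params$seed, noise = TRUE) {
  validate_params(params)
  rng <- bd_rng(seed)
  net <- if (is.null(init)) random_straight_fibres(params, seed = seed) else init
  k_sample <- max(1L, as.integer(round(sample_every / params$dt)))

  row0 <- dplyr::mutate(energy_breakdown(net, params), time = net$time)
  logs <- list(row0[c("time", "W_S", "W_B", "W_T", "W_A", "W_R",
                      "W_total", "n_agg")])
  steady_net <- NULL

  segments <- if (!is.null(steady_time) && steady_time > net$time &&
                  steady_time < t_end) {
    c(steady_time, t_end)
  } else {
    t_end
  }
  for (tk in segments) {
    n_steps <- round((tk - net$time) / params$dt)
    if (n_steps > 0) {
      out <- bd_run_cpp(net$positions, net$nodes_per_fibre, net$box,
                        par_for_cpp(params), n_steps, k_sample, rng, noise,
                        net$time, net$partner %||% integer(0))
      net$positions <- out$positions
      net$time <- out$time
      net$partner <- out$partner
      logs[[length(logs) + 1]] <- log_tibble(out$log)
    }
    if (!is.null(steady_time) && is.null(steady_net) &&
        net$time >= steady_time - 1e-12) {
      net <- declare_steady_state(net, params)
      steady_net <- net
    }
  }
  if (is.null(steady_net) && !is.null(steady_time)) {
    net <- declare_steady_state(net, params)
    steady_net <- net
  }
  log <- dplyr::bind_rows(logs)
  class(log) <- c("bd_log", class(log))
  structure(list(network = net, steady_network = steady_net, log = log,
                 params = params, seed = seed),
            class = "aggregation_run")
}

# freeze per-fibre reference contour lengths and the reference
# aggregation-bond set (also materialising the bond state for networks
# built without one)
declare_steady_state <- function(net, params) {
  net$l0 <- contour_lengths(net)
  pr <- aggregation_pairs(net, params)
  net$ref_pairs <- cbind(pr$i, pr$j)
  net$partner <- attr(pr, "partner")
  net
}

#' @export
print.aggregation_run <- function(x, ...) {
  cat(sprintf("<aggregation_run> %d fibres, t = %.4g ms, %d samples\n",
              x$network$n_fibres, x$network$time * 1e3, nrow(x$log)))
  invisible(x)
}

#' Detect the total-energy plateau of an aggregation run
#'
#' The plateau (steady state) is declared at the first sampled time `t`
#' for which the mean of `W_total` over `(t - window, t]` differs from the
#' mean over `(t - 2 window, t - window]` by less than `tol` in relative
#' terms.
#'
#' @param log a run log (tibble with `time` and `W_total`), or an
#'   `aggregation_run`.
#' @param window window length (s). Default 0.01 (10 ms).
#' @param tol relative-change threshold. Default 0.01.
#' @return The detection time (s), or `NA` if no plateau is found.
#' @export
plateau_time <- function(log, window = 0.01, tol = 0.01) {
  if (inherits(log, "aggregation_run")) log <- log$log
  tt <- log$time
  w <- log$W_total
  cands <- tt[tt >= 2 * window - 1e-12]
  for (t in cands) {
    recent <- w[tt > t - window - 1e-12 & tt <= t + 1e-12]
    before <- w[tt > t - 2 * window - 1e-12 & tt <= t - window + 1e-12]
    if (length(recent) < 2 || length(before) < 2) next
    m1 <- mean(recent); m0 <- mean(before)
    if (m0 > 0 && abs(m1 - m0) / m0 < tol) return(t)
  }
  NA_real_
}

#' Thermal-equilibrium statistics of a single fibre
#'
#' Runs one isolated protofibril at temperature `T` and compares the
#' stationary fluctuations of its quadratic modes with the closed forms:
#' bond length `<(|r| - r0_S)^2> = k_b T / k_S`, and bending angle
#' `<(theta - pi)^2> ~ 2 k_b T / k_B`. The factor 2 for the angle reflects
#' the two transverse bending modes behind one polar angle (the sin(theta)
#' Jacobian of the sphere); the exact expectation is evaluated by numerical
#' integration of the Boltzmann distribution.
#'
#' @param params a [fibrin_params()]; a step around 0.5 ns keeps the
#'   discretization bias of the fluctuation variances to a few percent.
#' @param t_total simulated duration (s). Default 50 us.
#' @param burn_in discarded initial transient (s). Default 5 us.
#' @param sample_every sampling cadence (s). Default 0.1 us.
#' @param seed RNG seed.
#' @return A tibble with one row per mode (`bond`, `angle`): observed and
#'   expected variance and the sample count. Flags `insufficient` when
#'   fewer than 100 snapshots contribute.
#' @export
equilibrium_statistics <- function(params, t_total = 5e-5, burn_in = 5e-6,
                                   sample_every = 1e-7,
                                   seed = params$seed) {
  p <- params
  p$n_fibres <- 1L
  validate_params(p)
  rng <- bd_rng(seed)
  npf <- p$nodes_per_fibre
  net <- fibre_network(
    cbind(0, 0, (seq_len(npf) - 1) * p$r0_S + p$box[3] / 2),
    p$box, npf)
  k_sample <- max(1L, round(sample_every / p$dt))
  n_burn <- round(burn_in / p$dt)
  out <- bd_run_cpp(net$positions, npf, net$box, par_for_cpp(p),
                    n_burn, 0L, rng, TRUE, 0, integer(0))
  pos <- out$positions
  n_chunks <- round((t_total - burn_in) / sample_every)
  bond_sq <- ang_sq <- numeric(0)
  for (i in seq_len(n_chunks)) {
    out <- bd_run_cpp(pos, npf, net$box, par_for_cpp(p), k_sample, 0L,
                      rng, TRUE, 0, integer(0))
    pos <- out$positions
    seg <- pos[-1, , drop = FALSE] - pos[-npf, , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    bond_sq <- c(bond_sq, (len - p$r0_S)^2)
    u <- seg[-(npf - 1), , drop = FALSE]
    v <- seg[-1, , drop = FALSE]
    ct <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    turn <- acos(pmax(-1, pmin(1, ct)))   # turn angle between consecutive bonds
    ang_sq <- c(ang_sq, turn^2)           # theta_ijk = pi - turn, so (theta-pi)^2 = turn^2
  }
  beta <- 1 / (p$k_b * p$temperature)
  # exact <(theta - pi)^2> under p(theta) ~ sin(theta) exp(-beta kB/2 (theta-pi)^2)
  num <- stats::integrate(function(th)
    (th - pi)^2 * sin(th) * exp(-beta * p$k_B * (th - pi)^2 / 2), 0, pi)$value
  den <- stats::integrate(function(th)
    sin(th) * exp(-beta * p$k_B * (th - pi)^2 / 2), 0, pi)$value
  tibble::tibble(
    mode = c("bond", "angle"),
    observed_variance = c(mean(bond_sq), mean(ang_sq)),
    expected_variance = c(p$k_b * p$temperature / p$k_S, num / den),
    n_samples = c(length(bond_sq), length(ang_sq)),
    insufficient = c(length(bond_sq), length(ang_sq)) < 100
  )
}
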