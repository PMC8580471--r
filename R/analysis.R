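#' Segment and fibre orientation statistics
#'
#' The orientation of segment `j` of fibre `i` is the axis angle between
#' the segment and the z (stretch) direction,
#' `theta_ij = arccos(|e_z . l_ij| / l_ij)`, folded into `[0, pi/2]` so the
#' two ends of a segment are equivalent. The per-fibre mean `<theta_i>` is
#' the segment-length-weighted mean over the 21 segments; the ensemble mean
#' `<theta>` is the unweighted mean over fibres.
#'
#' @param net a [fibre_network()] (unwrapped coordinates).
#' @return An object of class `orientation_stats`: list with
#'   \item{segments}{tibble `fibre`, `segment`, `theta` (rad), `length` (m);
#'     zero-length segments are excluded with a warning;}
#'   \item{fibres}{tibble `fibre`, `mean_theta`, `contour`;}
#'   \item{mean_theta}{the ensemble mean (rad).}
#' @export
segment_orientation <- function(net) {
  npf <- net$nodes_per_fibre
  p <- net$positions
  starts <- p[-seq(npf, nrow(p), by = npf), , drop = FALSE]
  ends <- p[-seq(1, nrow(p), by = npf), , drop = FALSE]
  seg <- ends - starts
  len <- sqrt(rowSums(seg^2))
  fib <- rep(seq_len(net$n_fibres), each = npf - 1)
  segi <- rep(seq_len(npf - 1), times = net$n_fibres)
  ok <- len > 0
  if (any(!ok)) warning(sum(!ok), " zero-length segment(s) excluded")
  theta <- acos(pmin(1, abs(seg[ok, 3]) / len[ok]))
  segments <- tibble::tibble(fibre = fib[ok], segment = segi[ok],
                             theta = theta, length = len[ok])
  fibres <- dplyr::summarise(
    dplyr::group_by(segments, .data$fibre),
    mean_theta = sum(.data$theta * .data$length) / sum(.data$length),
    contour = sum(.data$length), .groups = "drop")
  structure(list(segments = segments, fibres = fibres,
                 mean_theta = mean(fibres$mean_theta)),
            class = "orientation_stats")
}

#' @export
print.orientation_stats <- function(x, ...) {
  cat(sprintf("<orientation_stats> %d fibres, <theta> = %.1f deg\n",
              nrow(x$fibres), x$mean_theta * 180 / pi))
  invisible(x)
}

#' Orientation probability normalised by spherical band area
#'
#' Counts fibres whose mean orientation `<theta_i>` falls in each band
#' `[Theta, Theta + dTheta)` of `[0, pi/2]` and divides by the fibre count
#' and by the band's solid-angle fraction `cos(Theta) - cos(Theta + dTheta)`
#' (the fraction of the hemisphere the band occupies; for the first
#' `[0, pi/12]` band this is `1 - cos(pi/12)`). An isotropic network has
#' density 1 in every band, and the densities integrate to 1 against the
#' band fractions.
#'
#' @param stats an `orientation_stats` object (or a [fibre_network()]).
#' @param breaks band edges partitioning `[0, pi/2]`. Default `pi/12` bands.
#' @return A tibble with `lower`, `upper` (rad), `count`, `probability`
#'   (count/N) and `density` (probability / band fraction).
#' @export
orientation_probability <- function(stats, breaks = seq(0, pi / 2, pi / 12)) {
  if (inherits(stats, "fibre_network")) stats <- segment_orientation(stats)
  th <- stats$fibres$mean_theta
  if (!length(th)) stop("empty network: no fibre orientations")
  breaks <- sort(breaks)
  if (abs(breaks[1]) > 1e-12 || abs(breaks[length(breaks)] - pi / 2) > 1e-9)
    stop("breaks must partition [0, pi/2]")
  idx <- cut(th, breaks, include.lowest = TRUE, right = FALSE)
  cnt <- as.integer(table(idx))
  lower <- head(breaks, -1)
  upper <- breaks[-1]
  frac <- cos(lower) - cos(upper)
  tibble::tibble(lower = lower, upper = upper, count = cnt,
                 probability = cnt / length(th),
                 density = cnt / length(th) / frac)
}

#' Aligned fraction of the orientation distribution
#'
#' The share of the band-area-normalised orientation probability lying at
#' mean angles up to `limit` (default 45 degrees):
#' `sum(density[upper <= limit]) / sum(density)` over the
#' [orientation_probability()] bands. In this representation an isotropic
#' network scores exactly 0.5 for the 45-degree limit (half of the six
#' pi/12 bands), rising as fibres align with the z axis -- the natural
#' scale on which orientation distributions of stretched networks are
#' compared.
#'
#' @param stats an `orientation_stats` object or a [fibre_network()].
#' @param limit angle limit (rad). Default `pi/4`.
#' @param breaks band edges partitioning `[0, pi/2]`.
#' @return A fraction in `[0, 1]`.
#' @export
aligned_fraction <- function(stats, limit = pi / 4,
                             breaks = seq(0, pi / 2, pi / 12)) {
  pr <- orientation_probability(stats, breaks)
  if (sum(pr$density) == 0) return(NA_real_)
  sum(pr$density[pr$upper <= limit + 1e-12]) / sum(pr$density)
}

#' Tortuosity of each fibre
#'
#' Contour length over end-to-end Euclidean distance, both on unwrapped
#' coordinates; 1 for a straight rod and `>= 1` otherwise. Fibres with
#' coincident endpoints are flagged undefined (`NA`).
#'
#' @param net a [fibre_network()].
#' @return A tibble with `fibre`, `contour` (m), `end_to_end` (m) and
#'   `tortuosity`.
#' @export
tortuosity <- function(net) {
  npf <- net$nodes_per_fibre
  p <- net$positions
  contour <- contour_lengths(net)
  first <- p[seq(1, nrow(p), by = npf), , drop = FALSE]
  last <- p[seq(npf, nrow(p), by = npf), , drop = FALSE]
  e2e <- sqrt(rowSums((last - first)^2))
  tibble::tibble(fibre = seq_len(net$n_fibres), contour = contour,
                 end_to_end = e2e,
                 tortuosity = ifelse(e2e > 0, contour / e2e, NA_real_))
}

#' Fibre strain and the stretched-fibre fraction
#'
#' Fibre strain is `epsilon = l / l0 - 1`, with `l` the current contour
#' length and `l0` the reference frozen at the steady state.
#' `stretched_fraction()` is the fraction of fibres with
#' `epsilon >= threshold`.
#'
#' @param net a [fibre_network()] with `l0` set (see [run_aggregation()]).
#' @param l0 optional explicit reference lengths overriding `net$l0`.
#' @param threshold strain threshold. Default 0.05.
#' @return `fibre_strain()`: tibble with `fibre`, `length`, `l0`, `strain`;
#'   `stretched_fraction()`: a single fraction in `[0, 1]`.
#' @export
fibre_strain <- function(net, l0 = net$l0) {
  if (is.null(l0))
    stop("reference lengths l0 missing: declare a steady state first")
  len <- contour_lengths(net)
  tibble::tibble(fibre = seq_len(net$n_fibres), length = len, l0 = l0,
                 strain = len / l0 - 1)
}

#' @rdname fibre_strain
#' @export
stretched_fraction <- function(net, threshold = 0.05, l0 = net$l0) {
  mean(fibre_strain(net, l0)$strain >= threshold)
}

#' Aggregation survival ratio n_agg / n_agg0
#'
#' How much of the steady-state aggregation survives a deformation,
#' relative to the reference bond set frozen at the steady state. Two
#' countings are provided:
#' \describe{
#'   \item{`"count"` (default)}{the ratio of the current number of
#'     aggregation bonds to the number at the steady state -- the ratio of
#'     aggregated points. Bonds formed during the deformation count, so
#'     the ratio can marginally exceed 1.}
#'   \item{`"pairs"`}{the fraction of the *specific* reference pairs that
#'     are still bonded. Stricter: a broken-and-replaced bond registers as
#'     dissociation.}
#' }
#'
#' @param net a [fibre_network()] with `ref_pairs` set (see
#'   [run_aggregation()]).
#' @param params a [fibrin_params()].
#' @param method `"count"` or `"pairs"`.
#' @return A non-negative ratio (1 means full retention); `NA` with a
#'   warning if the reference set is empty.
#' @export
bond_survival <- function(net, params, method = c("count", "pairs")) {
  method <- match.arg(method)
  rp <- net$ref_pairs
  if (is.null(rp))
    stop("reference pair set missing: declare a steady state first")
  if (nrow(rp) == 0) {
    warning("empty reference pair set: survival undefined")
    return(NA_real_)
  }
  now <- aggregation_pairs(net, params)
  if (method == "count") {
    nrow(now) / nrow(rp)
  } else {
    mean(paste(rp[, 1], rp[, 2]) %in% paste(now$i, now$j))
  }
}
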