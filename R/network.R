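#' Construct a fibre network
#'
#' A `fibre_network` holds the unwrapped node coordinates of all
#' protofibrils in a periodic box, together with the box edge lengths, the
#' simulated time, and (once a steady state has been declared) the per-fibre
#' reference contour lengths `l0` and the reference aggregation pair set
#' used for fibre strain and bond-survival observables. Node `j` is bonded
#' to `j +/- 1` within the same fibre only; chains may straddle the periodic
#' boundary.
#'
#' @param positions numeric matrix (`n_fibres * nodes_per_fibre` rows, 3
#'   columns, metres), fibres stored contiguously, unwrapped.
#' @param box box edge lengths (m), length 1 or 3.
#' @param nodes_per_fibre nodes per fibre.
#' @param time simulated time (s).
#' @return An object of class `fibre_network`.
#' @export
fibre_network <- function(positions, box, nodes_per_fibre, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have three columns")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (length(box) == 1) box <- rep(box, 3)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive edge lengths")
  nodes_per_fibre <- as.integer(nodes_per_fibre)
  if (nodes_per_fibre < 2) stop("nodes_per_fibre must be >= 2")
  if (nrow(positions) %% nodes_per_fibre != 0)
    stop("row count must be a multiple of nodes_per_fibre")
  structure(
    list(positions = unname(positions), box = as.numeric(box),
         nodes_per_fibre = nodes_per_fibre,
         n_fibres = nrow(positions) %/% nodes_per_fibre,
         time = time, l0 = NULL, ref_pairs = NULL, partner = NULL),
    class = "fibre_network"
  )
}

#' @export
print.fibre_network <- function(x, ...) {
  cat(sprintf("<fibre_network> %d fibres x %d nodes, box %s nm, t = %.4g ms\n",
              x$n_fibres, x$nodes_per_fibre,
              paste(signif(x$box * 1e9, 4), collapse = " x "),
              x$time * 1e3))
  if (!is.null(x$l0))
    cat(sprintf("  steady-state references: l0 set, %d aggregation pairs\n",
                if (is.null(x$ref_pairs)) 0L else nrow(x$ref_pairs)))
  invisible(x)
}

#' @export
as_tibble.fibre_network <- function(x, ...) {
  tibble::tibble(
    fibre = rep(seq_len(x$n_fibres), each = x$nodes_per_fibre),
    node = rep(seq_len(x$nodes_per_fibre), times = x$n_fibres),
    x = x$positions[, 1], y = x$positions[, 2], z = x$positions[, 3]
  )
}

# fibre index of each node row
node_fibre <- function(net) {
  rep(seq_len(net$n_fibres), each = net$nodes_per_fibre)
}

#' Minimum-image displacement
#'
#' Maps each component of a displacement into `[-L/2, L/2)` so that
#' distances are measured to the nearest periodic copy.
#'
#' @param d displacement: numeric vector of length 3 or a matrix with 3
#'   columns.
#' @param box box edge lengths (m), length 1 or 3, strictly positive.
#' @return Same shape as `d`.
#' @examples
#' minimum_image(c(2.9e-6, 0, 0), 3e-6)   # -> (-0.1, 0, 0) um
#' @export
minimum_image <- function(d, box) {
  if (length(box) == 1) box <- rep(box, 3)
  if (any(!is.finite(box)) || any(box <= 0))
    stop("box lengths must be positive and finite")
  if (any(!is.finite(d))) stop("displacement must be finite")
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * floor(d[, k] / box[k] + 0.5)
    d
  } else {
    d - box * floor(d / box + 0.5)
  }
}

#' Wrapped view of node coordinates
#'
#' Coordinates are stored unwrapped for contour-length bookkeeping; this
#' returns a copy folded into `[0, L)` per axis, used for pair search and
#' imaging.
#'
#' @param net a [fibre_network()].
#' @return A numeric matrix of wrapped coordinates.
#' @export
wrap_positions <- function(net) {
  p <- net$positions
  for (k in 1:3) p[, k] <- p[, k] - net$box[k] * floor(p[, k] / net$box[k])
  p
}

# contour length of every fibre (sum of the segment lengths, unwrapped)
contour_lengths <- function(net) {
  p <- net$positions
  npf <- net$nodes_per_fibre
  seg <- p[-seq(npf, nrow(p), by = npf), , drop = FALSE] -
    p[-seq(1, nrow(p), by = npf), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  as.numeric(tapply(len, rep(seq_len(net$n_fibres), each = npf - 1), sum))
}
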