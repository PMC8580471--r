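term_bits <- c(stretch = 1L, bend = 2L, torsion = 4L,
               aggregation = 8L, repulsion = 16L)

field_call <- function(net, params, terms, forces = TRUE) {
  out <- field_cpp(net$positions, net$nodes_per_fibre, net$box,
                   par_for_cpp(params), terms, forces,
                   net$partner %||% integer(0))
  res <- list(
    energy = tibble::tibble(
      W_S = out$W_S, W_B = out$W_B, W_T = out$W_T,
      W_A = out$W_A, W_R = out$W_R, W_total = out$W_total),
    n_agg = out$n_agg
  )
  if (forces) res$forces <- out$forces
  res
}

#' Potential energies and forces of a configuration
#'
#' `total_field()` evaluates all five potential terms -- stretch, bend,
#' torsion, aggregation and repulsion -- returning the energy breakdown and
#' the per-node force vectors (newtons). The individual `*_term()` functions
#' evaluate a single term; forces are the exact analytic gradients of the
#' harmonic energies. `energy_breakdown()` returns the energies only.
#'
#' Bonded terms act between consecutive nodes of the same fibre on the
#' unwrapped coordinates. Aggregation acts on the current bond set -- by
#' default one persistent crosslink per node to a node of another fibre,
#' formed within the threshold `a_th = 45` nm and broken when stretched
#' back to it (minimum-image distances; see [aggregation_pairs()] and
#' [fibrin_params()]). Repulsion acts on every inter-fibre node pair
#' within the fibrinogen diameter `2a = 16` nm.
#'
#' @param net a [fibre_network()].
#' @param params a [fibrin_params()] object.
#' @return A list with `energy` (one-row tibble: `W_S`, `W_B`, `W_T`,
#'   `W_A`, `W_R`, `W_total` in joules), `forces` (matrix, N), and `n_agg`
#'   (number of aggregation pairs). `energy_breakdown()` returns just the
#'   tibble with `n_agg` as a column.
#' @examples
#' toy <- toy_configurations()
#' p <- fibrin_params()
#' energy_breakdown(toy$rest_fibre, p)$W_total  # 0
#' @export
total_field <- function(net, params) {
  field_call(net, params, 31L, forces = TRUE)
}

#' @rdname total_field
#' @export
energy_breakdown <- function(net, params) {
  out <- field_call(net, params, 31L, forces = FALSE)
  dplyr::mutate(out$energy, n_agg = out$n_agg)
}

#' @rdname total_field
#' @export
stretch_term <- function(net, params) field_call(net, params, 1L)

#' @rdname total_field
#' @export
bending_term <- function(net, params) field_call(net, params, 2L)

#' @rdname total_field
#' @export
torsion_term <- function(net, params) field_call(net, params, 4L)

#' @rdname total_field
#' @export
aggregation_term <- function(net, params) field_call(net, params, 8L)

#' @rdname total_field
#' @export
repulsive_term <- function(net, params) field_call(net, params, 16L)

#' Inter-fibre node pairs within a cutoff
#'
#' Finds all unordered pairs of nodes belonging to different fibres whose
#' minimum-image distance is strictly below `cutoff`. The default method is
#' a cell list; `method = "brute"` is the exhaustive O(N^2) reference and
#' returns the identical set.
#'
#' @param net a [fibre_network()].
#' @param cutoff pair cutoff (m); defaults to the aggregation threshold
#'   `a_th` of `params`. Must not exceed half the smallest box edge.
#' @param params optional [fibrin_params()] supplying the default cutoff.
#' @param method `"cell"` or `"brute"`.
#' @return A tibble with columns `fibre_i`, `node_i`, `fibre_j`, `node_j`,
#'   `i`, `j` (global node row indices) and `distance` (m), sorted by
#'   `(i, j)`.
#' @export
find_pairs <- function(net, cutoff = NULL, params = NULL,
                       method = c("cell", "brute")) {
  method <- match.arg(method)
  if (is.null(cutoff)) {
    if (is.null(params)) stop("supply `cutoff` or `params`")
    cutoff <- params$a_th
  }
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  if (cutoff > min(net$box) / 2)
    stop("cutoff exceeds half the smallest box edge: minimum image ambiguous")
  out <- pairs_cpp(net$positions, net$nodes_per_fibre, net$box, cutoff,
                   method == "brute")
  npf <- net$nodes_per_fibre
  tb <- tibble::tibble(
    i = out$i, j = out$j, distance = out$distance,
    fibre_i = (out$i - 1L) %/% npf + 1L,
    node_i = (out$i - 1L) %% npf + 1L,
    fibre_j = (out$j - 1L) %/% npf + 1L,
    node_j = (out$j - 1L) %% npf + 1L
  )
  dplyr::arrange(
    dplyr::select(tb, "fibre_i", "node_i", "fibre_j", "node_j",
                  "i", "j", "distance"),
    .data$i, .data$j)
}

#' Active aggregation bonds
#'
#' The aggregation bond set under the pairing rule of `params`. With the
#' default `"persistent"` rule each node carries at most one bond:
#' starting from the network's current bond state (`net$partner`; empty
#' for a freshly built network), bonds whose minimum-image length has
#' reached `a_th` are dissolved, then free nodes of different fibres are
#' bound greedily, closest candidate pair first. One crosslink per node
#' keeps the attraction bounded, so protofibrils zip laterally into
#' bundles; two parallel fibres at the rest spacing are zipped by exactly
#' one bond per node. `"nearest"` re-selects partners statelessly;
#' `"all"` returns every pair within the threshold (see
#' [fibrin_params()]).
#'
#' @param net a [fibre_network()].
#' @param params a [fibrin_params()].
#' @return A tibble like [find_pairs()]: `fibre_i`, `node_i`, `fibre_j`,
#'   `node_j`, `i`, `j`, `distance`; the updated partner vector is
#'   attached as attribute `"partner"`.
#' @export
aggregation_pairs <- function(net, params) {
  out <- agg_pairs_cpp(net$positions, net$nodes_per_fibre, net$box,
                       par_for_cpp(params), net$partner %||% integer(0))
  npf <- net$nodes_per_fibre
  tb <- tibble::tibble(
    i = out$i, j = out$j, distance = out$distance,
    fibre_i = (out$i - 1L) %/% npf + 1L,
    node_i = (out$i - 1L) %% npf + 1L,
    fibre_j = (out$j - 1L) %/% npf + 1L,
    node_j = (out$j - 1L) %% npf + 1L
  )
  tb <- dplyr::arrange(
    dplyr::select(tb, "fibre_i", "node_i", "fibre_j", "node_j",
                  "i", "j", "distance"),
    .data$i, .data$j)
  attr(tb, "partner") <- out$partner
  tb
}

#' Signed torsion (dihedral) angles of every consecutive node quadruple
#'
#' The dihedral at a quadruple (i, j, k, l) uses the plane normals
#' `m = r_ij x r_ik` and `n = r_ki x r_kl`; the sign is
#' `sgn(r_jk . (m x n))`, giving angles in (-pi, pi]. Mirror-image
#' configurations have opposite sign. Degenerate (collinear) quadruples
#' yield `NA`.
#'
#' @param net a [fibre_network()].
#' @return A tibble with columns `fibre`, `quad` (index of the first node
#'   in the quadruple within its fibre) and `phi` (rad).
#' @export
torsion_angles <- function(net) {
  npf <- net$nodes_per_fibre
  p <- net$positions
  rows <- lapply(seq_len(net$n_fibres), function(f) {
    base <- (f - 1L) * npf
    nq <- npf - 3L
    if (nq < 1L) return(NULL)
    phi <- vapply(seq_len(nq), function(b) {
      a <- p[base + b, ]; bb <- p[base + b + 1, ]
      cc <- p[base + b + 2, ]; d <- p[base + b + 3, ]
      m <- cross_vec(bb - a, cc - a)
      n <- cross_vec(a - cc, d - cc)
      M <- sqrt(sum(m^2)); N <- sqrt(sum(n^2))
      if (M < 1e-30 || N < 1e-30) return(NA_real_)
      u <- max(-1, min(1, sum(m * n) / (M * N)))
      s <- sign(sum((cc - bb) * cross_vec(m, n)))
      if (s == 0) s <- 1
      s * acos(u)
    }, numeric(1))
    tibble::tibble(fibre = f, quad = seq_len(nq), phi = phi)
  })
  dplyr::bind_rows(rows)
}

cross_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
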