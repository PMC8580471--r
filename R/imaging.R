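#' SEM-like projection of a network onto the x-y plane
#'
#' Rasterises the (wrapped) node positions onto a 2D luminosity grid at a
#' fixed pixel pitch (default 10 nm/pixel). Depth is encoded by binning the
#' z coordinate into slabs (default 0.3 um) mapped to `n_levels` luminosity
#' values, higher luminosity for higher z; overlapping nodes keep the
#' maximum. Optionally the bonded segments are drawn as lines for visual
#' fidelity (`draw = "segments"`, off by default).
#'
#' @param net a [fibre_network()].
#' @param pixel pixel pitch (m). Default 1e-8.
#' @param bin_height z-slab height (m). Default 3e-7.
#' @param n_levels number of luminosity levels. Default 10.
#' @param draw `"nodes"` (as observed projections are built) or
#'   `"segments"`.
#' @return A matrix of class `projection_image` (x by y, luminosity in
#'   `[0, 1]`), with attributes `pixel`, `bin_height`, `n_levels`, `box`.
#' @export
project_network <- function(net, pixel = 1e-8, bin_height = 3e-7,
                            n_levels = 10L, draw = c("nodes", "segments")) {
  draw <- match.arg(draw)
  wp <- wrap_positions(net)
  nx <- max(1L, as.integer(ceiling(net$box[1] / pixel - 1e-9)))
  ny <- max(1L, as.integer(ceiling(net$box[2] / pixel - 1e-9)))
  img <- matrix(0, nx, ny)
  rasterise <- function(xyz) {
    ix <- pmin(nx - 1L, pmax(0L, floor(xyz[, 1] / pixel))) + 1L
    iy <- pmin(ny - 1L, pmax(0L, floor(xyz[, 2] / pixel))) + 1L
    bin <- pmin(n_levels - 1L, pmax(0L, floor(xyz[, 3] / bin_height)))
    lum <- (bin + 1) / n_levels
    ord <- order(lum)                      # max wins: write brightest last
    idx <- cbind(ix[ord], iy[ord])
    img[idx] <<- pmax(img[idx], lum[ord])
  }
  if (nrow(wp)) rasterise(wp)
  if (draw == "segments" && nrow(wp)) {
    npf <- net$nodes_per_fibre
    starts <- wp[-seq(npf, nrow(wp), by = npf), , drop = FALSE]
    ends <- wp[-seq(1, nrow(wp), by = npf), , drop = FALSE]
    dvec <- minimum_image(ends - starts, net$box)
    nstep <- pmax(1L, ceiling(sqrt(rowSums(dvec^2)) / pixel))
    for (s in seq_len(nrow(starts))) {
      tfrac <- seq(0, 1, length.out = nstep[s] + 1)
      pts <- sweep(outer(tfrac, dvec[s, ]), 2, starts[s, ], `+`)
      for (k in 1:3) {
        pts[, k] <- pts[, k] - net$box[k] * floor(pts[, k] / net$box[k])
      }
      rasterise(pts)
    }
  }
  structure(img, class = "projection_image", pixel = pixel,
            bin_height = bin_height, n_levels = n_levels, box = net$box)
}

#' Sobel edge extraction and Gaussian smoothing of a projection
#'
#' Applies the 3x3 Sobel gradient-magnitude filter to bring out fibre
#' outlines, then a Gaussian blur (default sigma 2 px) to obtain smoothed
#' fibre structures, mimicking the processing applied to micrograph-style
#' renderings.
#'
#' @param image a [project_network()] image.
#' @param sobel apply the Sobel step.
#' @param sigma Gaussian standard deviation in pixels; 0 skips the blur.
#' @return A `projection_image` matrix.
#' @export
stylize <- function(image, sobel = TRUE, sigma = 2) {
  if (!length(image)) stop("empty image")
  at <- attributes(image)
  m <- unclass(image)
  attributes(m) <- list(dim = dim(image))
  if (sobel) {
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    gx <- EBImage::filter2(m, kx)
    gy <- EBImage::filter2(m, t(kx))
    m <- sqrt(gx^2 + gy^2)
  }
  if (sigma > 0) {
    m <- EBImage::gblur(m, sigma = sigma)
  }
  m <- as.matrix(m)
  structure(m, class = "projection_image", pixel = at$pixel,
            bin_height = at$bin_height, n_levels = at$n_levels,
            box = at$box)
}

#' Write a projection image to PNG
#'
#' @param image a `projection_image`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  rng <- range(m)
  if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
  # transpose so x runs along image width
  png::writePNG(t(m)[rev(seq_len(ncol(m))), , drop = FALSE], path)
  invisible(path)
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px at %.3g nm/px\n",
              nrow(x), ncol(x), attr(x, "pixel") * 1e9))
  invisible(x)
}
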