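#' Write and read network coordinates as XYZ
#'
#' Plain-text XYZ trajectory frame: first line the node count, second line
#' a metadata comment (`box_nm`, `time_s`, `nodes_per_fibre`), then one row
#' per node with the fibre id as the atom label and coordinates in nm.
#' `read_xyz()` reconstructs the [fibre_network()] (including steady-state
#' references is the caller's job).
#'
#' @param net a [fibre_network()].
#' @param path file path.
#' @return `write_xyz()`: `path` invisibly; `read_xyz()`: a
#'   `fibre_network`.
#' @export
write_xyz <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(net$positions)), con)
  writeLines(sprintf("box_nm=%.9g,%.9g,%.9g time_s=%.9g nodes_per_fibre=%d",
                     net$box[1] * 1e9, net$box[2] * 1e9, net$box[3] * 1e9,
                     net$time, net$nodes_per_fibre), con)
  fib <- node_fibre(net)
  writeLines(sprintf("F%d %.9f %.9f %.9f", fib,
                     net$positions[, 1] * 1e9, net$positions[, 2] * 1e9,
                     net$positions[, 3] * 1e9), con)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  meta <- lines[2]
  get <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[^ ]+"), meta))
    sub(paste0(key, "="), "", m)
  }
  box <- as.numeric(strsplit(get("box_nm"), ",")[[1]]) * 1e-9
  time <- as.numeric(get("time_s"))
  npf <- as.integer(get("nodes_per_fibre"))
  body <- do.call(rbind, strsplit(lines[3:(2 + n)], " +"))
  pos <- apply(body[, 2:4, drop = FALSE], 2, as.numeric) * 1e-9
  fibre_network(pos, box, npf, time = time)
}

#' Run manifest
#'
#' Serialises the provenance of a run -- parameter snapshot, seed(s), code
#' version, output paths and wall time -- as JSON next to the outputs, so
#' every output file is traceable to a configuration and seed.
#'
#' @param params a [fibrin_params()].
#' @param seeds integer vector of seeds used.
#' @param outputs named character vector/list of output paths.
#' @param path manifest file path.
#' @param elapsed elapsed wall time (s).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, seeds, outputs, path, elapsed = NA) {
  manifest <- list(
    package = "fibrinbd",
    version = as.character(utils::packageVersion("fibrinbd")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = elapsed,
    seeds = as.integer(seeds),
    params = params[setdiff(names(params), "c")],
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
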