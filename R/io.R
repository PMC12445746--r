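# Serialisation: environments to JSON, views to PGM, routes and trial
# tables to CSV, networks to a flat binary weight file with a JSON header.

#' Write / read an environment as JSON
#'
#' @param env an `ant_environment`.
#' @param path file path.
#' @return `write_environment_json` returns `path` invisibly;
#'   `read_environment_json` returns the `ant_environment`.
#' @export
write_environment_json <- function(env, path) {
  jsonlite::write_json(
    list(seed = env$seed, extent = env$extent, density = env$density,
         center = env$center, landmarks = env$landmarks),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_environment_json
#' @export
read_environment_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(seed = as.integer(x$seed), extent = x$extent, density = x$density,
         center = x$center, landmarks = tibble::as_tibble(x$landmarks)),
    class = "ant_environment"
  )
}

#' Export a view as a plain (ASCII) PGM image
#'
#' @param view a `pano_view`.
#' @param path file path (conventionally `.pgm`).
#' @param maxval maximum grey value.
#' @return `path`, invisibly.
#' @export
write_view_pgm <- function(view, path, maxval = 255) {
  m <- round(unclass(view) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  write(t(m), con, ncolumns = ncol(m))
  invisible(path)
}

#' Write a route's poses to CSV
#'
#' @param route an `ant_route` or `ant_recap`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_route_csv <- function(route, path) {
  if (inherits(route, "ant_recap")) route <- route$route
  write.csv(route$poses, path, row.names = FALSE)
  invisible(path)
}

#' Save / load an Infomax network
#'
#' Weights go to `<path>.bin` as little-endian doubles (row-major) and the
#' metadata (sizes, learning rate, calibration) to `<path>.json`.
#'
#' @param net an `infomax_network`.
#' @param path base file path (no extension).
#' @return `write_infomax` returns `path` invisibly; `read_infomax` the
#'   network.
#' @export
write_infomax <- function(net, path) {
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(t(net$W)), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(n_input = net$n_input, n_output = net$n_output, eta = net$eta,
         weight_norm = net$weight_norm, trained_views = net$trained_views,
         calibration = net$calibration[c("d_min", "d_max", "n_samples")]),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_infomax
#' @export
read_infomax <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  w <- readBin(con, "numeric", n = meta$n_input * meta$n_output, size = 8,
               endian = "little")
  close(con)
  calib <- NULL
  if (!is.null(meta$calibration) && length(meta$calibration)) {
    calib <- structure(as.list(meta$calibration), class = "novelty_calibration")
  }
  structure(
    list(W = matrix(w, meta$n_output, meta$n_input, byrow = TRUE),
         n_input = as.integer(meta$n_input),
         n_output = as.integer(meta$n_output), eta = meta$eta,
         weight_norm = meta$weight_norm,
         trained_views = as.integer(meta$trained_views),
         calibration = calib),
    class = "infomax_network"
  )
}
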