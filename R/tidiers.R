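# broom-style tidiers for the package's result objects.

#' Tidy an environment into its landmark table
#'
#' @param x an `ant_environment`.
#' @param ... unused.
#' @return the landmarks tibble.
#' @export
tidy.ant_environment <- function(x, ...) x$landmarks

#' @rdname tidy.ant_environment
#' @export
glance.ant_environment <- function(x, ...) {
  tibble::tibble(seed = x$seed, n_landmarks = nrow(x$landmarks),
                 extent = x$extent, density = x$density,
                 mean_height = mean(x$landmarks$height))
}

#' Tidy a route into its pose table
#'
#' @param x an `ant_route` or `ant_recap`.
#' @param ... unused.
#' @return a tibble of poses (`step`, `x`, `y`, `heading`, `l_path`, ...).
#' @export
tidy.ant_route <- function(x, ...) x$poses

#' @rdname tidy.ant_route
#' @export
glance.ant_route <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_poses = nrow(x$poses),
                 path_length = route_path_length(x),
                 nominal_length = x$nominal_length,
                 termination = x$termination)
}

#' @rdname tidy.ant_route
#' @export
tidy.ant_recap <- function(x, ...) x$steps

#' @rdname tidy.ant_route
#' @export
glance.ant_recap <- function(x, ...) {
  tibble::tibble(
    strategy = x$config$strategy, n_steps = nrow(x$steps),
    path_length = route_path_length(x$route),
    interrogations_total = sum(x$steps$interrogations),
    interrogations_per_step = mean(x$steps$interrogations),
    surge_fraction = mean(x$steps$surged),
    termination = x$termination
  )
}

#' Tidy a training result
#'
#' @param x an `ant_training`.
#' @param ... unused.
#' @return capture poses of the stored views (`tidy`) or a one-row summary
#'   (`glance`).
#' @export
tidy.ant_training <- function(x, ...) x$view_meta

#' @rdname tidy.ant_training
#' @export
glance.ant_training <- function(x, ...) {
  net <- x$network
  tibble::tibble(
    n_views = length(x$views),
    route_path_length = route_path_length(x$route),
    nominal_length = x$route$nominal_length,
    n_input = if (is.null(net)) NA_integer_ else net$n_input,
    n_output = if (is.null(net)) NA_integer_ else net$n_output,
    d_min = if (is.null(net)) NA_real_ else net$calibration$d_min,
    d_max = if (is.null(net)) NA_real_ else net$calibration$d_max
  )
}

#' @rdname tidy.ant_training
#' @export
glance.infomax_network <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input, n_output = x$n_output, eta = x$eta,
    weight_norm = x$weight_norm, trained_views = x$trained_views,
    d_min = if (is.null(x$calibration)) NA_real_ else x$calibration$d_min,
    d_max = if (is.null(x$calibration)) NA_real_ else x$calibration$d_max
  )
}
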