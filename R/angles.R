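# Angle conventions used throughout:
#  * headings are degrees counter-clockwise from the +x axis, stored in [0, 360)
#  * relative azimuths/bearings are degrees in [-180, 180), positive = CCW
#  * panoramas have rho = 2 degrees per column

#' Normalise a heading to [0, 360) degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in `[0, 360)`.
#' @export
wrap_heading <- function(x) x %% 360

#' Normalise an angle to [-180, 180) degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in `[-180, 180)`.
#' @export
wrap_relative <- function(x) ((x + 180) %% 360) - 180

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# bearing (degrees CCW from +x) from point a = c(x, y) towards point b
bearing_to <- function(ax, ay, bx, by) {
  rad2deg(atan2(by - ay, bx - ax))
}

# unit step displacement for a heading in degrees
heading_step <- function(heading, step) {
  c(step * cos(deg2rad(heading)), step * sin(deg2rad(heading)))
}
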