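# World module: procedural environments and low-resolution panoramic vision.
#
# Panorama geometry (fixed conventions, tested throughout):
#  * views are n_rows x 180 matrices of intensities in [0, 1]; landmark
#    silhouettes are 0 (dark), sky is 1; rho = 2 degrees per column
#  * column c (0-based) covers relative azimuth [-180 + 2c, -180 + 2(c+1));
#    the centre column pair (89, 90) straddles the view heading
#  * row 1 is the top of the view; rows span elevations [0, 72) degrees above
#    the horizon (the agent's eye sits 1 cm over a flat featureless ground,
#    so the sub-horizon half of the sphere carries no signal)

PANO_ROWS <- 36L
PANO_COLS <- 180L
PANO_RHO <- 2
EYE_HEIGHT <- 0.01
TRUNK_FRACTION <- 0.2 # trunk cylinder occupies the lowest 20% of tree height

#' Generate a procedural environment of tree-like landmarks
#'
#' Populates a square region with vertical frustum "trees": a trunk cylinder
#' up to 20% of the tree height topped by a wider canopy cylinder. Landmark
#' count is `round(density * extent^2)`; positions are uniform over the
#' square, heights uniform over `height_range`. The same seed always
#' reproduces the identical landmark table.
#'
#' @param seed integer seed for the environment stream.
#' @param extent side length (m) of the square region.
#' @param density landmarks per square metre (default 0.007).
#' @param center centre of the square region, `c(x, y)` in metres.
#' @param height_range tree height range in metres.
#' @param trunk_radius_range trunk radius range in metres.
#' @param canopy_factor_range canopy radius as a multiple of trunk radius.
#' @return an `ant_environment`: list with `seed`, `extent`, `density`,
#'   `center` and a `landmarks` tibble (`x`, `y`, `trunk_radius`,
#'   `canopy_radius`, `height`).
#' @export
#' @examples
#' env <- generate_environment(seed = 1, extent = 100)
#' nrow(env$landmarks) # 70 = round(0.007 * 100^2)
generate_environment <- function(seed, extent, density = 0.007,
                                 center = c(0, 0),
                                 height_range = c(0.1, 30),
                                 trunk_radius_range = c(0.05, 0.5),
                                 canopy_factor_range = c(2, 6)) {
  if (!is.numeric(extent) || length(extent) != 1 || extent <= 0) {
    stop("`extent` must be a single positive number", call. = FALSE)
  }
  if (density < 0) stop("`density` must be >= 0", call. = FALSE)
  n <- round(density * extent^2)
  landmarks <- withr::with_seed(as.integer(seed), {
    tibble::tibble(
      x = runif(n, center[1] - extent / 2, center[1] + extent / 2),
      y = runif(n, center[2] - extent / 2, center[2] + extent / 2),
      trunk_radius = runif(n, trunk_radius_range[1], trunk_radius_range[2]),
      canopy_radius = .data$trunk_radius *
        runif(n, canopy_factor_range[1], canopy_factor_range[2]),
      height = runif(n, height_range[1], height_range[2])
    )
  })
  structure(
    list(seed = as.integer(seed), extent = extent, density = density,
         center = center, landmarks = landmarks),
    class = "ant_environment"
  )
}

#' @export
print.ant_environment <- function(x, ...) {
  cat(sprintf(
    "<ant_environment> seed %d: %d landmarks over a %g m square (density %g /m^2)\n",
    x$seed, nrow(x$landmarks), x$extent, x$density
  ))
  invisible(x)
}

new_pano_view <- function(grid, heading, fov = 360, col_offset = 0L) {
  structure(grid, class = "pano_view", heading = wrap_heading(heading),
            rho = PANO_RHO, fov = fov, col_offset = as.integer(col_offset))
}

#' Create an agent pose
#'
#' @param x,y position in metres.
#' @param heading degrees counter-clockwise from the +x axis.
#' @return a `pose` list with heading normalised to `[0, 360)`.
#' @export
pose <- function(x, y, heading) {
  list(x = x, y = y, heading = wrap_heading(heading))
}

#' Render the panoramic view from a pose
#'
#' Paints each landmark within the clipping distance as a dark binary
#' silhouette on a light sky. A landmark is a trunk cylinder (lowest 20% of
#' its height) plus a canopy cylinder; each part spans the azimuths within
#' `atan(radius / distance)` of its bearing and the elevations up to
#' `atan((top - eye) / distance)`. Overlapping silhouettes take the maximum
#' darkness. Rendering is a pure function of (environment, pose, clip).
#'
#' @param env an `ant_environment`.
#' @param pose a [pose()]: the view is centred on `pose$heading`.
#' @param clip camera clipping distance in metres (default 50).
#' @return a `pano_view`: 36 x 180 matrix of intensities in `[0, 1]` with the
#'   view heading stored as an attribute.
#' @export
render_panorama <- function(env, pose, clip = 50) {
  if (clip <= 0) stop("`clip` must be positive", call. = FALSE)
  grid <- matrix(1, PANO_ROWS, PANO_COLS)
  lm <- env$landmarks
  if (nrow(lm) > 0) {
    dx <- lm$x - pose$x
    dy <- lm$y - pose$y
    dist <- sqrt(dx^2 + dy^2)
    keep <- which(dist <= clip)
    if (any(dist[keep] <= lm$trunk_radius[keep])) {
      # agent inside a trunk: fully occluded view
      grid[] <- 0
      return(new_pano_view(grid, pose$heading))
    }
    col_centers <- -179 + PANO_RHO * (0:(PANO_COLS - 1)) # relative azimuths
    row_centers <- 71 - PANO_RHO * (0:(PANO_ROWS - 1))   # elevations, row 1 top
    for (i in keep) {
      b <- wrap_relative(bearing_to(pose$x, pose$y, lm$x[i], lm$y[i]) -
                           pose$heading)
      d <- dist[i]
      trunk_top <- TRUNK_FRACTION * lm$height[i]
      parts <- list(
        c(r = lm$trunk_radius[i], z0 = 0, z1 = trunk_top),
        c(r = lm$canopy_radius[i], z0 = trunk_top, z1 = lm$height[i])
      )
      for (p in parts) {
        half_az <- rad2deg(atan(p[["r"]] / d))
        top_el <- rad2deg(atan((p[["z1"]] - EYE_HEIGHT) / d))
        bot_el <- rad2deg(atan((p[["z0"]] - EYE_HEIGHT) / d))
        if (top_el <= 0) next
        cols <- which(abs(wrap_relative(col_centers - b)) <= half_az)
        rows <- which(row_centers <= top_el & row_centers >= bot_el)
        if (length(cols) && length(rows)) grid[rows, cols] <- 0
      }
    }
  }
  new_pano_view(grid, pose$heading)
}

#' Rotate a full panoramic view in silico
#'
#' Circularly shifts the columns of a full 360-degree view by `k` columns,
#' equivalent to re-rendering at `heading + k * rho`. FOV-restricted views
#' cannot be rotated (information off-view is missing); re-render instead.
#'
#' @param view a full-panorama `pano_view`.
#' @param k integer number of columns (each `rho` = 2 degrees).
#' @return the rotated `pano_view`, with its heading attribute advanced.
#' @export
rotate_view <- function(view, k) {
  if (ncol(view) != PANO_COLS) {
    stop("only full 360-degree views can be rotated in silico; re-render",
         call. = FALSE)
  }
  k <- as.integer(k) %% PANO_COLS
  idx <- ((seq_len(PANO_COLS) - 1 + k) %% PANO_COLS) + 1
  new_pano_view(unclass(view)[, idx, drop = FALSE],
                attr(view, "heading") + k * PANO_RHO)
}

#' Restrict a panoramic view's field of view
#'
#' Drops peripheral columns symmetrically about the view heading. A 256
#' degree FOV drops the 52 most peripheral of the 180 columns, leaving a
#' 36 x 128 view.
#'
#' @param view a full-panorama `pano_view`.
#' @param fov field of view in degrees; must be a multiple of 4 (two times
#'   the angular resolution) to stay symmetric, otherwise it is rounded down
#'   with a warning.
#' @return a `pano_view` with `fov / 2` columns.
#' @export
restrict_fov <- function(view, fov) {
  if (ncol(view) != PANO_COLS) {
    stop("`view` must be a full panorama", call. = FALSE)
  }
  if (fov > 360 || fov < 2 * PANO_RHO) {
    stop("`fov` must be in [4, 360] degrees", call. = FALSE)
  }
  if (fov %% (2 * PANO_RHO) != 0) {
    fov_new <- fov - fov %% (2 * PANO_RHO)
    warning(sprintf("`fov` rounded down from %g to %g degrees", fov, fov_new))
    fov <- fov_new
  }
  if (fov == 360) return(view)
  keep <- fov / PANO_RHO
  offset <- (PANO_COLS - keep) / 2
  new_pano_view(unclass(view)[, (offset + 1):(offset + keep), drop = FALSE],
                attr(view, "heading"), fov = fov, col_offset = offset)
}

#' Extract the skyline of a view
#'
#' The skyline is, per column, the elevation (degrees) of the highest
#' occupied pixel: 2 degrees times the number of rows from the bottom of the
#' view up to and including the highest dark row (intensity < 0.5), or 0 for
#' an empty column.
#'
#' @param view a `pano_view`.
#' @return numeric vector of elevations in `[0, 72]`, one per column.
#' @export
extract_skyline <- function(view) {
  m <- unclass(view) < 0.5
  apply_cols <- function(col) {
    hit <- which(col)
    if (length(hit) == 0) 0 else PANO_RHO * (nrow(m) - min(hit) + 1)
  }
  apply(m, 2, apply_cols)
}

#' Scramble the columns of a view
#'
#' Permutes columns uniformly at random under a seed, preserving the multiset
#' of columns. Column-scrambled training views serve as "maximally novel"
#' probes with environment-like pixel statistics for novelty calibration.
#'
#' @param view a `pano_view`.
#' @param seed integer seed for the permutation.
#' @return a `pano_view` with permuted columns.
#' @export
scramble_columns <- function(view, seed) {
  perm <- withr::with_seed(as.integer(seed), sample.int(ncol(view)))
  out <- unclass(view)[, perm, drop = FALSE]
  new_pano_view(out, attr(view, "heading"), fov = attr(view, "fov"),
                col_offset = attr(view, "col_offset"))
}

# 1-based column index containing a relative azimuth (degrees)
column_at_azimuth <- function(azimuth) {
  (floor((wrap_relative(azimuth) + 180) / PANO_RHO) %% PANO_COLS) + 1
}

# relative azimuth (degrees) of a 1-based full-panorama column centre
column_center <- function(col) {
  -181 + PANO_RHO * col
}
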