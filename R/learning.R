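# Route learning: an agent walks a training route under innate heuristics
# (global vector, obstacle avoidance, optional beacon aiming / restricted
# FOV / gated oscillation / goal loops), storing views at a fixed distance
# density which sequentially train an Infomax network.

#' Configuration of the route-learning heuristics
#'
#' Defaults are the study conditions of the displacement-trial experiments:
#' 5 degree global-vector noise, 15 degree motor noise, 0.2 m steps, views
#' stored at 5 per metre, 20 degree obstacle threshold probed at 2 m depth,
#' oscillation amplitude 55 degrees and period factor 115 degrees per metre,
#' 8.2 m goal loops at plus/minus 45 degrees.
#'
#' @param use_beacon aim at the most prominent frontal skyline feature.
#' @param fov field of view in degrees for stored views (360 = full).
#' @param oscillation `NULL`, or a list with `A` (degrees), `B` (degrees per
#'   metre) and `gated` (store views only in the oscillation's second and
#'   fourth phase quarters).
#' @param goal_loops `NULL`, or a list with `length` (m) and `angle`
#'   (degrees) of the pair of inbound goal-directed learning legs.
#' @param gv_noise_sd sd (degrees) of global-vector heading noise.
#' @param motor_noise_sd sd (degrees) of motor noise on the executed heading.
#' @param step step size in metres (equals the view-storage interval).
#' @param storage_density stored views per metre of path.
#' @param oa_threshold skyline elevation (degrees) above which an obstacle is
#'   avoided.
#' @param oa_depth clipping distance (m) of the shallow obstacle-avoidance
#'   render.
#' @param beacon_threshold skyline elevation (degrees) a column must exceed
#'   to qualify as a beacon (10 pixels = 20 degrees).
#' @param beacon_window half-width (degrees) of the frontal beacon window.
#' @param eta Infomax learning rate.
#' @param m_frac network output size divisor: M = N / m_frac (2 = full
#'   scale; larger values give faster, smaller networks).
#' @param weight_norm Infomax update normalisation, see [infomax_network()].
#' @return a `heuristic_config` list.
#' @export
heuristic_config <- function(use_beacon = FALSE, fov = 360,
                             oscillation = NULL, goal_loops = NULL,
                             gv_noise_sd = 5, motor_noise_sd = 15,
                             step = 0.2, storage_density = 5,
                             oa_threshold = 20, oa_depth = 2,
                             beacon_threshold = 20, beacon_window = 45,
                             eta = 0.4, m_frac = 2,
                             weight_norm = "MN") {
  if (!is.null(oscillation)) {
    oscillation <- utils::modifyList(list(A = 55, B = 115, gated = TRUE),
                                     oscillation)
  }
  if (!is.null(goal_loops)) {
    goal_loops <- utils::modifyList(list(length = 8.2, angle = 45),
                                    goal_loops)
  }
  structure(
    list(use_beacon = use_beacon, fov = fov, oscillation = oscillation,
         goal_loops = goal_loops, gv_noise_sd = gv_noise_sd,
         motor_noise_sd = motor_noise_sd, step = step,
         storage_density = storage_density, oa_threshold = oa_threshold,
         oa_depth = oa_depth, beacon_threshold = beacon_threshold,
         beacon_window = beacon_window, eta = eta, m_frac = m_frac,
         weight_norm = weight_norm),
    class = "heuristic_config"
  )
}

#' Global-vector heading towards a target
#'
#' The bearing from the current position to the target, plus normally
#' distributed noise (sd 5 degrees by default) emulating path-integration
#' imprecision.
#'
#' @param pose a [pose()].
#' @param target target coordinates `c(x, y)`.
#' @param noise_sd noise sd in degrees (0 = exact bearing).
#' @param stream optional RNG stream (internal); otherwise the global RNG is
#'   used.
#' @return heading in degrees, in `[0, 360)`.
#' @export
global_vector_heading <- function(pose, target, noise_sd = 5, stream = NULL) {
  if (pose$x == target[1] && pose$y == target[2]) {
    stop("target coincides with the current position", call. = FALSE)
  }
  b <- bearing_to(pose$x, pose$y, target[1], target[2])
  if (noise_sd > 0) {
    eps <- if (is.null(stream)) rnorm(1, 0, noise_sd) else {
      stream$rnorm(1, 0, noise_sd)
    }
    b <- b + eps
  }
  wrap_heading(b)
}

#' Adjust a heading to avoid nearby obstacles
#'
#' Renders a shallow (2 m clip) panorama and extracts its skyline. If the
#' skyline at the directed heading exceeds the threshold (20 degrees), the
#' heading is deflected to the nearest azimuth, scanning alternately left and
#' right in 2 degree increments, whose skyline falls below it — i.e. the
#' nearest silhouette edge. Obstacle avoidance is always composed last,
#' during both learning and recapitulation.
#'
#' @param directed_heading commanded heading in degrees.
#' @param env an `ant_environment`.
#' @param pose the agent's [pose()] (its heading is ignored; the shallow
#'   render is taken facing `directed_heading`).
#' @param threshold skyline elevation threshold in degrees.
#' @param depth clipping distance of the shallow render in metres.
#' @return a heading in degrees; errors if no azimuth in the full circle is
#'   clear ("enclosed agent").
#' @export
avoid_obstacles <- function(directed_heading, env, pose, threshold = 20,
                            depth = 2) {
  probe <- pose
  probe$heading <- wrap_heading(directed_heading)
  sky <- extract_skyline(render_panorama(env, probe, clip = depth))
  centre <- column_at_azimuth(0)
  if (sky[centre] <= threshold) return(probe$heading)
  for (o in seq_len(PANO_COLS %/% 2)) {
    for (offs in c(o, -o) * PANO_RHO) {
      if (sky[column_at_azimuth(offs)] <= threshold) {
        return(wrap_heading(directed_heading + offs))
      }
    }
  }
  stop("enclosed agent: no clear heading within the full circle",
       call. = FALSE)
}

#' Bias a heading towards the nearest frontal beacon
#'
#' Extracts the full-depth skyline facing the global-vector heading and,
#' among columns within the frontal window (plus/minus 45 degrees) whose
#' skyline exceeds the beacon threshold, returns the azimuth of the one
#' closest in angle to the global vector. With no qualifying column the
#' global-vector heading is returned unchanged.
#'
#' @param env an `ant_environment`.
#' @param pose the agent's [pose()].
#' @param gv_heading global-vector heading in degrees.
#' @param threshold skyline elevation (degrees) to qualify as a beacon.
#' @param window half-width of the frontal window in degrees.
#' @param clip full-depth clipping distance in metres.
#' @return a heading in degrees.
#' @export
beacon_heading <- function(env, pose, gv_heading, threshold = 20, window = 45,
                           clip = 50) {
  probe <- pose
  probe$heading <- wrap_heading(gv_heading)
  sky <- extract_skyline(render_panorama(env, probe, clip = clip))
  centers <- column_center(seq_len(PANO_COLS))
  ok <- abs(centers) <= window & sky > threshold
  if (!any(ok)) return(probe$heading)
  best <- which(ok)[which.min(abs(centers[ok]))]
  wrap_heading(gv_heading + centers[best])
}

#' Oscillatory heading offset along a learning route
#'
#' The gated-oscillation heuristic drives the heading as
#' `theta_target + A * sin(B * l_path)`, an intrinsic oscillator clocked by
#' odometric path length and not subject to noise.
#'
#' @param l_path odometric distance travelled (m) from the route start.
#' @param gv_heading the target (global-vector) heading in degrees.
#' @param A oscillation amplitude in degrees.
#' @param B period factor in degrees per metre.
#' @return list with `heading` (degrees), `offset` (degrees) and `phase`
#'   (degrees in `[0, 360)`).
#' @export
oscillation_heading <- function(l_path, gv_heading, A = 55, B = 115) {
  if (l_path < 0) stop("`l_path` must be >= 0", call. = FALSE)
  phase <- (B * l_path) %% 360
  offset <- A * sin(deg2rad(phase))
  list(heading = wrap_heading(gv_heading + offset), offset = offset,
       phase = phase)
}

#' Gate view acquisition by oscillation phase
#'
#' Views are only stored while the agent is returning towards the central
#' axis of the oscillation: the second and fourth quarters of the cycle.
#'
#' @param phase oscillation phase in degrees, `[0, 360)`.
#' @return logical: `TRUE` if learning is permitted at this phase.
#' @export
learning_gate <- function(phase) {
  (phase >= 90 & phase < 180) | (phase >= 270 & phase < 360)
}

# step with a collision guard: if the proposed step lands inside a trunk,
# fall back to the unnoised avoidance heading, then scan outward in rho
# increments for a collision-free heading. Obstacle avoidance makes this
# rare; the guard keeps poses out of trunks in edge cases.
safe_step <- function(env, p, exec_heading, fallback_heading, step) {
  inside_trunk <- function(x, y) {
    lm <- env$landmarks
    if (nrow(lm) == 0) return(FALSE)
    any((lm$x - x)^2 + (lm$y - y)^2 <= lm$trunk_radius^2)
  }
  candidates <- c(exec_heading, fallback_heading,
                  fallback_heading + rep(PANO_RHO * 1:45, each = 2) * c(1, -1))
  for (h in candidates) {
    d <- heading_step(h, step)
    if (!inside_trunk(p$x + d[1], p$y + d[2])) {
      return(pose(p$x + d[1], p$y + d[2], h))
    }
  }
  p # fully boxed in: stay put (phase clock still advances)
}

store_view <- function(env, p, fov) {
  v <- render_panorama(env, p)
  if (fov < 360) v <- restrict_fov(v, fov) else v
}

#' Build a training route and train its route memory
#'
#' Steps the agent from `start` towards `goal` under the configured
#' heuristics. Each step composes: global vector (+5 degree noise) -> beacon
#' aiming (if enabled) -> oscillation offset (if enabled) -> obstacle
#' avoidance (always last) -> motor noise (sd 15 degrees), then advances one
#' 0.2 m step. A view facing the executed heading is stored every step
#' (density 5 per metre), subject to the learning gate when the oscillation
#' is gated. The route ends when the odometric path length reaches the
#' nominal start-goal distance, so a 20 m route stores exactly 100 ungated
#' views. Stored views (plus any goal-loop views) then train an Infomax
#' network sequentially, followed by novelty calibration.
#'
#' @param env an `ant_environment`.
#' @param start,goal route endpoints, `c(x, y)` in metres.
#' @param config a [heuristic_config()].
#' @param master_seed integer seed; noise streams (global vector, motor,
#'   weight init, scrambling) are derived as independent child streams.
#' @param train_network set `FALSE` to skip network training (route only).
#' @return an `ant_training`: list with `route` (an `ant_route`), `network`
#'   (calibrated `infomax_network` with `$calibration`, or `NULL`), `views`,
#'   `start`, `goal` and `config`.
#' @export
build_training_route <- function(env, start, goal,
                                 config = heuristic_config(),
                                 master_seed = 1, train_network = TRUE) {
  route_length <- sqrt(sum((goal - start)^2))
  if (route_length <= 0) stop("start and goal coincide", call. = FALSE)
  gv_stream <- rng_stream(child_seed(master_seed, "gv-noise"))
  motor_stream <- rng_stream(child_seed(master_seed, "motor-noise"))
  osc <- config$oscillation
  gated <- !is.null(osc) && isTRUE(osc$gated)

  n_steps <- ceiling(route_length / config$step)
  p <- pose(start[1], start[2], bearing_to(start[1], start[2],
                                           goal[1], goal[2]))
  l_path <- 0
  rows <- vector("list", n_steps + 1)
  views <- list()
  view_meta <- list()
  rows[[1]] <- tibble::tibble(step = 0L, x = p$x, y = p$y,
                              heading = p$heading, l_path = 0,
                              phase = NA_real_, stored = FALSE)
  for (i in seq_len(n_steps)) {
    gv <- global_vector_heading(p, goal, config$gv_noise_sd, gv_stream)
    h <- gv
    if (config$use_beacon) {
      h <- beacon_heading(env, p, h, config$beacon_threshold,
                          config$beacon_window)
    }
    phase <- NA_real_
    if (!is.null(osc)) {
      o <- oscillation_heading(l_path, h, osc$A, osc$B)
      h <- o$heading
    }
    h_oa <- avoid_obstacles(h, env, p, config$oa_threshold, config$oa_depth)
    exec <- wrap_heading(h_oa + motor_stream$rnorm(1, 0, config$motor_noise_sd))
    p <- safe_step(env, p, exec, h_oa, config$step)
    l_path <- i * config$step # step-count clock, avoids drift at gate edges
    # gate is evaluated on the phase clock at the moment of capture
    if (!is.null(osc)) phase <- (osc$B * l_path) %% 360
    store <- !gated || learning_gate(phase)
    if (store) {
      views[[length(views) + 1]] <- store_view(env, p, config$fov)
      view_meta[[length(view_meta) + 1]] <-
        tibble::tibble(x = p$x, y = p$y, heading = p$heading,
                       l_path = l_path, origin = "route")
    }
    rows[[i + 1]] <- tibble::tibble(step = i, x = p$x, y = p$y,
                                    heading = p$heading, l_path = l_path,
                                    phase = phase, stored = store)
  }
  poses <- dplyr::bind_rows(rows)

  if (!is.null(config$goal_loops)) {
    loops <- build_goal_loops(env, start, goal, config)
    views <- c(views, loops$views)
    view_meta <- c(view_meta, list(loops$meta))
  }

  net <- NULL
  if (train_network) {
    n_input <- PANO_ROWS * (config$fov / PANO_RHO)
    net <- infomax_network(n_input, n_output = n_input / config$m_frac,
                           eta = config$eta,
                           seed = child_seed(master_seed, "weights"),
                           weight_norm = config$weight_norm)
    for (v in views) net <- infomax_train(net, v)
    net$calibration <- calibrate_novelty(
      net, views, seed = child_seed(master_seed, "scramble"))
  }

  route <- new_ant_route(poses, kind = "training", start = start, goal = goal,
                         nominal_length = route_length)
  structure(
    list(route = route, network = net, views = views,
         view_meta = dplyr::bind_rows(view_meta), start = start, goal = goal,
         config = config, master_seed = master_seed),
    class = "ant_training"
  )
}

#' Goal-directed learning-walk views
#'
#' An abstracted learning walk: two straight inbound legs ending at the goal,
#' approaching at plus/minus 45 degrees to the nominal route direction, with
#' views stored every 0.2 m facing the direction of travel (learning occurs
#' only on the goal-bound portion). An 8.2 m leg contributes 41 views, so the
#' default pair adds 82 views covering a lateral half-width of
#' `8.2 * sin(45 deg) = 5.8` m.
#'
#' @param env an `ant_environment`.
#' @param start,goal the route endpoints (the approach axis is the
#'   start-to-goal bearing).
#' @param config a [heuristic_config()] with a non-`NULL` `goal_loops` entry.
#' @return list with `views` (list of `pano_view`) and `meta` (tibble of
#'   capture poses).
#' @export
build_goal_loops <- function(env, start, goal, config = heuristic_config(
                               goal_loops = list())) {
  gl <- config$goal_loops
  if (is.null(gl)) gl <- list(length = 8.2, angle = 45)
  if (gl$length <= 0) stop("goal-loop length must be positive", call. = FALSE)
  route_dir <- bearing_to(start[1], start[2], goal[1], goal[2])
  interval <- 1 / config$storage_density
  n_views <- round(gl$length * config$storage_density)
  views <- list()
  meta <- vector("list", 2 * n_views)
  k <- 0
  for (sign in c(1, -1)) {
    travel <- wrap_heading(route_dir + sign * gl$angle)
    u <- heading_step(travel, 1)
    for (j in seq_len(n_views)) {
      dist_from_goal <- gl$length - j * interval
      x <- goal[1] - u[1] * dist_from_goal
      y <- goal[2] - u[2] * dist_from_goal
      views[[length(views) + 1]] <-
        store_view(env, pose(x, y, travel), config$fov)
      k <- k + 1
      meta[[k]] <- tibble::tibble(x = x, y = y, heading = travel,
                                  l_path = NA_real_, origin = "goal_loop")
    }
  }
  list(views = views, meta = dplyr::bind_rows(meta))
}
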