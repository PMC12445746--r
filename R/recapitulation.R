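# Route recapitulation: rotational familiarity functions and the three
# test-phase controllers (view-based orientation, familiarity-based
# modulation, cast-and-surge), with optional familiarity-modulated scan
# ranges and the displacement-trial termination rules.

#' Configuration of a recapitulation strategy
#'
#' Defaults are the printed study parameters: VBO step 0.2 m; FBM turn gain
#' 80 degrees, step gain 0.15 m, minimum step 0.45 m; CS maximum cast 60
#' degrees with step 0.30 m on baseline routes (0.20 m suits gated
#' oscillation routes); scans span 360 degrees at 2 degrees per sample with
#' a 36 degree head scan when modulated; test routes run for 1.5 times the
#' training length or terminate within 0.25 m of the goal.
#'
#' @param strategy `"VBO"`, `"FBM"` or `"CS"`.
#' @param s_vbo VBO step size (m).
#' @param fbm list with `alpha` (degrees), `beta` (m) and `s_min` (m).
#' @param cs list with `alpha` (degrees) and `s_cs` (m).
#' @param scan list with `phi_max` (degrees), `phi_min` (degrees) and
#'   `modulated` (logical).
#' @param goal_radius termination radius around the goal (m).
#' @param max_path_factor termination cap as a multiple of the nominal
#'   training-route length.
#' @param motor_noise_sd motor noise sd in degrees.
#' @param fov field of view in degrees (match the training configuration).
#' @param oa_threshold,oa_depth obstacle-avoidance parameters, as during
#'   learning.
#' @return a `recap_config` list.
#' @export
recap_config <- function(strategy = c("VBO", "FBM", "CS"), s_vbo = 0.2,
                         fbm = list(alpha = 80, beta = 0.15, s_min = 0.45),
                         cs = list(alpha = 60, s_cs = 0.3),
                         scan = list(phi_max = 360, phi_min = 36,
                                     modulated = FALSE),
                         goal_radius = 0.25, max_path_factor = 1.5,
                         motor_noise_sd = 15, fov = 360,
                         oa_threshold = 20, oa_depth = 2) {
  strategy <- match.arg(strategy)
  fbm <- utils::modifyList(list(alpha = 80, beta = 0.15, s_min = 0.45), fbm)
  cs <- utils::modifyList(list(alpha = 60, s_cs = 0.3), cs)
  scan <- utils::modifyList(list(phi_max = 360, phi_min = 36,
                                 modulated = FALSE), scan)
  structure(
    list(strategy = strategy, s_vbo = s_vbo, fbm = fbm, cs = cs, scan = scan,
         goal_radius = goal_radius, max_path_factor = max_path_factor,
         motor_noise_sd = motor_noise_sd, fov = fov,
         oa_threshold = oa_threshold, oa_depth = oa_depth),
    class = "recap_config"
  )
}

# flattened-index permutations implementing in-silico rotation on the
# row-major flattening: element (r, c) sits at (r-1)*180 + c
rotation_permutation <- function(k) {
  r <- rep(seq_len(PANO_ROWS), each = PANO_COLS)
  c0 <- rep(seq_len(PANO_COLS), PANO_ROWS)
  (r - 1) * PANO_COLS + (((c0 - 1 + k) %% PANO_COLS) + 1)
}

# all 180 rotation permutations as one matrix, built once per session
.rotation_cache <- new.env(parent = emptyenv())
rotation_permutations <- function() {
  if (is.null(.rotation_cache$PERM)) {
    .rotation_cache$PERM <- vapply(
      0:(PANO_COLS - 1),
      function(k) as.integer(rotation_permutation(k)),
      integer(PANO_ROWS * PANO_COLS)
    )
  }
  .rotation_cache$PERM
}

#' Rotational familiarity function at a pose
#'
#' Evaluates the normalised novelty of the view at relative headings
#' `psi = -phi/2, -phi/2 + rho, ..., phi/2 - rho`. For full panoramas the
#' scan is computed by in-silico column rotation of a single rendered view
#' (bit-identical to re-rendering, by rotation equivariance); for restricted
#' fields of view each sample is re-rendered at the rotated heading.
#'
#' @param net a calibrated `infomax_network`.
#' @param env an `ant_environment`.
#' @param pose the agent's [pose()]; `psi = 0` is its current heading.
#' @param phi scan range in degrees (a multiple of `rho`, at most 360).
#' @param rho angular resolution in degrees per sample (2, the column width).
#' @param fov field of view of the stored/queried views.
#' @param calib novelty calibration (defaults to the network's).
#' @param view optionally, the already-rendered full panorama at `pose`
#'   (avoids re-rendering when several scans share one physical view).
#' @return an `ant_rff` tibble with columns `psi` (degrees) and `novelty`
#'   (in `[0, 1]`), and attributes `phi` and `rho`.
#' @export
compute_rff <- function(net, env, pose, phi = 360, rho = PANO_RHO,
                        fov = 360, calib = net$calibration, view = NULL) {
  if (phi < rho || phi > 360) stop("`phi` must be in [rho, 360]", call. = FALSE)
  psi <- seq(-phi / 2, phi / 2 - rho, by = rho)
  if (fov == 360) {
    if (is.null(view)) view <- render_panorama(env, pose)
    flat <- flatten_view(view)
    k_idx <- ((psi / rho) %% PANO_COLS) + 1
    S <- matrix(flat[rotation_permutations()[, k_idx]], nrow = length(flat))
  } else {
    S <- vapply(psi, function(a) {
      probe <- pose
      probe$heading <- wrap_heading(pose$heading + a)
      flatten_view(restrict_fov(render_panorama(env, probe), fov))
    }, numeric(PANO_ROWS * fov / PANO_RHO))
  }
  d <- novelty_batch(net, S, calib)
  structure(tibble::tibble(psi = psi, novelty = d),
            class = c("ant_rff", class(tibble::tibble())),
            phi = phi, rho = rho)
}

#' View-based-orientation heading from an RFF
#'
#' The relative heading of the minimum-novelty scan sample. Ties are broken
#' towards the smallest absolute relative heading (prefer going straight).
#'
#' @param rff an `ant_rff` (or any data frame with `psi` and `novelty`).
#' @return relative heading in degrees.
#' @export
vbo_heading <- function(rff) {
  if (nrow(rff) == 0) stop("empty RFF", call. = FALSE)
  best <- which(rff$novelty == min(rff$novelty))
  rff$psi[best[which.min(abs(rff$psi[best]))]]
}

#' Familiarity-based-modulation turn and step
#'
#' Klinokinesis-style control from the forward-facing view only: the turn is
#' `alpha * (-1)^n * d` (alternating sign, scaled by current novelty) and
#' the step is `beta * (1 - d) + s_min` (shrinking towards `s_min` as
#' novelty rises).
#'
#' @param d_current normalised novelty of the forward view, in `[0, 1]`.
#' @param n step index (0-based), driving the alternating sign.
#' @param alpha turn gain in degrees.
#' @param beta step gain in metres.
#' @param s_min minimum step in metres.
#' @return list with `theta` (relative heading, degrees) and `step` (m).
#' @export
fbm_step <- function(d_current, n, alpha = 80, beta = 0.15, s_min = 0.45) {
  list(theta = alpha * (-1)^n * d_current,
       step = beta * (1 - d_current) + s_min)
}

#' Cast heading superimposed on the VBO heading
#'
#' `theta_C = theta_VBO + m * alpha * (-1)^n`: an alternating cast whose
#' amplitude scales with the best (minimum) novelty of the scan, up to
#' `alpha` (60 degrees).
#'
#' @param theta_vbo VBO relative heading in degrees.
#' @param m_novelty minimum novelty of the RFF, in `[0, 1]`.
#' @param n step index (0-based).
#' @param alpha maximum cast in degrees.
#' @return relative heading in degrees.
#' @export
cast_heading <- function(theta_vbo, m_novelty, n, alpha = 60) {
  theta_vbo + m_novelty * alpha * (-1)^n
}

#' Cast-and-surge heading selection
#'
#' If the best novelty has not improved since the previous step
#' (`delta_d >= 0`) the agent casts (`theta_c`); if it has improved, all
#' rotation is suppressed and the agent surges straight along its pre-scan
#' orientation (relative heading 0).
#'
#' @param theta_c cast heading in degrees (relative).
#' @param delta_d change in best novelty since the previous step; the first
#'   step has no history and is treated as `delta_d >= 0` (cast).
#' @return relative heading in degrees.
#' @export
cast_and_surge_heading <- function(theta_c, delta_d) {
  if (is.na(delta_d) || delta_d >= 0) theta_c else 0
}

#' Familiarity-modulated scan range
#'
#' `phi = phi_min + m * (phi_max - phi_min)`: the body-scan range grows
#' linearly with the best novelty of the small head scan. When the result
#' does not exceed `phi_min` the body scan is skipped (the agent is already
#' well oriented in familiar surroundings).
#'
#' @param m_small best novelty of the `phi_min` head scan, in `[0, 1]`.
#' @param phi_min head-scan range in degrees.
#' @param phi_max maximum body-scan range in degrees.
#' @return scan range in degrees (not yet discretised to `rho`).
#' @export
modulated_scan_range <- function(m_small, phi_min = 36, phi_max = 360) {
  if (phi_max < phi_min) stop("`phi_max` must be >= `phi_min`", call. = FALSE)
  phi_min + m_small * (phi_max - phi_min)
}

#' Recapitulate a learned route from a release pose
#'
#' Runs the test-phase step loop: the strategy proposes a relative heading
#' (and step size), obstacle avoidance is applied last, motor noise (sd 15
#' degrees) perturbs the executed heading, and the agent steps. The run
#' terminates on reaching within `goal_radius` (0.25 m) of the goal or when
#' the path length exceeds `max_path_factor` (1.5) times the nominal
#' training length.
#'
#' @param env an `ant_environment`.
#' @param training an `ant_training` from [build_training_route()] (supplies
#'   the network, goal and nominal length).
#' @param start_pose the release [pose()].
#' @param config a [recap_config()].
#' @param seed integer seed for the motor-noise stream.
#' @return an `ant_recap`: list with `route` (an `ant_route` of kind
#'   `"test"`), a per-step `steps` tibble (chosen heading, step size, scan
#'   range, view interrogations, best novelty, novelty change, surge flag)
#'   and the termination reason.
#' @export
recapitulate <- function(env, training, start_pose,
                         config = recap_config(), seed = 1) {
  net <- training$network
  if (is.null(net) || is.null(net$calibration)) {
    stop("`training` must carry a trained, calibrated network", call. = FALSE)
  }
  goal <- training$goal
  nominal <- training$route$nominal_length
  max_path <- config$max_path_factor * nominal
  motor_stream <- rng_stream(child_seed(seed, "recap-motor"))
  rho <- PANO_RHO

  p <- start_pose
  path_len <- 0
  n <- 0L
  m_prev <- NA_real_
  pose_rows <- list(tibble::tibble(step = 0L, x = p$x, y = p$y,
                                   heading = p$heading, l_path = 0))
  step_rows <- list()
  termination <- "max_path"
  repeat {
    if (sqrt((p$x - goal[1])^2 + (p$y - goal[2])^2) <= config$goal_radius) {
      termination <- "goal"
      break
    }
    if (path_len >= max_path) break

    interrogations <- 0L
    scan_range <- NA_real_
    m <- NA_real_
    delta_d <- NA_real_
    surged <- FALSE
    if (config$strategy == "VBO") {
      rff <- compute_rff(net, env, p, phi = config$scan$phi_max, rho = rho,
                         fov = config$fov)
      interrogations <- nrow(rff)
      scan_range <- config$scan$phi_max
      theta <- vbo_heading(rff)
      m <- min(rff$novelty)
      step_size <- config$s_vbo
    } else if (config$strategy == "FBM") {
      v <- store_view(env, p, config$fov)
      d <- novelty(net, v)
      interrogations <- 1L
      out <- fbm_step(d, n, config$fbm$alpha, config$fbm$beta,
                      config$fbm$s_min)
      theta <- out$theta
      step_size <- out$step
      m <- d
    } else { # CS
      # one physical panorama serves both the head scan and the body scan
      cs_view <- if (config$fov == 360) render_panorama(env, p) else NULL
      head_n <- as.integer(config$scan$phi_min / rho)
      if (config$scan$modulated) {
        rff_small <- compute_rff(net, env, p, phi = config$scan$phi_min,
                                 rho = rho, fov = config$fov, view = cs_view)
        interrogations <- nrow(rff_small)
        m_small <- min(rff_small$novelty)
        phi_body <- modulated_scan_range(m_small, config$scan$phi_min,
                                         config$scan$phi_max)
        phi_body <- rho * floor(phi_body / rho)
        if (phi_body > config$scan$phi_min) {
          rff <- compute_rff(net, env, p, phi = phi_body, rho = rho,
                             fov = config$fov, view = cs_view)
          interrogations <- interrogations + nrow(rff)
          scan_range <- phi_body
        } else {
          rff <- rff_small # well oriented: reuse the head scan
          scan_range <- config$scan$phi_min
        }
      } else {
        # the head scan is still performed (and counted), but with a fixed
        # body-scan range its familiarity value influences nothing
        rff <- compute_rff(net, env, p, phi = config$scan$phi_max, rho = rho,
                           fov = config$fov, view = cs_view)
        interrogations <- head_n + nrow(rff)
        scan_range <- config$scan$phi_max
      }
      theta_vbo <- vbo_heading(rff)
      m <- min(rff$novelty)
      delta_d <- if (is.na(m_prev)) NA_real_ else m - m_prev
      theta_c <- cast_heading(theta_vbo, m, n, config$cs$alpha)
      theta <- cast_and_surge_heading(theta_c, delta_d)
      surged <- !is.na(delta_d) && delta_d < 0
      m_prev <- m
      step_size <- config$cs$s_cs
    }

    commanded <- wrap_heading(p$heading + theta)
    h_oa <- avoid_obstacles(commanded, env, p, config$oa_threshold,
                            config$oa_depth)
    exec <- wrap_heading(h_oa + motor_stream$rnorm(1, 0,
                                                   config$motor_noise_sd))
    pre <- p
    p <- safe_step(env, p, exec, h_oa, step_size)
    path_len <- path_len + step_size
    n <- n + 1L
    pose_rows[[n + 1]] <- tibble::tibble(step = n, x = p$x, y = p$y,
                                         heading = p$heading,
                                         l_path = path_len)
    step_rows[[n]] <- tibble::tibble(
      step = n, x_before = pre$x, y_before = pre$y,
      heading_before = pre$heading, theta = theta, step_size = step_size,
      scan_range = scan_range, interrogations = interrogations,
      m = m, delta_d = delta_d, surged = surged,
      x_after = p$x, y_after = p$y, heading_after = p$heading
    )
  }
  if (length(step_rows) == 0) {
    # typed empty prototype (e.g. released inside the goal radius)
    step_rows <- list(tibble::tibble(
      step = integer(0), x_before = numeric(0), y_before = numeric(0),
      heading_before = numeric(0), theta = numeric(0),
      step_size = numeric(0), scan_range = numeric(0),
      interrogations = integer(0), m = numeric(0), delta_d = numeric(0),
      surged = logical(0), x_after = numeric(0), y_after = numeric(0),
      heading_after = numeric(0)
    ))
  }
  route <- new_ant_route(dplyr::bind_rows(pose_rows), kind = "test",
                         start = c(start_pose$x, start_pose$y), goal = goal,
                         nominal_length = nominal, termination = termination)
  structure(
    list(route = route, steps = dplyr::bind_rows(step_rows),
         termination = termination, config = config, seed = seed),
    class = "ant_recap"
  )
}

#' @export
print.ant_recap <- function(x, ...) {
  cat(sprintf(
    "<ant_recap> %s: %d steps, %d view interrogations, terminated: %s\n",
    x$config$strategy, nrow(x$steps), sum(x$steps$interrogations),
    x$termination
  ))
  invisible(x)
}
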