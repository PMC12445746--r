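# Experiment protocols: displacement sweeps across strategies and the
# scan-range sweep, at configurable scale. Every strategy within one
# environment seed sees the identical landmark set, and all randomness fans
# out from the protocol's master seed, so results tables are bit-reproducible.

#' Named strategy presets (route-learning heuristic + recapitulation)
#'
#' Builds the paired learning and recapitulation configurations for a named
#' combination, e.g. `"baseline+VBO"`, `"gatedosc+CS"`. Heuristic
#' identifiers: `baseline`, `beacon`, `resfov`, `gatedosc`, `goalloop`,
#' `gatedosc_goalloop`. Recapitulation identifiers: `VBO`, `FBM`, `CS`. The
#' cast-and-surge step size is 0.30 m on baseline-style routes and 0.20 m on
#' gated-oscillation routes.
#'
#' @param label strategy label, `"<heuristic>+<recap>"`.
#' @param m_frac network size divisor passed to [heuristic_config()].
#' @param phi_max maximum scan range in degrees.
#' @param modulated modulate the scan range by familiarity.
#' @param eta Infomax learning rate.
#' @return list with `label`, `heuristic` ([heuristic_config()]) and `recap`
#'   ([recap_config()]).
#' @export
strategy_config <- function(label, m_frac = 2, phi_max = 360,
                            modulated = FALSE, eta = 0.4) {
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("strategy label must be '<heuristic>+<recap>'", call. = FALSE)
  }
  heur_id <- parts[1]
  recap_id <- parts[2]
  oscillation <- if (grepl("gatedosc", heur_id)) list(gated = TRUE) else NULL
  goal_loops <- if (grepl("goalloop", heur_id)) list() else NULL
  heur <- heuristic_config(
    use_beacon = heur_id == "beacon",
    fov = if (heur_id == "resfov") 256 else 360,
    oscillation = oscillation, goal_loops = goal_loops,
    m_frac = m_frac, eta = eta
  )
  if (!heur_id %in% c("baseline", "beacon", "resfov", "gatedosc", "goalloop",
                      "gatedosc_goalloop")) {
    stop("unknown heuristic: ", heur_id, call. = FALSE)
  }
  if (!recap_id %in% c("VBO", "FBM", "CS")) {
    stop("unknown recapitulation strategy: ", recap_id, call. = FALSE)
  }
  recap <- recap_config(
    strategy = recap_id,
    cs = list(s_cs = if (!is.null(oscillation)) 0.2 else 0.3),
    scan = list(phi_max = phi_max, modulated = modulated),
    fov = heur$fov
  )
  list(label = label, heuristic = heur, recap = recap)
}

#' Release points for a displacement trial
#'
#' Testing positions spaced along the line perpendicular to the initial
#' route direction through the start: `2 * max / spacing + 1` points. The
#' full-scale protocol (spacing 0.25 m up to +/-5.5 m) gives 45.
#'
#' @param spacing spacing between release points in metres.
#' @param max maximum absolute lateral displacement in metres.
#' @return numeric vector of lateral displacements.
#' @export
release_points <- function(spacing = 0.25, max = 5.5) {
  seq(-max, max, by = spacing)
}

#' Displacement-trial protocol
#'
#' Defaults are desk-scale (10 seeds, 9 release points over +/-2 m, network
#' M = N/8); the full-scale study conditions are 75 seeds and 45 release
#' points over +/-5.5 m at 0.25 m spacing with M = N/2, available as
#' `trial_protocol(n_seeds = 75, displacement_spacing = 0.25,
#' displacement_max = 5.5, m_frac = 2)`.
#'
#' @param route_length nominal training-route length in metres (20 or 100).
#' @param n_seeds number of environment seeds.
#' @param displacement_spacing release-point spacing in metres.
#' @param displacement_max maximum absolute displacement in metres.
#' @param strategies character vector of strategy labels, see
#'   [strategy_config()].
#' @param master_seed master seed for all randomness.
#' @param m_frac network size divisor (M = N / m_frac).
#' @param density landmark density per square metre.
#' @param eta Infomax learning rate.
#' @return a `trial_protocol` list.
#' @export
trial_protocol <- function(route_length = 20, n_seeds = 10,
                           displacement_spacing = 0.5,
                           displacement_max = 2,
                           strategies = c("baseline+VBO", "baseline+CS"),
                           master_seed = 1, m_frac = 8, density = 0.007,
                           eta = 0.4) {
  structure(
    list(route_length = route_length, n_seeds = n_seeds,
         displacement_spacing = displacement_spacing,
         displacement_max = displacement_max, strategies = strategies,
         master_seed = master_seed, m_frac = m_frac, density = density,
         eta = eta),
    class = "trial_protocol"
  )
}

trial_environment <- function(protocol, seed_index) {
  L <- protocol$route_length
  generate_environment(
    seed = child_seed(protocol$master_seed, "env", seed_index),
    extent = L + 110, density = protocol$density, center = c(L / 2, 0)
  )
}

#' Run a displacement trial
#'
#' For each environment seed: generates the environment, builds one training
#' route and network per strategy, then recapitulates from every release
#' point, emitting one per-trial summary row. Individual trial failures are
#' logged as warnings, not fatal. Passing a `previous` results table makes
#' the run resumable: completed (seed, strategy, displacement) triples are
#' skipped and the old rows kept.
#'
#' @param protocol a [trial_protocol()].
#' @param previous an earlier results tibble to resume from, or `NULL`.
#' @param progress print per-seed progress lines.
#' @return a tibble with one row per (seed, strategy, release point).
#' @export
run_displacement_trial <- function(protocol, previous = NULL,
                                   progress = FALSE) {
  L <- protocol$route_length
  displacements <- release_points(protocol$displacement_spacing,
                                  protocol$displacement_max)
  strategies <- lapply(protocol$strategies, strategy_config,
                       m_frac = protocol$m_frac, eta = protocol$eta)
  done <- if (is.null(previous)) character(0) else {
    paste(previous$seed, previous$strategy, previous$displacement)
  }
  rows <- if (is.null(previous)) list() else list(previous)
  for (seed_index in seq_len(protocol$n_seeds)) {
    env <- trial_environment(protocol, seed_index)
    if (progress) {
      message(sprintf("seed %d/%d", seed_index, protocol$n_seeds))
    }
    for (strat in strategies) {
      todo <- displacements[!paste(seed_index, strat$label, displacements)
                            %in% done]
      if (length(todo) == 0) next
      training <- tryCatch(
        build_training_route(
          env, start = c(0, 0), goal = c(L, 0), config = strat$heuristic,
          master_seed = child_seed(protocol$master_seed, "train", seed_index,
                                   strat$label)
        ),
        error = function(e) {
          warning(sprintf("training failed (seed %d, %s): %s", seed_index,
                          strat$label, conditionMessage(e)), call. = FALSE)
          NULL
        }
      )
      if (is.null(training)) next
      for (y in todo) {
        row <- tryCatch({
          recap <- recapitulate(
            env, training, pose(0, y, 0), config = strat$recap,
            seed = child_seed(protocol$master_seed, "recap", seed_index,
                              strat$label, format(y))
          )
          dplyr::bind_cols(
            tibble::tibble(seed = seed_index, strategy = strat$label,
                           displacement = y),
            trial_summary(training, recap)
          )
        }, error = function(e) {
          warning(sprintf("trial failed (seed %d, %s, y = %g): %s",
                          seed_index, strat$label, y, conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
        if (!is.null(row)) rows[[length(rows) + 1]] <- row
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Scan-range sweep protocol
#'
#' Defaults follow the scan-modulation experiment: baseline + cast-and-surge
#' over 5 release points spanning +/-2 m, with the maximum scan range varied
#' from 36 to 360 degrees (including the 160 degree plateau point), run both
#' with and without familiarity modulation.
#'
#' @param route_length nominal training-route length (m).
#' @param n_seeds number of environment seeds (10 in the full protocol).
#' @param displacements release displacements in metres.
#' @param phi_max_values maximum scan ranges (degrees) to sweep.
#' @param modulated conditions to run (default both).
#' @param master_seed,m_frac,density,eta as in [trial_protocol()].
#' @return a `scan_sweep_protocol` list.
#' @export
scan_sweep_protocol <- function(route_length = 20, n_seeds = 10,
                                displacements = seq(-2, 2, by = 1),
                                phi_max_values = c(36, 80, 120, 160, 200,
                                                   280, 360),
                                modulated = c(TRUE, FALSE),
                                master_seed = 1, m_frac = 8,
                                density = 0.007, eta = 0.4) {
  structure(
    list(route_length = route_length, n_seeds = n_seeds,
         displacements = displacements, phi_max_values = phi_max_values,
         modulated = modulated, master_seed = master_seed, m_frac = m_frac,
         density = density, eta = eta),
    class = "scan_sweep_protocol"
  )
}

#' Run a scan-range sweep
#'
#' Baseline + cast-and-surge trials across the maximum-scan-range grid, in
#' matched modulated and fixed conditions (same environments, training
#' routes and release points), recording displacement metrics and
#' view-interrogation counts per condition.
#'
#' @param protocol a [scan_sweep_protocol()].
#' @param progress print per-seed progress lines.
#' @return a tibble with one row per (seed, phi_max, modulated, release
#'   point).
#' @export
run_scan_sweep <- function(protocol, progress = FALSE) {
  L <- protocol$route_length
  rows <- list()
  for (seed_index in seq_len(protocol$n_seeds)) {
    env <- generate_environment(
      seed = child_seed(protocol$master_seed, "env", seed_index),
      extent = L + 110, density = protocol$density, center = c(L / 2, 0)
    )
    if (progress) {
      message(sprintf("seed %d/%d", seed_index, protocol$n_seeds))
    }
    base <- strategy_config("baseline+CS", m_frac = protocol$m_frac,
                            eta = protocol$eta)
    training <- build_training_route(
      env, start = c(0, 0), goal = c(L, 0), config = base$heuristic,
      master_seed = child_seed(protocol$master_seed, "train", seed_index,
                               "baseline+CS")
    )
    for (phi_max in protocol$phi_max_values) {
      for (mod in protocol$modulated) {
        cfg <- recap_config(
          strategy = "CS", cs = base$recap$cs,
          scan = list(phi_max = phi_max, modulated = mod)
        )
        for (y in protocol$displacements) {
          row <- tryCatch({
            recap <- recapitulate(
              env, training, pose(0, y, 0), config = cfg,
              seed = child_seed(protocol$master_seed, "recap", seed_index,
                                phi_max, format(y))
            )
            dplyr::bind_cols(
              tibble::tibble(seed = seed_index, phi_max = phi_max,
                             modulated = mod, displacement = y),
              trial_summary(training, recap)
            )
          }, error = function(e) {
            warning(sprintf(
              "sweep trial failed (seed %d, phi %g, mod %s, y = %g): %s",
              seed_index, phi_max, mod, y, conditionMessage(e)),
              call. = FALSE)
            NULL
          })
          if (!is.null(row)) rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
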