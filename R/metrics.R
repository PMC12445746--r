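# Navigation performance metrics: route displacement (stepping through the
# training route), goal-region displacement, rapid-divergence classification
# and trial aggregation.

min_dist_to <- function(from, to) {
  # per row of `from`, the minimum Euclidean distance to any row of `to`
  d2 <- outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Route displacement between a training and a test route
#'
#' The mean, over training-route positions, of the Euclidean distance to the
#' nearest test-route position. The calculation deliberately steps through
#' the training route (not the test route), so a test path that stalls near
#' one point of the route still scores poorly, while a path that passes the
#' goal and continues is not penalised.
#'
#' @param train,test routes: `ant_route`/`ant_recap` objects, data frames
#'   with `x`/`y` columns, or two-column matrices.
#' @return mean displacement in metres.
#' @export
route_displacement <- function(train, test) {
  r <- route_positions(train)
  s <- route_positions(test)
  if (nrow(r) == 0 || nrow(s) == 0) stop("empty route", call. = FALSE)
  mean(min_dist_to(r, s))
}

#' Route displacement over the goal region
#'
#' Route displacement restricted to the final 5% of training-route positions
#' (`ceiling(0.05 * N)` of them), measuring destination reaching rather than
#' convergence to the whole route.
#'
#' @inheritParams route_displacement
#' @param tail_fraction fraction of the training route to keep (default
#'   0.05).
#' @return mean displacement in metres.
#' @export
goal_displacement <- function(train, test, tail_fraction = 0.05) {
  r <- route_positions(train)
  s <- route_positions(test)
  if (nrow(r) == 0 || nrow(s) == 0) stop("empty route", call. = FALSE)
  n_tail <- ceiling(tail_fraction * nrow(r))
  r <- r[(nrow(r) - n_tail + 1):nrow(r), , drop = FALSE]
  mean(min_dist_to(r, s))
}

#' Classify a test route as rapidly divergent
#'
#' A test route is rapidly divergent if it never enters the closed disk of
#' radius half the start-goal distance centred on the goal (boundary contact
#' counts as entering).
#'
#' @param test a test route (see [route_displacement()] for accepted forms).
#' @param start,goal route endpoints `c(x, y)`.
#' @return logical.
#' @export
is_rapidly_divergent <- function(test, start, goal) {
  s <- route_positions(test)
  radius <- sqrt(sum((goal - start)^2)) / 2
  d <- sqrt((s[, 1] - goal[1])^2 + (s[, 2] - goal[2])^2)
  !any(d <= radius)
}

#' Per-trial displacement summary
#'
#' Computes all the per-trial metrics for one training/test route pair.
#'
#' @param training an `ant_training`.
#' @param recap an `ant_recap`.
#' @return a one-row tibble: route and goal displacement (m), rapid
#'   divergence flag, total and mean per-step view interrogations, path
#'   length and termination reason.
#' @export
trial_summary <- function(training, recap) {
  tibble::tibble(
    route_displacement = route_displacement(training$route, recap),
    goal_displacement = goal_displacement(training$route, recap),
    rapidly_divergent = is_rapidly_divergent(recap, training$start,
                                             training$goal),
    interrogations_total = sum(recap$steps$interrogations),
    interrogations_per_step = mean(recap$steps$interrogations),
    n_steps = nrow(recap$steps),
    path_length = route_path_length(recap$route),
    termination = recap$termination
  )
}

#' Aggregate displacement trials to means and standard errors
#'
#' Matches the aggregation order of the displacement-trial protocol: trial
#' values are first averaged within each environment seed (across release
#' points), giving one score per seed, then summarised across seeds as mean
#' and standard error (`sd / sqrt(n_seeds)`; 0 for a single seed).
#'
#' @param trials a tibble of per-trial rows including `seed` and the grouping
#'   columns.
#' @param values character vector of metric columns to summarise.
#' @param group character vector of grouping columns (default `"strategy"`).
#' @return a tibble with one row per (group, metric): `mean`, `sem`,
#'   `n_seeds`, `n_trials`.
#' @export
summarize_trials <- function(trials,
                             values = c("route_displacement",
                                        "goal_displacement"),
                             group = "strategy") {
  if (nrow(trials) == 0) stop("no trials to summarise", call. = FALSE)
  long <- tidyr::pivot_longer(
    dplyr::select(trials, dplyr::all_of(c(group, "seed", values))),
    dplyr::all_of(values), names_to = "metric", values_to = "value"
  )
  per_seed <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(group, "metric",
                                                        "seed")))),
    value = mean(.data$value), n_trials = dplyr::n(), .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(per_seed, dplyr::across(dplyr::all_of(c(group,
                                                            "metric")))),
    mean = mean(.data$value),
    sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
    n_seeds = dplyr::n(),
    n_trials = sum(.data$n_trials),
    .groups = "drop"
  )
}
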