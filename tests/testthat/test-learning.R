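test_that("global-vector headings point at the target with calibrated noise", {
  p <- pose(0, 0, 0)
  expect_equal(global_vector_heading(p, c(10, 0), noise_sd = 0), 0)
  expect_equal(global_vector_heading(p, c(0, 10), noise_sd = 0), 90)
  expect_equal(global_vector_heading(p, c(-5, 0), noise_sd = 0), 180)
  expect_error(global_vector_heading(p, c(0, 0)), "coincides")
  # Monte-Carlo: sample sd of the noisy bearing is ~5 degrees
  draws <- withr::with_seed(1, {
    replicate(1e4, global_vector_heading(p, c(10, 0), noise_sd = 5))
  })
  draws <- ((draws + 180) %% 360) - 180
  expect_lt(abs(sd(draws) - 5), 0.2)
})

test_that("obstacle avoidance deflects to the silhouette edge of near trees", {
  p <- pose(0, 0, 0)
  expect_equal(avoid_obstacles(0, empty_env(), p), 0)
  # a tree just beyond the 2 m probe depth is ignored
  env_far <- single_tree_env(2.6, 0, radius = 0.3, height = 2)
  expect_equal(avoid_obstacles(0, env_far, p), 0)
  # a near tree dead ahead subtending > 20 degrees: deflection lands at the
  # tangent bearing of its silhouette within one scan increment
  for (case in list(c(d = 1.5, r = 0.4), c(d = 1, r = 0.25))) {
    env <- single_tree_env(case[["d"]], 0, case[["r"]], height = 3)
    got <- avoid_obstacles(0, env, p)
    got_rel <- abs(((got + 180) %% 360) - 180)
    tangent <- atan(case[["r"]] / case[["d"]]) * 180 / pi
    expect_gte(got_rel, tangent - 2)
    expect_lte(got_rel, tangent + 4)
  }
  # enclosed agent: a tight ring of fat trees leaves no clear azimuth
  ring <- tibble::tibble(
    x = 1.2 * cos(seq(0, 2 * pi, length.out = 40)[-40]),
    y = 1.2 * sin(seq(0, 2 * pi, length.out = 40)[-40]),
    trunk_radius = 0.4, canopy_radius = 0.4, height = 5
  )
  expect_error(avoid_obstacles(0, env_from_landmarks(ring), p), "enclosed")
})

test_that("beacon aiming snaps to the qualifying column nearest the vector", {
  p <- pose(0, 0, 0)
  expect_equal(beacon_heading(empty_env(), p, 10), 10)
  # one tall tree 30 degrees CCW of the vector
  env <- single_tree_env(20 * cos(pi / 6), 20 * sin(pi / 6), 1, 25)
  got <- beacon_heading(env, p, 0)
  expect_lt(abs(got - 30), 3)
  # of two qualifying beacons the angularly closer one wins
  two <- env_from_landmarks(tibble::tibble(
    x = c(15 * cos(-10 * pi / 180), 15 * cos(20 * pi / 180)),
    y = c(15 * sin(-10 * pi / 180), 15 * sin(20 * pi / 180)),
    trunk_radius = 1, canopy_radius = 1, height = 25
  ))
  got2 <- ((beacon_heading(two, p, 0) + 180) %% 360) - 180
  # the qualifying column nearest the vector is the -10 degree tree's inner
  # silhouette edge (half-width atan(1/15) ~ 3.8 degrees)
  expect_lte(abs(got2 - (-10)), 4)
  expect_lt(got2, 0)
  # beacons outside the +/-45 degree window are ignored
  side <- single_tree_env(20 * cos(pi / 2), 20 * sin(pi / 2), 1, 25)
  expect_equal(beacon_heading(side, p, 0), 0)
})

test_that("the oscillator follows theta_target + A sin(B l_path)", {
  o0 <- oscillation_heading(0, gv_heading = 90)
  expect_equal(o0$offset, 0)
  expect_equal(o0$heading, 90)
  expect_equal(o0$phase, 0)
  # quarter cycle: B * l_path = 90 -> full +55 degree excursion
  l_quarter <- 90 / 115
  o1 <- oscillation_heading(l_quarter, 0)
  expect_equal(o1$offset, 55)
  expect_equal(o1$phase, 90)
  o3 <- oscillation_heading(3 * l_quarter, 0)
  expect_equal(o3$offset, -55)
  expect_equal(o3$phase, 270)
  expect_error(oscillation_heading(-1, 0), ">= 0")
})

test_that("the learning gate opens in the second and fourth quarters", {
  expect_false(learning_gate(45))
  expect_true(learning_gate(135))
  expect_false(learning_gate(200))
  expect_true(learning_gate(300))
  expect_false(learning_gate(0))
  expect_true(learning_gate(90))   # quarter boundaries, half-open
  expect_false(learning_gate(180))
  expect_true(learning_gate(270))
})

test_that("a noise-free baseline route is a straight line of exact steps", {
  cfg <- heuristic_config(gv_noise_sd = 0, motor_noise_sd = 0)
  tr <- build_training_route(empty_env(), c(0, 0), c(10, 0), cfg,
                             master_seed = 1, train_network = FALSE)
  poses <- tr$route$poses
  expect_equal(nrow(poses), 51) # 50 steps of 0.2 m plus the start
  expect_equal(max(abs(poses$y)), 0)
  expect_equal(poses$x, seq(0, 10, by = 0.2))
  expect_equal(length(tr$views), 50) # 10 m x 5 per metre
  # consecutive-pose spacing equals the step size
  d <- sqrt(diff(poses$x)^2 + diff(poses$y)^2)
  expect_equal(d, rep(0.2, 50), tolerance = 1e-12)
})

test_that("stored-view counts follow route length, density and gating", {
  env <- trial_env(2)
  tr20 <- build_training_route(env, c(0, 0), c(20, 0), heuristic_config(),
                               master_seed = 5, train_network = FALSE)
  expect_equal(length(tr20$views), 100) # 20 m at 5 per metre
  # gated oscillation stores roughly half the views, all at gated phases
  cfg_osc <- heuristic_config(oscillation = list(gated = TRUE))
  osc <- build_training_route(env, c(0, 0), c(20, 0), cfg_osc,
                              master_seed = 5, train_network = FALSE)
  stored_phases <- osc$route$poses$phase[osc$route$poses$stored &
                                           osc$route$poses$step > 0]
  expect_true(all(learning_gate(stored_phases)))
  # independent count over the odometric phase sequence
  want <- sum(learning_gate((115 * 0.2 * (1:100)) %% 360))
  expect_equal(length(osc$views), want)
  expect_gt(length(osc$views), 35)
  expect_lt(length(osc$views), 65)
})

test_that("gated stored views head back towards the oscillation axis", {
  # noise-free, empty world: every stored heading must lie strictly inside
  # the +/-55 degree envelope around the global vector of its own step
  # (the gate only admits the returning quarters of the cycle)
  cfg <- heuristic_config(gv_noise_sd = 0, motor_noise_sd = 0,
                          oscillation = list(gated = TRUE))
  tr <- build_training_route(empty_env(), c(0, 0), c(20, 0), cfg,
                             master_seed = 1, train_network = FALSE)
  poses <- tr$route$poses
  stored_k <- which(poses$stored & poses$step > 0)
  gv <- atan2(0 - poses$y[stored_k - 1], 20 - poses$x[stored_k - 1]) *
    180 / pi
  rel <- abs(((poses$heading[stored_k] - gv + 180) %% 360) - 180)
  # the half-open gate admits the quarter-start itself, where the offset
  # equals the extreme; everywhere else it must be strictly inside
  expect_true(all(rel <= 55 + 1e-9))
  expect_gt(mean(rel < 55 - 1e-9), 0.9)
})

test_that("routes are reproducible and avoid trunk interiors", {
  env <- trial_env(7)
  cfg <- heuristic_config()
  a <- build_training_route(env, c(0, 0), c(20, 0), cfg, master_seed = 3,
                            train_network = FALSE)
  b <- build_training_route(env, c(0, 0), c(20, 0), cfg, master_seed = 3,
                            train_network = FALSE)
  expect_identical(a$route$poses, b$route$poses)
  c_ <- build_training_route(env, c(0, 0), c(20, 0), cfg, master_seed = 4,
                             train_network = FALSE)
  expect_false(identical(a$route$poses, c_$route$poses))
  lm <- env$landmarks
  for (i in seq_len(nrow(a$route$poses))) {
    inside <- (lm$x - a$route$poses$x[i])^2 + (lm$y - a$route$poses$y[i])^2 <
      lm$trunk_radius^2
    expect_false(any(inside))
  }
})

test_that("goal loops add two 41-view inbound legs at +/-45 degrees", {
  env <- empty_env()
  cfg <- heuristic_config(goal_loops = list())
  loops <- build_goal_loops(env, c(0, 0), c(20, 0), cfg)
  expect_equal(length(loops$views), 82) # 2 x 8.2 m x 5 per metre
  meta <- loops$meta
  expect_true(all(meta$origin == "goal_loop"))
  expect_equal(sort(unique(meta$heading)), c(45, 315))
  # legs end exactly at the goal
  ends <- meta[c(41, 82), ]
  expect_equal(ends$x, c(20, 20))
  expect_equal(ends$y, c(0, 0), tolerance = 1e-12)
  # lateral half-width covered = 8.2 sin(45 deg) = 5.8 m
  first_a <- meta[1, ]
  expect_equal(abs(first_a$y), (8.2 - 0.2) * sin(pi / 4), tolerance = 1e-9)
  start_dist <- sqrt((first_a$x - 20)^2 + first_a$y^2)
  expect_equal(start_dist, 8.2 - 0.2, tolerance = 1e-9)
  expect_equal(8.2 * sin(pi / 4), 5.8, tolerance = 0.02)
  # a goal-loop training run appends the extra views
  tr <- build_training_route(env, c(0, 0), c(4, 0), cfg, master_seed = 2,
                             train_network = FALSE)
  expect_equal(nrow(tr$view_meta), 20 + 82)
})
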