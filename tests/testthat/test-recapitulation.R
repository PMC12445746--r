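test_that("RFF sampling follows the psi enumeration and scan range", {
  fx <- baseline_training()
  net <- fx$training$network
  p <- pose(1, 0, 10)
  rff <- compute_rff(net, fx$env, p, phi = 360)
  expect_equal(nrow(rff), 180)
  expect_equal(rff$psi, seq(-180, 178, by = 2))
  expect_true(all(rff$novelty >= 0 & rff$novelty <= 1))
  small <- compute_rff(net, fx$env, p, phi = 36)
  expect_equal(nrow(small), 18)
  expect_equal(small$psi, seq(-18, 16, by = 2))
  # the head scan is a contiguous slice of the full scan (same rendering)
  expect_equal(small$novelty,
               rff$novelty[rff$psi >= -18 & rff$psi <= 16])
  expect_error(compute_rff(net, fx$env, p, phi = 500), "phi")
})

test_that("RFF is shift-equivariant under physical rotation of the agent", {
  fx <- baseline_training()
  net <- fx$training$network
  for (k in c(7, 45, 90)) {
    r0 <- compute_rff(net, fx$env, pose(2, 0.5, 20))
    rk <- compute_rff(net, fx$env, pose(2, 0.5, 20 + 2 * k))
    # rotating the agent by k * rho shifts the novelty samples by -k
    expect_equal(rk$novelty, r0$novelty[((0:179 + k) %% 180) + 1],
                 tolerance = 1e-12)
  }
})

test_that("on-route noise-free RFF minima sit at psi = 0 within one sample", {
  fx <- baseline_training()
  net <- fx$training$network
  meta <- fx$training$view_meta
  hits <- vapply(seq(20, 80, by = 15), function(i) {
    rff <- compute_rff(net, fx$env,
                       pose(meta$x[i], meta$y[i], meta$heading[i]))
    abs(vbo_heading(rff)) <= 2
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("the VBO heading is the argmin with straight-ahead tie-breaking", {
  mk <- function(psi, d) {
    structure(tibble::tibble(psi = psi, novelty = d),
              class = c("ant_rff", class(tibble::tibble())))
  }
  psi <- seq(-180, 178, by = 2)
  d <- rep(0.9, 180)
  d[91] <- 0.1 # psi = 0
  expect_equal(vbo_heading(mk(psi, d)), 0)
  d2 <- rep(0.9, 180)
  d2[1] <- 0.05 # first sample
  expect_equal(vbo_heading(mk(psi, d2)), -180)
  # argmin index 1 (0-based) of a full scan: 2 * 1 - 180 = -178
  d3 <- rep(0.9, 180)
  d3[2] <- 0.2
  expect_equal(vbo_heading(mk(psi, d3)), -178)
  # ties break towards the smallest |psi|
  d4 <- rep(0.9, 180)
  d4[c(31, 101, 151)] <- 0.3 # psi -120, +20, +120
  expect_equal(vbo_heading(mk(psi, d4)), 20)
  expect_error(vbo_heading(mk(numeric(0), numeric(0))), "empty")
})

test_that("FBM limit cases follow the printed turn and step laws", {
  out0 <- fbm_step(0, n = 0)
  expect_equal(out0$theta, 0)
  expect_equal(out0$step, 0.60) # beta + s_min = 0.15 + 0.45
  out1 <- fbm_step(1, n = 0)
  expect_equal(out1$theta, 80)
  expect_equal(out1$step, 0.45)
  expect_equal(fbm_step(1, n = 1)$theta, -80)
  expect_equal(fbm_step(0.5, n = 2)$theta, 40)
  expect_equal(fbm_step(0.5, n = 2)$step, 0.15 * 0.5 + 0.45)
})

test_that("cast amplitude scales with best novelty and alternates sign", {
  expect_equal(cast_heading(12, 0, n = 0), 12) # m = 0: pure VBO
  expect_equal(cast_heading(0, 1, n = 0), 60)
  expect_equal(cast_heading(0, 1, n = 1), -60)
  expect_equal(cast_heading(10, 0.5, n = 1), 10 - 30)
})

test_that("surging suppresses rotation exactly when novelty improves", {
  expect_equal(cast_and_surge_heading(25, delta_d = -0.1), 0)
  expect_equal(cast_and_surge_heading(25, delta_d = 0), 25) # boundary: cast
  expect_equal(cast_and_surge_heading(25, delta_d = 0.2), 25)
  expect_equal(cast_and_surge_heading(25, delta_d = NA), 25) # first step
})

test_that("scan-range modulation interpolates and skips small body scans", {
  expect_equal(modulated_scan_range(0, 36, 360), 36)
  expect_equal(modulated_scan_range(1, 36, 360), 360)
  expect_equal(modulated_scan_range(0.5, 36, 160), 98) # 36 + 0.5 * 124
  expect_error(modulated_scan_range(0.5, 36, 20), "phi_max")
})

test_that("termination rules: goal radius and the 1.5x path cap", {
  fx <- baseline_training()
  # released at the goal: immediate termination, zero path
  at_goal <- recapitulate(fx$env, fx$training, pose(20, 0, 0),
                          recap_config(strategy = "FBM"), seed = 1)
  expect_equal(at_goal$termination, "goal")
  expect_equal(nrow(at_goal$steps), 0)
  expect_equal(nrow(at_goal$route$poses), 1)
  # a run that never reaches the goal is capped at 1.5 x 20 m = 30 m
  fbm <- recapitulate(fx$env, fx$training, pose(0, 2, 0),
                      recap_config(strategy = "FBM"), seed = 2)
  if (fbm$termination == "max_path") {
    expect_gte(sum(fbm$steps$step_size), 30)
    expect_lt(sum(fbm$steps$step_size) - max(fbm$steps$step_size), 30)
  }
  # FBM turn signs alternate whenever novelty is positive
  s <- fbm$steps
  active <- which(s$m > 0)
  run <- active[active > 1 & (active - 1) %in% active]
  if (length(run) > 3) {
    expect_true(all(sign(s$theta[run]) != sign(s$theta[run - 1])))
  }
})

test_that("noise-free on-route VBO stays within the route corridor", {
  # straight, obstacle-free route with a noise-free test agent
  env <- trial_env(9)
  cfg <- heuristic_config(m_frac = 8)
  tr <- build_training_route(env, c(0, 0), c(10, 0), cfg, master_seed = 21)
  rc <- recap_config(strategy = "VBO", motor_noise_sd = 0)
  r <- recapitulate(env, tr, pose(0, 0, 0), rc, seed = 3)
  expect_lt(route_displacement(tr$route, r), 0.75)
})

test_that("cast-and-surge reduces to VBO when all novelty reads zero", {
  fx <- baseline_training()
  forced <- fx$training
  # calibration forced so every view normalises (and clamps) to d = 0
  forced$network$calibration$d_min <- 1e12
  forced$network$calibration$d_max <- 2e12
  rc_cs <- recap_config(strategy = "CS", cs = list(s_cs = 0.2))
  rc_vbo <- recap_config(strategy = "VBO")
  r_cs <- recapitulate(fx$env, forced, pose(0, 1, 0), rc_cs, seed = 5)
  r_vbo <- recapitulate(fx$env, forced, pose(0, 1, 0), rc_vbo, seed = 5)
  expect_equal(r_cs$route$poses[c("x", "y", "heading")],
               r_vbo$route$poses[c("x", "y", "heading")])
  expect_true(all(r_cs$steps$m == 0))
  expect_false(any(r_cs$steps$surged)) # delta_d = 0 casts, amplitude 0
})

test_that("per-step interrogation counts follow the scan bookkeeping", {
  fx <- baseline_training()
  short <- function(cfg, seed = 4) {
    r <- recapitulate(fx$env, fx$training, pose(0, 4, 0), cfg, seed = seed)
    r$steps
  }
  vbo <- short(recap_config(strategy = "VBO"))
  expect_true(all(vbo$interrogations == 180))
  fbm <- short(recap_config(strategy = "FBM"))
  expect_true(all(fbm$interrogations == 1))
  fixed <- short(recap_config(strategy = "CS",
                              scan = list(phi_max = 160, modulated = FALSE)))
  expect_true(all(fixed$interrogations == 160 / 2 + 36 / 2))
  mod <- short(recap_config(strategy = "CS",
                            scan = list(phi_max = 160, modulated = TRUE)))
  expect_true(all(mod$interrogations <= 160 / 2 + 36 / 2))
  expect_true(all(mod$interrogations >= 36 / 2))
  # scan ranges recorded per step stay within [phi_min, phi_max]
  expect_true(all(mod$scan_range >= 36 & mod$scan_range <= 160))
})

test_that("strategy headings are invariant to rigid world relabelling", {
  # translating and rotating world coordinates (environment, route and
  # agent together) leaves the strategy's relative headings unchanged
  fx <- baseline_training()
  shift <- c(13, -7)
  rot <- 90
  lm <- fx$env$landmarks
  rotxy <- function(x, y) {
    cbind(x * cos(rot * pi / 180) - y * sin(rot * pi / 180),
          x * sin(rot * pi / 180) + y * cos(rot * pi / 180))
  }
  lm2 <- lm
  xy <- rotxy(lm$x, lm$y)
  lm2$x <- xy[, 1] + shift[1]
  lm2$y <- xy[, 2] + shift[2]
  env2 <- env_from_landmarks(lm2, extent = fx$env$extent)
  p1 <- pose(2, 1, 15)
  xy_p <- rotxy(2, 1)
  p2 <- pose(xy_p[1] + shift[1], xy_p[2] + shift[2], 15 + rot)
  r1 <- compute_rff(fx$training$network, fx$env, p1)
  r2 <- compute_rff(fx$training$network, env2, p2)
  expect_equal(r2$novelty, r1$novelty, tolerance = 1e-9)
  expect_equal(vbo_heading(r2), vbo_heading(r1))
})
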