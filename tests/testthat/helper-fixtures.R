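# Shared fixtures, built in code. Expensive objects (a trained baseline
# route) are memoised for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# an environment built from an explicit landmark table (bypasses the
# generator so scenes can be constructed exactly)
env_from_landmarks <- function(landmarks, extent = 200) {
  structure(
    list(seed = 0L, extent = extent,
         density = nrow(landmarks) / extent^2, center = c(0, 0),
         landmarks = tibble::as_tibble(landmarks)),
    class = "ant_environment"
  )
}

# a single cylindrical tree (trunk and canopy share one radius, so the
# silhouette is a simple box and analytic geometry applies)
single_tree_env <- function(x, y, radius, height) {
  env_from_landmarks(tibble::tibble(
    x = x, y = y, trunk_radius = radius, canopy_radius = radius,
    height = height
  ))
}

empty_env <- function(extent = 100) {
  env_from_landmarks(tibble::tibble(
    x = numeric(0), y = numeric(0), trunk_radius = numeric(0),
    canopy_radius = numeric(0), height = numeric(0)
  ), extent = extent)
}

# the standard small trial world: 20 m route through a default-density wood
trial_env <- function(seed_index = 1, master = 1, L = 20) {
  generate_environment(child_seed(master, "env", seed_index),
                       extent = L + 110, density = 0.007,
                       center = c(L / 2, 0))
}

# one trained baseline route shared across test files (reduced network)
baseline_training <- function() {
  fixture("baseline_training", function() {
    L <- 20
    env <- trial_env(1, master = 1, L = L)
    cfg <- heuristic_config(m_frac = 8)
    list(env = env,
         training = build_training_route(env, c(0, 0), c(L, 0), cfg,
                                         master_seed = 11))
  })
}

# hand-rolled single-step oracle of the Infomax learning rule, element
# loops only
infomax_update_oracle <- function(W, s, eta, denom) {
  M <- nrow(W)
  N <- ncol(W)
  h <- numeric(M)
  for (i in 1:M) for (j in 1:N) h[i] <- h[i] + W[i, j] * s[j]
  y <- tanh(h)
  W_new <- W
  for (i in 1:M) {
    for (j in 1:N) {
      u_j <- 0
      for (k in 1:M) u_j <- u_j + h[k] * W[k, j]
      W_new[i, j] <- W[i, j] + (eta / denom) * (W[i, j] - (y[i] + h[i]) * u_j)
    }
  }
  W_new
}

# brute-force route-displacement oracle: per training position, scan all
# test positions with explicit loops
brute_displacement <- function(train, test) {
  tot <- 0
  for (i in seq_len(nrow(train))) {
    best <- Inf
    for (j in seq_len(nrow(test))) {
      d <- sqrt(sum((train[i, ] - test[j, ])^2))
      if (d < best) best <- d
    }
    tot <- tot + best
  }
  tot / nrow(train)
}

# independent per-pixel ray-casting oracle for single-cylinder scenes:
# sub-samples each pixel at 0.5 degrees and marks it dark when at least
# half of the sub-rays hit the cylinder within the clipping distance
raycast_oracle <- function(env, p, clip = 50, sub = 0.5) {
  lm <- env$landmarks
  stopifnot(nrow(lm) == 1)
  eye <- 0.01
  cx <- lm$x - p$x
  cy <- lm$y - p$y
  d <- sqrt(cx^2 + cy^2)
  bearing <- atan2(cy, cx) * 180 / pi
  hit <- function(az_world, el) {
    delta <- ((az_world - bearing + 180) %% 360) - 180
    if (abs(delta) >= 90) return(FALSE)
    perp <- d * abs(sin(delta * pi / 180))
    if (perp > lm$trunk_radius) return(FALSE)
    t_hit <- d * cos(delta * pi / 180) -
      sqrt(lm$trunk_radius^2 - perp^2)
    if (t_hit > clip || t_hit <= 0) return(FALSE)
    z <- eye + t_hit * tan(el * pi / 180)
    z >= 0 && z <= lm$height
  }
  grid <- matrix(1, 36, 180)
  offs <- seq(-1 + sub / 2, 1 - sub / 2, by = sub) # within a 2-degree pixel
  for (col in 1:180) {
    az_center <- -181 + 2 * col + p$heading
    for (row in 1:36) {
      el_center <- 73 - 2 * row
      hits <- 0
      for (da in offs) for (de in offs) {
        if (hit(az_center + da, el_center + de)) hits <- hits + 1
      }
      if (hits >= length(offs)^2 / 2) grid[row, col] <- 0
    }
  }
  grid
}
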