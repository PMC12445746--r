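# Infomax familiarity network: a single fully connected layer trained with
# the anti-Hebbian Infomax rule. Trained outputs respond weakly to views
# resembling the training set, so the summed absolute activation acts as a
# novelty signal. Raw novelty is normalised to [0, 1] between the mean
# response to training views (d_min) and to column-scrambled training views
# (d_max), the latter being environment-like but spatially incoherent.

# row-major flattening (row 1 first); must match between training and query
flatten_view <- function(view) {
  if (is.matrix(view)) as.numeric(t(unclass(view))) else as.numeric(view)
}

#' Initialise an Infomax familiarity network
#'
#' Weights are drawn uniformly in \[-0.5, 0.5\] and then standardised to
#' global mean 0 and standard deviation 1. The number of output units
#' defaults to half the input size.
#'
#' @param n_input input size N (pixels of a flattened view).
#' @param n_output number of output units M (default `n_input / 2`; smaller
#'   values, e.g. `n_input / 8`, trade discrimination for speed).
#' @param eta learning rate (default 0.4; see the methods vignette).
#' @param seed integer seed for weight initialisation.
#' @param weight_norm update normalisation: `"MN"` (default) divides the
#'   weight update by M * N; `"N"` divides by N only, the form common in
#'   earlier Infomax familiarity work. With binary panoramas (input norm of
#'   order N) the per-update gain is about `eta * |h|^2 / denom`; dividing
#'   by M * N keeps it well below 1 for any output size, whereas dividing by
#'   N alone is unstable once M is more than a few units.
#' @return an `infomax_network`: list with weight matrix `W` (M x N), sizes,
#'   learning rate, view counter and (once calibrated) a calibration.
#' @export
infomax_network <- function(n_input, n_output = n_input / 2, eta = 0.4,
                            seed = 1, weight_norm = c("MN", "N")) {
  weight_norm <- match.arg(weight_norm)
  if (n_input < 1 || n_output < 1) {
    stop("`n_input` and `n_output` must be positive", call. = FALSE)
  }
  n_input <- as.integer(n_input)
  n_output <- as.integer(n_output)
  W <- withr::with_seed(as.integer(seed), {
    matrix(runif(n_output * n_input, -0.5, 0.5), n_output, n_input)
  })
  W <- (W - mean(W)) / sd(W)
  structure(
    list(W = W, n_input = n_input, n_output = n_output, eta = eta,
         weight_norm = weight_norm, trained_views = 0L, calibration = NULL),
    class = "infomax_network"
  )
}

#' @export
print.infomax_network <- function(x, ...) {
  cat(sprintf(
    "<infomax_network> %d -> %d units, eta = %g, trained on %d views%s\n",
    x$n_input, x$n_output, x$eta, x$trained_views,
    if (is.null(x$calibration)) " (uncalibrated)" else " (calibrated)"
  ))
  invisible(x)
}

check_input <- function(net, s) {
  if (length(s) != net$n_input) {
    stop(sprintf("view has %d pixels but the network expects %d",
                 length(s), net$n_input), call. = FALSE)
  }
  s
}

#' Output-unit activations for a view
#'
#' The linear response `h = W s` of the network to a flattened view.
#'
#' @param net an `infomax_network`.
#' @param view a `pano_view` or numeric vector of length `n_input`.
#' @return numeric vector of length `n_output`.
#' @export
infomax_activations <- function(net, view) {
  s <- check_input(net, flatten_view(view))
  drop(net$W %*% s)
}

#' Train the network on a single view
#'
#' Applies one Infomax weight update for the view: with `h = W s`,
#' `y = tanh(h)` and `u_j = sum_k h_k w_kj`, the update is
#' `dW = eta / (M N) * (W - (y + h) u')` (or `eta / N` under the `"N"`
#' normalisation). Each training view is applied exactly once and then
#' discarded.
#'
#' @inheritParams infomax_activations
#' @return the updated network.
#' @export
infomax_train <- function(net, view) {
  s <- check_input(net, flatten_view(view))
  h <- drop(net$W %*% s)
  y <- tanh(h)
  u <- drop(crossprod(net$W, h)) # u_j = sum_k h_k w_kj
  denom <- switch(net$weight_norm,
    N = net$n_input,
    MN = as.numeric(net$n_output) * net$n_input
  )
  gain <- net$eta / denom
  net$W <- (1 + gain) * net$W - tcrossprod(gain * (y + h), u)
  net$trained_views <- net$trained_views + 1L
  net
}

#' Raw novelty of a view
#'
#' The summed absolute activation `sum_i |h_i|`; low for views resembling the
#' training set, higher for unfamiliar views.
#'
#' @inheritParams infomax_activations
#' @return a non-negative scalar in raw-novelty units.
#' @export
raw_novelty <- function(net, view) {
  sum(abs(infomax_activations(net, view)))
}

# batch raw novelty: S is an n_input x k matrix of flattened views
raw_novelty_batch <- function(net, S) {
  colSums(abs(net$W %*% S))
}

#' Calibrate the novelty normalisers of a trained network
#'
#' Passes a sample of the training views (by default all of them) through the
#' trained network to estimate the minimum expected novelty `d_min`, and the
#' same sample with randomly scrambled columns to estimate the maximum
#' `d_max`. Scramble permutations are drawn per view from `seed`.
#'
#' @param net a trained `infomax_network`.
#' @param training_views list of views the network was trained on.
#' @param n_samples number of views to sample (default: all).
#' @param seed integer seed for the scramble permutations (and the sample,
#'   when `n_samples` is smaller than the training set).
#' @return a `novelty_calibration`: list with `d_min`, `d_max`, `n_samples`.
#' @export
calibrate_novelty <- function(net, training_views,
                              n_samples = length(training_views), seed = 1) {
  if (length(training_views) == 0) {
    stop("no training views to calibrate on", call. = FALSE)
  }
  n_samples <- min(n_samples, length(training_views))
  idx <- if (n_samples < length(training_views)) {
    withr::with_seed(child_seed(seed, "calibration-sample"),
                     sample.int(length(training_views), n_samples))
  } else {
    seq_along(training_views)
  }
  plain <- vapply(training_views[idx], function(v) raw_novelty(net, v),
                  numeric(1))
  scrambled <- vapply(seq_along(idx), function(i) {
    v <- scramble_columns(training_views[[idx[i]]],
                          child_seed(seed, "scramble", i))
    raw_novelty(net, v)
  }, numeric(1))
  d_min <- mean(plain)
  d_max <- mean(scrambled)
  if (d_max <= d_min) {
    stop("novelty calibration failed: scrambled views are no more novel ",
         "than training views (degenerate environment?)", call. = FALSE)
  }
  structure(list(d_min = d_min, d_max = d_max, n_samples = n_samples),
            class = "novelty_calibration")
}

#' Normalised novelty of a view
#'
#' Linearly rescales raw novelty between the calibrated `d_min` (-> 0,
#' highly familiar) and `d_max` (-> 1, highly novel), clamped to `[0, 1]` so
#' downstream controllers can treat it as a proportion.
#'
#' @inheritParams infomax_activations
#' @param calib a `novelty_calibration` (defaults to the one attached to the
#'   network by the training pipeline).
#' @return a scalar in `[0, 1]`.
#' @export
novelty <- function(net, view, calib = net$calibration) {
  if (is.null(calib)) stop("network is not calibrated", call. = FALSE)
  d <- (raw_novelty(net, view) - calib$d_min) / (calib$d_max - calib$d_min)
  min(max(d, 0), 1)
}

novelty_batch <- function(net, S, calib = net$calibration) {
  d <- (raw_novelty_batch(net, S) - calib$d_min) / (calib$d_max - calib$d_min)
  pmin(pmax(d, 0), 1)
}
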