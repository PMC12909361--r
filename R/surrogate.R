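#' Specify the neural surrogate architecture
#'
#' A fully connected `tanh` network maps (scaled) time to per-state moment
#' outputs. Each observed state owns two output channels (central tendency
#' and spread, the spread being a variance or an SD depending on
#' `spread`); each unobserved state owns a single central-tendency channel.
#' All outputs pass through `softplus` (plus a small positive bias on
#' spread channels) so moments are strictly positive, and are then mapped
#' to the data scale by the min-max unscaling in `scaling`.
#'
#' @param hidden_layers Number of hidden layers, >= 1.
#' @param hidden_width Nodes per hidden layer, >= 1.
#' @param n_observed Number of observed states (each gets 2 channels).
#' @param n_unobserved Number of unobserved states (1 channel each).
#' @param spread `"variance"` or `"sd"`: what the spread channel encodes.
#' @param spread_bias Positive floor added after softplus on spread
#'   channels (default `1e-6`).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(hidden_layers = 2L, hidden_width = 3L,
                         n_observed = 1L, n_unobserved = 0L,
                         spread = c("variance", "sd"), spread_bias = 1e-6) {
  spread <- match.arg(spread)
  stopifnot(hidden_layers >= 1, hidden_width >= 1, n_observed >= 1,
            n_unobserved >= 0)
  n_out <- 2L * n_observed + n_unobserved
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_width = as.integer(hidden_width),
                 n_observed = as.integer(n_observed),
                 n_unobserved = as.integer(n_unobserved),
                 n_out = n_out, spread = spread, spread_bias = spread_bias,
                 layer_sizes = c(1L, rep(as.integer(hidden_width), hidden_layers),
                                 n_out)),
            class = "network_spec")
}

#' Min-max scaling specification for surrogate outputs
#'
#' Per output channel, the network's softplus output is interpreted on the
#' scaled `[0, 1]`-ish scale and mapped back by
#' `x = x_min + (x_max - x_min) * x_scaled`. Identity scaling is
#' `(x_min, x_max) = (0, 1)`.
#'
#' @param x_min,x_max Numeric vectors, one entry per output channel, with
#'   `x_max > x_min` elementwise.
#' @return An object of class `scaling_spec`.
#' @export
scaling_spec <- function(x_min, x_max) {
  if (length(x_min) != length(x_max)) stop("x_min/x_max length mismatch")
  if (any(x_max <= x_min)) stop("x_max must exceed x_min")
  structure(list(x_min = as.numeric(x_min), x_max = as.numeric(x_max)),
            class = "scaling_spec")
}

#' Identity scaling for a network spec
#' @param spec A [network_spec()].
#' @return A [scaling_spec()] with `(0, 1)` bounds on every channel.
#' @export
identity_scaling <- function(spec) {
  scaling_spec(rep(0, spec$n_out), rep(1, spec$n_out))
}

#' Initialise network weights (Glorot normal)
#'
#' Weights `W_l ~ N(0, 2 / (fan_in + fan_out))`, biases zero. Uses the
#' current RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param spec A [network_spec()].
#' @return List of `W` (out x in matrices) and `b` (vectors) per layer.
#' @export
init_network <- function(spec) {
  sizes <- spec$layer_sizes
  L <- length(sizes) - 1L
  weights <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    sd <- sqrt(2 / (fan_in + fan_out))
    weights[[l]] <- list(
      W = matrix(stats::rnorm(fan_out * fan_in, 0, sd), fan_out, fan_in),
      b = rep(0, fan_out)
    )
  }
  weights
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))

# Doubled forward pass: propagates both the activation and its derivative
# with respect to (unscaled) time through the network, returning outputs on
# the data scale together with their exact time derivatives. This is the
# workhorse behind forward_moments() / time_derivatives().
surrogate_forward <- function(weights, spec, t, scaling,
                              t_range = c(0, 1),
                              paper_literal_sd_scaling = FALSE,
                              input_log_time = FALSE) {
  nt <- length(t)
  span <- t_range[2] - t_range[1]
  if (input_log_time) {
    # log-warped time input: uniform resolution across decades
    ls <- log1p(span)
    a <- matrix(log1p(t - t_range[1]) / ls, 1, nt)
    adot <- matrix(1 / ((1 + t - t_range[1]) * ls), 1, nt)
  } else {
    a <- matrix((t - t_range[1]) / span, 1, nt)
    adot <- matrix(1 / span, 1, nt)
  }
  L <- length(weights)
  for (l in seq_len(L - 1L)) {
    z <- weights[[l]]$W %*% a + weights[[l]]$b
    zdot <- weights[[l]]$W %*% adot
    a <- tanh(z)
    adot <- (1 - a^2) * zdot
  }
  z <- weights[[L]]$W %*% a + weights[[L]]$b
  zdot <- weights[[L]]$W %*% adot
  y_scaled <- softplus(z)
  ydot_scaled <- sigmoid(z) * zdot
  # spread channels carry a small positive bias so SD/variance never hit 0
  is_spread <- rep(FALSE, spec$n_out)
  if (spec$n_observed >= 1) is_spread[seq(2, 2 * spec$n_observed, by = 2)] <- TRUE
  y_scaled[is_spread, ] <- y_scaled[is_spread, , drop = FALSE] + spec$spread_bias
  span_out <- scaling$x_max - scaling$x_min
  deriv_factor <- span_out
  if (paper_literal_sd_scaling && spec$spread == "sd") {
    deriv_factor[is_spread] <- span_out[is_spread]^2
  }
  outputs <- t(scaling$x_min + span_out * y_scaled)
  derivs <- t(deriv_factor * ydot_scaled)
  list(outputs = outputs, derivs = derivs)
}

#' Evaluate the surrogate's moment outputs
#'
#' Runs the network on a batch of times and returns the (unscaled,
#' strictly positive) per-channel outputs: observed-state mean and spread
#' first, then unobserved-state means.
#'
#' @param weights Network weights from [init_network()] (or a fit).
#' @param spec A [network_spec()].
#' @param t Times (hours).
#' @param scaling A [scaling_spec()]; identity by default.
#' @param t_range Time-input normalisation interval (the training domain).
#' @param input_log_time Feed `log1p`-warped time to the network (used for
#'   horizons spanning several decades).
#' @return Matrix `length(t) x n_out` of outputs.
#' @export
forward_moments <- function(weights, spec, t, scaling = identity_scaling(spec),
                            t_range = c(0, 1), input_log_time = FALSE) {
  surrogate_forward(weights, spec, t, scaling, t_range,
                    input_log_time = input_log_time)$outputs
}

#' Time derivatives of the surrogate's outputs
#'
#' Exact derivatives of each output channel with respect to time, computed
#' by tangent propagation through the network and mapped to the data scale
#' with the linear chain-rule factor `(x_max - x_min)`. Setting
#' `paper_literal_sd_scaling = TRUE` applies a squared factor to SD
#' channels instead (a printed-formula variant kept for comparison; the
#' linear factor is the chain-rule-consistent default).
#'
#' @inheritParams forward_moments
#' @param paper_literal_sd_scaling Use the squared factor on SD channels.
#' @return Matrix `length(t) x n_out` of time derivatives.
#' @export
time_derivatives <- function(weights, spec, t, scaling = identity_scaling(spec),
                             t_range = c(0, 1),
                             paper_literal_sd_scaling = FALSE,
                             input_log_time = FALSE) {
  surrogate_forward(weights, spec, t, scaling, t_range,
                    paper_literal_sd_scaling, input_log_time)$derivs
}

# Flatten network weights into a single vector (column-major W then b per
# layer); unflatten reverses. Shared layout with the compiled trainer.
flatten_weights <- function(weights) {
  unlist(lapply(weights, function(l) c(as.numeric(l$W), l$b)))
}

unflatten_weights <- function(par, spec) {
  sizes <- spec$layer_sizes
  L <- length(sizes) - 1L
  weights <- vector("list", L)
  pos <- 1L
  for (l in seq_len(L)) {
    n_in <- sizes[l]; n_out <- sizes[l + 1L]
    nw <- n_out * n_in
    weights[[l]] <- list(
      W = matrix(par[pos:(pos + nw - 1L)], n_out, n_in),
      b = par[(pos + nw):(pos + nw + n_out - 1L)]
    )
    pos <- pos + nw + n_out
  }
  weights
}

n_weight_params <- function(spec) {
  sizes <- spec$layer_sizes
  sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
}
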