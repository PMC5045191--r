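#' Minimal triplet STDP parameters
#'
#' Amplitudes and trace time constants of the minimal triplet STDP rule
#' `dw/dt = A_plus * y(t) * ybar_plus(t-) * xbar_plus(t-) - A_minus * x(t) * ybar_minus(t-)`
#' where `x`, `y` are pre-/post-synaptic spike trains and the bars are
#' low-pass traces with time constants `tau_plus` (post, LTP), `tau_x` (pre)
#' and `tau_minus` (post, LTD). Defaults are the visual-cortex fit.
#'
#' Two trace conventions are supported, and the LTD factor of the rate
#' reduction depends on which is used:
#' `"unit_area"` increments a trace by the reciprocal of its time constant in
#' seconds, so the trace estimates the instantaneous rate in Hz (this is the
#' integral form `tau dybar/dt = -ybar + y`); `"jump_by_one"` increments by 1.
#'
#' @param A_plus,A_minus dimensionless LTP/LTD amplitudes.
#' @param tau_plus,tau_x,tau_minus trace time constants, ms.
#' @param trace_convention `"unit_area"` or `"jump_by_one"`.
#' @export
triplet_params <- function(A_plus = 6.5e-3, A_minus = 5.3e-3,
                           tau_plus = 114.0, tau_x = 16.8, tau_minus = 33.7,
                           trace_convention = c("unit_area", "jump_by_one")) {
  trace_convention <- match.arg(trace_convention)
  if (any(c(tau_plus, tau_x, tau_minus) <= 0)) {
    nlh_stop("trace time constants must be positive", "nlhebb_configuration_error")
  }
  structure(list(A_plus = A_plus, A_minus = A_minus, tau_plus = tau_plus,
                 tau_x = tau_x, tau_minus = tau_minus,
                 trace_convention = trace_convention),
            class = "triplet_params")
}

trace_increments <- function(params) {
  if (params$trace_convention == "jump_by_one") {
    c(y_plus = 1, x_plus = 1, y_minus = 1)
  } else {
    # 1/tau with tau in seconds: traces read out the rate in Hz.
    c(y_plus = 1000 / params$tau_plus, x_plus = 1000 / params$tau_x,
      y_minus = 1000 / params$tau_minus)
  }
}

#' Spike train
#'
#' Strictly increasing spike times in ms within `[0, duration)`.
#'
#' @param times numeric vector, ms.
#' @param duration total duration, ms.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    nlh_stop("spike times must be strictly increasing", "nlhebb_input_error")
  }
  if (length(times) && (times[1] < 0 || times[length(times)] >= duration)) {
    nlh_stop("spike times must lie in [0, duration)", "nlhebb_input_error")
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

poisson_train <- function(rate_hz, duration_ms) {
  n <- stats::rpois(1, rate_hz * duration_ms / 1000)
  spike_train(unique(sort(stats::runif(n, 0, duration_ms))) * (1 - 1e-12), duration_ms)
}

#' Simulate minimal triplet STDP on a spike-train pair
#'
#' Event-driven evaluation: traces decay exponentially between spikes; at each
#' post-synaptic spike the weight change gains
#' `A_plus * ybar_plus(t-) * xbar_plus(t-)`; at each pre-synaptic spike it
#' loses `A_minus * ybar_minus(t-)`. Traces are read strictly before the
#' current spike's own increment; simultaneous pre/post spikes are processed
#' pre first.
#'
#' @param pre,post [spike_train()]s over a common duration.
#' @param params a [triplet_params()].
#' @param init_traces optional starting trace values
#'   `c(y_plus, x_plus, y_minus)`, for chaining windows.
#' @return total weight change (scalar) with attribute `traces`, the trace
#'   values decayed to the end of the duration.
#' @export
simulate_triplet <- function(pre, post, params, init_traces = c(0, 0, 0)) {
  stopifnot(inherits(pre, "spike_train"), inherits(post, "spike_train"),
            inherits(params, "triplet_params"))
  duration <- max(pre$duration, post$duration)
  inc <- trace_increments(params)
  times <- c(pre$times, post$times)
  type <- c(rep(0L, length(pre$times)), rep(1L, length(post$times)))
  o <- order(times, type)  # pre before post at equal timestamps
  times <- times[o]; type <- type[o]

  yp <- init_traces[1]; xp <- init_traces[2]; ym <- init_traces[3]
  tp <- params$tau_plus; tx <- params$tau_x; tm <- params$tau_minus
  Ap <- params$A_plus; Am <- params$A_minus
  iyp <- inc[["y_plus"]]; ixp <- inc[["x_plus"]]; iym <- inc[["y_minus"]]
  dw <- 0; tlast <- 0
  for (i in seq_along(times)) {
    dt <- times[i] - tlast
    if (dt > 0) {
      yp <- yp * exp(-dt / tp)
      xp <- xp * exp(-dt / tx)
      ym <- ym * exp(-dt / tm)
      tlast <- times[i]
    }
    if (type[i] == 0L) {
      dw <- dw - Am * ym
      xp <- xp + ixp
    } else {
      dw <- dw + Ap * yp * xp
      yp <- yp + iyp
      ym <- ym + iym
    }
  }
  dt <- duration - tlast
  out <- dw
  attr(out, "traces") <- c(y_plus = yp * exp(-dt / tp), x_plus = xp * exp(-dt / tx),
                           y_minus = ym * exp(-dt / tm))
  out
}

#' Dense-grid reference integrator for triplet STDP
#'
#' Clock-driven counterpart of [simulate_triplet()]: traces are decayed bin by
#' bin on a regular grid (exact exponential decay factor per bin) and spikes
#' are applied in their bins, pre before post. Used as an independent
#' cross-check of the event-driven simulator.
#'
#' @inheritParams simulate_triplet
#' @param dt grid step, ms (default 0.01).
#' @return total weight change (scalar).
#' @export
simulate_triplet_dense <- function(pre, post, params, dt = 0.01) {
  stopifnot(inherits(pre, "spike_train"), inherits(post, "spike_train"))
  duration <- max(pre$duration, post$duration)
  n_bins <- as.integer(ceiling(duration / dt))
  inc <- trace_increments(params)
  # spikes indexed by bin; within a bin, pre processed before post. The 1e-9
  # guard keeps on-grid spike times in their own bin under floating rounding.
  pre_bin <- floor(pre$times / dt + 1e-9) + 1L
  post_bin <- floor(post$times / dt + 1e-9) + 1L
  dyp <- exp(-dt / params$tau_plus)
  dxp <- exp(-dt / params$tau_x)
  dym <- exp(-dt / params$tau_minus)
  yp <- 0; xp <- 0; ym <- 0; dw <- 0
  ip <- 1L; io <- 1L
  np <- length(pre_bin); no <- length(post_bin)
  for (b in seq_len(n_bins)) {
    while (ip <= np && pre_bin[ip] == b) {
      dw <- dw - params$A_minus * ym
      xp <- xp + inc[["x_plus"]]
      ip <- ip + 1L
    }
    while (io <= no && post_bin[io] == b) {
      dw <- dw + params$A_plus * yp * xp
      yp <- yp + inc[["y_plus"]]
      ym <- ym + inc[["y_minus"]]
      io <- io + 1L
    }
    yp <- yp * dyp; xp <- xp * dxp; ym <- ym * dym
  }
  dw
}

#' Poisson pairing protocol
#'
#' Generates independent pre- and post-synaptic Poisson spike trains per
#' trial (pre-synaptic rate fixed, default 20 Hz) and measures the mean
#' weight-change rate as a function of the post-synaptic rate — the
#' rate-domain plasticity function `h(y)` of the triplet rule.
#'
#' @param post_rates post-synaptic rates, Hz.
#' @param pre_rate pre-synaptic rate, Hz (default 20).
#' @param duration trial duration, seconds (default 100).
#' @param n_trials trials per rate (default 100).
#' @param params a [triplet_params()].
#' @param seed integer seed.
#' @return data.frame with `post_rate`, `mean_dw_rate` (weight change per
#'   second), `se` (standard error over trials), `n_trials`.
#' @export
pairing_curve <- function(post_rates, pre_rate = 20, duration = 100,
                          n_trials = 100, params = triplet_params(), seed = 1L) {
  if (any(post_rates < 0) || pre_rate < 0) {
    nlh_stop("rates must be non-negative", "nlhebb_input_error")
  }
  dur_ms <- duration * 1000
  res <- lapply(seq_along(post_rates), function(i) {
    y <- post_rates[i]
    dws <- with_seed(spawn_seed(seed, paste0("rate", i)), {
      vapply(seq_len(n_trials), function(trial) {
        pre <- poisson_train(pre_rate, dur_ms)
        post <- poisson_train(y, dur_ms)
        as.numeric(simulate_triplet(pre, post, params)) / duration
      }, numeric(1))
    })
    c(mean = mean(dws), se = stats::sd(dws) / sqrt(n_trials))
  })
  data.frame(post_rate = post_rates,
             mean_dw_rate = vapply(res, `[[`, numeric(1), "mean"),
             se = vapply(res, `[[`, numeric(1), "se"),
             n_trials = n_trials)
}

#' Analytic Poisson drift of the triplet rule
#'
#' Expected weight-change rate (per second) for independent stationary
#' Poisson trains, by the stationary trace means: under `"unit_area"`,
#' `A_plus x y^2 - A_minus x y`; under `"jump_by_one"`,
#' `A_plus tau_plus tau_x x y^2 - A_minus tau_minus x y` (time constants in
#' seconds), for `x`, `y` in Hz.
#'
#' @param pre_rate,post_rate rates in Hz.
#' @param params a [triplet_params()].
#' @export
analytic_pairing_drift <- function(pre_rate, post_rate, params) {
  x <- pre_rate; y <- post_rate
  if (params$trace_convention == "unit_area") {
    params$A_plus * x * y^2 - params$A_minus * x * y
  } else {
    (params$A_plus * (params$tau_plus / 1000) * (params$tau_x / 1000)) * x * y^2 -
      (params$A_minus * (params$tau_minus / 1000)) * x * y
  }
}

#' Analytic LTD factor of the rate reduction
#'
#' The post-synaptic rate at which the analytic Poisson drift crosses zero,
#' i.e. the `b` of `h(y) = scale * (y^2 - b y)`:
#' `A_minus/A_plus` under `"unit_area"`,
#' `A_minus tau_minus / (A_plus tau_plus tau_x)` (time constants in seconds)
#' under `"jump_by_one"`. Neither reproduces the published 22.1 Hz for the
#' default amplitudes; see the package vignette.
#'
#' @param params a [triplet_params()].
#' @return LTD factor in Hz.
#' @export
analytic_ltd_factor <- function(params) {
  if (params$trace_convention == "unit_area") {
    params$A_minus / params$A_plus
  } else {
    params$A_minus * (params$tau_minus / 1000) /
      (params$A_plus * (params$tau_plus / 1000) * (params$tau_x / 1000))
  }
}

#' Fit the quadratic rate-plasticity function
#'
#' Least-squares fit of `dw(y) = scale * (y^2 - b * y)` to a pairing curve,
#' returning the scale and the LTD factor `b` (Hz).
#'
#' @param curve a data.frame from [pairing_curve()], or a numeric vector of
#'   post rates.
#' @param dw_rates weight-change rates (ignored when `curve` is a data.frame).
#' @return list with `scale` and `b`.
#' @export
fit_quadratic_plasticity <- function(curve, dw_rates = NULL) {
  if (is.data.frame(curve)) {
    y <- curve$post_rate; dw <- curve$mean_dw_rate
  } else {
    y <- curve; dw <- dw_rates
  }
  if (length(y) < 4) {
    nlh_stop("quadratic fit needs at least 4 rate points", "nlhebb_fit_error")
  }
  if (length(unique(y[y > 0])) < 2) {
    nlh_stop("degenerate design: need at least two distinct positive rates",
             "nlhebb_fit_error")
  }
  co <- stats::coef(stats::lm(dw ~ 0 + I(y^2) + y))
  scale <- unname(co[1])
  if (!is.finite(scale) || scale == 0) {
    nlh_stop("degenerate quadratic fit", "nlhebb_fit_error")
  }
  list(scale = scale, b = -unname(co[2]) / scale)
}

#' Piecewise-linear f-I fit of a cortical spiking neuron
#'
#' The published linear-rectifier fit of a generalized integrate-and-fire
#' pyramidal-neuron model: slope 143 Hz/nA, threshold 0.08 nA. Composing it
#' with [nl_quadratic_plasticity()] (e.g. `b = 22.1` Hz) yields the
#' quadratic-rectifier effective nonlinearity with LTD threshold 0.08 nA and
#' LTP threshold `theta + b/a` nA.
#'
#' @export
nl_gif_fI <- function() nl_piecewise_linear_fI(a_fI = 143, theta_fI = 0.08)
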