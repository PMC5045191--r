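#' Learning configuration
#'
#' Bundles the constants of the learning dynamics: feed-forward and lateral
#' learning rates, the inference solver constants (membrane time constant,
#' Euler step, iteration cap, convergence threshold), the activity-EMA
#' horizon, the f-I curve `g` and plasticity function `h`, and the seed that
#' drives weight initialization and per-epoch sample shuffling.
#'
#' @param eta_w feed-forward learning rate (> 0).
#' @param eta_v lateral (anti-Hebbian) learning rate (>= 0; 0 freezes V).
#' @param tau_u membrane time constant of the inference dynamics (solver time
#'   units).
#' @param dt forward-Euler step; must satisfy `dt < tau_u` (default `tau_u/10`).
#' @param n_iter maximum inference iterations (default 200).
#' @param conv_tol inference convergence threshold on `max|du|` (default 1e-6).
#' @param tau_ema horizon of the exponential moving average of activities, in
#'   samples (default 1000).
#' @param g f-I curve [nonlinearity] (activation of the network units).
#' @param h plasticity [nonlinearity] applied to the rate in the weight
#'   update; `NULL` means identity (`dw ~ x y`).
#' @param seed integer seed.
#' @export
learn_config <- function(eta_w = 0.05, eta_v = 0.02, tau_u = 1, dt = tau_u / 10,
                         n_iter = 200L, conv_tol = 1e-6, tau_ema = 1000,
                         g = nl_linear(), h = NULL, seed = 1L) {
  if (eta_w <= 0) nlh_stop("eta_w must be > 0", "nlhebb_configuration_error")
  if (eta_v < 0) nlh_stop("eta_v must be >= 0", "nlhebb_configuration_error")
  if (dt >= tau_u) nlh_stop("dt must be smaller than tau_u", "nlhebb_configuration_error")
  stopifnot(inherits(g, "nonlinearity"), is.null(h) || inherits(h, "nonlinearity"))
  structure(list(eta_w = eta_w, eta_v = eta_v, tau_u = tau_u, dt = dt,
                 n_iter = as.integer(n_iter), conv_tol = conv_tol,
                 tau_ema = tau_ema, g = g, h = h, seed = as.integer(seed)),
            class = "learn_config")
}

init_weights <- function(d, K, seed) {
  W <- with_seed(seed, matrix(stats::rnorm(d * K), d, K))
  for (j in seq_len(K)) W[, j] <- unit_vec(W[, j])
  W
}

epoch_order <- function(n, seed, epoch) {
  with_seed(spawn_seed(seed, paste0("order", epoch)), sample.int(n))
}

#' One nonlinear Hebbian update with multiplicative normalization
#'
#' `w' = normalize(w + eta * x * f(w'x))`: exactly one evaluation of `f` per
#' step, followed by renormalization to unit L2 norm.
#'
#' @param w unit-norm weight vector.
#' @param x input sample.
#' @param f effective Hebbian [nonlinearity].
#' @param eta learning rate.
#' @return updated unit-norm weight vector.
#' @export
hebbian_step <- function(w, x, f, eta) {
  u <- drop(crossprod(x, w))
  fu <- f$f(u)
  w2 <- w + (eta * fu) * x
  nrm <- sqrt(sum(w2 * w2))
  if (!is.finite(nrm) || nrm == 0) {
    nlh_stop(sprintf("weight norm collapsed after update (eta = %g)", eta),
             "nlhebb_normalization_error")
  }
  w2 / nrm
}

#' Learn a single-neuron receptive field
#'
#' Sequential nonlinear Hebbian learning `w <- normalize(w + eta x f(w'x))`
#' over seeded shuffled passes through the ensemble. Weights are initialized
#' from a zero-mean normal (then normalized). A warning is raised for
#' non-whitened input, where second-order correlations dominate learning.
#'
#' @param ensemble a [patch_ensemble].
#' @param f effective Hebbian [nonlinearity].
#' @param config a [learn_config()]; uses `eta_w` and `seed`.
#' @param n_epochs passes over the ensemble.
#' @param w0 optional initial weights (normalized internally).
#' @param checkpoint_every store a weight snapshot every this many steps
#'   (`NULL` for none).
#' @param eta_schedule optional per-epoch learning rates (length `n_epochs`),
#'   overriding the constant `config$eta_w`.
#' @return a `learn_result`: `w` (final weights), `checkpoints` (matrix,
#'   one row per snapshot, possibly 0-row), `n_steps`.
#' @details The sequential update loop runs compiled; it is step-for-step
#'   identical to iterating [hebbian_step()] (the two paths are cross-checked
#'   in the package tests).
#' @export
learn_single_neuron <- function(ensemble, f, config, n_epochs = 1L, w0 = NULL,
                                checkpoint_every = NULL, eta_schedule = NULL) {
  stopifnot(inherits(f, "nonlinearity"), inherits(config, "learn_config"))
  if (ensemble$whitened == "none") {
    nlh_warn("learning on non-whitened input: second-order correlations will dominate",
             "nlhebb_whitening_warning")
  }
  X <- ensemble_data(ensemble)
  n <- nrow(X); d <- ncol(X)
  w <- if (is.null(w0)) init_weights(d, 1L, config$seed)[, 1] else unit_vec(w0)
  ord <- unlist(lapply(seq_len(n_epochs), function(e) epoch_order(n, config$seed, e)))
  eta <- if (is.null(eta_schedule)) {
    config$eta_w
  } else {
    stopifnot(length(eta_schedule) == n_epochs)
    rep(as.numeric(eta_schedule), each = n)
  }
  res <- tryCatch(
    .hebb_learn_cpp(t(X), w, ord, eta, nl_stage_spec(f),
                    as.integer(checkpoint_every %||% 0L)),
    error = function(e) {
      if (grepl("diverged", conditionMessage(e))) {
        nlh_stop(conditionMessage(e), "nlhebb_instability_error")
      }
      stop(e)
    })
  structure(list(w = res$w, checkpoints = res$checkpoints,
                 n_steps = res$n_steps, config = config),
            class = "learn_result")
}

#' Network state
#'
#' Feed-forward weights `W` (d x K, unit-norm columns), lateral inhibitory
#' weights `V` (K x K, non-negative, zero diagonal), and the activity EMAs
#' `y_mean`.
#'
#' @param W d x K matrix of feed-forward weights.
#' @param V K x K lateral weight matrix (default all zero).
#' @param y_mean K-vector of activity moving averages (default zero).
#' @export
network_state <- function(W, V = NULL, y_mean = NULL) {
  W <- as.matrix(W)
  K <- ncol(W)
  if (is.null(V)) V <- matrix(0, K, K)
  if (is.null(y_mean)) y_mean <- numeric(K)
  norms <- sqrt(colSums(W^2))
  if (any(abs(norms - 1) > 1e-8)) {
    nlh_stop("columns of W must have unit L2 norm", "nlhebb_invalid_specification")
  }
  if (any(V < 0) || any(diag(V) != 0) || !all(dim(V) == K)) {
    nlh_stop("V must be K x K, non-negative, with zero diagonal",
             "nlhebb_invalid_specification")
  }
  structure(list(W = W, V = V, y_mean = y_mean, K = K), class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state: K = %d neurons, d = %d inputs, %d nonzero lateral weights>\n",
              x$K, nrow(x$W), sum(x$V > 0)))
  invisible(x)
}

#' Recurrent inference of network activity
#'
#' Solves the lateral-inhibition fixed point
#' `y_j = g(w_j'x - sum_k v_jk y_k)` by forward-Euler integration of the
#' membrane equation `tau_u du/dt = -u + (W'x - V y)`, `y = g(u)`, starting
#' from `u = 0`, until `max|du| < conv_tol` or `n_iter` steps. With no lateral
#' weights the fixed point `y = g(W'x)` is returned directly (exact).
#'
#' @param state a [network_state()].
#' @param x input sample.
#' @param config a [learn_config()] providing `g`, `tau_u`, `dt`, `n_iter`,
#'   `conv_tol`.
#' @return activity K-vector with attributes `converged` (logical) and
#'   `iterations`.
#' @export
network_inference <- function(state, x, config) {
  gf <- config$g$f
  b <- drop(crossprod(x, state$W))
  if (all(state$V == 0)) {
    y <- gf(b)
    attr(y, "converged") <- TRUE
    attr(y, "iterations") <- 0L
    return(y)
  }
  u <- numeric(state$K)
  y <- gf(u)
  alpha <- config$dt / config$tau_u
  converged <- FALSE
  iter <- 0L
  while (iter < config$n_iter) {
    iter <- iter + 1L
    du <- alpha * (-u + b - drop(state$V %*% y))
    u <- u + du
    if (any(!is.finite(u))) {
      nlh_stop("inference dynamics produced non-finite values",
               "nlhebb_instability_error")
    }
    y <- gf(u)
    if (max(abs(du)) < config$conv_tol) { converged <- TRUE; break }
  }
  attr(y, "converged") <- converged
  attr(y, "iterations") <- iter
  y
}

#' Network activities over a whole ensemble
#'
#' Vectorized counterpart of [network_inference()]: solves the recurrent
#' fixed point for every sample at once (forward Euler on the full activity
#' matrix), convenient for measuring activity statistics after learning.
#'
#' @param state a [network_state()].
#' @param ensemble a [patch_ensemble].
#' @param config a [learn_config()].
#' @return `n_samples x K` activity matrix.
#' @export
network_activities <- function(state, ensemble, config) {
  X <- ensemble_data(ensemble)
  gf <- config$g$f
  B <- X %*% state$W
  if (all(state$V == 0)) return(gf(B))
  U <- matrix(0, nrow(X), state$K)
  Y <- gf(U)
  alpha <- config$dt / config$tau_u
  for (it in seq_len(config$n_iter)) {
    dU <- alpha * (-U + B - Y %*% t(state$V))
    U <- U + dU
    Y <- gf(U)
    if (max(abs(dU)) < config$conv_tol) break
  }
  Y
}

#' Learn a laterally inhibited network
#'
#' Per input sample: recurrent inference, then the Hebbian feed-forward
#' update `dw_j = eta_w * x * h(y_j)` (with `h` identity this is `dw ~ x y`)
#' followed by multiplicative column renormalization, then the anti-Hebbian
#' lateral update `dv_jk = eta_v * (y_j - <y_j>) * y_k`, clamped at
#' `v_jk >= 0` (Dale's constraint) with the diagonal held at zero, and an EMA
#' update of `<y_j>` with horizon `tau_ema` samples. Lateral weights start at
#' zero. At the anti-Hebbian fixed point, pairwise activity covariances
#' vanish.
#'
#' @param ensemble a [patch_ensemble].
#' @param config a [learn_config()] (`g`, `h`, rates, solver constants, seed).
#' @param K number of neurons.
#' @param n_epochs passes over the ensemble.
#' @param state0 optional [network_state()] to resume from (its `K` overrides
#'   the `K` argument).
#' @return a [network_state()] with a `provenance` attribute recording the
#'   non-converged inference fraction (plus a note if it exceeds 10%).
#' @export
network_learning <- function(ensemble, config, K, n_epochs = 1L, state0 = NULL) {
  stopifnot(inherits(config, "learn_config"), K >= 1)
  if (ensemble$whitened == "none") {
    nlh_warn("learning on non-whitened input: second-order correlations will dominate",
             "nlhebb_whitening_warning")
  }
  X <- ensemble_data(ensemble)
  n <- nrow(X); d <- ncol(X)
  if (is.null(state0)) {
    W <- init_weights(d, K, config$seed)
    V <- matrix(0, K, K)
    y_mean <- numeric(K)
  } else {
    stopifnot(inherits(state0, "network_state"))
    W <- state0$W; V <- state0$V; y_mean <- state0$y_mean; K <- state0$K
  }
  ord <- unlist(lapply(seq_len(n_epochs), function(e) epoch_order(n, config$seed, e)))
  h_stages <- if (is.null(config$h)) list() else nl_stage_spec(config$h)
  res <- tryCatch(
    .net_learn_cpp(t(X), W, V, y_mean, ord, config$eta_w, config$eta_v,
                   nl_stage_spec(config$g), h_stages,
                   config$dt / config$tau_u, config$n_iter, config$conv_tol,
                   config$tau_ema),
    error = function(e) {
      if (grepl("diverged", conditionMessage(e))) {
        nlh_stop(conditionMessage(e), "nlhebb_instability_error")
      }
      stop(e)
    })
  state <- network_state(res$W, res$V, res$y_mean)
  frac <- if (res$n_steps > 0) res$n_unconverged / res$n_steps else 0
  prov <- list(n_steps = res$n_steps, unconverged_fraction = frac)
  if (frac > 0.1) {
    nlh_warn(sprintf("inference failed to converge on %.1f%% of samples", 100 * frac),
             "nlhebb_convergence_warning")
    prov$note <- sprintf("inference failed to converge on %.1f%% of samples", 100 * frac)
  }
  attr(state, "provenance") <- prov
  state
}
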