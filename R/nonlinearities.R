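#' Scalar nonlinearities for Hebbian learning
#'
#' A `nonlinearity` bundles a scalar function `f` (the effective Hebbian
#' nonlinearity driving weight updates `dw ~ x f(w'x)`), its antiderivative
#' `F(u) = int_0^u f`, which is the projection-pursuit objective the learning
#' dynamics ascend, and the parameters that define them. Constructors cover
#' the standard model families: rectifiers (linear, quadratic, symmetric),
#' sigmoids, rectified powers, trigonometric and cubic functions, sparse-coding
#' activations derived from L0/L1/Cauchy penalties, a piecewise-linear f-I
#' curve and the quadratic rate-plasticity of triplet STDP.
#'
#' `eval_F` uses the closed-form antiderivative when one exists and falls back
#' to adaptive quadrature from 0 (piecewise over the function's kink points)
#' for composed or tabulated kinds.
#'
#' @name nonlinearity
NULL

new_nonlinearity <- function(kind, params, f, F = NULL, knots = numeric(0),
                             label = kind) {
  structure(list(kind = kind, params = params, f = f, F = F,
                 knots = knots, label = label),
            class = "nonlinearity")
}

#' @export
print.nonlinearity <- function(x, ...) {
  ps <- x$params[!vapply(x$params, is.list, logical(1))]
  pstr <- if (length(ps)) {
    paste(names(ps), vapply(ps, function(v) format(v, digits = 4), ""),
          sep = "=", collapse = ", ")
  } else ""
  cat(sprintf("<nonlinearity: %s%s>\n", x$label,
              if (nzchar(pstr)) paste0(" (", pstr, ")") else ""))
  invisible(x)
}

check_param <- function(params, name, kind) {
  if (is.null(params[[name]]) || !is.finite(params[[name]])) {
    nlh_stop(sprintf("nonlinearity '%s' requires finite parameter '%s'", kind, name),
             "nlhebb_configuration_error")
  }
  params[[name]]
}

#' Evaluate a nonlinearity
#'
#' @param nl a [nonlinearity] object.
#' @param u numeric scalar or vector; finite.
#' @return `f(u)`, element-wise, same shape as `u`.
#' @export
eval_f <- function(nl, u) {
  if (!inherits(nl, "nonlinearity")) {
    nlh_stop("eval_f expects a nonlinearity object", "nlhebb_invalid_specification")
  }
  if (any(!is.finite(u))) nlh_stop("u must be finite", "nlhebb_invalid_specification")
  nl$f(u)
}

#' Evaluate the optimization function F(u) = int_0^u f
#'
#' `F(0) = 0` exactly. Closed forms are used where available; composed and
#' tabulated kinds are integrated by adaptive quadrature from 0, split at the
#' function's kink points (absolute tolerance 1e-10 per call).
#'
#' @inheritParams eval_f
#' @param abs_tol absolute quadrature tolerance for the fallback path.
#' @return `F(u)`, element-wise.
#' @export
eval_F <- function(nl, u, abs_tol = 1e-10) {
  if (!inherits(nl, "nonlinearity")) {
    nlh_stop("eval_F expects a nonlinearity object", "nlhebb_invalid_specification")
  }
  if (!is.null(nl$F)) return(nl$F(u))
  quad_F(nl, u, abs_tol = abs_tol)
}

# Quadrature fallback: cumulative integration through the sorted evaluation
# points so each segment is integrated once.
quad_F <- function(nl, u, abs_tol = 1e-10) {
  pts <- sort(unique(c(0, u)))
  segs <- numeric(length(pts))
  for (i in seq_along(pts)[-1L]) {
    segs[i] <- piecewise_integrate(nl$f, pts[i - 1L], pts[i],
                                   knots = nl$knots, abs_tol = abs_tol)
  }
  cum <- cumsum(segs)
  cum <- cum - cum[match(0, pts)]
  out <- cum[match(u, pts)]
  attributes(out) <- attributes(u)
  out
}

# ---- constructors -----------------------------------------------------------

#' @rdname nonlinearity
#' @export
nl_linear <- function() {
  new_nonlinearity("linear", list(), f = function(u) u, F = function(u) u^2 / 2)
}

#' @rdname nonlinearity
#' @param theta activation threshold (input units).
#' @export
nl_linear_rectifier <- function(theta) {
  theta <- check_param(list(theta = theta), "theta", "linear_rectifier")
  F0 <- pmax(-theta, 0)^2 / 2
  new_nonlinearity("linear_rectifier", list(theta = theta),
    f = function(u) pmax(u - theta, 0),
    F = function(u) pmax(u - theta, 0)^2 / 2 - F0,
    knots = theta)
}

#' @rdname nonlinearity
#' @param theta1 LTD threshold; `f` is zero below it.
#' @param b LTD factor, so the LTP threshold is `theta2 = theta1 + b`.
#' @export
nl_quadratic_rectifier <- function(theta1, b) {
  theta1 <- check_param(list(theta1 = theta1), "theta1", "quadratic_rectifier")
  b <- check_param(list(b = b), "b", "quadratic_rectifier")
  Fr <- function(u) { t <- pmax(u - theta1, 0); t^3 / 3 - b * t^2 / 2 }
  F0 <- Fr(0)
  new_nonlinearity("quadratic_rectifier", list(theta1 = theta1, b = b),
    f = function(u) { t <- pmax(u - theta1, 0); t * (t - b) },
    F = function(u) Fr(u) - F0,
    knots = c(theta1, theta1 + b))
}

#' @rdname nonlinearity
#' @param a sigmoid center.
#' @export
nl_sigmoid <- function(a) {
  a <- check_param(list(a = a), "a", "sigmoid")
  F0 <- softplus(-2 * a) / 2
  new_nonlinearity("sigmoid", list(a = a),
    f = function(u) 1 / (1 + exp(-2 * (u - a))),
    F = function(u) softplus(2 * (u - a)) / 2 - F0)
}

#' @rdname nonlinearity
#' @details The negative sigmoid is the centered odd form
#' `f(u) = 1 - 2/(1 + e^{-2(u-a)}) = -tanh(u - a)` used in ICA contexts.
#' The negated Table-form sigmoid `-(1+e^{-2(u-a)})^{-1}` is available as
#' `nl_negate(nl_sigmoid(a))`; the two differ by an additive constant in `f`.
#' @export
nl_negative_sigmoid <- function(a) {
  a <- check_param(list(a = a), "a", "negative_sigmoid")
  F0 <- -logcosh(-a)
  new_nonlinearity("negative_sigmoid", list(a = a),
    f = function(u) -tanh(u - a),
    F = function(u) -logcosh(u - a) - F0)
}

#' @rdname nonlinearity
#' @param p exponent of the rectified power `f(u) = u_+^p`.
#' @export
nl_power_rectified <- function(p) {
  p <- check_param(list(p = p), "p", "power_rectified")
  if (p <= 0) nlh_stop("power exponent p must be > 0", "nlhebb_configuration_error")
  new_nonlinearity("power_rectified", list(p = p),
    f = function(u) pmax(u, 0)^p,
    F = function(u) pmax(u, 0)^(p + 1) / (p + 1),
    knots = 0)
}

#' @rdname nonlinearity
#' @export
nl_cubic <- function() {
  new_nonlinearity("cubic", list(), f = function(u) u^3, F = function(u) u^4 / 4)
}

#' @rdname nonlinearity
#' @export
nl_sine <- function() {
  new_nonlinearity("sine", list(), f = function(u) sin(u), F = function(u) 1 - cos(u))
}

#' @rdname nonlinearity
#' @export
nl_cosine <- function() {
  new_nonlinearity("cosine", list(), f = function(u) cos(u), F = function(u) sin(u))
}

#' @rdname nonlinearity
#' @details The symmetric rectifier is `f(u) = (|u| - theta)_+`, an even
#' function whose optimization function is odd.
#' @export
nl_symmetric_rectifier <- function(theta) {
  theta <- check_param(list(theta = theta), "theta", "symmetric_rectifier")
  new_nonlinearity("symmetric_rectifier", list(theta = theta),
    f = function(u) pmax(abs(u) - theta, 0),
    F = function(u) sign(u) * pmax(abs(u) - theta, 0)^2 / 2,
    knots = c(-theta, theta))
}

#' @rdname nonlinearity
#' @param a_fI f-I slope (rate units per input unit, e.g. Hz/nA).
#' @param theta_fI f-I threshold (input units, e.g. nA).
#' @export
nl_piecewise_linear_fI <- function(a_fI, theta_fI) {
  a_fI <- check_param(list(a_fI = a_fI), "a_fI", "piecewise_linear_fI")
  theta_fI <- check_param(list(theta_fI = theta_fI), "theta_fI", "piecewise_linear_fI")
  F0 <- a_fI * pmax(-theta_fI, 0)^2 / 2
  new_nonlinearity("piecewise_linear_fI", list(a_fI = a_fI, theta_fI = theta_fI),
    f = function(u) a_fI * pmax(u - theta_fI, 0),
    F = function(u) a_fI * pmax(u - theta_fI, 0)^2 / 2 - F0,
    knots = theta_fI)
}

#' @rdname nonlinearity
#' @details `nl_quadratic_plasticity` is the rate-domain reduction of triplet
#' STDP, `h(y) = y^2 - b y`, with LTD factor `b` in the rate units of `y`
#' (Hz). `b` may be supplied directly (e.g. a fitted value) or computed from
#' triplet parameters via [analytic_ltd_factor()] under an explicit trace
#' convention.
#' @export
nl_quadratic_plasticity <- function(b) {
  b <- check_param(list(b = b), "b", "quadratic_plasticity")
  new_nonlinearity("quadratic_plasticity", list(b = b),
    f = function(y) y^2 - b * y,
    F = function(y) y^3 / 3 - b * y^2 / 2)
}

#' @rdname nonlinearity
#' @param lambda sparsity weight of the penalty the activation derives from.
#' @export
nl_l0_activation <- function(lambda) {
  lambda <- check_param(list(lambda = lambda), "lambda", "l0_activation")
  if (lambda <= 0) nlh_stop("lambda must be > 0", "nlhebb_configuration_error")
  new_nonlinearity("l0_activation", list(lambda = lambda),
    f = function(u) ifelse(u < lambda, 0, u),
    F = function(u) ifelse(u < lambda, 0, (u^2 - lambda^2) / 2),
    knots = lambda)
}

#' @rdname nonlinearity
#' @details The Cauchy activation is `f = T^{-1}` with
#' `T(y) = y + 2*lambda*y/(1+y^2)` for `y >= 0`, clamped to 0 for `u < 0`.
#' `T` is monotone increasing iff `lambda <= 4` (its derivative
#' `1 + 2*lambda*(1-y^2)/(1+y^2)^2` attains its minimum `1 - lambda/4` at
#' `y = sqrt(3)`); the constructor rejects `lambda > 4` rather than picking a
#' branch of a multivalued inverse. The inverse is computed by bisection to
#' relative tolerance 1e-10, and `F` follows in closed form by substituting
#' `v = T(y)` in `int_0^u T^{-1}(v) dv`.
#' @export
nl_cauchy_activation <- function(lambda) {
  lambda <- check_param(list(lambda = lambda), "lambda", "cauchy_activation")
  if (lambda <= 0) nlh_stop("lambda must be > 0", "nlhebb_configuration_error")
  if (lambda > 4) {
    nlh_stop("cauchy activation requires lambda <= 4 (T is not monotone otherwise)",
             "nlhebb_invalid_specification")
  }
  Tfun <- function(y) y + 2 * lambda * y / (1 + y^2)
  inv <- function(u) {
    y <- numeric(length(u))
    pos <- which(u > 0)
    if (length(pos)) {
      up <- u[pos]
      lo <- rep(0, length(up))
      hi <- up  # T(y) >= y for y >= 0, so T^{-1}(u) <= u
      for (i in 1:64) {
        mid <- (lo + hi) / 2
        below <- Tfun(mid) < up
        lo[below] <- mid[below]
        hi[!below] <- mid[!below]
      }
      y[pos] <- (lo + hi) / 2
    }
    y
  }
  new_nonlinearity("cauchy_activation", list(lambda = lambda),
    f = function(u) { out <- inv(u); attributes(out) <- attributes(u); out },
    F = function(u) {
      Y <- inv(u)
      out <- Y^2 / 2 + lambda * (2 - 2 / (1 + Y^2) - log1p(Y^2))
      attributes(out) <- attributes(u)
      out
    },
    knots = 0)
}

#' @rdname nonlinearity
#' @param u_grid,f_values grid and values defining a tabulated nonlinearity,
#'   interpolated linearly (constant beyond the grid).
#' @export
nl_tabulated <- function(u_grid, f_values) {
  if (length(u_grid) != length(f_values) || length(u_grid) < 2 ||
      is.unsorted(u_grid, strictly = TRUE)) {
    nlh_stop("u_grid must be strictly increasing and match f_values",
             "nlhebb_invalid_specification")
  }
  ap <- stats::approxfun(u_grid, f_values, rule = 2)
  new_nonlinearity("tabulated", list(u_grid = u_grid, f_values = f_values),
    f = function(u) ap(u), F = NULL, knots = u_grid)
}

# ---- combinators ------------------------------------------------------------

#' Compose two nonlinearities
#'
#' Returns the effective Hebbian nonlinearity `f = h o g`, the composition of
#' an f-I curve `g` with a plasticity function `h`, so that
#' `eval_f(compose, u) = eval_f(h, eval_f(g, u))`. Its optimization function
#' is computed by quadrature.
#'
#' @param g inner nonlinearity (typically the f-I curve).
#' @param h outer nonlinearity (typically the plasticity function).
#' @export
nl_compose <- function(g, h) {
  stopifnot(inherits(g, "nonlinearity"), inherits(h, "nonlinearity"))
  new_nonlinearity("composed", list(g = g, h = h),
    f = function(u) h$f(g$f(u)),
    F = NULL, knots = g$knots,
    label = paste0(h$label, " o ", g$label))
}

#' Negate a nonlinearity
#'
#' `nl_negate(f)` evaluates to `-f(u)`; both `eval_f` and `eval_F` flip sign
#' exactly.
#'
#' @param nl a [nonlinearity].
#' @export
nl_negate <- function(nl) {
  stopifnot(inherits(nl, "nonlinearity"))
  new_nonlinearity("negated", list(inner = nl),
    f = function(u) -nl$f(u),
    F = if (is.null(nl$F)) NULL else function(u) -nl$F(u),
    knots = nl$knots,
    label = paste0("-", nl$label))
}

#' Activation function derived from a sparse-coding penalty
#'
#' For a sparse-coding energy `0.5*||x - W y||^2 + lambda*S(y)` with `y >= 0`,
#' the inference fixed point defines the activation `g = T^{-1}` with
#' `T(y) = y + lambda*S'(y)`. The L1 penalty gives a linear rectifier with
#' threshold `lambda`; the L0 penalty gives a hard threshold (`f(u) = 0` below
#' `lambda`, `f(u) = u` at or above); the Cauchy penalty
#' `S(y) = log(1 + y^2)` gives `T(y) = y + 2*lambda*y/(1+y^2)`, inverted
#' numerically.
#'
#' @param penalty one of `"L0"`, `"L1"`, `"cauchy"`.
#' @param lambda positive sparsity weight (`lambda <= 4` for `"cauchy"`).
#' @return a [nonlinearity].
#' @export
activation_from_penalty <- function(penalty = c("L1", "L0", "cauchy"), lambda) {
  penalty <- match.arg(penalty)
  if (!is.finite(lambda) || lambda <= 0) {
    nlh_stop("lambda must be a positive scalar", "nlhebb_configuration_error")
  }
  switch(penalty,
    L1 = nl_linear_rectifier(theta = lambda),
    L0 = nl_l0_activation(lambda),
    cauchy = nl_cauchy_activation(lambda))
}

# ---- compiled-evaluator marshalling ----------------------------------------

# Flatten a nonlinearity into the stage chain understood by the compiled
# learning loops (src/learn.cpp); composition appends stages, negation
# appends a -1 scale.
nl_stage_spec <- function(nl) {
  stopifnot(inherits(nl, "nonlinearity"))
  st <- function(op, par = numeric(0), ...) list(op = as.integer(op), par = par, ...)
  p <- nl$params
  switch(nl$kind,
    linear = list(st(0)),
    linear_rectifier = list(st(1, p$theta)),
    quadratic_rectifier = list(st(2, c(p$theta1, p$b))),
    sigmoid = list(st(3, p$a)),
    negative_sigmoid = list(st(4, p$a)),
    power_rectified = list(st(5, p$p)),
    cubic = list(st(6)),
    sine = list(st(7)),
    cosine = list(st(8)),
    symmetric_rectifier = list(st(9, p$theta)),
    piecewise_linear_fI = list(st(10, c(p$a_fI, p$theta_fI))),
    quadratic_plasticity = list(st(11, p$b)),
    l0_activation = list(st(12, p$lambda)),
    cauchy_activation = list(st(15, p$lambda)),
    tabulated = list(st(14, numeric(0), grid_u = p$u_grid, grid_f = p$f_values)),
    composed = c(nl_stage_spec(p$g), nl_stage_spec(p$h)),
    negated = c(nl_stage_spec(p$inner), list(st(13, -1))),
    nlh_stop(paste0("no compiled evaluator for kind: ", nl$kind),
             "nlhebb_invalid_specification"))
}

# ---- serialization ----------------------------------------------------------

#' Serialize a nonlinearity to/from a plain-text config block
#'
#' `nl_to_config` returns a plain list (kind plus named scalar parameters;
#' nested for composed/negated kinds) suitable for YAML/JSON;
#' `nl_from_config` rebuilds the nonlinearity. Thresholds are in input units,
#' rate-domain parameters (`b` of the quadratic plasticity, `a_fI`) in Hz.
#'
#' @param nl a [nonlinearity].
#' @param config a list as produced by `nl_to_config`.
#' @export
nl_to_config <- function(nl) {
  stopifnot(inherits(nl, "nonlinearity"))
  if (nl$kind == "composed") {
    list(kind = "composed", g = nl_to_config(nl$params$g), h = nl_to_config(nl$params$h))
  } else if (nl$kind == "negated") {
    list(kind = "negated", inner = nl_to_config(nl$params$inner))
  } else {
    c(list(kind = nl$kind), nl$params)
  }
}

#' @rdname nl_to_config
#' @export
nl_from_config <- function(config) {
  if (is.null(config$kind)) {
    nlh_stop("config must contain a 'kind' entry", "nlhebb_invalid_specification")
  }
  kind <- config$kind
  p <- config[setdiff(names(config), "kind")]
  switch(kind,
    linear = nl_linear(),
    linear_rectifier = nl_linear_rectifier(p$theta),
    quadratic_rectifier = nl_quadratic_rectifier(p$theta1, p$b),
    sigmoid = nl_sigmoid(p$a),
    negative_sigmoid = nl_negative_sigmoid(p$a),
    power_rectified = nl_power_rectified(p$p),
    cubic = nl_cubic(),
    sine = nl_sine(),
    cosine = nl_cosine(),
    symmetric_rectifier = nl_symmetric_rectifier(p$theta),
    piecewise_linear_fI = nl_piecewise_linear_fI(p$a_fI, p$theta_fI),
    quadratic_plasticity = nl_quadratic_plasticity(p$b),
    l0_activation = nl_l0_activation(p$lambda),
    cauchy_activation = nl_cauchy_activation(p$lambda),
    tabulated = nl_tabulated(unlist(p$u_grid), unlist(p$f_values)),
    composed = nl_compose(nl_from_config(p$g), nl_from_config(p$h)),
    negated = nl_negate(nl_from_config(p$inner)),
    nlh_stop(paste0("unknown nonlinearity kind: ", kind),
             "nlhebb_invalid_specification")
  )
}
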