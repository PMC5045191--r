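#' Selectivity index and projection-pursuit objective
#'
#' Nonlinear Hebbian learning ascends `R = <F(w'x)>`. Whether a nonlinearity
#' can learn kurtotic (long-tailed) features is quantified by the selectivity
#' index `SI = (<F(l)> - <F(g)>) / sigma_F`, comparing a unit-variance
#' Laplacian variable `l` (the kurtotic prototype) against a standard Gaussian
#' `g`. `SI > 0` marks nonlinearities suited to learning localized, oriented
#' receptive fields from whitened natural input.
#'
#' @name selectivity
NULL

# Unit-variance Laplace density (scale 1/sqrt(2)).
dlaplace_unit <- function(u) exp(-sqrt(2) * abs(u)) / sqrt(2)

rlaplace_unit <- function(n) (stats::rexp(n) - stats::rexp(n)) / sqrt(2)

#' Selectivity index of a nonlinearity
#'
#' Computes `SI = (<F(l)> - <F(g)>) / sigma_F` with `l` Laplacian and `g`
#' Gaussian, both unit variance. By default `sigma_F` is the geometric mean
#' `sqrt(sigma_F(l) * sigma_F(g))` with `sigma_F(.) = sqrt(<F(.)^2>)`, which
#' makes SI exactly invariant under multiplicative scaling of `f`; the plain
#' product convention is available via `sigma_convention = "product"` (it
#' rescales SI but never changes its sign or zero crossings).
#'
#' @param nl a [nonlinearity].
#' @param method `"quadrature"` (integration over `[-domain, domain]` standard
#'   units, split at the nonlinearity's kink points) or `"monte_carlo"`.
#' @param n_samples Monte-Carlo sample count per reference distribution.
#' @param seed integer seed for the Monte-Carlo method.
#' @param abs_tol absolute quadrature tolerance.
#' @param sigma_convention `"geometric"` (default) or `"product"`.
#' @param domain half-width of the quadrature domain in standard units.
#' @return a `selectivity_result` with fields `si`, `numerator`, `sigma_l`,
#'   `sigma_g`, `method`, and for Monte Carlo `n_samples`, `seed`, `se` (a
#'   standard-error estimate of `si` from the numerator variance).
#' @export
selectivity_index <- function(nl, method = c("quadrature", "monte_carlo"),
                              n_samples = 1e6, seed = 1L, abs_tol = 1e-10,
                              sigma_convention = c("geometric", "product"),
                              domain = 12) {
  method <- match.arg(method)
  sigma_convention <- match.arg(sigma_convention)
  notes <- character(0)

  if (method == "quadrature") {
    knots <- c(0, nl$knots)
    Fl <- piecewise_integrate(function(u) eval_F(nl, u) * dlaplace_unit(u),
                              -domain, domain, knots, abs_tol)
    Fg <- piecewise_integrate(function(u) eval_F(nl, u) * stats::dnorm(u),
                              -domain, domain, knots, abs_tol)
    sl <- sqrt(piecewise_integrate(function(u) eval_F(nl, u)^2 * dlaplace_unit(u),
                                   -domain, domain, knots, abs_tol))
    sg <- sqrt(piecewise_integrate(function(u) eval_F(nl, u)^2 * stats::dnorm(u),
                                   -domain, domain, knots, abs_tol))
    se <- NA_real_
    n_samples <- NA_real_
    seed <- NA_integer_
  } else {
    seed <- as.integer(seed)
    if (n_samples < 1e4) {
      notes <- c(notes, "n_samples < 1e4: Monte-Carlo SI estimate is noisy")
    }
    sims <- with_seed(seed, {
      l <- rlaplace_unit(n_samples)
      g <- stats::rnorm(n_samples)
      list(Fl = eval_F(nl, l), Fg = eval_F(nl, g))
    })
    Fl <- mean(sims$Fl); Fg <- mean(sims$Fg)
    sl <- sqrt(mean(sims$Fl^2)); sg <- sqrt(mean(sims$Fg^2))
    se_num <- sqrt(stats::var(sims$Fl) / n_samples + stats::var(sims$Fg) / n_samples)
    se <- NA_real_ # filled after sigma_F below
  }

  if (sl == 0 || sg == 0) {
    nlh_stop("sigma_F is zero: F vanishes on the reference support",
             "nlhebb_numerical_error")
  }
  sigma_F <- if (sigma_convention == "geometric") sqrt(sl * sg) else sl * sg
  num <- Fl - Fg
  if (method == "monte_carlo") se <- se_num / sigma_F

  structure(list(si = num / sigma_F, numerator = num, sigma_l = sl, sigma_g = sg,
                 method = method, n_samples = n_samples, seed = seed,
                 abs_tol = abs_tol, sigma_convention = sigma_convention,
                 se = se, notes = notes),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("<selectivity_result: SI = %.6g (%s%s)>\n", x$si, x$method,
              if (!is.na(x$se)) sprintf(", se = %.2g", x$se) else ""))
  invisible(x)
}

#' Critical parameter where the selectivity index changes sign
#'
#' Bisection root of `SI(param)` for a parametrized family of nonlinearities,
#' using quadrature SI. The interval must bracket a sign change.
#'
#' @param family a function `param -> nonlinearity`.
#' @param param_interval numeric length-2 bracket `c(lo, hi)`.
#' @param tol absolute tolerance on the parameter (default 1e-4).
#' @param ... passed to [selectivity_index()] (quadrature method enforced).
#' @return the root, a scalar.
#' @export
critical_parameter <- function(family, param_interval, tol = 1e-4, ...) {
  stopifnot(is.function(family), length(param_interval) == 2)
  lo <- param_interval[1]; hi <- param_interval[2]
  si_at <- function(p) selectivity_index(family(p), method = "quadrature", ...)$si
  s_lo <- si_at(lo); s_hi <- si_at(hi)
  if (sign(s_lo) == sign(s_hi)) {
    nlh_stop(sprintf(
      "no SI sign change on [%g, %g]: SI(lo) = %.4g, SI(hi) = %.4g",
      lo, hi, s_lo, s_hi), "nlhebb_bracket_error")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    s_mid <- si_at(mid)
    if (s_mid == 0) return(mid)
    if (sign(s_mid) == sign(s_lo)) { lo <- mid; s_lo <- s_mid } else hi <- mid
  }
  (lo + hi) / 2
}

#' Projection-pursuit objective of a feature on an ensemble
#'
#' `R = <F(w'x)>`, the sample mean of the optimization function over the
#' ensemble's projections onto `w`.
#'
#' @param nl a [nonlinearity].
#' @param w weight vector, length matching the ensemble dimension.
#' @param ensemble a [patch_ensemble].
#' @return scalar `R`.
#' @export
objective_value <- function(nl, w, ensemble) {
  X <- ensemble_data(ensemble)
  if (length(w) != ncol(X)) {
    nlh_stop(sprintf("w has length %d but ensemble dimension is %d",
                     length(w), ncol(X)), "nlhebb_shape_error")
  }
  mean(eval_F(nl, as.numeric(X %*% w)))
}

#' Relative objective across candidate features
#'
#' Evaluates `R` per feature and normalizes to `[0, 1]` relative to the
#' minimum and maximum among the considered features:
#' `R* = (R - R_min) / (R_max - R_min)`.
#'
#' @param nl a [nonlinearity].
#' @param features a list of weight vectors, or a matrix with one feature per
#'   column; names/colnames become labels.
#' @param ensemble a [patch_ensemble].
#' @return an `objective_result` data.frame with columns `label`, `R`, `R_star`.
#' @export
relative_objective <- function(nl, features, ensemble) {
  if (is.matrix(features)) {
    labels <- colnames(features)
    features <- lapply(seq_len(ncol(features)), function(j) features[, j])
    names(features) <- labels
  }
  if (length(features) < 2) {
    nlh_stop("relative_objective needs at least 2 features", "nlhebb_shape_error")
  }
  R <- vapply(features, function(w) objective_value(nl, w, ensemble), numeric(1))
  rng <- range(R)
  if (diff(rng) == 0) {
    nlh_stop("all features have identical R: normalization is degenerate",
             "nlhebb_degenerate_normalization_error")
  }
  labels <- names(features)
  if (is.null(labels)) labels <- paste0("feature_", seq_along(features))
  out <- data.frame(label = labels, R = R,
                    R_star = (R - rng[1]) / diff(rng),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("objective_result", "data.frame")
  out
}

#' Objective map over a grid of Gabor receptive fields
#'
#' For each grid cell (a partial Gabor specification, e.g. a width/length or
#' center-position combination), evaluates `R = <F(w'x)>` for unit-norm Gabor
#' filters over a frequency and phase sub-grid and keeps the maximum, the
#' convention used for receptive-field optimality landscapes.
#'
#' @param nl a [nonlinearity].
#' @param ensemble a [patch_ensemble] with a single channel.
#' @param cells data.frame; recognised columns are `sigma_x`, `sigma_y`,
#'   `x_c`, `y_c`, `theta`, `phase`, `frequency` — columns present vary per
#'   cell, the rest fall back to `defaults`.
#' @param frequencies numeric vector of spatial frequencies (cycles/pixel) to
#'   maximize over (ignored for cells that pin `frequency`).
#' @param phases phases to maximize over; default `c(0, pi/2)`.
#' @param defaults named list of fallback Gabor parameters (default: patch
#'   center, `theta = pi/3`).
#' @return an `objective_result` data.frame: the cells plus `R` and `R_star`.
#' @export
objective_map <- function(nl, ensemble, cells, frequencies = c(0.1, 0.15, 0.2, 0.3),
                          phases = c(0, pi / 2), defaults = list()) {
  if (!is.data.frame(cells) || nrow(cells) == 0) {
    nlh_stop("cells must be a non-empty data.frame", "nlhebb_configuration_error")
  }
  geom <- ensemble_geometry(ensemble)
  patch_size <- geom[1:2]
  base <- list(x_c = (patch_size[2] - 1) / 2, y_c = (patch_size[1] - 1) / 2,
               sigma_x = 1.5, sigma_y = 2, theta = pi / 3)
  base[names(defaults)] <- defaults

  X <- ensemble_data(ensemble)
  R <- vapply(seq_len(nrow(cells)), function(i) {
    p <- base
    for (nm in names(cells)) p[[nm]] <- cells[[nm]][i]
    fr <- if (!is.null(p$frequency)) p$frequency else frequencies
    ph <- if (!is.null(p$phase)) p$phase else phases
    best <- -Inf
    for (f in fr) for (phi in ph) {
      w <- make_filter(gabor_spec(x_c = p$x_c, y_c = p$y_c, frequency = f,
                                  sigma_x = p$sigma_x, sigma_y = p$sigma_y,
                                  phase = phi, theta = p$theta), patch_size)
      best <- max(best, mean(eval_F(nl, as.numeric(X %*% w))))
    }
    best
  }, numeric(1))

  out <- cells
  out$R <- R
  rng <- range(R)
  out$R_star <- if (diff(rng) > 0) (R - rng[1]) / diff(rng) else rep(NA_real_, length(R))
  class(out) <- c("objective_result", "data.frame")
  out
}
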