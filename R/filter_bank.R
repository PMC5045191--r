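#' Filter specifications
#'
#' Parametric receptive-field generators. All realized filters are flattened
#' row-major and normalized to unit L2 norm.
#'
#' The Gabor form is an oriented sinusoidal carrier under an anisotropic
#' Gaussian envelope: with rotated coordinates
#' `x' = (x - x_c) cos(theta) + (y - y_c) sin(theta)` and
#' `y' = -(x - x_c) sin(theta) + (y - y_c) cos(theta)`,
#' `w(x, y) = A exp(-(x'^2/(2 sigma_x^2) + y'^2/(2 sigma_y^2))) cos(2 pi f x' + phase)`.
#' The carrier varies along `x'`, so `sigma_x` is the envelope width across
#' the bars ("width") and `sigma_y` the extent along them ("length"). Width
#' and length in pixels are conventionally reported as 2.5 times these
#' standard deviations.
#'
#' @param x_c,y_c center, 0-based pixel coordinates (x = column, y = row,
#'   origin top-left).
#' @param frequency spatial frequency of the carrier, cycles/pixel.
#' @param sigma_x,sigma_y envelope standard deviations, pixels.
#' @param phase carrier phase, radians.
#' @param theta orientation, radians.
#' @param amplitude carrier amplitude before normalization.
#' @export
gabor_spec <- function(x_c, y_c, frequency, sigma_x, sigma_y, phase = 0,
                       theta = 0, amplitude = 1) {
  if (sigma_x <= 0 || sigma_y <= 0 || frequency <= 0) {
    nlh_stop("gabor sigma and frequency must be positive", "nlhebb_parameter_error")
  }
  structure(list(kind = "gabor", x_c = x_c, y_c = y_c, frequency = frequency,
                 sigma_x = sigma_x, sigma_y = sigma_y, phase = phase,
                 theta = theta, amplitude = amplitude),
            class = "filter_spec")
}

#' @rdname gabor_spec
#' @param T_x,T_y spatial periods in pixels along the x (column) and y (row)
#'   index; the filter is `w_ab = sin(2 pi a / T_x) * cos(2 pi b / T_y)` with
#'   0-based indices `a` (column) and `b` (row).
#' @export
fourier_spec <- function(T_x, T_y) {
  if (T_x <= 0 || T_y <= 0) nlh_stop("periods must be positive", "nlhebb_parameter_error")
  structure(list(kind = "fourier", T_x = T_x, T_y = T_y), class = "filter_spec")
}

#' @rdname gabor_spec
#' @param sigma1,sigma2 standard deviations of the two centered Gaussians
#'   (`sigma2 > sigma1`); the lobes are balanced (each Gaussian carries unit
#'   mass before differencing), so the filter integrates to approximately 0.
#' @export
dog_spec <- function(sigma1, sigma2) {
  if (sigma1 <= 0 || sigma2 <= sigma1) {
    nlh_stop("difference-of-Gaussians requires 0 < sigma1 < sigma2",
             "nlhebb_parameter_error")
  }
  structure(list(kind = "dog", sigma1 = sigma1, sigma2 = sigma2),
            class = "filter_spec")
}

#' @rdname gabor_spec
#' @param seed integer seed for the random-normal connectivity filter.
#' @export
random_spec <- function(seed = 1L) {
  structure(list(kind = "random", seed = as.integer(seed)), class = "filter_spec")
}

pixel_grid <- function(patch_size) {
  h <- patch_size[1]; w <- patch_size[2]
  list(x = matrix(rep(0:(w - 1), each = h), h, w),
       y = matrix(rep(0:(h - 1), times = w), h, w))
}

gabor_image <- function(spec, patch_size) {
  g <- pixel_grid(patch_size)
  xr <- (g$x - spec$x_c) * cos(spec$theta) + (g$y - spec$y_c) * sin(spec$theta)
  yr <- -(g$x - spec$x_c) * sin(spec$theta) + (g$y - spec$y_c) * cos(spec$theta)
  spec$amplitude * exp(-(xr^2 / (2 * spec$sigma_x^2) + yr^2 / (2 * spec$sigma_y^2))) *
    cos(2 * pi * spec$frequency * xr + spec$phase)
}

#' Realize a filter specification as a unit-norm weight vector
#'
#' @param spec a `filter_spec` ([gabor_spec()], [fourier_spec()],
#'   [dog_spec()], [random_spec()]).
#' @param patch_size integer `c(h, w)`.
#' @return unit-norm numeric vector of length `h * w` (row-major).
#' @export
make_filter <- function(spec, patch_size) {
  stopifnot(inherits(spec, "filter_spec"))
  h <- patch_size[1]; w <- patch_size[2]
  img <- switch(spec$kind,
    gabor = gabor_image(spec, patch_size),
    fourier = {
      g <- pixel_grid(patch_size)
      sin(2 * pi * g$x / spec$T_x) * cos(2 * pi * g$y / spec$T_y)
    },
    dog = {
      g <- pixel_grid(patch_size)
      r2 <- (g$x - (w - 1) / 2)^2 + (g$y - (h - 1) / 2)^2
      exp(-r2 / (2 * spec$sigma1^2)) / (2 * pi * spec$sigma1^2) -
        exp(-r2 / (2 * spec$sigma2^2)) / (2 * pi * spec$sigma2^2)
    },
    random = with_seed(spec$seed, matrix(stats::rnorm(h * w), h, w)),
    nlh_stop(paste0("unknown filter kind: ", spec$kind), "nlhebb_invalid_specification"))
  unit_vec(flatten_patch(img))
}

#' The five standard candidate features
#'
#' The probe set used to compare optimization values across models: a
#' random-normal connectivity filter, a high-frequency Fourier filter
#' (`T_x = T_y = 8`), a difference-of-Gaussians filter (3, 4), a
#' low-frequency Fourier filter (`T_x = 16, T_y = 32`), and a centered
#' localized Gabor (`sigma_x = 1.5`, `sigma_y = 2.0`, `f = 0.2`,
#' `theta = pi/3`, `phase = pi/2`). All unit norm.
#'
#' @param patch_size integer `c(h, w)` (default `c(16, 16)`).
#' @param seed seed of the random filter.
#' @return named list of 5 unit-norm weight vectors.
#' @export
candidate_features <- function(patch_size = c(16, 16), seed = 1L) {
  h <- patch_size[1]; w <- patch_size[2]
  list(
    random = make_filter(random_spec(seed), patch_size),
    fourier_high = make_filter(fourier_spec(8, 8), patch_size),
    dog = make_filter(dog_spec(3, 4), patch_size),
    fourier_low = make_filter(fourier_spec(16, 32), patch_size),
    gabor = make_filter(gabor_spec(x_c = (w - 1) / 2, y_c = (h - 1) / 2,
                                   frequency = 0.2, sigma_x = 1.5, sigma_y = 2.0,
                                   phase = pi / 2, theta = pi / 3), patch_size)
  )
}

# Initial Gabor guess from the dominant FFT peak of the patch (frequency and
# orientation) plus energy centroid and second moments.
gabor_init_guess <- function(P) {
  h <- nrow(P); w <- ncol(P)
  Fm <- Mod(stats::fft(P))
  kx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1))
  ky <- c(0:(floor(h / 2)), -((ceiling(h / 2) - 1):1))
  KX <- matrix(rep(kx, each = h), h, w)
  KY <- matrix(rep(ky, times = w), h, w)
  Fm[1, 1] <- 0
  pk <- arrayInd(which.max(Fm), dim(Fm))
  fx <- KX[pk]; fy <- KY[pk]
  f0 <- max(0.03, sqrt((fx / w)^2 + (fy / h)^2))
  theta0 <- atan2(fy / h, fx / w) %% pi
  E <- P^2
  tot <- sum(E)
  g <- pixel_grid(c(h, w))
  xc <- sum(g$x * E) / tot; yc <- sum(g$y * E) / tot
  vx <- sum((g$x - xc)^2 * E) / tot; vy <- sum((g$y - yc)^2 * E) / tot
  s0 <- sqrt(max(0.5, (vx + vy) / 2))
  list(x_c = xc, y_c = yc, frequency = f0, sigma_x = max(0.6, s0 / 1.5),
       sigma_y = max(0.8, s0), phase = 0, theta = theta0)
}

gabor_par_vec <- function(p) c(p$x_c, p$y_c, p$frequency, p$sigma_x, p$sigma_y,
                               p$phase, p$theta, p$amplitude)

#' Fit a Gabor function to a weight vector
#'
#' Nonlinear least squares (Levenberg-Marquardt, multi-start) over the eight
#' Gabor parameters (center, frequency, width, length, phase, orientation,
#' amplitude). Restarts are seeded from the dominant FFT peak of the filter
#' plus jitter. The fit is canonicalized to `theta` in `[0, pi)`, positive
#' sigmas and positive amplitude (sign folded into the phase, phase mod
#' 2 pi). Fits explaining less than 0.6 of the weight variance are rejected.
#'
#' @param w weight vector (unit norm).
#' @param patch_size integer `c(h, w)`.
#' @param n_restarts number of multi-start attempts (default 8).
#' @param seed integer seed for the restart jitter.
#' @return a `gabor_fit`: `params` (named list), `variance_explained`,
#'   `accepted` (`variance_explained >= 0.6`), `rss`, `converged`. Optimizer
#'   failure on all restarts yields `accepted = FALSE` with the residual
#'   recorded, not an error.
#' @export
fit_gabor <- function(w, patch_size, n_restarts = 8L, seed = 1L) {
  h <- patch_size[1]; wd <- patch_size[2]
  P <- unflatten_patch(w, h, wd)
  tss <- sum(w^2)
  guess <- gabor_init_guess(P)

  resid_fn <- function(par) {
    spec <- gabor_spec(x_c = par[1], y_c = par[2],
                       frequency = max(par[3], 1e-3),
                       sigma_x = max(par[4], 0.15), sigma_y = max(par[5], 0.15),
                       phase = par[6], theta = par[7], amplitude = par[8])
    as.vector(t(gabor_image(spec, patch_size))) - w
  }

  starts <- with_seed(seed, lapply(seq_len(n_restarts), function(r) {
    p <- guess
    if (r > 1) {
      p$x_c <- p$x_c + stats::rnorm(1, sd = 1)
      p$y_c <- p$y_c + stats::rnorm(1, sd = 1)
      p$frequency <- p$frequency * stats::runif(1, 0.6, 1.6)
      p$sigma_x <- p$sigma_x * stats::runif(1, 0.5, 2)
      p$sigma_y <- p$sigma_y * stats::runif(1, 0.5, 2)
      p$phase <- stats::runif(1, 0, 2 * pi)
      p$theta <- (p$theta + stats::rnorm(1, sd = 0.3)) %% pi
    }
    p$amplitude <- max(abs(P)) * sample(c(1, -1), 1)
    p
  }))

  best <- NULL
  any_converged <- FALSE
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = gabor_par_vec(p0), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    any_converged <- TRUE
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }

  if (is.null(best)) {
    return(structure(list(params = NULL, variance_explained = 0,
                          accepted = FALSE, rss = tss, converged = FALSE),
                     class = "gabor_fit"))
  }

  par <- best$par
  params <- list(x_c = par[1], y_c = par[2], frequency = max(par[3], 1e-3),
                 sigma_x = max(abs(par[4]), 0.15), sigma_y = max(abs(par[5]), 0.15),
                 phase = par[6], theta = par[7], amplitude = par[8])
  # canonical form: amplitude > 0 (sign into phase), theta in [0, pi) with the
  # carrier-axis flip absorbed by negating the phase, phase in [0, 2*pi)
  if (params$amplitude < 0) {
    params$amplitude <- -params$amplitude
    params$phase <- params$phase + pi
  }
  th <- params$theta %% (2 * pi)
  if (th >= pi) {
    th <- th - pi
    params$phase <- -params$phase
  }
  params$theta <- th
  params$phase <- params$phase %% (2 * pi)
  ve <- 1 - best$rss / tss
  structure(list(params = params, variance_explained = ve,
                 accepted = ve >= 0.6, rss = best$rss, converged = any_converged),
            class = "gabor_fit")
}

#' @export
print.gabor_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("<gabor_fit: failed (rejected)>\n")
  } else {
    cat(sprintf(
      "<gabor_fit: ve = %.3f (%s), f = %.3f, sigma = (%.2f, %.2f), theta = %.1f deg>\n",
      x$variance_explained, if (x$accepted) "accepted" else "rejected",
      x$params$frequency, x$params$sigma_x, x$params$sigma_y,
      180 * x$params$theta / pi))
  }
  invisible(x)
}

#' @export
as.data.frame.gabor_fit <- function(x, ...) {
  p <- x$params
  if (is.null(p)) {
    p <- list(x_c = NA_real_, y_c = NA_real_, frequency = NA_real_,
              sigma_x = NA_real_, sigma_y = NA_real_, phase = NA_real_,
              theta = NA_real_, amplitude = NA_real_)
  }
  data.frame(x_c = p$x_c, y_c = p$y_c, frequency = p$frequency,
             sigma_x = p$sigma_x, sigma_y = p$sigma_y, phase = p$phase,
             theta = p$theta, amplitude = p$amplitude,
             width_px = 2.5 * p$sigma_x, length_px = 2.5 * p$sigma_y,
             variance_explained = x$variance_explained, accepted = x$accepted)
}
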