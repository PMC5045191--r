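#' Synthetic data generators
#'
#' Desk-scale stand-ins for the external corpora: a linear generative model
#' with heavy-tailed latents over a known dictionary (emulating the kurtotic
#' statistics of whitened natural image patches, with full provenance for
#' plant-and-recover tests), stationary image stacks, a V1 complex-cell
#' energy front-end producing V2-like inputs, and gammatone log-spectrogram
#' segments from synthetic speech-like audio. Every generator is a pure
#' function of its parameters and seed.
#'
#' @name synthetic_data
NULL

#' Random Gabor dictionary
#'
#' `m` unit-norm Gabor filters with random centers, orientations, phases and
#' frequencies on an `h x w` patch, as a `d x m` matrix (row-major flattened
#' columns).
#'
#' @param patch_size integer `c(h, w)`.
#' @param m number of dictionary elements.
#' @param seed integer seed.
#' @export
gabor_dictionary <- function(patch_size = c(16, 16), m = 64, seed = 1L) {
  h <- patch_size[1]; w <- patch_size[2]
  with_seed(seed, {
    A <- matrix(0, h * w, m)
    specs <- vector("list", m)
    for (j in seq_len(m)) {
      # parameter ranges scale with the patch so small patches stay valid
      specs[[j]] <- gabor_spec(
        x_c = stats::runif(1, 0.25 * (w - 1), 0.75 * (w - 1)),
        y_c = stats::runif(1, 0.25 * (h - 1), 0.75 * (h - 1)),
        frequency = stats::runif(1, 2, 4.8) / w,
        sigma_x = max(0.5, stats::runif(1, 0.075, 0.14) * w),
        sigma_y = max(0.7, stats::runif(1, 0.11, 0.2) * h),
        phase = stats::runif(1, 0, 2 * pi), theta = stats::runif(1, 0, pi))
      A[, j] <- make_filter(specs[[j]], patch_size)
    }
    attr(A, "specs") <- specs
    A
  })
}

#' Linear generative model with heavy-tailed latents
#'
#' `x = dictionary %*% s + noise` with i.i.d. latents `s` drawn from a
#' Laplacian (excess kurtosis 3), Gaussian, or Bernoulli-Gaussian law. The
#' dictionary columns are forced to unit norm.
#'
#' @param dictionary `d x m` matrix of features.
#' @param latent_law `"laplacian"`, `"gaussian"`, or `"bernoulli_gaussian"`.
#' @param latent_scale standard deviation of the latents: a scalar, or a
#'   length-`m` vector of per-feature scales (unequal scales give the data a
#'   dominant, non-white second-order structure).
#' @param noise_sd isotropic Gaussian pixel noise level.
#' @param bernoulli_p activation probability for `"bernoulli_gaussian"`.
#' @param geometry patch geometry; default square single-channel from `d`.
#' @param seed integer seed.
#' @export
generative_model <- function(dictionary, latent_law = c("laplacian", "gaussian",
                                                        "bernoulli_gaussian"),
                             latent_scale = 1, noise_sd = 0.1,
                             bernoulli_p = 0.1, geometry = NULL, seed = 1L) {
  latent_law <- match.arg(latent_law)
  dictionary <- apply(as.matrix(dictionary), 2, unit_vec)
  d <- nrow(dictionary)
  if (!length(latent_scale) %in% c(1L, ncol(dictionary))) {
    nlh_stop("latent_scale must be a scalar or one value per dictionary column",
             "nlhebb_configuration_error")
  }
  if (is.null(geometry)) {
    s <- round(sqrt(d))
    if (s * s != d) nlh_stop("supply geometry for non-square dimensions",
                             "nlhebb_geometry_error")
    geometry <- c(s, s, 1L)
  }
  structure(list(dictionary = dictionary, latent_law = latent_law,
                 latent_scale = latent_scale, noise_sd = noise_sd,
                 bernoulli_p = bernoulli_p, geometry = as.integer(geometry),
                 seed = as.integer(seed)),
            class = "generative_model")
}

#' @rdname generative_model
#' @param model a `generative_model`.
#' @param n number of samples.
#' @return a [patch_ensemble] whose provenance carries the full generative
#'   record (dictionary, law, seed) for recovery tests.
#' @export
generate_patch_ensemble <- function(model, n) {
  stopifnot(inherits(model, "generative_model"), n >= 1)
  m <- ncol(model$dictionary)
  with_seed(model$seed, {
    S <- switch(model$latent_law,
      laplacian = matrix((stats::rexp(n * m) - stats::rexp(n * m)) / sqrt(2), n, m),
      gaussian = matrix(stats::rnorm(n * m), n, m),
      bernoulli_gaussian = {
        z <- matrix(stats::rbinom(n * m, 1, model$bernoulli_p), n, m)
        g <- matrix(stats::rnorm(n * m, sd = 1 / sqrt(model$bernoulli_p)), n, m)
        z * g
      })
    S <- if (length(model$latent_scale) == 1) S * model$latent_scale
         else sweep(S, 2, model$latent_scale, `*`)
    X <- tcrossprod(S, model$dictionary)
    if (model$noise_sd > 0) {
      X <- X + matrix(stats::rnorm(n * ncol(X), sd = model$noise_sd), n)
    }
    patch_ensemble(X, model$geometry, whitened = "none",
                   provenance = list(source = "generative_model", model = model))
  })
}

#' Stationary synthetic image stack
#'
#' Images generated as a circular convolution of heavy-tailed (sparse
#' Laplacian) white noise with an oriented kernel, giving an exactly
#' stationary (torus) process with kurtotic local structure; with
#' `kind = "gaussian"` the driving noise is Gaussian instead.
#'
#' @param n_images number of images.
#' @param size image side, pixels.
#' @param kind `"kurtotic"` or `"gaussian"` driving noise.
#' @param kernel_sigma isotropic blur width of the mixing kernel, pixels.
#' @param seed integer seed.
#' @return `size x size x n_images` array.
#' @export
synthetic_image_stack <- function(n_images = 10, size = 64,
                                  kind = c("kurtotic", "gaussian"),
                                  kernel_sigma = 1.5, seed = 1L) {
  kind <- match.arg(kind)
  kf <- {
    fr <- fft_radial_freq(size)
    exp(-2 * (pi * kernel_sigma * fr / size)^2)  # FFT of a Gaussian blur
  }
  with_seed(seed, {
    out <- array(0, c(size, size, n_images))
    for (k in seq_len(n_images)) {
      noise <- if (kind == "kurtotic") {
        matrix((stats::rexp(size^2) - stats::rexp(size^2)) / sqrt(2), size)
      } else {
        matrix(stats::rnorm(size^2), size)
      }
      out[, , k] <- Re(stats::fft(stats::fft(noise) * kf, inverse = TRUE)) / size^2
    }
    out
  })
}

#' V1 complex-cell energy front-end
#'
#' Models V2 input: for each image, quadrature-phase Gabor simple cells
#' (phases 0 and pi/2) are evaluated on a grid of centers and orientations,
#' and each complex-cell response is the sum of the two squared simple-cell
#' responses — orientation selective but phase invariant. The default grid is
#' 8 x 8 centers at 3.1-pixel spacing with 8 orientations (512 dimensions),
#' with Gabor parameters `sigma_x = 1.2`, `sigma_y = 2.4`, `f = 0.3`.
#'
#' @param images matrix, array, or list of matrices (all equal, square size).
#' @param grid_spec list with `n_grid`, `spacing`, `n_orient`, `sigma_x`,
#'   `sigma_y`, `frequency`.
#' @return a [patch_ensemble] of dimension
#'   `n_grid^2 * n_orient`, geometry `(n_grid, n_grid, n_orient)`.
#' @export
complex_cell_frontend <- function(images,
                                  grid_spec = list(n_grid = 8, spacing = 3.1,
                                                   n_orient = 8, sigma_x = 1.2,
                                                   sigma_y = 2.4, frequency = 0.3)) {
  imgs <- as_image_list(images)
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  gs <- grid_spec
  footprint <- (gs$n_grid - 1) * gs$spacing
  if (footprint >= min(h, w)) {
    nlh_stop("complex-cell grid footprint exceeds the image", "nlhebb_geometry_error")
  }
  off_x <- (w - 1 - footprint) / 2
  off_y <- (h - 1 - footprint) / 2
  centers <- expand.grid(gy = 0:(gs$n_grid - 1), gx = 0:(gs$n_grid - 1))
  orients <- (0:(gs$n_orient - 1)) * pi / gs$n_orient
  # filter bank: for each (center, orientation), a quadrature pair
  n_units <- nrow(centers) * gs$n_orient
  G0 <- matrix(0, h * w, n_units)
  G90 <- matrix(0, h * w, n_units)
  u <- 0L
  for (ci in seq_len(nrow(centers))) {
    xc <- off_x + centers$gx[ci] * gs$spacing
    yc <- off_y + centers$gy[ci] * gs$spacing
    for (th in orients) {
      u <- u + 1L
      G0[, u] <- make_filter(gabor_spec(xc, yc, gs$frequency, gs$sigma_x,
                                        gs$sigma_y, phase = 0, theta = th), c(h, w))
      G90[, u] <- make_filter(gabor_spec(xc, yc, gs$frequency, gs$sigma_x,
                                         gs$sigma_y, phase = pi / 2, theta = th), c(h, w))
    }
  }
  X <- t(vapply(imgs, function(im) {
    v <- flatten_patch(im)
    drop(crossprod(G0, v))^2 + drop(crossprod(G90, v))^2
  }, numeric(n_units)))
  patch_ensemble(X, c(gs$n_grid, gs$n_grid, gs$n_orient), whitened = "none",
                 provenance = list(source = "complex_cell_frontend", grid = gs))
}

#' Synthetic speech-like audio
#'
#' Harmonic stacks (random fundamental, random onset/duration) plus broadband
#' noise bursts — enough temporal and spectral structure to exercise the
#' spectrogram pipeline without external recordings.
#'
#' @param duration_s length in seconds.
#' @param sample_rate Hz (default 16000).
#' @param n_events number of harmonic/noise events.
#' @param seed integer seed.
#' @return numeric waveform vector with attribute `sample_rate`.
#' @export
synthetic_audio <- function(duration_s = 10, sample_rate = 16000, n_events = 40,
                            seed = 1L) {
  with_seed(seed, {
    n <- round(duration_s * sample_rate)
    t <- (0:(n - 1)) / sample_rate
    x <- stats::rnorm(n, sd = 0.005)
    for (e in seq_len(n_events)) {
      t0 <- stats::runif(1, 0, duration_s - 0.3)
      len <- stats::runif(1, 0.1, 0.3)
      idx <- which(t >= t0 & t < t0 + len)
      env <- sin(pi * (t[idx] - t0) / len)^2
      if (stats::runif(1) < 0.75) {
        f0 <- stats::runif(1, 100, 350)
        sig <- 0
        for (hh in 1:10) {
          if (f0 * hh >= sample_rate / 2) break
          sig <- sig + stats::runif(1, 0.2, 1) / hh * sin(2 * pi * f0 * hh * t[idx] +
                                                          stats::runif(1, 0, 2 * pi))
        }
      } else {
        sig <- stats::rnorm(length(idx), sd = 0.5)
      }
      x[idx] <- x[idx] + env * sig
    }
    structure(x / max(abs(x)), sample_rate = sample_rate)
  })
}

# 4th-order gammatone impulse response, sampled; bandwidth by the standard
# equivalent-rectangular-bandwidth rule (a filterbank convention, not a claim
# about any particular corpus).
gammatone_ir <- function(fc, sample_rate, dur = 0.064) {
  t <- seq(0, dur, by = 1 / sample_rate)
  erb <- 24.7 * (4.37 * fc / 1000 + 1)
  b <- 1.019 * erb
  ir <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * fc * t)
  ir / sqrt(sum(ir^2))
}

#' Gammatone log-spectrogram segments
#'
#' Filters audio with a 4th-order gammatone bank (20 center frequencies
#' equally spaced in Hz between 0.2 and 4.0 kHz), takes the absolute value
#' and the log (floored at `log_floor` of the peak magnitude), mean-pools to
#' 50 Hz frames, and cuts 20-frame x 20-channel segments (400 ms each) at
#' random offsets.
#'
#' @param audio waveform vector with a `sample_rate` attribute (>= 8 kHz), or
#'   `NULL` to generate [synthetic_audio()] internally.
#' @param n_segments number of segments to cut.
#' @param seed integer seed (drives both the synthetic audio and the offsets).
#' @param n_channels,n_frames segment geometry (defaults 20 x 20).
#' @param freq_range channel center range in Hz.
#' @param frame_rate pooled frame rate, Hz (default 50).
#' @param log_floor floor on magnitudes, relative to the peak (default 1e-5).
#' @return a [patch_ensemble] with geometry `(n_channels, n_frames, 1)`:
#'   rows of the patch are frequency channels, columns time frames.
#' @export
spectrogram_segments <- function(audio = NULL, n_segments = 100, seed = 1L,
                                 n_channels = 20, n_frames = 20,
                                 freq_range = c(200, 4000), frame_rate = 50,
                                 log_floor = 1e-5) {
  if (is.null(audio)) {
    audio <- synthetic_audio(duration_s = max(10, n_segments * 0.15 + 1), seed = spawn_seed(seed, "audio"))
  }
  sr <- attr(audio, "sample_rate")
  if (is.null(sr) || sr < 8000) {
    nlh_stop("audio must carry a sample_rate attribute >= 8000 Hz",
             "nlhebb_input_error")
  }
  fcs <- seq(freq_range[1], freq_range[2], length.out = n_channels)
  hop <- round(sr / frame_rate)
  n_frames_total <- floor(length(audio) / hop)
  if (n_frames_total < n_frames) {
    nlh_stop("audio too short for a single segment", "nlhebb_input_error")
  }
  S <- matrix(0, n_channels, n_frames_total)
  for (ch in seq_len(n_channels)) {
    ir <- gammatone_ir(fcs[ch], sr)
    y <- abs(fft_convolve(as.numeric(audio), ir))
    # mean-pool 1/frame_rate-second frames
    y <- y[seq_len(n_frames_total * hop)]
    S[ch, ] <- colMeans(matrix(y, hop, n_frames_total))
  }
  floor_val <- log_floor * max(S)
  if (floor_val <= 0) floor_val <- log_floor  # silent input: flat floor
  S <- log(pmax(S, floor_val))
  offs <- with_seed(spawn_seed(seed, "segments"),
                    sample.int(n_frames_total - n_frames + 1L, n_segments, replace = TRUE) - 1L)
  X <- t(vapply(offs, function(o) flatten_patch(S[, o + 1:n_frames, drop = FALSE]),
                numeric(n_channels * n_frames)))
  patch_ensemble(X, c(n_channels, n_frames, 1L), whitened = "none",
                 provenance = list(source = "spectrogram_segments", seed = seed,
                                   sample_rate = sr, channels = fcs,
                                   frame_rate = frame_rate))
}

# FFT-based linear convolution, output aligned to the input ("same" mode,
# no group-delay compensation).
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- 2^ceiling(log2(n))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_along(x)] / nfft
}
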