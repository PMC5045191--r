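#' Patch ensembles
#'
#' A `patch_ensemble` is a samples-by-dimensions matrix of flattened patches
#' plus geometry metadata (patch height, width, channel count) and a
#' provenance record. Patches are flattened row-major with the origin at the
#' top-left and 0-based offsets throughout the package.
#'
#' @param data numeric matrix, `n_samples x d`.
#' @param geometry integer vector `c(height, width, channels)` with
#'   `d = height * width * channels`.
#' @param whitened one of `"none"`, `"exact"`, `"powerlaw"`.
#' @param provenance free-form list (source, seed, parameters).
#' @export
patch_ensemble <- function(data, geometry, whitened = "none", provenance = list()) {
  data <- as.matrix(data)
  geometry <- as.integer(geometry)
  if (length(geometry) == 2) geometry <- c(geometry, 1L)
  if (length(geometry) != 3 || prod(geometry) != ncol(data)) {
    nlh_stop(sprintf("geometry %s does not match data dimension %d",
                     paste(geometry, collapse = "x"), ncol(data)),
             "nlhebb_geometry_error")
  }
  whitened <- match.arg(whitened, c("none", "exact", "powerlaw"))
  structure(list(data = data, geometry = geometry, whitened = whitened,
                 provenance = provenance),
            class = "patch_ensemble")
}

#' @rdname patch_ensemble
#' @param x,ensemble a `patch_ensemble`.
#' @export
ensemble_data <- function(ensemble) {
  stopifnot(inherits(ensemble, "patch_ensemble"))
  ensemble$data
}

#' @rdname patch_ensemble
#' @export
ensemble_geometry <- function(ensemble) {
  stopifnot(inherits(ensemble, "patch_ensemble"))
  ensemble$geometry
}

#' @rdname patch_ensemble
#' @param ... ignored.
#' @export
print.patch_ensemble <- function(x, ...) {
  cat(sprintf("<patch_ensemble: %d samples, %dx%dx%d (d = %d), whitened = %s>\n",
              nrow(x$data), x$geometry[1], x$geometry[2], x$geometry[3],
              ncol(x$data), x$whitened))
  invisible(x)
}

# Row-major flattening helpers (origin top-left).
flatten_patch <- function(m) as.vector(t(m))
unflatten_patch <- function(v, h, w) matrix(v, h, w, byrow = TRUE)

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
rot90_cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

as_image_list <- function(images) {
  if (is.list(images)) return(images)
  if (is.matrix(images)) return(list(images))
  if (is.array(images) && length(dim(images)) == 3) {
    return(lapply(seq_len(dim(images)[3]), function(k) images[, , k]))
  }
  nlh_stop("images must be a matrix, a 3-d array, or a list of matrices",
           "nlhebb_geometry_error")
}

#' Sample patches from an image stack
#'
#' Extracts `n` patches at uniformly random integer offsets from randomly
#' chosen images. With `rotate_augment`, each patch is independently rotated
#' by -90, 0 or +90 degrees with equal probability (set
#' `rotation_outcomes = "two"` for the strict two-outcome -90/+90 variant);
#' square patches are required for rotation.
#'
#' @param images matrix, `h x w x k` array, or list of matrices.
#' @param patch_size integer `c(height, width)`.
#' @param n number of patches.
#' @param rotate_augment logical; rotate patches by multiples of 90 degrees to
#'   remove orientation bias.
#' @param seed integer seed; the ensemble is a pure function of
#'   (images, parameters, seed).
#' @param rotation_outcomes `"three"` (default, includes identity) or `"two"`.
#' @param wrap logical; sample with torus wrap-around (patch offsets over the
#'   full image, pixels taken modulo the image size), which makes the patch
#'   distribution exactly stationary for stationary images.
#' @return a [patch_ensemble].
#' @export
sample_patches <- function(images, patch_size, n, rotate_augment = FALSE,
                           seed = 1L, rotation_outcomes = c("three", "two"),
                           wrap = FALSE) {
  rotation_outcomes <- match.arg(rotation_outcomes)
  imgs <- as_image_list(images)
  ph <- patch_size[1]; pw <- patch_size[2]
  for (im in imgs) {
    if (!wrap && (nrow(im) < ph || ncol(im) < pw)) {
      nlh_stop("patch larger than image", "nlhebb_geometry_error")
    }
  }
  if (rotate_augment && ph != pw) {
    nlh_stop("rotation augmentation requires square patches", "nlhebb_geometry_error")
  }
  with_seed(seed, {
    X <- matrix(0, n, ph * pw)
    img_idx <- sample.int(length(imgs), n, replace = TRUE)
    # offsets are drawn before the rotation choices so that augmented and
    # unaugmented ensembles with the same seed sample the same patches
    r0 <- integer(n); c0 <- integer(n)
    for (i in seq_len(n)) {
      im <- imgs[[img_idx[i]]]
      if (wrap) {
        r0[i] <- sample.int(nrow(im), 1) - 1L
        c0[i] <- sample.int(ncol(im), 1) - 1L
      } else {
        r0[i] <- sample.int(nrow(im) - ph + 1L, 1) - 1L
        c0[i] <- sample.int(ncol(im) - pw + 1L, 1) - 1L
      }
    }
    rots <- if (!rotate_augment) rep(0L, n)
            else if (rotation_outcomes == "three") sample(c(-1L, 0L, 1L), n, replace = TRUE)
            else sample(c(-1L, 1L), n, replace = TRUE)
    for (i in seq_len(n)) {
      im <- imgs[[img_idx[i]]]
      patch <- if (wrap) {
        im[(r0[i] + 0:(ph - 1)) %% nrow(im) + 1L,
           (c0[i] + 0:(pw - 1)) %% ncol(im) + 1L, drop = FALSE]
      } else {
        im[r0[i] + 1:ph, c0[i] + 1:pw, drop = FALSE]
      }
      if (rots[i] == 1L) patch <- rot90_ccw(patch)
      if (rots[i] == -1L) patch <- rot90_cw(patch)
      X[i, ] <- flatten_patch(patch)
    }
    patch_ensemble(X, c(ph, pw, 1L), whitened = "none",
                   provenance = list(source = "sample_patches", seed = seed,
                                     n_images = length(imgs),
                                     rotate_augment = rotate_augment,
                                     rotation_outcomes = rotation_outcomes,
                                     wrap = wrap))
  })
}

#' Fit an exact whitening transform
#'
#' Mean subtraction plus the symmetric (ZCA-style) whitening transform
#' `M = R D^{-1/2} R'` from the eigendecomposition `C = R D R'` of the sample
#' covariance. Eigenvalues below `eigenvalue_floor` times the largest are
#' excluded from the inversion (their directions map to zero).
#'
#' @param ensemble a [patch_ensemble].
#' @param eigenvalue_floor relative floor on eigenvalues (default 1e-8).
#' @return a `whitening_model` with fields `mean`, `R`, `D`, `M`,
#'   `eigenvalue_floor`, `retained`.
#' @export
fit_whitening <- function(ensemble, eigenvalue_floor = 1e-8) {
  X <- ensemble_data(ensemble)
  if (nrow(X) <= ncol(X)) {
    nlh_warn(sprintf("fitting whitening with n = %d <= d = %d samples",
                     nrow(X), ncol(X)), "nlhebb_sample_size_warning")
  }
  mu <- colMeans(X)
  C <- stats::cov(X)
  eg <- eigen(C, symmetric = TRUE)
  if (!any(eg$values > 0)) {
    nlh_stop("input has zero variance: covariance is degenerate",
             "nlhebb_degenerate_covariance_error")
  }
  floor_abs <- eigenvalue_floor * max(eg$values)
  retained <- eg$values > floor_abs
  inv_sqrt <- numeric(length(eg$values))
  inv_sqrt[retained] <- 1 / sqrt(eg$values[retained])
  M <- eg$vectors %*% (inv_sqrt * t(eg$vectors))
  structure(list(mean = mu, R = eg$vectors, D = eg$values, M = M,
                 eigenvalue_floor = eigenvalue_floor, retained = retained),
            class = "whitening_model")
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf("<whitening_model: d = %d, %d/%d eigendirections retained>\n",
              length(x$mean), sum(x$retained), length(x$retained)))
  invisible(x)
}

#' Apply a fitted whitening transform
#'
#' `x* = M (x - mean)`; the returned ensemble is tagged `whitened = "exact"`.
#'
#' @param model a `whitening_model` from [fit_whitening()].
#' @param ensemble a [patch_ensemble] of matching dimension.
#' @export
apply_whitening <- function(model, ensemble) {
  stopifnot(inherits(model, "whitening_model"))
  X <- ensemble_data(ensemble)
  if (ncol(X) != length(model$mean)) {
    nlh_stop(sprintf("ensemble dimension %d does not match model dimension %d",
                     ncol(X), length(model$mean)), "nlhebb_shape_error")
  }
  Xw <- sweep(X, 2, model$mean) %*% model$M
  patch_ensemble(Xw, ensemble_geometry(ensemble), whitened = "exact",
                 provenance = c(ensemble$provenance, list(whitening = "exact")))
}

# Radial frequency magnitude grid (cycles per image) for an s x s FFT layout:
# integer frequency indices with the standard half-spectrum symmetry, so the
# result is independent of FFT storage conventions.
fft_radial_freq <- function(s) {
  k <- c(0:(floor(s / 2)), -((ceiling(s / 2) - 1):1))
  kx <- matrix(rep(k, each = s), s, s)
  ky <- matrix(rep(k, times = s), s, s)
  sqrt(kx^2 + ky^2)
}

#' Power-law whitening filter for square images
#'
#' Frequency-domain filter `M(f) = f * exp(-(f/f0)^4)` with `f` the radial
#' spatial frequency in cycles per image: the linear factor cancels an ideal
#' 1/f amplitude spectrum, the quartic exponential low-passes high-frequency
#' noise. The DC component maps to 0. This is the approximate-whitening
#' preprocessing of the classic sparse-coding pipeline; it leaves residual
#' low-frequency variance when the true spectrum decays faster than 1/f.
#'
#' @param images square matrix, stack array, or list of square matrices.
#' @param f0 low-pass knee in cycles per image (default 200).
#' @return filtered images, in the same container type as the input.
#' @export
powerlaw_whiten_images <- function(images, f0 = 200) {
  imgs <- as_image_list(images)
  out <- lapply(imgs, function(im) {
    if (nrow(im) != ncol(im)) {
      nlh_stop("power-law whitening requires square images", "nlhebb_geometry_error")
    }
    s <- nrow(im)
    gain <- fft_radial_freq(s)
    gain <- gain * exp(-(gain / f0)^4)
    gain[1, 1] <- 0
    Re(stats::fft(stats::fft(im) * gain, inverse = TRUE)) / (s * s)
  })
  if (is.matrix(images)) return(out[[1]])
  if (is.array(images) && length(dim(images)) == 3) {
    return(array(unlist(out), dim = c(dim(out[[1]]), length(out))))
  }
  out
}

#' Concatenate left/right-eye ensembles (strabismus model)
#'
#' Row-wise concatenation of two equal-geometry ensembles into two-eye
#' patches (e.g. 16x16 + 16x16 -> 16x32). `mode = "independent"` pairs
#' unrelated samples, modeling strabismic rearing with non-overlapping eye
#' inputs; `mode = "identical"` duplicates the left patch into both eyes, the
#' binocular control.
#'
#' @param left,right [patch_ensemble]s with equal sample counts and geometry.
#' @param mode `"independent"` or `"identical"`.
#' @return a [patch_ensemble] with doubled width; the provenance records the
#'   two-eye structure.
#' @export
concat_strabismus <- function(left, right, mode = c("independent", "identical")) {
  mode <- match.arg(mode)
  gl <- ensemble_geometry(left); gr <- ensemble_geometry(right)
  Xl <- ensemble_data(left); Xr <- ensemble_data(right)
  if (!identical(gl, gr) || nrow(Xl) != nrow(Xr)) {
    nlh_stop("left and right ensembles must have equal sample counts and geometry",
             "nlhebb_shape_error")
  }
  X <- if (mode == "independent") cbind(Xl, Xr) else cbind(Xl, Xl)
  patch_ensemble(X, c(gl[1], 2L * gl[2], gl[3]),
                 whitened = if (left$whitened == right$whitened) left$whitened else "none",
                 provenance = list(source = "concat_strabismus", mode = mode,
                                   eyes = 2L, eye_width = gl[2]))
}
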