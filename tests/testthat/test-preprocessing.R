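test_that("sample_patches draws uniform offsets and is deterministic", {
  # encode position in pixel values so each patch reveals its offset
  img <- outer(0:15, 0:15, function(r, c) r + 100 * c)
  ens <- sample_patches(img, c(4, 4), 4000, seed = 3)
  expect_identical(ensemble_data(ens),
                   ensemble_data(sample_patches(img, c(4, 4), 4000, seed = 3)))
  tl <- ensemble_data(ens)[, 1]                 # top-left pixel = r0 + 100*c0
  r0 <- tl %% 100; c0 <- tl %/% 100
  expect_true(all(r0 %in% 0:12), all(c0 %in% 0:12))
  # offsets uniform over the 13 x 13 grid (chi-square, alpha = 0.01)
  counts <- table(factor(r0 + 13 * c0, levels = 0:(13 * 13 - 1)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
  # constant image -> constant patches
  cens <- sample_patches(matrix(2, 8, 8), c(3, 3), 10, seed = 1)
  expect_true(all(ensemble_data(cens) == 2))
  expect_error_class(sample_patches(matrix(0, 3, 3), c(4, 4), 1), "nlhebb_geometry_error")
})

test_that("rotation augmentation applies -90/0/+90 with equal probability", {
  img <- matrix(rnorm(64 * 64), 64)
  ens0 <- sample_patches(img, c(5, 5), 3000, seed = 9, rotate_augment = FALSE)
  ens1 <- sample_patches(img, c(5, 5), 3000, seed = 9, rotate_augment = TRUE)
  # classify each augmented patch against the unrotated ensemble's rotations
  P0 <- ensemble_data(ens0); P1 <- ensemble_data(ens1)
  rot_of <- function(v) {
    m <- matrix(v, 5, 5, byrow = TRUE)
    list(`0` = v, `1` = as.vector(t(t(m)[5:1, ])), `-1` = as.vector(t(t(m)[, 5:1])))
  }
  labs <- vapply(seq_len(nrow(P1)), function(i) {
    cand <- rot_of(P0[i, ])
    names(cand)[which.min(vapply(cand, function(c) sum((c - P1[i, ])^2), 0))]
  }, "")
  counts <- table(factor(labs, levels = c("-1", "0", "1")))
  expect_true(all(counts > 0))
  expect_gt(chisq.test(counts)$p.value, 0.01)
  # two-outcome variant never leaves a patch unrotated (same n, so the same
  # seed draws the same patches)
  ens2 <- sample_patches(img, c(5, 5), 3000, seed = 9, rotate_augment = TRUE,
                         rotation_outcomes = "two")
  P2 <- ensemble_data(ens2)[1:500, ]
  labs2 <- vapply(seq_len(nrow(P2)), function(i) {
    cand <- rot_of(P0[i, ])
    names(cand)[which.min(vapply(cand, function(c) sum((c - P2[i, ])^2), 0))]
  }, "")
  expect_false(any(labs2 == "0"))
})

test_that("whitening produces identity covariance and closed-form transforms", {
  set.seed(11)
  X <- matrix(rnorm(4000 * 9), ncol = 9) %*% diag(sqrt(c(9, 4, 4, 1, 1, 1, .5, .5, .1)))
  ens <- patch_ensemble(X, c(3, 3, 1))
  wm <- fit_whitening(ens)
  out <- apply_whitening(wm, ens)
  expect_equal(cov(ensemble_data(out)), diag(9), tolerance = 1e-6)
  expect_identical(out$whitened, "exact")
  expect_true(isSymmetric(wm$M, tol = 1e-12))
  # d = 2 closed form: covariance diag(4, 1) -> M = diag(1/2, 1)
  set.seed(2)
  X2 <- cbind(rnorm(20000, sd = 2), rnorm(20000))
  wm2 <- fit_whitening(patch_ensemble(X2, c(1, 2, 1)))
  expect_lt(max(abs(abs(wm2$M) - diag(c(0.5, 1)))), 0.05)
  # already-white data: M near identity (sampling-noise bound ~ sqrt(d/n))
  set.seed(3)
  Xw <- matrix(rnorm(1600 * 16 * 16), ncol = 16)
  wmw <- fit_whitening(patch_ensemble(Xw, c(4, 4, 1)))
  expect_lt(norm(wmw$M - diag(16), "2"), 5e-2)
  # refit on whitened output is the identity again
  wm3 <- fit_whitening(out)
  expect_lt(norm(wm3$M - diag(9), "2"), 5e-2)
  # a zero input row maps to -M mean
  ens0 <- patch_ensemble(rbind(ensemble_data(ens), 0), c(3, 3, 1))
  mapped <- apply_whitening(wm, ens0)
  expect_equal(ensemble_data(mapped)[4001, ], as.numeric(-wm$M %*% wm$mean),
               tolerance = 1e-12)
  # pseudo-inverse round trip on retained directions
  Minv <- with(eigen(wm$M, symmetric = TRUE),
               vectors %*% diag(ifelse(values > 1e-8, 1 / values, 0)) %*% t(vectors))
  rec <- ensemble_data(out) %*% Minv + rep(1, nrow(X)) %o% wm$mean
  expect_equal(rec, X, tolerance = 1e-8)
  # degenerate input
  expect_error_class(fit_whitening(patch_ensemble(matrix(1, 50, 4), c(2, 2, 1))),
                     "nlhebb_degenerate_covariance_error")
  # n <= d warning
  expect_warning(fit_whitening(patch_ensemble(matrix(rnorm(32), 4, 8), c(2, 4, 1))),
                 class = "nlhebb_sample_size_warning")
})

test_that("power-law filter has the analytic single-frequency gain", {
  s <- 64
  f0 <- 200
  # constant image is annihilated (DC -> 0)
  expect_equal(powerlaw_whiten_images(matrix(5, s, s), f0), matrix(0, s, s),
               tolerance = 1e-12)
  # pure sinusoid at integer radial frequency: amplitude scaled by f e^-(f/f0)^4
  for (k in c(3, 10)) {
    img <- outer(0:(s - 1), 0:(s - 1), function(y, x) sin(2 * pi * k * x / s))
    out <- powerlaw_whiten_images(img, f0)
    gain <- k * exp(-(k / f0)^4)
    expect_equal(out, gain * img, tolerance = 1e-6, info = paste("k =", k))
  }
  # linearity
  set.seed(4)
  A <- matrix(rnorm(s * s), s); B <- matrix(rnorm(s * s), s)
  expect_equal(powerlaw_whiten_images(2.5 * A + B),
               2.5 * powerlaw_whiten_images(A) + powerlaw_whiten_images(B),
               tolerance = 1e-10)
  expect_error_class(powerlaw_whiten_images(matrix(0, 4, 6)), "nlhebb_geometry_error")
})

test_that("strabismic concatenation builds two-eye patches", {
  set.seed(5)
  mk <- function(seed) {
    ens <- patch_ensemble(matrix(rnorm(3000 * 16), ncol = 16), c(4, 4, 1))
    apply_whitening(suppressWarnings(fit_whitening(ens)), ens)
  }
  left <- mk(1); right <- mk(2)
  ind <- concat_strabismus(left, right, "independent")
  expect_equal(ensemble_geometry(ind), c(4L, 8L, 1L))
  # independent whitened halves: cross-eye correlations near zero
  cc <- cor(ensemble_data(ind))[1:16, 17:32]
  expect_lt(max(abs(cc)), 4 / sqrt(3000))
  same <- concat_strabismus(left, right, "identical")
  expect_identical(ensemble_data(same)[, 1:16], ensemble_data(same)[, 17:32])
  short <- patch_ensemble(matrix(rnorm(10 * 16), ncol = 16), c(4, 4, 1))
  expect_error_class(concat_strabismus(left, short, "independent"), "nlhebb_shape_error")
})
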