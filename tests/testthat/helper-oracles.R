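# Closed-form oracles and shared fixtures, independent of the package's own
# quadrature path wherever a closed form exists.

# Gaussian partial moments E[(X - th)_+^n] for X ~ N(0,1), by the recursion
# I_{n+1} = n I_{n-1} - th I_n with I_0 = 1 - Phi(th), I_1 = phi(th) - th I_0.
gauss_plus_moment <- function(n, th) {
  I <- c(1 - pnorm(th), dnorm(th) - th * (1 - pnorm(th)))
  if (n <= 1) return(I[n + 1])
  for (k in 2:n) I <- c(I, (k - 1) * I[k - 1] - th * I[k])
  I[n + 1]
}

# Laplace (unit variance, scale 1/sqrt(2)) partial moments E[(X - th)_+^n],
# th >= 0: n! exp(-sqrt(2) th) / sqrt(2)^(n+2).
laplace_plus_moment <- function(n, th) {
  stopifnot(th >= 0)
  factorial(n) * exp(-sqrt(2) * th) / sqrt(2)^(n + 2)
}

# Root of the quadratic-rectifier SI numerator (theta1 = 1):
# (1/3) dE3 = (b/2) dE2  =>  b* = (2/3) dE3 / dE2.
quadrect_bstar_oracle <- function(theta1 = 1) {
  dE3 <- laplace_plus_moment(3, theta1) - gauss_plus_moment(3, theta1)
  dE2 <- laplace_plus_moment(2, theta1) - gauss_plus_moment(2, theta1)
  (2 / 3) * dE3 / dE2
}

# Small kurtotic generative ensemble with known whitened dictionary.
make_recovery_problem <- function(seed, n = 50000, patch = c(16, 16), m = 64,
                                  noise_sd = 0.1) {
  D <- gabor_dictionary(patch, m, seed = spawn_seed(seed, "dict"))
  gm <- generative_model(D, "laplacian", noise_sd = noise_sd,
                         seed = spawn_seed(seed, "lat"))
  ens <- generate_patch_ensemble(gm, n)
  wm <- suppressWarnings(fit_whitening(ens))
  ensw <- apply_whitening(wm, ens)
  B <- apply(wm$M %*% D, 2, function(cl) cl / sqrt(sum(cl^2)))
  list(ensemble = ensw, whitened_dictionary = B, dictionary = D, model = wm)
}

# The standard annealed learning schedule used for dictionary recovery:
# a search phase followed by refinement phases with decreasing step size.
recovery_schedule <- function() c(rep(2e-3, 30), rep(5e-4, 20), rep(2e-4, 10))

# Run single-neuron learning on a recovery problem; returns max |cos| with
# the whitened dictionary.
recovery_alignment <- function(seed, f, n = 50000) {
  prob <- make_recovery_problem(seed, n = n)
  sched <- recovery_schedule()
  lc <- learn_config(eta_w = sched[1], seed = spawn_seed(seed, "learn"))
  res <- learn_single_neuron(prob$ensemble, f, lc, n_epochs = length(sched),
                             eta_schedule = sched)
  list(cos = max(abs(drop(crossprod(prob$whitened_dictionary, res$w)))),
       w = res$w, prob = prob)
}

# Simple deterministic grating image (0-based pixel coordinates).
grating_image <- function(size, frequency, theta, phase = 0) {
  outer(0:(size - 1), 0:(size - 1), function(y, x)
    cos(2 * pi * frequency * (x * cos(theta) + y * sin(theta)) + phase))
}

expect_error_class <- function(expr, class) {
  expect_true(inherits(tryCatch(expr, error = function(e) e), class))
}
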