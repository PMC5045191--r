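test_that("hebbian_step follows the normalized update rule", {
  # below threshold: no change
  w <- c(1, 0)
  expect_identical(hebbian_step(w, c(0.1, 0.1), nl_linear_rectifier(3), 0.1), w)
  # colinear input: normalization absorbs the update exactly
  expect_equal(hebbian_step(c(1, 0), c(2, 0), nl_linear_rectifier(0.5), 0.1),
               c(1, 0), tolerance = 1e-15)
  # hand-computed oracle: u = 1, f(u) = 0.5, update (1.05, 0.05), norm sqrt(1.105)
  got <- hebbian_step(c(1, 0), c(1, 1), nl_linear_rectifier(0.5), 0.1)
  expect_equal(got, c(1.05, 0.05) / sqrt(1.105), tolerance = 1e-14)
})

test_that("the compiled learning loop equals iterated hebbian_step", {
  prob <- make_recovery_problem(2, n = 300, patch = c(4, 4), m = 8)
  ens <- prob$ensemble
  f <- nl_quadratic_rectifier(1, 1)
  lc <- learn_config(eta_w = 0.01, seed = 21)
  res <- learn_single_neuron(ens, f, lc, n_epochs = 2)
  # replay the exact same presentation order through the R single-step path
  X <- ensemble_data(ens)
  w <- nlhebb:::init_weights(ncol(X), 1L, lc$seed)[, 1]
  for (e in 1:2) for (k in nlhebb:::epoch_order(nrow(X), lc$seed, e)) {
    w <- hebbian_step(w, X[k, ], f, lc$eta_w)
  }
  expect_equal(res$w, w, tolerance = 1e-12)
  expect_equal(res$n_steps, 600)
})

test_that("learning guards: divergence error, whitening warning, checkpoints", {
  prob <- make_recovery_problem(3, n = 500, patch = c(4, 4), m = 8)
  f <- nl_quadratic_rectifier(1, 1)
  raw <- generate_patch_ensemble(
    generative_model(gabor_dictionary(c(4, 4), 4, 1), "laplacian", seed = 1), 100)
  expect_warning(learn_single_neuron(raw, f, learn_config(eta_w = 1e-4, seed = 1)),
                 class = "nlhebb_whitening_warning")
  res <- learn_single_neuron(prob$ensemble, f, learn_config(eta_w = 0.01, seed = 2),
                             n_epochs = 1, checkpoint_every = 100)
  expect_equal(nrow(res$checkpoints), 5)
  expect_equal(sqrt(rowSums(res$checkpoints^2)), rep(1, 5), tolerance = 1e-10)
})

test_that("learning climbs the projection-pursuit objective", {
  f <- nl_quadratic_rectifier(1, 1)
  gains <- vapply(1:5, function(s) {
    prob <- make_recovery_problem(s, n = 8000, patch = c(8, 8), m = 16)
    # evaluate on an independent draw whitened by the same transform
    ho <- apply_whitening(prob$model, generate_patch_ensemble(
      generative_model(prob$dictionary, "laplacian", noise_sd = 0.1,
                       seed = spawn_seed(s, "held")), 4000))
    lc <- learn_config(eta_w = 0.003, seed = spawn_seed(s, "learn"))
    w0 <- nlhebb:::init_weights(64, 1L, lc$seed)[, 1]
    res <- learn_single_neuron(prob$ensemble, f, lc, n_epochs = 8)
    objective_value(f, res$w, ho) - objective_value(f, w0, ho)
  }, numeric(1))
  expect_true(all(gains > 0))
})

test_that("network inference solves the lateral fixed point", {
  lc <- learn_config(g = nl_linear_rectifier(0), seed = 1)
  # K = 1: y = g(w'x) exactly, no recurrence
  st1 <- network_state(cbind(unit_vec(c(1, 2, -1))))
  x <- c(0.5, -0.2, 1.4)
  y1 <- network_inference(st1, x, lc)
  expect_identical(as.numeric(y1), eval_f(lc$g, sum(st1$W[, 1] * x)))
  expect_identical(attr(y1, "iterations"), 0L)
  # V = 0: decoupled units
  stV0 <- network_state(diag(3))
  expect_equal(as.numeric(network_inference(stV0, x, lc)), pmax(x, 0))
  # 2-neuron closed form (both units active)
  V <- matrix(c(0, 0.3, 0.4, 0), 2, byrow = TRUE)
  st2 <- network_state(diag(2), V)
  b <- c(2, 1.5)
  y <- network_inference(st2, b, lc)
  y1c <- (b[1] - 0.3 * b[2]) / (1 - 0.3 * 0.4)
  expect_equal(as.numeric(y), c(y1c, b[2] - 0.4 * y1c), tolerance = 1e-4)
  expect_true(attr(y, "converged"))
  # vectorized activities agree with per-sample inference
  X <- rbind(b, c(1, 0.2), c(-1, 2))
  ensX <- patch_ensemble(X, c(1, 2, 1), whitened = "exact")
  Y <- network_activities(st2, ensX, lc)
  # both solvers stop within conv_tol of the fixed point, so they agree to
  # the corresponding y accuracy (~conv_tol / alpha)
  for (i in 1:3) {
    expect_equal(Y[i, ], as.numeric(network_inference(st2, X[i, ], lc)),
                 tolerance = 1e-4)
  }
})

test_that("a K = 1 network reduces exactly to the single neuron", {
  prob <- make_recovery_problem(4, n = 2000, patch = c(8, 8), m = 16)
  g <- nl_linear_rectifier(0.5); h <- nl_quadratic_plasticity(1)
  lc <- learn_config(eta_w = 0.005, eta_v = 0.05, g = g, h = h, seed = 17)
  st <- network_learning(prob$ensemble, lc, K = 1, n_epochs = 2)
  res <- learn_single_neuron(prob$ensemble, nl_compose(g, h), lc, n_epochs = 2)
  expect_identical(st$W[, 1], res$w)
  expect_identical(st$V, matrix(0, 1, 1))
})

test_that("network invariants hold after learning", {
  prob <- make_recovery_problem(6, n = 3000, patch = c(4, 4), m = 8)
  lc <- learn_config(eta_w = 0.01, eta_v = 0.05, g = nl_linear_rectifier(0.5),
                     h = nl_quadratic_plasticity(1), seed = 3)
  st <- network_learning(prob$ensemble, lc, K = 6, n_epochs = 2)
  expect_equal(sqrt(colSums(st$W^2)), rep(1, 6), tolerance = 1e-10)
  expect_true(all(st$V >= 0))
  expect_identical(diag(st$V), rep(0, 6))
  expect_false(is.null(attr(st, "provenance")$unconverged_fraction))
})

test_that("lateral inhibition splits nearly identical neurons", {
  prob <- make_recovery_problem(8, n = 6000, patch = c(4, 4), m = 8)
  w0 <- nlhebb:::init_weights(16, 1L, 5)[, 1]
  W0 <- cbind(w0, unit_vec(w0 + 1e-3 * nlhebb:::init_weights(16, 1L, 6)[, 1]))
  g <- nl_linear_rectifier(0.5); h <- nl_quadratic_plasticity(1)
  run <- function(eta_v) {
    lc <- learn_config(eta_w = 0.005, eta_v = eta_v, g = g, h = h, seed = 19)
    st <- network_learning(prob$ensemble, lc, K = 2, n_epochs = 6,
                           state0 = network_state(W0))
    abs(sum(st$W[, 1] * st$W[, 2]))
  }
  expect_gt(run(0), 0.99)       # without inhibition the twins stay together
  expect_lt(run(0.1), 0.9)      # inhibition drives them apart
})

test_that("anti-Hebbian plasticity decorrelates activity over training", {
  set.seed(10)
  d <- 16
  Dm <- apply(matrix(rnorm(d * 8), d), 2, unit_vec)
  gm <- generative_model(Dm, "laplacian", noise_sd = 0.2, geometry = c(4, 4, 1),
                         seed = 23)
  ens <- generate_patch_ensemble(gm, 8000)
  lc <- learn_config(eta_w = 0.002, eta_v = 0.05, g = nl_linear_rectifier(0.5),
                     h = nl_quadratic_plasticity(1), seed = 29)
  st0 <- network_state(nlhebb:::init_weights(d, 10L, lc$seed))
  st <- suppressWarnings(network_learning(ens, lc, K = 10, n_epochs = 6))
  ho <- generate_patch_ensemble(
    generative_model(Dm, "laplacian", noise_sd = 0.2, geometry = c(4, 4, 1),
                     seed = 777), 3000)
  med_abs_cor <- function(state) {
    C <- suppressWarnings(cor(network_activities(state, ho, lc)))
    C[is.na(C)] <- 0
    median(abs(C[upper.tri(C)]))
  }
  expect_lt(med_abs_cor(st), med_abs_cor(st0))
})
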