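test_that("quadrature SI reproduces closed-form truncated moments", {
  # f(u) = u_+^2, F = u_+^3/3: numerator from exact partial moments
  r <- selectivity_index(nl_power_rectified(2))
  num_oracle <- (laplace_plus_moment(3, 0) - gauss_plus_moment(3, 0)) / 3
  # the +/-12 standard-unit quadrature domain truncates ~1e-5 of the cubic
  # Laplace tail, so the oracle is matched at 5e-4 relative
  expect_equal(r$numerator, num_oracle, tolerance = 5e-4)
  expect_gt(r$si, 0)
  # a rectifier with positive threshold prefers the kurtotic reference
  expect_gt(selectivity_index(nl_linear_rectifier(1))$si, 0)
  # sign flip negates SI exactly (sigma terms invariant)
  nl <- nl_quadratic_rectifier(1, 1)
  rp <- selectivity_index(nl); rn <- selectivity_index(nl_negate(nl))
  expect_equal(rn$si, -rp$si, tolerance = 1e-12)
  expect_equal(rn$sigma_l, rp$sigma_l)
})

test_that("SI is invariant under multiplicative scaling and additive shifts", {
  base <- nl_quadratic_rectifier(1, 1)
  si0 <- selectivity_index(base)$si
  for (alpha in c(0.1, 10)) {
    scaled <- nl_negate(nl_negate(base))          # start from a wrapped copy
    scaled$f <- function(u) alpha * base$f(u)
    scaled$F <- function(u) alpha * base$F(u)
    expect_equal(selectivity_index(scaled)$si, si0, tolerance = 1e-10,
                 info = paste("alpha =", alpha))
    # plain-product convention rescales SI but keeps the sign
    expect_equal(sign(selectivity_index(scaled, sigma_convention = "product")$si),
                 sign(si0))
  }
  # additive constant beta in f adds beta*u to F; zero-mean references leave
  # the numerator unchanged
  beta <- 0.7
  shifted <- nl_negate(nl_negate(base))
  shifted$f <- function(u) base$f(u) + beta
  shifted$F <- function(u) base$F(u) + beta * u
  expect_equal(selectivity_index(shifted)$numerator,
               selectivity_index(base)$numerator, tolerance = 1e-9)
})

test_that("Monte-Carlo SI agrees with quadrature and records its seed", {
  nl <- nl_quadratic_rectifier(1, 1)
  q <- selectivity_index(nl)
  mc <- selectivity_index(nl, method = "monte_carlo", n_samples = 2e5, seed = 42)
  expect_lt(abs(mc$si - q$si), 3 * mc$se)
  expect_identical(mc$seed, 42L)
  expect_identical(mc, selectivity_index(nl, "monte_carlo", n_samples = 2e5, seed = 42))
  small <- selectivity_index(nl, "monte_carlo", n_samples = 5e3, seed = 1)
  expect_true(length(small$notes) > 0)
})

test_that("critical_parameter locates SI sign changes", {
  # symmetry forces the linear-rectifier crossing to theta = 0
  th <- critical_parameter(function(t) nl_linear_rectifier(t), c(-1, 1))
  expect_lt(abs(th), 2e-4)
  # quadratic rectifier crossing vs the closed-form moment oracle
  b1 <- critical_parameter(function(b) nl_quadratic_rectifier(1, b), c(0, 6))
  expect_equal(b1, quadrect_bstar_oracle(1), tolerance = 1e-3)
  # bracket independence
  b2 <- critical_parameter(function(b) nl_quadratic_rectifier(1, b), c(1, 4))
  expect_equal(b1, b2, tolerance = 2e-4)
  # no sign change -> bracket error naming the endpoint signs
  err <- tryCatch(critical_parameter(function(b) nl_quadratic_rectifier(1, b), c(0, 1)),
                  error = function(e) e)
  expect_s3_class(err, "nlhebb_bracket_error")
  expect_match(conditionMessage(err), "SI\\(lo\\)")
})

test_that("objective_value is the mean of F over projections", {
  prob <- make_recovery_problem(5, n = 4000, patch = c(8, 8), m = 16)
  ens <- prob$ensemble
  w <- prob$whitened_dictionary[, 1]
  # constant f (F(u) = u) has zero objective on whitened, mean-centred data
  const1 <- nl_tabulated(c(-100, 100), c(1, 1))
  expect_lt(abs(objective_value(const1, w, ens)), 1e-10)
  # whitening pins the projected variance at exactly 1 (n-1 convention)
  proj <- ensemble_data(ens) %*% w
  expect_equal(as.numeric(var(proj)), 1, tolerance = 1e-6)
  expect_equal(objective_value(nl_linear(), w, ens),
               mean(eval_F(nl_linear(), as.numeric(proj))))
  expect_error_class(objective_value(nl_linear(), w[-1], ens), "nlhebb_shape_error")
})

test_that("relative objective normalizes to [0,1] and finds the planted Gabor", {
  feats <- candidate_features(c(16, 16), seed = 2)
  # generative dictionary containing the localized Gabor candidate
  D <- cbind(feats$gabor, gabor_dictionary(c(16, 16), 15, seed = 31))
  gm <- generative_model(D, "laplacian", noise_sd = 0.1, seed = 7)
  ens <- generate_patch_ensemble(gm, 20000)
  ensw <- apply_whitening(suppressWarnings(fit_whitening(ens)), ens)
  res <- relative_objective(nl_quadratic_rectifier(1, 1), feats, ensw)
  expect_equal(range(res$R_star), c(0, 1))
  expect_equal(res$label[which.max(res$R_star)], "gabor")
  # two features -> endpoints
  res2 <- relative_objective(nl_quadratic_rectifier(1, 1), feats[c(1, 5)], ensw)
  expect_setequal(res2$R_star, c(0, 1))
  # permutation invariance
  res3 <- relative_objective(nl_quadratic_rectifier(1, 1), rev(feats), ensw)
  expect_equal(res3$R_star, rev(res$R_star), tolerance = 1e-12)
  # identical features -> degenerate normalization
  expect_error_class(relative_objective(nl_linear(), feats[c(1, 1)], ensw),
                     "nlhebb_degenerate_normalization_error")
})

test_that("objective_map reduces to objective_value and recovers a planted scale", {
  # single planted Gabor of known envelope
  spec <- gabor_spec(x_c = 7.5, y_c = 7.5, frequency = 0.2, sigma_x = 1.5,
                     sigma_y = 2.5, phase = 0, theta = pi / 3)
  D <- cbind(make_filter(spec, c(16, 16)))
  gm <- generative_model(D, "laplacian", noise_sd = 0.1, seed = 8)
  ens <- generate_patch_ensemble(gm, 15000)
  ensw <- apply_whitening(suppressWarnings(fit_whitening(ens)), ens)
  nl <- nl_quadratic_rectifier(1, 1)
  # single cell with pinned frequency and phase equals objective_value
  one <- objective_map(nl, ensw,
                       data.frame(sigma_x = 1.5, sigma_y = 2.5, frequency = 0.2,
                                  phase = 0),
                       defaults = list(x_c = 7.5, y_c = 7.5, theta = pi / 3))
  expect_equal(one$R, objective_value(nl, D[, 1], ensw), tolerance = 1e-12)
  # width/length grid: the planted envelope cell attains the maximum
  cells <- expand.grid(sigma_x = c(0.8, 1.5, 3), sigma_y = c(1, 2.5, 4))
  map <- objective_map(nl, ensw, cells, frequencies = c(0.1, 0.2, 0.3),
                       defaults = list(x_c = 7.5, y_c = 7.5, theta = pi / 3))
  best <- map[which.max(map$R), ]
  expect_equal(c(best$sigma_x, best$sigma_y), c(1.5, 2.5))
  expect_equal(range(map$R_star), c(0, 1))
  expect_error_class(objective_map(nl, ensw, data.frame()), "nlhebb_configuration_error")
})
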