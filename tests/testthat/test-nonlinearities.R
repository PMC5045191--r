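# All Table-style nonlinearities with closed-form antiderivatives, for
# parameterised checks.
closed_form_kinds <- function() {
  list(linear = nl_linear(),
       linear_rectifier = nl_linear_rectifier(1),
       linear_rectifier_neg_theta = nl_linear_rectifier(-0.5),
       quadratic_rectifier = nl_quadratic_rectifier(1, 1),
       sigmoid = nl_sigmoid(1),
       negative_sigmoid = nl_negative_sigmoid(0.5),
       power = nl_power_rectified(2),
       cubic = nl_cubic(),
       sine = nl_sine(),
       cosine = nl_cosine(),
       symmetric_rectifier = nl_symmetric_rectifier(2),
       fI = nl_piecewise_linear_fI(143, 0.08),
       quadratic_plasticity = nl_quadratic_plasticity(22.1),
       l0 = nl_l0_activation(3),
       cauchy = nl_cauchy_activation(3))
}

test_that("eval_f matches the closed forms at reference points", {
  expect_equal(eval_f(nl_linear_rectifier(3), 5), 2)
  expect_equal(eval_f(nl_quadratic_rectifier(1, 1), 1), 0)
  expect_equal(eval_f(nl_quadratic_rectifier(1, 1), 3), 2)  # (u-1)^2 - (u-1) at u=3
  expect_equal(eval_f(nl_quadratic_rectifier(1, 1), 2), 0)  # LTP threshold
  # vectorized output keeps shape
  u <- matrix(seq(-2, 4, length.out = 6), 2)
  expect_identical(dim(eval_f(nl_sigmoid(0), u)), dim(u))
})

test_that("rectifier-family members vanish below their thresholds", {
  cases <- list(list(nl_linear_rectifier(1.5), 1.5),
                list(nl_quadratic_rectifier(0.7, 2), 0.7),
                list(nl_l0_activation(2.5), 2.5),
                list(nl_piecewise_linear_fI(143, 0.08), 0.08),
                list(nl_power_rectified(2), 0),
                list(nl_cauchy_activation(1), 0))
  for (cs in cases) {
    u <- seq(cs[[2]] - 3, cs[[2]] - 1e-9, length.out = 50)
    expect_true(all(eval_f(cs[[1]], u) == 0), info = cs[[1]]$kind)
  }
})

test_that("construction and evaluation errors are classed and informative", {
  expect_error_class(nl_from_config(list(kind = "parabolic")),
                     "nlhebb_invalid_specification")
  expect_error_class(nl_linear_rectifier(NULL), "nlhebb_configuration_error")
  expect_error_class(nl_quadratic_rectifier(1, NA), "nlhebb_configuration_error")
  expect_error_class(eval_f(nl_linear(), c(1, Inf)), "nlhebb_invalid_specification")
})

test_that("eval_F anchors at zero and matches closed forms / quadrature", {
  for (nl in closed_form_kinds()) {
    expect_equal(eval_F(nl, 0), 0, info = nl$kind)
  }
  expect_equal(eval_F(nl_linear_rectifier(1), 3), 2)  # (u-theta)_+^2/2
  # sigmoid closed form vs its analytic value
  expect_equal(eval_F(nl_sigmoid(0), 1), 0.5 * log1p(exp(2)) - 0.5 * log(2),
               tolerance = 1e-12)
  # closed form agrees with direct quadrature of f on a grid, every kind
  grid <- seq(-4, 4, length.out = 9)
  for (nl in closed_form_kinds()) {
    for (u in grid) {
      expect_equal(eval_F(nl, u),
                   integrate(function(v) eval_f(nl, v), 0, u,
                             rel.tol = 1e-12, abs.tol = 1e-12)$value,
                   tolerance = 1e-8, info = paste(nl$kind, u))
    }
  }
})

test_that("composition evaluates h(g(u)) and integrates by quadrature", {
  # identity composition
  g <- nl_quadratic_rectifier(1, 1)
  expect_equal(eval_f(nl_compose(g, nl_linear()), seq(-2, 4, 0.5)),
               eval_f(g, seq(-2, 4, 0.5)))
  # rectifier then square equals squared rectifier pointwise
  comp <- nl_compose(nl_linear_rectifier(1), nl_power_rectified(2))
  u <- seq(-2, 4, length.out = 61)
  expect_equal(eval_f(comp, u), pmax(u - 1, 0)^2, tolerance = 1e-14)
  expect_equal(eval_F(comp, 3), (3 - 1)^3 / 3, tolerance = 1e-9)
  # f-I curve composed with triplet quadratic plasticity: zero crossings at
  # the f-I threshold and at theta + b/a
  eff <- nl_compose(nl_gif_fI(), nl_quadratic_plasticity(22.1))
  expect_equal(eval_f(eff, 0.08), 0)
  ltp <- uniroot(function(u) eval_f(eff, u), c(0.1, 1), tol = 1e-10)$root
  expect_equal(ltp, 0.08 + 22.1 / 143, tolerance = 1e-7)
  # associativity on a grid
  a <- nl_linear_rectifier(0.5); b <- nl_power_rectified(2); cc <- nl_sigmoid(0)
  u <- seq(-3, 3, length.out = 41)
  expect_equal(eval_f(nl_compose(nl_compose(a, b), cc), u),
               eval_f(nl_compose(a, nl_compose(b, cc)), u), tolerance = 1e-12)
})

test_that("negation flips f and F exactly", {
  u <- seq(-3, 3, length.out = 31)
  for (nl in list(nl_sigmoid(1), nl_quadratic_rectifier(1, 2), nl_sine())) {
    expect_identical(eval_f(nl_negate(nl), u), -eval_f(nl, u))
    expect_identical(eval_F(nl_negate(nl), u), -eval_F(nl, u))
  }
})

test_that("penalty-derived activations match their defining inverses", {
  # L0: hard threshold
  expect_equal(eval_f(activation_from_penalty("L0", 3), c(2.9, 3.0)), c(0, 3))
  # L1: linear rectifier at lambda
  expect_equal(eval_f(activation_from_penalty("L1", 2), 5), 3)
  # Cauchy: forward-evaluate T then invert
  ca <- activation_from_penalty("cauchy", 3)
  expect_equal(eval_f(ca, 0), 0)
  expect_equal(eval_f(ca, 4), 1, tolerance = 1e-8)  # T(1) = 1 + 2*3*1/2 = 4
  # round trip T(activation(u)) = u on [0, 100]
  Tfun <- function(y) y + 2 * 3 * y / (1 + y^2)
  u <- seq(0, 100, length.out = 200)
  expect_equal(Tfun(eval_f(ca, u)), u, tolerance = 1e-8)
  # monotonicity bound on lambda
  expect_error_class(activation_from_penalty("cauchy", 4.5),
                     "nlhebb_invalid_specification")
  expect_silent(activation_from_penalty("cauchy", 4))
  # cauchy closed-form F agrees with quadrature of the inverse
  expect_equal(eval_F(ca, 5),
               integrate(function(v) eval_f(ca, v), 0, 5, rel.tol = 1e-10)$value,
               tolerance = 1e-8)
})

test_that("config serialization round-trips every kind", {
  kinds <- c(closed_form_kinds(),
             list(composed = nl_compose(nl_piecewise_linear_fI(143, 0.08),
                                        nl_quadratic_plasticity(22.1)),
                  negated = nl_negate(nl_sigmoid(1.2)),
                  tabulated = nl_tabulated(seq(-2, 2, 0.5), tanh(seq(-2, 2, 0.5)))))
  u <- seq(-2.5, 2.5, length.out = 21)
  for (nl in kinds) {
    rt <- nl_from_config(nl_to_config(nl))
    expect_equal(eval_f(rt, u), eval_f(nl, u), info = nl$kind)
    # and through YAML text (YAML prints finitely many digits)
    rt2 <- nl_from_config(yaml::yaml.load(yaml::as.yaml(nl_to_config(nl))))
    expect_equal(eval_f(rt2, u), eval_f(nl, u), tolerance = 1e-6, info = nl$kind)
  }
})

test_that("compiled stage-chain evaluator agrees with the R closures", {
  u <- seq(-4, 4, length.out = 101)
  kinds <- c(closed_form_kinds(),
             list(composed = nl_compose(nl_linear_rectifier(0.5),
                                        nl_quadratic_plasticity(1)),
                  negated = nl_negate(nl_quadratic_rectifier(1, 1)),
                  tabulated = nl_tabulated(seq(-2, 2, 0.1), sin(seq(-2, 2, 0.1)))))
  for (nl in kinds) {
    expect_equal(nlhebb:::.eval_chain_cpp(nlhebb:::nl_stage_spec(nl), u),
                 as.numeric(eval_f(nl, u)), tolerance = 1e-12, info = nl$kind)
  }
})
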