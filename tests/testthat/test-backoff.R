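test_that("confidence levels map to the tabulated backoff parameters", {
  # normal quantiles at the four standard confidence levels
  expect_equal(backoff_from_confidence(0.80), 0.84)
  expect_equal(backoff_from_confidence(0.90), 1.28)
  expect_equal(backoff_from_confidence(0.95), 1.65)
  expect_equal(backoff_from_confidence(0.975), 1.96)
  expect_equal(backoff_from_confidence(0.5), 0)
  # distribution-free Cantelli-Chebyshev bound
  expect_equal(backoff_from_confidence(0.95, "cantelli"), 4.36)
  expect_error(backoff_from_confidence(1), "between 0 and 1")
  expect_error(backoff_from_confidence(0), "between 0 and 1")
})

test_that("backoff properties: monotone quantile, Cantelli dominates", {
  betas <- c(0.55, 0.7, 0.8, 0.9, 0.95, 0.99)
  q <- vapply(betas, backoff_from_confidence, 0)
  expect_true(all(diff(q) > 0))
  cant <- vapply(betas, backoff_from_confidence, 0, method = "cantelli")
  expect_true(all(cant >= q))
})

test_that("robustified constraint margins follow the backoff formula", {
  # exactly active at zero variance
  expect_equal(robustify_constraint(0.90, 0, 1.65, 0.90, "ge"), 0)
  # 1.0 - 1.65 * 0.2 - 0.90
  expect_equal(robustify_constraint(1.0, 0.04, 1.65, 0.90, "ge"), -0.23)
  # alpha = 0 reduces to the nominal margin
  expect_equal(robustify_constraint(1.0, 0.04, 0, 0.90, "ge"), 0.1)
  # symmetric upper bound
  expect_equal(robustify_constraint(0.8, 0.04, 1.0, 1.0, "le"),
               1.0 - 0.8 - 0.2)
  expect_error(robustify_constraint(1, -0.1, 1, 0.9), "negative variance")
})

test_that("robustified objectives support both penalty forms", {
  expect_equal(robustify_objective(6.5, 0, 1.96, "sqrt_variance"), 6.5)
  expect_equal(robustify_objective(6.5, 0, 1.96, "variance"), 6.5)
  expect_equal(robustify_objective(6.5, 0.49, 1.96, "sqrt_variance"),
               6.5 + 1.96 * 0.7)
  expect_equal(robustify_objective(6.5, 0.49, 1.96, "variance"),
               6.5 + 1.96 * 0.49)
})

test_that("backoff policies resolve alpha from confidence", {
  p <- backoff_policy(confidence = 0.95)
  expect_equal(p$alpha, 1.65)
  expect_equal(p$alpha_objective, 1.65)
  p2 <- backoff_policy(alpha = 1.96, penalty = "variance")
  expect_equal(p2$penalty, "variance")
  expect_error(backoff_policy(), "alpha or confidence")
  expect_error(backoff_policy(alpha = -1), "non-negative")
})

test_that("robust OCP assembly embeds the technique dynamics", {
  m2 <- case2_model()
  spec <- spec_case2()
  pol <- backoff_policy(alpha = 1.96, penalty = "variance")
  states <- vapply(c("nominal", "linearization", "sigma_points", "pce1",
                     "pce2"), function(tech)
    assemble_robust_ocp(m2, tech, spec, pol)$n_dynamic_states, 0)
  expect_equal(unname(states), c(9, 36, 63, 36, 90))
  # constraint evaluator reproduces the backoff margin at a synthetic state
  ocp <- assemble_robust_ocp(m2, "sigma_points", spec, pol)
  xf <- rep(as.numeric(case2_model()$x0), 7)
  xf[4 + 9 * (0:6)] <- 0.9            # S5 identical in every replica
  margin <- ocp$constraints[[1]]$fun(xf, 30)
  expect_equal(margin, 0.9 - 0.675, tolerance = 1e-10)  # Var = 0
  expect_error(assemble_robust_ocp(m2, "sigma_points"), "uncertainty_spec")
})

test_that("zero backoff and zero covariance reduce to the nominal problem", {
  em <- energy_model()
  spec0 <- uncertainty_spec("normal", c(p = 1), rel_std = 1e-6)
  nom <- solve_ocp(assemble_robust_ocp(em, "nominal"), 8,
                   options = test_opts)
  for (tech in c("linearization", "sigma_points")) {
    ocp <- assemble_robust_ocp(em, tech, spec0, backoff_policy(alpha = 0))
    sol <- solve_ocp(ocp, 8, options = test_opts)
    expect_equal(sol$objective, nom$objective, tolerance = 1e-4)
  }
})
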