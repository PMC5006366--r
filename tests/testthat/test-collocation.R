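test_that("Radau nodes and quadrature have the stated order", {
  tau <- radau_nodes(3)
  expect_equal(tau, c((4 - sqrt(6)) / 10, (4 + sqrt(6)) / 10, 1),
               tolerance = 1e-10)
  w <- radau_weights(3)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # 3-point right-Radau is exact up to degree 2*3-2 = 4
  for (k in 0:4)
    expect_equal(sum(w * tau^k), 1 / (k + 1), tolerance = 1e-12)
  expect_gt(abs(sum(w * tau^5) - 1 / 6), 1e-5)
  expect_error(radau_nodes(0), "unsupported degree")
  # other degrees: endpoint included, quadrature exact to 2d-2
  for (d in c(2, 4)) {
    taud <- radau_nodes(d); wd <- radau_weights(d)
    expect_equal(taud[d], 1, tolerance = 1e-10)
    for (k in seq(0, 2 * d - 2))
      expect_equal(sum(wd * taud^k), 1 / (k + 1), tolerance = 1e-9)
  }
})

test_that("implicit collocation steps reproduce closed-form dynamics", {
  cm <- colloc_matrices(3)
  # differentiation matrix rows sum to zero (derivative of a constant)
  expect_equal(colSums(cm$C), rep(0, 3), tolerance = 1e-12)
  # linear decay x' = -x over [0, 1]
  rhs <- function(x, u, theta = NULL, t = 0) -x
  jx <- function(x, u, ...) matrix(-1, 1, 1)
  ju <- function(x, u, ...) matrix(0, 1, 1)
  x <- 1
  for (e in 1:10)
    x <- robustoc:::colloc_element(rhs, jx, ju, x, 0, 0.1, cm)$x_end
  expect_equal(x, exp(-1), tolerance = 1e-8)
})

test_that("transcription counts and residuals are consistent", {
  m2 <- case2_model()
  ocp <- assemble_robust_ocp(m2, "nominal")
  grid <- collocation_grid(10, 30)
  nlp <- transcribe(ocp, grid)
  expect_equal(nlp$n_continuity, (10 - 1) * 9)
  expect_equal(nlp$n_collocation, 10 * 3 * 9)
  expect_equal(nlp$n_w, 9 * 4)      # first element pinned at r(0)
  w <- rep(0.08, nlp$n_w)
  expect_lt(robustoc:::collocation_residuals(nlp, w), 1e-9)
  # eliminated states agree with an independent implicit integration
  sim <- nlp$run_sim(w)
  tr <- simulate_model(m2, control_profile(grid$boundaries,
                                           nlp$controls_of(w)))
  expect_equal(unname(sim$xf), unname(tr$states[nrow(tr$states), ]),
               tolerance = 1e-4)
})

test_that("reduced gradients match finite differences", {
  m1 <- case1_model()
  ocp <- assemble_robust_ocp(m1, "linearization", spec_case1(),
                             backoff_policy(alpha = 1.65))
  nlp <- transcribe(ocp, collocation_grid(4, 10))
  set.seed(7)
  w <- runif(nlp$n_w, 0.1, 0.3)
  fe <- nlp$eval_f(w)
  ge <- nlp$eval_g(w)
  h <- 1e-6
  for (i in c(1, 5, nlp$n_w)) {
    wp <- w; wm <- w
    wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
    expect_equal(fe$grad[i],
                 (nlp$eval_f(wp)$value - nlp$eval_f(wm)$value) / (2 * h),
                 tolerance = 1e-5)
    expect_equal(unname(ge$jac[1, i]),
                 (nlp$eval_g(wp)$value[1] - nlp$eval_g(wm)$value[1]) /
                   (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("the NLP solver recovers closed-form optima", {
  # min c(1) = int u^2 with x' = u, x(1) >= 1: optimum u = 1, cost 1
  em <- energy_model()
  sol <- solve_ocp(assemble_robust_ocp(em, "nominal"), n_elements = 10,
                   options = test_opts)
  expect_equal(sol$objective, 1, tolerance = 1e-5)
  expect_true(all(abs(sol$controls - 1) < 1e-3))
  expect_true(sol$feasible)
})

test_that("grid refinement leaves the nominal optimum stable", {
  s10 <- case1_nominal_sol(10)
  s20 <- cached("case1_nom_20",
                solve_ocp(assemble_robust_ocp(case1_model(), "nominal"), 20,
                          init = s10$profile, options = test_opts))
  expect_lt(abs(s10$objective - s20$objective), 1e-2)
})
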