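test_that("case-study right-hand sides match hand-computed fluxes", {
  m1 <- case1_model()
  # only e1 active: v1 = k1*S1*e1 = 1, so S2 grows at 1 and nothing else
  d <- evaluate_rhs(m1, c(S1 = 1, S2 = 0, S3 = 0, S4 = 0, x_extra = 0),
                    u = c(1, 0, 0), theta = c(1, 1, 1))
  expect_equal(unname(d), c(0, 1, 0, 0, 0))
  # intermediate accumulation integrand is S2 + S3
  d2 <- evaluate_rhs(m1, c(S1 = 1, S2 = 0.4, S3 = 0.3, S4 = 0, x_extra = 0),
                     u = c(0, 0, 0))
  expect_equal(unname(d2["x_extra"]), 0.7)

  m2 <- case2_model()
  # half-saturated Michaelis-Menten flux: S2 = K_M = 1 gives v2 = 0.5 e2
  d3 <- evaluate_rhs(m2, c(S2 = 1, S3 = 0, S4 = 0, S5 = 0, e1 = 0, e2 = 1,
                           e3 = 0, e4 = 0, x_extra = 0), u = rep(0, 4))
  expect_equal(unname(d3["S2"]), -0.5)
  expect_equal(unname(d3["S3"]), 0.5)
  # enzyme synthesis/decay: de/dt = r - lambda e
  d4 <- evaluate_rhs(m2, rep(0, 9), u = c(0.5, 0, 0, 0))
  expect_equal(unname(d4[c("e1", "e2", "e3", "e4")]), c(0.5, 0, 0, 0))
})

test_that("rhs validates dimensions", {
  m1 <- case1_model()
  expect_error(evaluate_rhs(m1, rep(0, 4), u = c(1, 0, 0)), "state")
  expect_error(evaluate_rhs(m1, rep(0, 5), u = c(1, 0)), "control")
  expect_error(evaluate_rhs(m1, rep(0, 5), u = rep(0, 3), theta = 1),
               "parameter")
})

test_that("model bookkeeping matches the case-study definitions", {
  m1 <- case1_model()
  expect_equal(m1$n_x, 5)
  expect_equal(unname(m1$theta_nom), c(1, 1, 1))
  expect_equal(m1$control_upper, rep(1, 3))   # E_T = 1 mM
  expect_equal(m1$terminal_constraints[[1]]$bound, 0.90)
  expect_equal(m1$t_f, 10)
  # buffered species has an all-zero stoichiometric row
  expect_true(all(m1$stoichiometry["S1", ] == 0))

  m2 <- case2_model()
  expect_equal(m2$n_x, 9)
  expect_equal(unname(m2$theta_nom[c("k_cat", "K_M", "lambda")]),
               c(1, 1, 0.5))
  expect_equal(m2$terminal_constraints[[1]]$bound, 0.675)
  expect_equal(m2$control_sum_bound, 0.5)
  expect_equal(m2$control_t0, c(0.5, 0, 0, 0))
  expect_error(get_model("case3"), "unknown model")
})

test_that("simulation reproduces closed-form trajectories", {
  m1 <- case1_model()
  # no enzymes: all fluxes zero, states constant
  tr0 <- simulate_model(m1, constant_controls(m1, c(0, 0, 0), t_f = 2),
                        theta = c(2, 3, 4))
  expect_equal(max(abs(sweep(tr0$states, 2, m1$x0))), 0, tolerance = 1e-10)
  # only v1 active: dS2/dt = 1 exactly
  tr1 <- simulate_model(m1, constant_controls(m1, c(1, 0, 0), t_f = 1))
  expect_equal(unname(tr1$states[nrow(tr1$states), "S2"]), 1,
               tolerance = 1e-7)
  # pure enzyme decay in case 2: e(t) = e0 exp(-lambda t)
  m2 <- case2_model(x0 = c(S2 = 0, S3 = 0, S4 = 0, S5 = 0, e1 = 1,
                           e2 = 0.5, e3 = 0, e4 = 0, x_extra = 0))
  tr2 <- simulate_model(m2, constant_controls(m2, rep(0, 4), t_f = 2))
  ef <- tr2$states[nrow(tr2$states), c("e1", "e2")]
  expect_equal(unname(ef), c(exp(-1), 0.5 * exp(-1)), tolerance = 1e-7)
})

test_that("buffered substrate stays constant and mass accounting holds", {
  m1 <- case1_model()
  set.seed(1)
  prof <- control_profile(seq(0, 10, length.out = 6),
                          matrix(runif(15, 0, 1 / 3), 5, 3))
  tr <- simulate_model(m1, prof)
  expect_true(all(abs(tr$states[, "S1"] - 1) < 1e-9))
  # d(S2+S3+S4)/dt = v1 >= 0: the pathway total is non-decreasing
  tot <- rowSums(tr$states[, c("S2", "S3", "S4")])
  expect_true(all(diff(tot) > -1e-9))
  # concentrations stay non-negative under non-negative controls
  expect_true(min(tr$states) > -1e-9)
})

test_that("integration tolerance refinement leaves terminal states stable", {
  m2 <- case2_model()
  prof <- control_profile(c(0, 10, 20, 30),
                          matrix(c(0.5, 0, 0, 0,
                                   0, 0.25, 0.25, 0,
                                   0, 0, 0, 0.5), 3, 4, byrow = TRUE))
  xa <- simulate_model(m2, prof, rtol = 1e-8, atol = 1e-10)
  xb <- simulate_model(m2, prof, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(xa$states[nrow(xa$states), ] -
                    xb$states[nrow(xb$states), ])), 1e-7)
})

test_that("threshold crossing times interpolate linearly", {
  traj <- structure(list(
    times = 0:4,
    states = cbind(S4 = c(0, 0.2, 0.4, 0.8, 1.2)),
    model = "synthetic"), class = "trajectory")
  expect_equal(threshold_time(traj, "S4", 1.0), 3.5)
  expect_equal(threshold_time(traj, "S4", 0.2), 1)
  # already above at t = 0
  traj$states <- cbind(S4 = rep(0.95, 5))
  expect_equal(threshold_time(traj, "S4", 0.9), 0)
  # never reached
  traj$states <- cbind(S4 = rep(0.5, 5))
  expect_true(is.na(threshold_time(traj, "S4", 0.9)))
  expect_error(threshold_time(traj, "nope", 0.9), "unknown species")
})

test_that("model configuration round-trips losslessly", {
  for (m in list(case1_model(), case2_model())) {
    f <- withr::local_tempfile(fileext = ".yaml")
    write_model_config(m, f)
    m2 <- read_model_config(f)
    expect_equal(m2$state_names, m$state_names)
    expect_equal(m2$stoichiometry, m$stoichiometry)
    expect_equal(unname(m2$theta_nom), unname(m$theta_nom))
    expect_equal(unname(m2$x0), unname(m$x0))
    expect_equal(m2$terminal_constraints, m$terminal_constraints)
    expect_equal(m2$control_sum_bound, m$control_sum_bound)
    # identical dynamics
    x <- seq_len(m$n_x) / 10
    u <- rep(0.1, m$n_u)
    expect_equal(m2$rhs(x, u, as.numeric(m$theta_nom), 0),
                 m$rhs(x, u, as.numeric(m$theta_nom), 0))
  }
  expect_error(write_model_config(scalar_growth_model(), tempfile()),
               "custom rhs")
})

test_that("trajectory writers emit tidy and wide tables", {
  m1 <- case1_model()
  tr <- simulate_model(m1, constant_controls(m1, c(0.3, 0.3, 0.3), t_f = 1),
                       output_times = c(0, 0.5, 1))
  fw <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, fw, "wide")
  write_trajectory(tr, ft, "tidy")
  wide <- read.csv(fw)
  expect_equal(nrow(wide), 3)
  expect_true(all(c("time", "S1", "x_extra") %in% names(wide)))
  tidy <- read.delim(ft)
  expect_equal(nrow(tidy), 3 * 5)
  expect_equal(sort(unique(tidy$state)), sort(m1$state_names))
})
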