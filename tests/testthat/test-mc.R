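test_that("parameter sampling matches the declared distributions", {
  spec <- spec_case1()
  th <- sample_parameters(spec, 1000, seed = 11)
  expect_equal(dim(th), c(1000, 3))
  expect_equal(unname(colMeans(th)), c(1, 1, 1), tolerance = 4 * 0.2 / sqrt(1000) * 3)
  expect_equal(unname(apply(th, 2, sd)), rep(0.2, 3), tolerance = 0.02 * 3)
  # degenerate: every draw equals the nominal vector
  th0 <- sample_parameters(uncertainty_spec("normal", c(a = 2), rel_std = 0),
                           50, seed = 1)
  expect_true(all(th0 == 2))
  # uniform support is exactly theta_nom +/- sqrt(3) sd
  spu <- uncertainty_spec("uniform", c(a = 1), rel_std = 0.2)
  thu <- sample_parameters(spu, 2000, seed = 3)
  expect_true(all(thu >= 1 - sqrt(3) * 0.2 & thu <= 1 + sqrt(3) * 0.2))
  expect_equal(sd(thu), 0.2, tolerance = 0.02)
  expect_error(sample_parameters(spec, 0), "at least 1")
})

test_that("sampling is reproducible and truncation enforces positivity", {
  spec <- spec_case1()
  expect_identical(sample_parameters(spec, 100, seed = 5),
                   sample_parameters(spec, 100, seed = 5))
  spec_wide <- uncertainty_spec("normal", c(a = 0.1), rel_std = 3)
  tht <- sample_parameters(spec_wide, 500, seed = 5, truncate = TRUE)
  expect_true(all(tht > 0))
})

test_that("batch RK4 and lsoda Monte-Carlo simulations agree", {
  m1 <- case1_model()
  prof <- control_profile(seq(0, 10, length.out = 6),
                          matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0.3, 0.3,
                                       0.3, 0, 0, 1), 1), 5, 3,
                                 byrow = TRUE))
  spec <- spec_case1()
  th <- sample_parameters(spec, 25, seed = 2)
  ra <- validate_controls(m1, prof, th, integrator = "lsoda")
  rb <- validate_controls(m1, prof, th, integrator = "rk4")
  expect_equal(ra$constraint, rb$constraint, tolerance = 1e-6)
  expect_equal(ra$violations, rb$violations)
  expect_equal(ra$J_mean, rb$J_mean, tolerance = 1e-6)
})

test_that("violation accounting uses strict comparison and zero noise
           gives zero violations", {
  m1 <- case1_model()
  prof <- constant_controls(m1, c(0.4, 0.3, 0.3), t_f = 10, n_elements = 5)
  spec0 <- uncertainty_spec("normal", m1$theta_nom, rel_std = 0)
  rep0 <- validate_controls(m1, prof, spec0, N = 20, seed = 1,
                            integrator = "rk4")
  # with nominal parameters this profile clears the bound
  expect_equal(rep0$violations, 0)
  expect_equal(rep0$violation_pct, 0)
  expect_equal(rep0$N, 20)
  # report invariants
  spec <- spec_case1()
  repn <- validate_controls(m1, prof, spec, N = 200, seed = 9,
                            integrator = "rk4")
  expect_equal(repn$violation_pct, 100 * repn$violations / 200)
  expect_gte(repn$J_sd, 0)
  expect_gte(repn$ct_sd, 0)
})

test_that("mc reports and tables are reproducible given the seed", {
  m1 <- case1_model()
  prof <- constant_controls(m1, c(0.4, 0.3, 0.3), t_f = 10, n_elements = 5)
  spec <- spec_case1()
  r1 <- validate_controls(m1, prof, spec, N = 100, seed = 4,
                          integrator = "rk4")
  r2 <- validate_controls(m1, prof, spec, N = 100, seed = 4,
                          integrator = "rk4")
  expect_identical(r1$constraint, r2$constraint)
  f <- withr::local_tempfile(fileext = ".csv")
  write_mc_table(list(nominal = r1), f)
  tab <- read.csv(f, row.names = 1)
  expect_equal(tab["violation_pct", "nominal"], r1$violation_pct)
})
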