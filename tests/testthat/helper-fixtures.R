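# Shared fixtures and a cross-file cache for expensive solves (several
# acceptance properties reuse the same optimal profiles).

.solve_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .solve_cache))
    assign(key, force(expr), envir = .solve_cache)
  get(key, envir = .solve_cache)
}

# quiet solver defaults used in tests
test_opts <- list(verbose = FALSE)

# scalar linear-growth model x' = theta * x, x(0) = 1 (closed form
# x(T) = exp(theta T)); used as an analytically tractable propagation
# fixture.
scalar_growth_model <- function() {
  network_model(
    "scalar_growth", species = "x", stoichiometry = matrix(0, 1, 0),
    rate_laws = list(), control_names = "u", control_lower = 0,
    control_upper = 1, param_names = "theta", theta_nom = 1,
    x0 = c(x = 1), t_f = 1,
    terminal_constraints = list(list(state = "x", bound = 0,
                                     direction = "ge", robustify = TRUE)),
    objectives = list(list(type = "terminal_state", state = "x")),
    rhs = function(x, u, theta, t) theta[1] * x[1])
}

# two-state integrator fixture: x' = u, c' = u^2 (energy), used for the
# closed-form optimal-control checks.
energy_model <- function(bound = 1) {
  network_model(
    "energy", species = c("x", "c"), stoichiometry = matrix(0, 2, 0),
    rate_laws = list(), control_names = "u", control_lower = 0,
    control_upper = 5, param_names = "p", theta_nom = 1,
    x0 = c(x = 0, c = 0), t_f = 1,
    terminal_constraints = list(list(state = "x", bound = bound,
                                     direction = "ge", robustify = FALSE)),
    objectives = list(list(type = "terminal_state", state = "c")),
    rhs = function(x, u, theta, t) c(u[1], u[1]^2))
}

toy_biobjective <- function() {
  network_model(
    "toy_biobj", species = c("x1", "x2"), stoichiometry = matrix(0, 2, 0),
    rate_laws = list(), control_names = "u", control_lower = 0,
    control_upper = 1, param_names = "p", theta_nom = 1, t_f = 1,
    objectives = list(list(type = "terminal_state", state = "x1"),
                      list(type = "terminal_state", state = "x2")),
    rhs = function(x, u, theta, t) c(u[1]^2, (u[1] - 1)^2))
}

spec_case1 <- function(family = "normal")
  uncertainty_spec(family, case1_model()$theta_nom, rel_std = 0.2)

spec_case2 <- function(family = "normal")
  uncertainty_spec(family, case2_model()$theta_nom, rel_std = 0.1)

# nominal case-study solutions shared across files (coarse grids keep the
# suite fast; values are grid-converged well below the assertion
# tolerances)
case1_nominal_sol <- function(n_elements = 10)
  cached(paste0("case1_nom_", n_elements),
         solve_ocp(assemble_robust_ocp(case1_model(), "nominal"),
                   n_elements, options = test_opts))

# refined Case 1 profile (same resolution as the acceptance script), warm
# started from the coarse solve
case1_nominal_fine <- function()
  cached("case1_nom_fine",
         solve_ocp(assemble_robust_ocp(case1_model(), "nominal"), 25,
                   init = case1_nominal_sol(10)$profile,
                   options = test_opts))

case2_nominal_sol <- function(n_elements = 20)
  cached(paste0("case2_nom_", n_elements),
         solve_ocp(assemble_robust_ocp(case2_model(), "nominal"),
                   n_elements, t_f = 30, init = "sequential",
                   options = test_opts))

case1_lin_robust_sol <- function(alpha = 1.96, n_elements = 10) {
  key <- paste0("case1_lin_", alpha, "_", n_elements)
  cached(key, {
    nom <- case1_nominal_sol(n_elements)
    ocp <- assemble_robust_ocp(case1_model(), "linearization", spec_case1(),
                               backoff_policy(alpha = alpha))
    solve_ocp(ocp, n_elements, init = nom$profile, options = test_opts)
  })
}
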