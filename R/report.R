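#' Solve the nominal optimal-control problem of a registered model
#'
#' Step one of the workflow: the deterministic problem at the nominal
#' parameters. Optionally writes the solution artifacts (controls CSV,
#' trajectory tables, manifest) to a directory.
#'
#' @param model a model id (`"case1"`, `"case2"`) or a [network_model()].
#' @param n_elements finite elements of the control discretization.
#' @param t_f horizon override.
#' @param objective objective index for multi-objective models.
#' @param out_dir optional output directory.
#' @param options solver options ([solve_nlp()]).
#' @return the `robust_solution`, with the threshold-crossing time of the
#'   terminally constrained species attached as `$threshold_time`.
#' @export
run_nominal <- function(model, n_elements = 30, t_f = NULL,
                        objective = NULL, init = "multi", out_dir = NULL,
                        options = list()) {
  if (is.character(model)) model <- get_model(model)
  ocp <- assemble_robust_ocp(model, "nominal")
  sol <- solve_ocp(ocp, n_elements, t_f = t_f, objective = objective,
                   init = init, options = options)
  tc <- model$terminal_constraints[[1]]
  traj <- simulate_model(model, sol$profile,
                         output_times = seq(0, sol$t_f, length.out = 401))
  sol$trajectory <- traj
  # the terminal constraint is typically active to solver tolerance, so the
  # crossing detection gets matching numerical slack
  sol$threshold_time <- threshold_time(traj, tc$state, tc$bound, tol = 1e-6)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_control_profile(sol$profile, file.path(out_dir, "controls.csv"),
                          model$control_names)
    write_trajectory(traj, file.path(out_dir, "trajectory_wide.csv"),
                     "wide")
    write_trajectory(traj, file.path(out_dir, "trajectory.tsv"), "tidy")
    write_manifest(run_manifest(model, n_elements = n_elements,
                                t_f = sol$t_f, options = options),
                   file.path(out_dir, "manifest.json"))
  }
  sol
}

#' Solve a robustified problem for one technique and backoff
#'
#' Step two: the backoff-robustified problem. The solve is warm-started
#' from the nominal solution unless an explicit initial guess is given.
#'
#' @inheritParams run_nominal
#' @param technique `"linearization"`, `"sigma_points"`, `"pce1"`, `"pce2"`.
#' @param alpha backoff parameter (or use `confidence`).
#' @param confidence confidence level converted via
#'   [backoff_from_confidence()].
#' @param family,rel_std parametric uncertainty distribution.
#' @param penalty objective penalty form, see [backoff_policy()].
#' @param init `"warm"` (nominal warm start), `"multi"`, or a profile; for
#'   `run_nominal` the default tries the bundled structured guesses.
#' @return the `robust_solution` with propagated `(E, Var)` in `$moments`.
#' @export
run_robust <- function(model, technique, alpha = NULL, confidence = NULL,
                       family = "normal", rel_std = 0.2, penalty = NULL,
                       n_elements = 30, t_f = NULL, objective = NULL,
                       init = "warm", out_dir = NULL, options = list()) {
  if (is.character(model)) model <- get_model(model)
  spec <- uncertainty_spec(family, model$theta_nom, rel_std = rel_std)
  penalty <- penalty %||%
    if (any(vapply(model$objectives, function(o)
      isTRUE(o$robustify), TRUE))) "variance" else "sqrt_variance"
  policy <- backoff_policy(alpha = alpha, confidence = confidence,
                           penalty = penalty)
  ocp <- assemble_robust_ocp(model, technique, spec, policy)
  if (identical(init, "warm")) {
    nom <- solve_ocp(assemble_robust_ocp(model, "nominal"), n_elements,
                     t_f = t_f, objective = objective, options = options)
    init <- nom$profile
  }
  sol <- solve_ocp(ocp, n_elements, t_f = t_f, objective = objective,
                   init = init, options = options)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_control_profile(sol$profile, file.path(out_dir, "controls.csv"),
                          model$control_names)
    utils::write.csv(sol$moments, file.path(out_dir, "moments.csv"),
                     row.names = FALSE)
    write_manifest(run_manifest(model, technique, ocp$policy$alpha, family,
                                rel_std, n_elements, sol$t_f,
                                options = options),
                   file.path(out_dir, "manifest.json"))
  }
  sol
}

#' Monte-Carlo assessment of a control profile
#'
#' Step four: fixed-control Monte-Carlo simulation over the parametric
#' uncertainty, reporting violation counts and empirical moments.
#'
#' @inheritParams run_robust
#' @param controls a [control_profile()] or the path of a CSV written by
#'   [write_control_profile()].
#' @param N realizations.
#' @param seed RNG seed.
#' @param integrator see [validate_controls()].
#' @return the `mc_report`.
#' @export
run_validate <- function(model, controls, family = "normal", rel_std = 0.2,
                         N = 1000, seed = 1L, integrator = "lsoda",
                         out_dir = NULL) {
  if (is.character(model)) model <- get_model(model)
  if (is.character(controls)) controls <- read_control_profile(controls)
  if (N < 1) stop("N must be positive")
  spec <- uncertainty_spec(family, model$theta_nom, rel_std = rel_std)
  rep <- validate_controls(model, controls, spec, N = N, seed = seed,
                           integrator = integrator)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mc_table(list(report = rep), file.path(out_dir, "mc_report.csv"))
    write_manifest(run_manifest(model, family = family, rel_std = rel_std,
                                seed = seed, options = list(N = N)),
                   file.path(out_dir, "manifest.json"))
  }
  rep
}

#' Robustified Pareto fronts over a backoff sweep
#'
#' Step three for two-objective models: one NBI front per requested
#' backoff value.
#'
#' @inheritParams run_robust
#' @param alphas backoff parameter values (one front each).
#' @param n_points Pareto points per front.
#' @return named list of `pareto_front` objects.
#' @export
run_pareto <- function(model, technique, alphas, family = "normal",
                       rel_std = 0.1, n_points = 10, n_elements = 20,
                       out_dir = NULL, options = list()) {
  if (is.character(model)) model <- get_model(model)
  if (length(model$objectives) != 2)
    stop("Pareto fronts require a two-objective model; '", model$name,
         "' has ", length(model$objectives),
         " (use run_nominal/run_robust instead)")
  spec <- uncertainty_spec(family, model$theta_nom, rel_std = rel_std)
  fronts <- list()
  for (a in alphas) {
    pol <- backoff_policy(alpha = a, penalty = "variance")
    ocp <- assemble_robust_ocp(model, technique, spec, pol)
    fr <- nbi_front(ocp, n_points = n_points, n_elements = n_elements,
                    free_tf = TRUE, options = options)
    fronts[[paste0("alpha_", a)]] <- fr
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_front(fr, file.path(out_dir,
                                sprintf("front_%s_alpha%.2f.csv",
                                        technique, a)))
    }
  }
  if (!is.null(out_dir))
    write_manifest(run_manifest(model, technique, paste(alphas,
                                                        collapse = ","),
                                family, rel_std, n_elements),
                   file.path(out_dir, "manifest.json"))
  fronts
}

#' Technique-comparison table
#'
#' Assembles the propagated expected values and standard deviations of one
#' or more solved techniques side by side (columns ordered nominal,
#' linearization, sigma points, PCE1, PCE2).
#'
#' @param solutions named list of `robust_solution`s.
#' @param file optional CSV path.
#' @return the comparison data frame (rows: objective E, constraint E and
#'   sd, states of the transcription).
#' @export
technique_table <- function(solutions, file = NULL) {
  ord <- c("nominal", "linearization", "sigma_points", "pce1", "pce2")
  solutions <- solutions[order(match(vapply(solutions, function(s)
    s$nlp$ocp$technique, ""), ord))]
  tab <- data.frame(row.names = c("states", "E_J", "E_ct", "sd_ct"))
  for (nm in names(solutions)) {
    s <- solutions[[nm]]
    mom <- s$moments
    ct <- mom[mom$quantity == mom$quantity[1], ]
    jrow <- mom[nrow(mom), ]
    tab[[nm]] <- c(s$nlp$n_dynamic_states, s$objective, ct$E[1], ct$sd[1])
  }
  if (!is.null(file)) utils::write.csv(tab, file)
  tab
}
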