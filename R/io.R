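#' Write a declarative model configuration
#'
#' Serializes the declarative description of a [network_model()] (states,
#' stoichiometry, rate laws, bounds, constraints, objectives) to a YAML
#' file that [read_model_config()] restores losslessly. Models built with a
#' custom right-hand-side function cannot be serialized.
#'
#' @param model a [network_model()].
#' @param file output path.
#' @export
write_model_config <- function(model, file) {
  if (isTRUE(model$custom_rhs))
    stop("models with a custom rhs cannot be written as a config")
  cfg <- list(
    name = model$name,
    species = model$species,
    stoichiometry = apply(model$stoichiometry, 1, as.integer,
                          simplify = FALSE),
    rate_laws = model$rate_laws,
    control_names = model$control_names,
    control_lower = model$control_lower,
    control_upper = model$control_upper,
    param_names = model$param_names,
    theta_nom = as.numeric(model$theta_nom),
    control_kind = model$control_kind,
    buffered = model$buffered,
    buffered_mode = model$buffered_mode,
    buffered_values = as.list(model$buffered_values),
    enzyme_states = model$enzyme_states,
    decay_param = model$decay_param,
    extra_states = model$extra_states,
    x0 = as.list(model$x0),
    t_f = model$t_f, t_f_max = model$t_f_max,
    control_sum_bound = model$control_sum_bound,
    state_sum_constraint = model$state_sum_constraint,
    terminal_constraints = model$terminal_constraints,
    objectives = model$objectives,
    control_t0 = model$control_t0)
  yaml::write_yaml(cfg, file, precision = 15)
  invisible(file)
}

#' Read a model configuration
#'
#' @param file YAML path written by [write_model_config()].
#' @return a [network_model()].
#' @export
read_model_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  network_model(
    name = cfg$name, species = unlist(cfg$species),
    stoichiometry = do.call(rbind, cfg$stoichiometry),
    rate_laws = cfg$rate_laws,
    control_names = unlist(cfg$control_names),
    control_lower = as.numeric(unlist(cfg$control_lower)),
    control_upper = as.numeric(unlist(cfg$control_upper)),
    param_names = unlist(cfg$param_names),
    theta_nom = as.numeric(unlist(cfg$theta_nom)),
    control_kind = cfg$control_kind,
    buffered = as.character(unlist(cfg$buffered)),
    buffered_mode = cfg$buffered_mode,
    buffered_values = unlist(cfg$buffered_values) %||% numeric(),
    enzyme_states = as.character(unlist(cfg$enzyme_states)),
    decay_param = cfg$decay_param,
    extra_states = lapply(cfg$extra_states, function(ex)
      list(name = ex$name, vars = unlist(ex$vars),
           coefs = as.numeric(unlist(ex$coefs)))),
    x0 = unlist(cfg$x0),
    t_f = cfg$t_f, t_f_max = cfg$t_f_max,
    control_sum_bound = cfg$control_sum_bound,
    state_sum_constraint = if (!is.null(cfg$state_sum_constraint))
      list(states = unlist(cfg$state_sum_constraint$states),
           bound = cfg$state_sum_constraint$bound),
    terminal_constraints = cfg$terminal_constraints,
    objectives = cfg$objectives,
    control_t0 = if (!is.null(cfg$control_t0))
      as.numeric(unlist(cfg$control_t0)))
}

#' Write a control profile as CSV
#'
#' Columns: element start, element end, one column per control.
#' @param profile a [control_profile()].
#' @param file output path.
#' @param control_names optional column names.
#' @export
write_control_profile <- function(profile, file, control_names = NULL) {
  n_el <- nrow(profile$values)
  df <- data.frame(t_start = profile$grid[-(n_el + 1)],
                   t_end = profile$grid[-1])
  V <- as.data.frame(profile$values)
  names(V) <- control_names %||% paste0("u", seq_len(ncol(V)))
  utils::write.csv(cbind(df, V), file, row.names = FALSE)
  invisible(file)
}

#' Read a control profile written by [write_control_profile()]
#' @param file CSV path.
#' @return a [control_profile()].
#' @export
read_control_profile <- function(file) {
  df <- utils::read.csv(file)
  grid <- c(df$t_start, df$t_end[nrow(df)])
  control_profile(grid, as.matrix(df[, -(1:2), drop = FALSE]))
}

#' Write a Pareto front
#' @param front a [nbi_front()] result.
#' @param file CSV path.
#' @export
write_front <- function(front, file) {
  utils::write.csv(as.data.frame(front), file, row.names = FALSE)
  invisible(file)
}

# Run manifest: everything needed to reproduce an emitted artifact.
run_manifest <- function(model, technique = "nominal", alpha = 0,
                         family = NA, rel_std = NA, n_elements = NA,
                         t_f = NA, seed = NA, options = list()) {
  list(model = model$name, technique = technique, alpha = alpha,
       family = family, rel_std = rel_std, n_elements = n_elements,
       t_f = t_f, seed = seed, options = options,
       package = "robustoc",
       version = as.character(utils::packageVersion("robustoc")))
}

write_manifest <- function(manifest, file) {
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
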