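#' Three-step linear pathway (case study 1)
#'
#' A linear pathway S1 -> S2 -> S3 -> S4 with mass-action kinetics
#' \eqn{v_j = k_j S_j e_j}, catalysed by three enzymes whose concentrations
#' `e1..e3` are the controls (each in `[0, E_T]`, with the total enzyme pool
#' bounded by `sum(e) <= E_T`). The substrate S1 is buffered: it is kept as
#' a trivially integrated state with an all-zero stoichiometric row, so the
#' model has five integrated states (S1..S4 plus the intermediate
#' accumulation integrator `x_extra`). The product must satisfy the
#' terminal constraint `S4(t_f) >= 0.90` mM at the fixed final time of 10 s,
#' and the objective is the accumulated intermediate burden
#' \eqn{J = \int_0^{t_f} (S_2 + S_3)\,dt}, which is minimized because high
#' intermediate concentrations are harmful to the cell. The three rate
#' constants `k1, k2, k3` (nominal 1 /(mM s)) are the uncertain parameters.
#'
#' Initial conditions are not part of the published model statement; the
#' defaults (buffered S1 at 1 mM, everything else 0) are the package's
#' convention and can be overridden.
#'
#' @param E_T total enzyme concentration bound (mM).
#' @param t_f final time (s).
#' @param x0 optional named initial state override.
#' @return a [network_model()].
#' @export
case1_model <- function(E_T = 1, t_f = 10, x0 = NULL) {
  N <- matrix(c(0, 0, 0,
                1, -1, 0,
                0, 1, -1,
                0, 0, 1), 4, 3, byrow = TRUE)
  if (is.null(x0))
    x0 <- c(S1 = 1, S2 = 0, S3 = 0, S4 = 0, x_extra = 0)
  network_model(
    name = "case1",
    species = c("S1", "S2", "S3", "S4"),
    stoichiometry = N,
    rate_laws = list(
      list(kind = "mass_action", substrate = "S1", enzyme = "e1", param = "k1"),
      list(kind = "mass_action", substrate = "S2", enzyme = "e2", param = "k2"),
      list(kind = "mass_action", substrate = "S3", enzyme = "e3", param = "k3")),
    control_names = c("e1", "e2", "e3"),
    control_lower = rep(0, 3), control_upper = rep(E_T, 3),
    param_names = c("k1", "k2", "k3"), theta_nom = c(1, 1, 1),
    control_kind = "direct_concentration",
    buffered = "S1", buffered_mode = "zero_row",
    extra_states = list(list(name = "x_extra", vars = c("S2", "S3"),
                             coefs = c(1, 1))),
    x0 = x0, t_f = t_f,
    control_sum_bound = E_T,
    terminal_constraints = list(
      list(state = "S4", bound = 0.90, direction = "ge", robustify = TRUE)),
    objectives = list(
      list(type = "terminal_state", state = "x_extra", robustify = FALSE))
  )
}

#' Glycolysis-inspired branched network (case study 2)
#'
#' A five-metabolite network with a branch, producing one extracellular
#' product S5 from a buffered substrate S1 through four Michaelis-Menten
#' reactions \eqn{v_j = k_{cat} e_j S/(K_M + S)}. The enzymes `e1..e4` are
#' states synthesised at the controlled expression rates `r1..r4`
#' (`de/dt = r - lambda e`) and are limited by the total pool
#' `sum(e) <= E_T`. Expression is bounded by `sum(r) <= 0.5` with the
#' initial allocation pinned at `r(0) = (0.5, 0, 0, 0)`. The buffered
#' substrate is treated as a constant, giving nine integrated states
#' (S2..S5, e1..e4, and the enzymatic-cost integrator `x_extra`). The
#' terminal constraint requires `S5(t_f) >= 0.675` mM; the two conflicting
#' objectives are the final time \eqn{J_1 = t_f} (at most 30 s) and the
#' enzymatic cost \eqn{J_2 = \int_0^{t_f} \sum_i e_i\, dt}, a proxy for the
#' protein-synthesis burden. The uncertain parameters are `k_cat` (1 /s),
#' `K_M` (1 mM) and the degradation rate `lambda` (0.5 /s).
#'
#' As in [case1_model()], initial conditions (all zero except the buffered
#' S1 at 1 mM) and `E_T = 1` mM are package conventions, not published
#' values, and can be overridden.
#'
#' @param E_T total enzyme pool bound (mM).
#' @param t_f default final time for fixed-horizon analyses (s); also the
#'   upper bound when the final time is free.
#' @param S1 buffered substrate concentration (mM).
#' @param x0 optional named initial state override.
#' @return a [network_model()].
#' @export
case2_model <- function(E_T = 1, t_f = 30, S1 = 1, x0 = NULL) {
  N <- matrix(c(0, 0, 0, 0,
                1, -1, 0, 0,
                0, 1, -1, 0,
                0, 1, 1, -1,
                0, 0, 0, 1), 5, 4, byrow = TRUE)
  if (is.null(x0))
    x0 <- c(S2 = 0, S3 = 0, S4 = 0, S5 = 0,
            e1 = 0, e2 = 0, e3 = 0, e4 = 0, x_extra = 0)
  network_model(
    name = "case2",
    species = c("S1", "S2", "S3", "S4", "S5"),
    stoichiometry = N,
    rate_laws = list(
      list(kind = "michaelis_menten", substrate = "S1", enzyme = "e1",
           vmax_param = "k_cat", km_param = "K_M"),
      list(kind = "michaelis_menten", substrate = "S2", enzyme = "e2",
           vmax_param = "k_cat", km_param = "K_M"),
      list(kind = "michaelis_menten", substrate = "S3", enzyme = "e3",
           vmax_param = "k_cat", km_param = "K_M"),
      list(kind = "michaelis_menten", substrate = "S4", enzyme = "e4",
           vmax_param = "k_cat", km_param = "K_M")),
    control_names = c("r1", "r2", "r3", "r4"),
    control_lower = rep(0, 4), control_upper = rep(0.5, 4),
    param_names = c("k_cat", "K_M", "lambda"), theta_nom = c(1, 1, 0.5),
    control_kind = "expression_rate",
    buffered = "S1", buffered_mode = "constant",
    buffered_values = c(S1 = S1),
    enzyme_states = c("e1", "e2", "e3", "e4"), decay_param = "lambda",
    extra_states = list(list(name = "x_extra",
                             vars = c("e1", "e2", "e3", "e4"),
                             coefs = rep(1, 4))),
    x0 = x0, t_f = t_f, t_f_max = t_f,
    control_sum_bound = 0.5,
    state_sum_constraint = list(states = c("e1", "e2", "e3", "e4"),
                                bound = E_T),
    terminal_constraints = list(
      list(state = "S5", bound = 0.675, direction = "ge", robustify = TRUE)),
    objectives = list(
      list(type = "final_time"),
      list(type = "terminal_state", state = "x_extra", robustify = TRUE)),
    control_t0 = c(0.5, 0, 0, 0)
  )
}

#' Registry of bundled case-study models
#'
#' @param id model identifier, `"case1"` or `"case2"`.
#' @param ... passed to the model constructor.
#' @return a [network_model()].
#' @export
get_model <- function(id, ...) {
  switch(id,
         case1 = case1_model(...),
         case2 = case2_model(...),
         stop("unknown model id: ", id,
              " (registered models: case1, case2)"))
}
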