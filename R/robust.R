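#' Backoff parameter from a target confidence level
#'
#' Converts a confidence level `beta` for a single chance constraint into a
#' backoff parameter `alpha` multiplying the constraint's standard
#' deviation. Two choices are available:
#' \describe{
#'   \item{normal_quantile}{the one-sided standard-normal quantile, reported
#'     at the conventional two-decimal rounding of the 3-decimal quantile
#'     (so 0.95 gives 1.645 -> 1.65); appropriate when the constrained
#'     quantity is approximately normal.}
#'   \item{cantelli}{the distribution-free Cantelli-Chebyshev bound
#'     \eqn{\sqrt{\beta/(1-\beta)}}, valid for any distribution but
#'     conservative (4.36 at 95 %).}
#' }
#'
#' @param beta confidence level in (0, 1).
#' @param method `"normal_quantile"` or `"cantelli"`.
#' @return the backoff parameter `alpha` (dimensionless, >= 0 for
#'   `beta >= 0.5`).
#' @export
#' @examples
#' backoff_from_confidence(0.95)               # 1.65
#' backoff_from_confidence(0.95, "cantelli")   # 4.36
backoff_from_confidence <- function(beta,
                                    method = c("normal_quantile", "cantelli")) {
  method <- match.arg(method)
  if (!is.numeric(beta) || any(beta <= 0 | beta >= 1))
    stop("beta must lie strictly between 0 and 1")
  if (method == "cantelli") return(round(sqrt(beta / (1 - beta)), 2))
  q3 <- round(stats::qnorm(beta), 3)
  # round half away from zero at the second decimal (1.645 -> 1.65)
  sign(q3) * floor(abs(q3) * 100 + 0.5) / 100
}

#' Backoff policy for robustified problems
#'
#' Bundles the backoff parameters applied to the probabilistic constraints
#' and objectives of a robustified optimal-control problem. Either `alpha`
#' is given directly or it is derived from a `confidence` level via
#' [backoff_from_confidence()].
#'
#' @param alpha backoff applied to robustified constraints.
#' @param confidence alternative to `alpha`.
#' @param alpha_objective backoff applied to robustified objectives
#'   (defaults to `alpha`).
#' @param method quantile rule used when converting `confidence`.
#' @param penalty objective penalty form: `"sqrt_variance"` adds
#'   `alpha * sqrt(Var[J])`, `"variance"` adds `alpha * Var[J]`.
#' @return an object of class `backoff_policy`.
#' @export
backoff_policy <- function(alpha = NULL, confidence = NULL,
                           alpha_objective = NULL,
                           method = c("normal_quantile", "cantelli"),
                           penalty = c("sqrt_variance", "variance")) {
  method <- match.arg(method)
  penalty <- match.arg(penalty)
  if (is.null(alpha)) {
    if (is.null(confidence)) stop("supply alpha or confidence")
    alpha <- backoff_from_confidence(confidence, method)
  }
  if (alpha < 0) stop("alpha must be non-negative")
  structure(list(alpha = alpha,
                 alpha_objective = alpha_objective %||% alpha,
                 confidence = confidence, method = method, penalty = penalty),
            class = "backoff_policy")
}

#' Robustified constraint margin
#'
#' Deterministic backoff approximation of a single chance constraint: for a
#' lower bound `c_min <= x` the margin is
#' `E - alpha * sqrt(Var) - c_min`; for an upper bound `x <= c_max` it is
#' `c_max - E - alpha * sqrt(Var)`. The constraint is feasible when the
#' margin is non-negative.
#'
#' @param E expected value of the constrained quantity.
#' @param Var its variance (>= 0).
#' @param alpha backoff parameter.
#' @param bound the constraint bound.
#' @param direction `"ge"` (lower bound) or `"le"` (upper bound).
#' @return the scalar margin.
#' @export
robustify_constraint <- function(E, Var, alpha, bound,
                                 direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (any(Var < 0)) stop("negative variance")
  backoff <- alpha * sqrt(Var)
  if (direction == "ge") E - backoff - bound else bound - E - backoff
}

#' Robustified objective value
#'
#' @inheritParams robustify_constraint
#' @param form `"sqrt_variance"` returns `E + alpha * sqrt(Var)`;
#'   `"variance"` returns `E + alpha * Var`.
#' @return the penalized objective.
#' @export
robustify_objective <- function(E, Var, alpha,
                                form = c("sqrt_variance", "variance")) {
  form <- match.arg(form)
  if (any(Var < 0)) stop("negative variance")
  if (form == "sqrt_variance") E + alpha * sqrt(Var) else E + alpha * Var
}

#' Assemble a robustified optimal-control problem
#'
#' Combines a kinetic model, an uncertainty-propagation technique, an
#' uncertainty specification and a backoff policy into a robustified OCP:
#' the technique's augmented dynamics (sensitivity equations, or model
#' replicas at the sigma/PCE sampling points sharing one control
#' trajectory) become the dynamic constraints, and every constraint or
#' objective marked `robustify` in the model is replaced by its backoff
#' form. Control bounds and non-probabilistic constraints pass through
#' unchanged. With `technique = "nominal"` (or a zero covariance and zero
#' backoff) the problem reduces exactly to the original deterministic OCP.
#'
#' Only single chance constraints are supported; each robustified
#' constraint is backed off individually.
#'
#' @param model a [network_model()].
#' @param technique `"nominal"`, `"linearization"`, `"sigma_points"`,
#'   `"pce1"` or `"pce2"`.
#' @param spec an [uncertainty_spec()] (ignored for `"nominal"`).
#' @param policy a [backoff_policy()].
#' @return an object of class `robust_ocp`.
#' @export
assemble_robust_ocp <- function(model, technique = "nominal", spec = NULL,
                                policy = backoff_policy(alpha = 0)) {
  if (technique != "nominal" && is.null(spec))
    stop("an uncertainty_spec is required for technique '", technique, "'")
  if (technique == "nominal" && is.null(spec))
    spec <- uncertainty_spec("normal", model$theta_nom, rel_std = 0)
  prop <- build_propagation(model, technique, spec)
  aug <- prop$aug
  n_x <- model$n_x

  constraint_funs <- lapply(model$terminal_constraints, function(tc) {
    idx <- match(tc$state, model$state_names)
    a <- if (isTRUE(tc$robustify)) policy$alpha else 0
    list(
      name = paste0(tc$state, "_", tc$direction, "_", tc$bound),
      state = tc$state,
      fun = function(xf, tf) {
        mm <- prop$moments(xf, idx)
        robustify_constraint(mm$E, mm$Var, a, tc$bound, tc$direction)
      },
      support = prop$support(idx))
  })

  objective_funs <- lapply(model$objectives, function(ob) {
    if (ob$type == "final_time") {
      list(name = "t_f", fun = function(xf, tf) tf, support = integer(0),
           uses_tf = TRUE)
    } else {
      idx <- match(ob$state, model$state_names)
      a <- if (isTRUE(ob$robustify)) policy$alpha_objective else 0
      list(
        name = ob$state,
        fun = function(xf, tf) {
          mm <- prop$moments(xf, idx)
          robustify_objective(mm$E, mm$Var, a, policy$penalty)
        },
        support = prop$support(idx), uses_tf = FALSE)
    }
  })

  structure(list(
    model = model, technique = technique, spec = spec, policy = policy,
    aug = aug, moments = prop$moments, support = prop$support,
    n_dynamic_states = aug$n_states,
    constraints = constraint_funs, objectives = objective_funs
  ), class = "robust_ocp")
}

#' @export
print.robust_ocp <- function(x, ...) {
  cat("robust_ocp:", x$model$name, "/", x$technique, "\n")
  cat("  dynamic states:", x$n_dynamic_states,
      "| alpha =", x$policy$alpha,
      "| objective penalty:", x$policy$penalty, "\n")
  cat("  robustified constraints:",
      paste(vapply(x$constraints, `[[`, "", "name"), collapse = ", "), "\n")
  invisible(x)
}
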