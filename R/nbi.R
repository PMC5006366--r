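#' Anchor points of a two-objective problem
#'
#' Solves the two single-objective problems (each objective minimized alone
#' subject to all constraints), returning the endpoints of the Pareto
#' front.
#'
#' @param ocp a two-objective [assemble_robust_ocp()] result.
#' @param n_elements,free_tf,options passed to [solve_ocp()].
#' @param t_f horizon used when the final time is fixed.
#' @param inits optional per-anchor initial guesses (list of two
#'   [solve_ocp()] `init` values), e.g. for warm-starting a backoff sweep
#'   from the previous sweep's anchors.
#' @return list of two `robust_solution`s with an `F` attribute holding the
#'   2 x 2 matrix of objective vectors (columns = anchors).
#' @export
anchor_points <- function(ocp, n_elements = 20, free_tf = TRUE,
                          t_f = NULL, options = list(), inits = NULL) {
  if (length(ocp$objectives) != 2)
    stop("anchor points require exactly two objectives")
  sols <- lapply(1:2, function(k)
    solve_ocp(ocp, n_elements, t_f = t_f, free_tf = free_tf, objective = k,
              init = if (is.null(inits)) "multi" else inits[[k]],
              options = options))
  F <- vapply(sols, function(s) objective_vector(ocp, s), numeric(2))
  attr(sols, "F") <- F
  sols
}

objective_vector <- function(ocp, sol) {
  vapply(ocp$objectives, function(ob) ob$fun(sol$xf, sol$t_f), 0)
}

#' Normal Boundary Intersection Pareto front
#'
#' Computes a two-objective Pareto front by NBI scalarization: after
#' normalizing the objective space with the anchor values, subproblems
#' maximize the advance `t` along the quasi-normal direction from evenly
#' spaced points on the line joining the normalized anchors, subject to
#' `F(w) <= P(beta) + t n` componentwise together with all original
#' constraints. Subproblems are warm-started by continuation from the
#' neighbouring point; failed subproblems are recorded and the front is
#' returned partially.
#'
#' @param ocp a two-objective [assemble_robust_ocp()] result.
#' @param n_points number of Pareto points including the anchors.
#' @param n_elements,free_tf,t_f,options as in [solve_ocp()].
#' @param anchors optional precomputed [anchor_points()] result.
#' @return an object of class `pareto_front`: a data frame with columns
#'   `beta_nbi`, `J1`, `J2`, `status`, carrying the control profiles as an
#'   attribute.
#' @export
nbi_front <- function(ocp, n_points = 10, n_elements = 20, free_tf = TRUE,
                      t_f = NULL, options = list(), anchors = NULL) {
  if (length(ocp$objectives) != 2)
    stop("NBI requires exactly two objectives")
  if (n_points < 2) stop("need at least the two anchors")
  if (is.null(anchors))
    anchors <- anchor_points(ocp, n_elements, free_tf, t_f, options)
  F_anchor <- attr(anchors, "F")
  utopia <- pmin(F_anchor[, 1], F_anchor[, 2])
  spread <- pmax(F_anchor[, 1], F_anchor[, 2]) - utopia
  spread[spread < 1e-9] <- 1                    # degenerate: identical anchors
  norm_F <- function(F) (F - utopia) / spread
  A <- vapply(1:2, function(k) norm_F(F_anchor[, k]), numeric(2))

  betas <- seq(0, 1, length.out = n_points)
  rows <- list()
  profiles <- list()
  # anchor rows
  grid0 <- collocation_grid(n_elements, t_f %||% ocp$model$t_f)
  for (k in 1:2) {
    b <- if (k == 1) 0 else 1
    rows[[length(rows) + 1]] <- data.frame(
      beta_nbi = b, J1 = F_anchor[1, k], J2 = F_anchor[2, k],
      status = anchors[[k]]$status)
    profiles[[length(profiles) + 1]] <- anchors[[k]]$profile
  }
  interior <- betas[betas > 0 & betas < 1]
  nlp <- transcribe(ocp, grid0, objective = 1, free_tf = free_tf)
  warm <- profile_to_w(nlp, anchors[[1]]$profile)
  nhat <- c(-1, -1) / sqrt(2)
  for (b in interior) {
    P <- (1 - b) * A[, 1] + b * A[, 2]
    sub <- nbi_subproblem(nlp, ocp, P, nhat, utopia, spread)
    sol <- tryCatch(solve_nlp(sub, c(warm, 0), options),
                    error = function(e) NULL)
    if (is.null(sol) || max(0, sol$constraints) > 1e-4) {
      rows[[length(rows) + 1]] <- data.frame(
        beta_nbi = b, J1 = NA_real_, J2 = NA_real_, status = "failed")
      next
    }
    Fw <- objective_vector(ocp, sol)
    rows[[length(rows) + 1]] <- data.frame(
      beta_nbi = b, J1 = Fw[1], J2 = Fw[2], status = sol$status)
    prof <- control_profile(sol$t_f * grid0$boundaries / grid0$t_f,
                            sol$controls)
    profiles[[length(profiles) + 1]] <- prof
    warm <- sol$w[-length(sol$w)]
  }
  out <- do.call(rbind, rows)
  ord <- order(out$J1)
  out <- out[ord, ]
  front <- structure(out, class = c("pareto_front", "data.frame"),
                     profiles = profiles[ord], technique = ocp$technique,
                     alpha = ocp$policy$alpha, F_anchor = F_anchor)
  front
}

# Wrap a transcribed NLP into the NBI subproblem: decision (w, t),
# objective -t, constraints F_norm(w) - P - t*nhat <= 0 plus the original
# inequality constraints.
nbi_subproblem <- function(nlp, ocp, P, nhat, utopia, spread) {
  n_w <- nlp$n_w
  obj_evals <- lapply(ocp$objectives, function(ob) {
    force(ob)
    function(sim) nlp$terminal_eval(sim, ob$fun, ob$support,
                                    isTRUE(ob$uses_tf))
  })
  sub <- nlp
  sub$n_w <- n_w + 1
  sub$lower <- c(nlp$lower, -10)
  sub$upper <- c(nlp$upper, 10)
  sub$eval_f <- function(w) {
    list(value = -w[n_w + 1], grad = c(numeric(n_w), -1))
  }
  sub$eval_g <- function(w) {
    sim <- nlp$run_sim(w[seq_len(n_w)])
    base <- nlp$eval_g(w[seq_len(n_w)])
    evs <- lapply(obj_evals, function(f) f(sim))
    Fw <- vapply(evs, `[[`, 0, "value")
    Fn <- (Fw - utopia) / spread
    gv <- Fn - P - w[n_w + 1] * nhat
    gmat <- do.call(rbind, lapply(seq_along(evs), function(k)
      evs[[k]]$grad / spread[k]))
    gj <- cbind(gmat, -nhat)
    if (length(base$value))
      gj <- rbind(gj, cbind(base$jac, 0))
    list(value = c(gv, base$value), jac = gj,
         names = c("nbi_J1", "nbi_J2", base$names))
  }
  sub
}
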