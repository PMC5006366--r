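#' Collocation grid over the control horizon
#'
#' Uniform partition of `[0, t_f]` into finite elements, each carrying the
#' element start plus `degree` Radau collocation nodes (four interpolation
#' points for the default cubic Lagrange basis, the last coinciding with
#' the element end).
#'
#' @param n_elements number of finite elements.
#' @param t_f horizon length in seconds (for free-final-time problems the
#'   grid is interpreted as fractions of the final time).
#' @param degree collocation degree (nodes per element).
#' @return an object of class `collocation_grid`.
#' @export
collocation_grid <- function(n_elements, t_f = 1, degree = 3) {
  if (n_elements < 1) stop("need at least one element")
  b <- seq(0, t_f, length.out = n_elements + 1)
  cm <- colloc_matrices(degree)
  nodes <- lapply(seq_len(n_elements), function(e)
    b[e] + diff(b)[e] * cm$tau[-1])
  structure(list(n_elements = n_elements, boundaries = b, t_f = t_f,
                 degree = degree, cm = cm, nodes = nodes),
            class = "collocation_grid")
}

# One implicit collocation step over a single finite element.
#
# Solves the collocation equations
#   sum_j C[j, r] X_j = h f(X_r, u),  X_0 = x_start,  r = 1..degree
# by (chord) Newton iteration, and optionally returns the exact derivatives
# of the element end state with respect to x_start, u and h obtained from
# the implicit-function theorem on the converged system.
colloc_element <- function(rhs, jac_x, jac_u, x_start, u, h, cm,
                           sens = FALSE, tol = 1e-10, maxit = 20) {
  n <- length(x_start)
  d <- ncol(cm$C)
  X <- matrix(rep(x_start, d), n, d)
  resid <- function(X) {
    R <- matrix(0, n, d)
    for (r in seq_len(d)) {
      R[, r] <- cm$C[1, r] * x_start - h * rhs(X[, r], u)
      for (j in seq_len(d)) R[, r] <- R[, r] + cm$C[j + 1, r] * X[, j]
    }
    R
  }
  build_M <- function(X) {
    M <- matrix(0, n * d, n * d)
    for (r in seq_len(d)) {
      rows <- (r - 1) * n + seq_len(n)
      Jr <- jac_x(X[, r], u)
      for (j in seq_len(d)) {
        cols <- (j - 1) * n + seq_len(n)
        block <- diag(cm$C[j + 1, r], n)
        if (j == r) block <- block - h * Jr
        M[rows, cols] <- block
      }
    }
    M
  }
  M <- NULL; lu <- NULL
  prev <- Inf
  for (it in seq_len(maxit)) {
    R <- resid(X)
    nr <- max(abs(R))
    if (nr < tol * max(1, max(abs(X)))) break
    if (is.null(M) || nr > 0.25 * prev) {
      M <- build_M(X)
      lu <- tryCatch(lu_factor(M), error = function(e)
        stop("singular collocation system"))
    }
    X <- X - matrix(lu_solve(lu, as.vector(R)), n, d)
    prev <- nr
    if (it == maxit) stop("collocation Newton did not converge (residual ",
                          signif(nr, 3), ")")
  }
  out <- list(X = X, x_end = X[, d])
  if (sens) {
    # refresh the Jacobian at the solution for exact sensitivities
    M <- build_M(X)
    lu <- lu_factor(M)
    n_u <- length(u)
    RHS <- matrix(0, n * d, n + n_u + 1)
    for (r in seq_len(d)) {
      rows <- (r - 1) * n + seq_len(n)
      RHS[rows, seq_len(n)] <- diag(-cm$C[1, r], n)
      RHS[rows, n + seq_len(n_u)] <- h * jac_u(X[, r], u)
      RHS[rows, n + n_u + 1] <- rhs(X[, r], u)
    }
    dX <- lu_solve(lu, RHS)          # solves M dX = -dF/dp with RHS = -dF/dp
    last <- (d - 1) * n + seq_len(n)
    out$A <- dX[last, seq_len(n), drop = FALSE]
    out$B <- dX[last, n + seq_len(n_u), drop = FALSE]
    out$c <- dX[last, n + n_u + 1]
  }
  out
}

lu_factor <- function(M) qr(M, LAPACK = TRUE)
lu_solve <- function(lu, b) qr.coef(lu, b)

#' Transcribe a robustified OCP by orthogonal collocation
#'
#' Full discretization of states and controls: the augmented dynamic states
#' live at the collocation nodes of every finite element, controls are
#' piecewise constant per element, the collocation equations and
#' inter-element continuity conditions are equality constraints, and the
#' robustified terminal constraints plus the control/state path constraints
#' are inequalities. The returned object exposes both the full-space
#' constraint structure (for inspection and verification) and a reduced
#' evaluator in which the collocation equalities are eliminated by an
#' implicit per-element Newton solve, yielding exact objective and
#' constraint gradients with respect to the remaining decision variables
#' (controls and, optionally, the final time).
#'
#' @param ocp a [assemble_robust_ocp()] result.
#' @param grid a [collocation_grid()]; its `t_f` is the horizon for
#'   fixed-final-time problems and is rescaled when `free_tf = TRUE`.
#' @param objective index of the model objective to minimize.
#' @param free_tf make the final time a decision variable.
#' @param tf_bounds bounds on the free final time.
#' @return an object of class `transcribed_nlp`.
#' @export
transcribe <- function(ocp, grid, objective = NULL, free_tf = FALSE,
                       tf_bounds = c(1e-2, ocp$model$t_f_max %||% grid$t_f)) {
  model <- ocp$model
  aug <- ocp$aug
  n <- aug$n_states
  n_u <- model$n_u
  n_el <- grid$n_elements
  if (is.null(objective))
    objective <- which(vapply(ocp$objectives, function(o)
      !isTRUE(o$uses_tf), TRUE))[1]
  pinned <- !is.null(model$control_t0)
  free_el <- if (pinned) seq_len(n_el)[-1] else seq_len(n_el)
  n_w_u <- length(free_el) * n_u
  n_w <- n_w_u + as.integer(free_tf)
  ucol <- function(e) {
    stopifnot(e %in% free_el)
    (match(e, free_el) - 1) * n_u + seq_len(n_u)
  }
  tf_col <- if (free_tf) n_w else NA_integer_
  frac <- grid$boundaries / grid$t_f

  lower <- c(rep(model$control_lower, length(free_el)),
             if (free_tf) tf_bounds[1])
  upper <- c(rep(model$control_upper, length(free_el)),
             if (free_tf) tf_bounds[2])

  controls_of <- function(w) {
    U <- matrix(0, n_el, n_u)
    if (pinned) U[1, ] <- model$control_t0
    for (e in free_el) U[e, ] <- w[ucol(e)]
    U
  }
  tf_of <- function(w) if (free_tf) w[tf_col] else grid$t_f

  # single forward elimination sweep with sensitivity propagation (memoized)
  cache <- new.env(parent = emptyenv())
  run_sim <- function(w) {
    if (!is.null(cache$w) && identical(cache$w, w)) return(cache$sim)
    U <- controls_of(w)
    tf <- tf_of(w)
    x <- aug$x0
    G <- matrix(0, n, n_w)
    boundaries <- vector("list", n_el)
    nodes <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      dtau <- frac[e + 1] - frac[e]
      h <- tf * dtau
      st <- colloc_element(aug$rhs, aug$jac_x, aug$jac_u, x, U[e, ], h,
                           grid$cm, sens = TRUE)
      G <- st$A %*% G
      if (e %in% free_el) G[, ucol(e)] <- G[, ucol(e)] + st$B
      if (free_tf) G[, tf_col] <- G[, tf_col] + st$c * dtau
      x <- st$x_end
      boundaries[[e]] <- list(x = x, G = G)
      nodes[[e]] <- st$X
    }
    sim <- list(U = U, tf = tf, xf = x, G = G, boundaries = boundaries,
                nodes = nodes)
    cache$w <- w; cache$sim <- sim
    sim
  }

  # terminal functional value + gradient in w
  terminal_eval <- function(sim, fun, support, uses_tf = FALSE) {
    val <- fun(sim$xf, sim$tf)
    dxf <- fd_gradient(function(v) fun(v, sim$tf), sim$xf, support)
    gw <- drop(crossprod(sim$G, dxf))
    if (free_tf) {
      dtf <- if (uses_tf) 1 else 0
      gw[tf_col] <- gw[tf_col] + dtf
    }
    list(value = val, grad = gw)
  }

  state_path <- model$state_sum_constraint
  sp_idx <- if (!is.null(state_path))
    match(state_path$states, model$state_names) else integer(0)

  eval_f <- function(w) {
    sim <- run_sim(w)
    ob <- ocp$objectives[[objective]]
    terminal_eval(sim, ob$fun, ob$support, isTRUE(ob$uses_tf))
  }

  # inequality constraints g(w) <= 0 with Jacobian
  eval_g <- function(w) {
    sim <- run_sim(w)
    vals <- numeric(0); jac <- NULL; names_g <- character(0)
    for (tc in ocp$constraints) {
      te <- terminal_eval(sim, tc$fun, tc$support)
      vals <- c(vals, -te$value)
      jac <- rbind(jac, -te$grad)
      names_g <- c(names_g, tc$name)
    }
    if (!is.null(model$control_sum_bound)) {
      for (e in free_el) {
        vals <- c(vals, sum(sim$U[e, ]) - model$control_sum_bound)
        row <- numeric(n_w); row[ucol(e)] <- 1
        jac <- rbind(jac, row)
        names_g <- c(names_g, paste0("u_sum_el", e))
      }
    }
    if (length(sp_idx)) {
      for (e in seq_len(n_el)) {
        b <- sim$boundaries[[e]]
        vals <- c(vals, sum(b$x[sp_idx]) - state_path$bound)
        ind <- numeric(n); ind[sp_idx] <- 1
        jac <- rbind(jac, drop(crossprod(b$G, ind)))
        names_g <- c(names_g, paste0("e_sum_el", e))
      }
    }
    list(value = vals, jac = jac, names = names_g)
  }

  structure(list(
    ocp = ocp, grid = grid, free_tf = free_tf, objective = objective,
    n_dynamic_states = n, n_w = n_w, n_el = n_el,
    n_collocation = n_el * grid$degree * n,
    n_continuity = (n_el - 1) * n,
    lower = lower, upper = upper,
    free_elements = free_el, ucol = ucol, tf_col = tf_col,
    controls_of = controls_of, tf_of = tf_of,
    run_sim = run_sim, eval_f = eval_f, eval_g = eval_g,
    terminal_eval = terminal_eval
  ), class = "transcribed_nlp")
}

#' @export
print.transcribed_nlp <- function(x, ...) {
  cat("transcribed_nlp:", x$ocp$model$name, "/", x$ocp$technique, "\n")
  cat("  elements:", x$n_el, "| dynamic states:", x$n_dynamic_states,
      "| decision variables:", x$n_w, "\n")
  cat("  collocation equations:", x$n_collocation,
      "| continuity constraints:", x$n_continuity, "\n")
  invisible(x)
}

# Residual check of a reduced solution against the full-space collocation
# and continuity equations (used for verification).
collocation_residuals <- function(nlp, w) {
  sim <- nlp$run_sim(w)
  aug <- nlp$ocp$aug
  cm <- nlp$grid$cm
  n <- nlp$n_dynamic_states
  frac <- nlp$grid$boundaries / nlp$grid$t_f
  x_start <- aug$x0
  worst <- 0
  for (e in seq_len(nlp$n_el)) {
    h <- sim$tf * (frac[e + 1] - frac[e])
    X <- sim$nodes[[e]]
    for (r in seq_len(ncol(X))) {
      res <- cm$C[1, r] * x_start - h * aug$rhs(X[, r], sim$U[e, ])
      for (j in seq_len(ncol(X))) res <- res + cm$C[j + 1, r] * X[, j]
      worst <- max(worst, max(abs(res)))
    }
    # continuity: element start of e+1 equals last node of e (by construction
    # of the elimination sweep this is exact)
    x_start <- sim$boundaries[[e]]$x
  }
  worst
}
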