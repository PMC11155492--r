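#' Linear operator defined by forward/adjoint oracles
#'
#' Wraps a pair of matrix-free oracles as the linear constraint maps A, B of a
#' split problem. The iterates may be plain vectors or matrices (e.g. one
#' column per material in tomography); the oracles must accept and return that
#' shape, and \code{n_in}/\code{n_out} count total elements.
#'
#' @param forward function mapping a domain array to a range array.
#' @param adjoint function implementing the transpose map.
#' @param n_in,n_out total element counts of domain and range.
#' @return An object of class \code{"linear_map"}.
#' @seealso [linear_map_dense()], [linear_map_identity()], [check_adjoint()]
#' @export
linear_map <- function(forward, adjoint, n_in, n_out) {
  stopifnot(is.function(forward), is.function(adjoint),
            n_in >= 1, n_out >= 1)
  structure(list(forward = forward, adjoint = adjoint,
                 n_in = as.integer(n_in), n_out = as.integer(n_out)),
            class = "linear_map")
}

#' @rdname linear_map
#' @param M a dense or sparse matrix.
#' @export
linear_map_dense <- function(M) {
  linear_map(function(v) as.numeric(M %*% v),
             function(u) as.numeric(Matrix::crossprod(M, u)),
             ncol(M), nrow(M))
}

#' @rdname linear_map
#' @param n dimension.
#' @param scale scalar multiple of the identity (e.g. -1 for B = -I).
#' @export
linear_map_identity <- function(n, scale = 1) {
  linear_map(function(v) scale * v, function(u) scale * u, n, n)
}

#' Verify the adjoint identity of a linear map
#'
#' Checks \code{<A v, u> == <v, A' u>} on random probe pairs; a mismatch means
#' the forward and adjoint oracles do not describe the same operator.
#'
#' @param map a \code{linear_map}.
#' @param n_probes number of random probes.
#' @param tol relative tolerance.
#' @param seed probe seed.
#' @return Invisibly, the maximum relative discrepancy. Errors on violation.
#' @export
check_adjoint <- function(map, n_probes = 5, tol = 1e-8, seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  worst <- 0
  for (i in seq_len(n_probes)) {
    v <- stats::rnorm(map$n_in)
    u <- stats::rnorm(map$n_out)
    lhs <- sum(map$forward(v) * u)
    rhs <- sum(v * map$adjoint(u))
    rel <- abs(lhs - rhs) / (1 + abs(lhs))
    worst <- max(worst, rel)
  }
  if (worst > tol)
    stop(sprintf("adjoint identity violated: relative error %.3g > %.3g",
                 worst, tol), call. = FALSE)
  invisible(worst)
}

# Save/restore .Random.seed so internal probe draws don't disturb user RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

zero_fn <- function(x) 0
zero_grad <- function(x) x * 0

#' Assemble a split composite problem
#'
#' Bundles the oracles defining
#' \deqn{\min_{x,y} \; f_c(x) + f_d(x) + g_c(y) + g_d(y)
#'       \quad \mathrm{s.t.} \quad Ax + By = c,}
#' where \code{fc}, \code{gc} are convex (possibly nonsmooth, prox-friendly)
#' and \code{fd}, \code{gd} are differentiable (possibly nonconvex) parts that
#' the solver linearizes at each sweep.
#'
#' Prox oracles take \code{(v, metric)} and must return the minimizer of
#' \code{fc(x) + sum(metric * (x - v)^2) / 2} for a positive elementwise
#' \code{metric}. Value oracles may return \code{Inf} outside their domain;
#' prox oracles must always return in-domain points. An optional
#' \code{y_subproblem_solver(y_t, x_next, u_t, problem, cfg)} replaces the
#' prox-based y step when \code{gc} is not prox-friendly (as in tomography,
#' where each ray's subproblem is solved by Newton's method).
#'
#' @param A,B \code{linear_map}s for the constraint.
#' @param c_vec constraint right-hand side (array conformable with the range).
#' @param fc_prox,gc_prox prox oracles (default: identity, i.e. the zero
#'   function).
#' @param fc_value,fd_value,gc_value,gd_value value oracles (default 0).
#' @param fd_grad,gd_grad gradient oracles of the smooth parts (default 0).
#' @param y_subproblem_solver optional replacement for the y prox step.
#' @param x_subproblem_solver optional replacement for the x prox step (dense
#'   mode; same signature with roles of the blocks swapped).
#' @return An object of class \code{"split_problem"}.
#' @export
split_problem <- function(A, B, c_vec,
                          fc_prox = NULL, fc_value = zero_fn,
                          fd_value = zero_fn, fd_grad = zero_grad,
                          gc_prox = NULL, gc_value = zero_fn,
                          gd_value = zero_fn, gd_grad = zero_grad,
                          y_subproblem_solver = NULL,
                          x_subproblem_solver = NULL) {
  stopifnot(inherits(A, "linear_map"), inherits(B, "linear_map"))
  if (A$n_out != B$n_out || length(c_vec) != A$n_out)
    stop("split_problem: range dimensions of A, B and length of c must agree",
         call. = FALSE)
  if (is.null(fc_prox)) fc_prox <- function(v, metric) v
  if (is.null(gc_prox)) gc_prox <- function(v, metric) v
  structure(list(
    dim_x = A$n_in, dim_y = B$n_in, dim_c = A$n_out,
    A = A, B = B, c_vec = c_vec,
    fc_prox = fc_prox, fc_value = fc_value,
    fd_value = fd_value, fd_grad = fd_grad,
    gc_prox = gc_prox, gc_value = gc_value,
    gd_value = gd_value, gd_grad = gd_grad,
    y_subproblem_solver = y_subproblem_solver,
    x_subproblem_solver = x_subproblem_solver), class = "split_problem")
}

#' Step-size configuration for the linearized sweeps
#'
#' The solver's fast path takes the combined metrics
#' \code{Df = Hf + A' Sigma A} and \code{Eg = Hg + B' Sigma B} directly as
#' strictly positive diagonals (supplied elementwise, conformable with x and
#' y). Both applications shipped with the package choose \code{Hf} precisely
#' so that this sum is diagonal, and the update formulas only ever use the
#' sum, so the solver never needs \code{Hf}/\code{Hg} themselves. The sweeps
#' are well-posed iff these diagonals are positive, which is the practical
#' form of the requirement that \code{Hf + A' Sigma A} and
#' \code{Hg + B' Sigma B} be positive definite.
#'
#' \code{sigma} is the diagonal of the penalty matrix (elementwise,
#' conformable with the constraint residual); a small dense symmetric
#' positive-definite \code{sigma_dense} may be given instead for vector-shaped
#' problems.
#'
#' @param sigma positive penalty diagonal, or a scalar (recycled).
#' @param Df positive diagonal of \code{Hf + A' Sigma A} (scalar recycled).
#' @param Eg positive diagonal of \code{Hg + B' Sigma B} (scalar recycled).
#' @param dim_x,dim_y,dim_c dimensions used to recycle scalars.
#' @param sigma_dense optional dense SPD penalty matrix (overrides
#'   \code{sigma}).
#' @return An object of class \code{"step_config"}.
#' @export
step_config <- function(sigma, Df, Eg, dim_x = NULL, dim_y = NULL,
                        dim_c = NULL, sigma_dense = NULL) {
  recycle <- function(v, n) if (length(v) == 1L && !is.null(n)) rep(v, n) else v
  sigma <- recycle(sigma, dim_c); Df <- recycle(Df, dim_x)
  Eg <- recycle(Eg, dim_y)
  if (is.null(sigma_dense)) {
    if (any(sigma <= 0)) stop("step_config: 'sigma' must be positive", call. = FALSE)
  } else {
    if (!isSymmetric(unname(sigma_dense)) ||
        min(eigen(sigma_dense, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("step_config: 'sigma_dense' must be symmetric positive definite",
           call. = FALSE)
  }
  if (any(Df <= 0))
    stop("step_config: 'Df' must be strictly positive (Hf + A'SA must be positive definite)",
         call. = FALSE)
  if (any(Eg <= 0))
    stop("step_config: 'Eg' must be strictly positive (Hg + B'SB must be positive definite)",
         call. = FALSE)
  structure(list(sigma_diag = sigma, sigma_dense = sigma_dense,
                 Df_diag = Df, Eg_diag = Eg), class = "step_config")
}

apply_sigma <- function(cfg, r) {
  if (is.null(cfg$sigma_dense)) cfg$sigma_diag * r
  else as.numeric(cfg$sigma_dense %*% r)
}

#' Penalty-weighted constraint residual norm
#'
#' Returns \code{sqrt(t(r) Sigma r)} for the residual \code{r = Ax + By - c};
#' zero iff the pair is feasible.
#'
#' @param x,y current points.
#' @param problem a \code{split_problem}.
#' @param cfg a \code{step_config}.
#' @return Nonnegative scalar.
#' @export
primal_residual <- function(x, y, problem, cfg) {
  r <- problem$A$forward(x) + problem$B$forward(y) - problem$c_vec
  sqrt(sum(r * apply_sigma(cfg, r)))
}

#' Augmented Lagrangian value
#'
#' Evaluates
#' \deqn{L_\Sigma(x, y, u) = f(x) + g(y) + \langle u, Ax + By - c\rangle
#'   + \tfrac12 \|Ax + By - c\|_\Sigma^2,}
#' returning \code{Inf} iff x or y lies outside its domain.
#'
#' @inheritParams primal_residual
#' @param u dual variable.
#' @return Extended-real scalar.
#' @export
augmented_lagrangian <- function(x, y, u, problem, cfg) {
  fv <- problem$fc_value(x) + problem$fd_value(x)
  gv <- problem$gc_value(y) + problem$gd_value(y)
  if (!is.finite(fv) || !is.finite(gv)) return(Inf)
  r <- problem$A$forward(x) + problem$B$forward(y) - problem$c_vec
  fv + gv + sum(u * r) + 0.5 * sum(r * apply_sigma(cfg, r))
}

admm_objective <- function(x, y, problem) {
  problem$fc_value(x) + problem$fd_value(x) +
    problem$gc_value(y) + problem$gd_value(y)
}

#' Single linearized sweeps
#'
#' The three update steps of the engine. \code{x_update} solves the linearized
#' x subproblem in the diagonal metric \code{Df}: it forms
#' \code{v = x_t - Df^{-1} [grad fd(x_t) + A'(u_t + Sigma (A x_t + B y_t - c))]}
#' and returns \code{fc_prox(v, Df)}. \code{y_update} is the analogue with the
#' already-updated x in the penalty term (or delegates to a registered
#' \code{y_subproblem_solver}). \code{u_update} is the exact dual ascent step
#' \code{u + Sigma (A x_{t+1} + B y_{t+1} - c)}.
#'
#' @param state list with elements \code{x}, \code{y}, \code{u}.
#' @param problem a \code{split_problem}.
#' @param cfg a \code{step_config}.
#' @param x_next,y_next updated primal blocks.
#' @return The updated block.
#' @export
x_update <- function(state, problem, cfg) {
  if (!is.null(problem$x_subproblem_solver))
    return(problem$x_subproblem_solver(state$x, state$y, state$u, problem, cfg))
  r <- problem$A$forward(state$x) + problem$B$forward(state$y) - problem$c_vec
  grad <- problem$fd_grad(state$x) +
    problem$A$adjoint(state$u + apply_sigma(cfg, r))
  v <- state$x - grad / cfg$Df_diag
  out <- problem$fc_prox(v, cfg$Df_diag)
  if (any(!is.finite(out)))
    stop("x_update: prox oracle returned non-finite values", call. = FALSE)
  out
}

#' @rdname x_update
#' @export
y_update <- function(state, x_next, problem, cfg) {
  if (!is.null(problem$y_subproblem_solver))
    return(problem$y_subproblem_solver(state$y, x_next, state$u, problem, cfg))
  r <- problem$A$forward(x_next) + problem$B$forward(state$y) - problem$c_vec
  grad <- problem$gd_grad(state$y) +
    problem$B$adjoint(state$u + apply_sigma(cfg, r))
  v <- state$y - grad / cfg$Eg_diag
  out <- problem$gc_prox(v, cfg$Eg_diag)
  if (any(!is.finite(out)))
    stop("y_update: prox oracle returned non-finite values", call. = FALSE)
  out
}

#' @rdname x_update
#' @export
u_update <- function(state, x_next, y_next, problem, cfg) {
  r <- problem$A$forward(x_next) + problem$B$forward(y_next) - problem$c_vec
  state$u + apply_sigma(cfg, r)
}

#' Run the linearized ADMM engine
#'
#' Executes \code{iters} full sweeps (x, y, then dual update) from the given
#' initialization, logging per-iteration metrics, and returns both the final
#' iterates and the running averages \code{xbar = mean of x_1..x_T},
#' \code{ybar = mean of y_1..y_T}. The convergence guarantee for this class of
#' algorithms concerns the averaged iterates, so averaging starts at the first
#' sweep with no burn-in by default.
#'
#' @param problem a \code{split_problem}.
#' @param cfg a \code{step_config}.
#' @param iters number of sweeps T (fixed budget; this is the quantity the
#'   averaged-iterate guarantee is stated in).
#' @param init optional list \code{(x, y, u)}; default all zeros.
#' @param truth optional list with elements \code{x} and/or \code{y}; when
#'   given, root-mean-square errors of the iterate and of the running average
#'   are logged.
#' @param rmse_denom divisor for the RMSE (default \code{sqrt(length(x))};
#'   tomography divides by the square root of the pixel count only).
#' @param callback optional
#'   \code{function(t, x_prev, y_prev, u_prev, x, y, u, xbar, ybar)} returning
#'   a named numeric vector appended to the log (used by the applications for
#'   loss curves and curvature diagnostics).
#' @param keep_history store \code{(x_{t+1}, y_t)} snapshot pairs every
#'   \code{history_every} sweeps (the staggered pair the restricted-strong-
#'   convexity diagnostic needs).
#' @param history_every snapshot stride.
#' @param burn_in number of initial sweeps excluded from the running average
#'   (default 0).
#' @param early_stop optional list \code{(primal, change)}: stop early once
#'   the penalty-weighted residual and the successive-iterate change both fall
#'   below these tolerances. Off by default: the guarantee is for a fixed
#'   budget with averaging.
#' @return An object of class \code{"admm_run"}: list with final \code{x},
#'   \code{y}, \code{u}, averages \code{xbar}, \code{ybar}, the per-iteration
#'   \code{log} data frame, iteration count \code{iters}, and (optionally)
#'   \code{history}.
#' @export
run_admm <- function(problem, cfg, iters, init = NULL, truth = NULL,
                     rmse_denom = NULL, callback = NULL,
                     keep_history = FALSE, history_every = 1L,
                     burn_in = 0L, early_stop = NULL) {
  stopifnot(iters >= 1)
  # Matrix-shaped problems must pass shaped arrays in `init`; the vector
  # default covers the common case.
  x <- if (!is.null(init$x)) init$x else numeric(problem$dim_x)
  y <- if (!is.null(init$y)) init$y else numeric(problem$dim_y)
  u <- if (!is.null(init$u)) init$u else problem$c_vec * 0
  if (is.null(rmse_denom)) rmse_denom <- sqrt(problem$dim_x)

  xsum <- x * 0; ysum <- y * 0; n_avg <- 0L
  log_rows <- vector("list", iters)
  history <- if (keep_history) list() else NULL
  xbar <- x; ybar <- y

  for (t in seq_len(iters)) {
    state <- list(x = x, y = y, u = u)
    step <- function(expr, what) {
      tryCatch(expr, error = function(e)
        stop(sprintf("%s failed at iteration %d: %s", what, t,
                     conditionMessage(e)), call. = FALSE))
    }
    x_new <- step(x_update(state, problem, cfg), "x update")
    y_new <- step(y_update(state, x_new, problem, cfg), "y update")
    u_new <- step(u_update(state, x_new, y_new, problem, cfg), "dual update")

    if (t > burn_in) {
      xsum <- xsum + x_new; ysum <- ysum + y_new; n_avg <- n_avg + 1L
      xbar <- xsum / n_avg; ybar <- ysum / n_avg
    }
    if (keep_history && (t %% history_every == 0L || t == iters))
      history[[length(history) + 1L]] <-
        list(t = t, x_next = x_new, y_prev = y)

    row <- c(t = t,
             objective = admm_objective(x_new, y_new, problem),
             aug_lagrangian = augmented_lagrangian(x_new, y_new, u_new,
                                                   problem, cfg),
             primal_residual = primal_residual(x_new, y_new, problem, cfg),
             rmse_x = if (!is.null(truth$x))
               sqrt(sum((x_new - truth$x)^2)) / rmse_denom else NA_real_,
             rmse_xbar = if (!is.null(truth$x))
               sqrt(sum((xbar - truth$x)^2)) / rmse_denom else NA_real_)
    if (!is.null(callback))
      row <- c(row, callback(t, x, y, u, x_new, y_new, u_new, xbar, ybar))
    log_rows[[t]] <- row

    moved <- sqrt(sum((x_new - x)^2) + sum((y_new - y)^2))
    x <- x_new; y <- y_new; u <- u_new
    if (!is.null(early_stop) &&
        row[["primal_residual"]] <= early_stop$primal &&
        moved <= early_stop$change) {
      log_rows <- log_rows[seq_len(t)]
      break
    }
  }

  log_df <- as.data.frame(do.call(rbind, log_rows))
  structure(list(x = x, y = y, u = u, xbar = xbar, ybar = ybar,
                 log = log_df, iters = nrow(log_df), history = history,
                 cfg = cfg),
            class = "admm_run")
}

#' @export
print.admm_run <- function(x, ...) {
  cat("Linearized ADMM run:", x$iters, "sweeps\n")
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final objective:        %.6g\n", last$objective))
  cat(sprintf("  final primal residual:  %.3g\n", last$primal_residual))
  if (!is.na(last$rmse_xbar))
    cat(sprintf("  final RMSE (averaged):  %.4g\n", last$rmse_xbar))
  invisible(x)
}

#' @export
summary.admm_run <- function(object, ...) {
  lg <- object$log
  out <- list(iters = object$iters,
              objective_final = lg$objective[nrow(lg)],
              objective_min = min(lg$objective),
              primal_residual_final = lg$primal_residual[nrow(lg)],
              rmse_xbar_final = lg$rmse_xbar[nrow(lg)])
  class(out) <- "summary.admm_run"
  out
}

#' @export
print.summary.admm_run <- function(x, ...) {
  cat("ADMM run over", x$iters, "sweeps\n")
  cat(sprintf("  objective: final %.6g (min %.6g)\n",
              x$objective_final, x$objective_min))
  cat(sprintf("  primal residual: %.3g\n", x$primal_residual_final))
  if (!is.na(x$rmse_xbar_final))
    cat(sprintf("  RMSE of averaged iterate: %.4g\n", x$rmse_xbar_final))
  invisible(x)
}

#' @export
plot.admm_run <- function(x, which = c("objective", "primal_residual"), ...) {
  lg <- x$log
  which <- match.arg(which, choices = names(lg), several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (w in which) {
    vals <- lg[[w]]
    logy <- if (all(vals > 0, na.rm = TRUE)) "y" else ""
    graphics::plot(lg$t, vals, type = "l", log = logy,
                   xlab = "iteration", ylab = w, ...)
  }
  invisible(x)
}

#' Write an iteration log to CSV
#'
#' One row per sweep, with the header columns \code{t}, \code{objective},
#' \code{aug_lagrangian}, \code{primal_residual}, \code{rmse_x},
#' \code{rmse_xbar} plus any application-specific columns.
#'
#' @param run an \code{admm_run} (or an object containing one in
#'   \code{$run}).
#' @param path output file.
#' @export
write_iteration_log <- function(run, path) {
  lg <- if (inherits(run, "admm_run")) run$log else run$run$log
  utils::write.csv(lg, path, row.names = FALSE)
  invisible(path)
}

#' Check the step-size matrix conditions on a dense instance
#'
#' For small problems where the step-size matrices can be materialized, this
#' reports the minimum eigenvalues of \code{Hf}, \code{Hf + A' Sigma A}, and
#' \code{Hf - Hess fd(x)} at each probe point (and the analogues for the y
#' block), flagging any value below \code{-tol}. These are the conditions
#' under which each sweep is a well-posed majorization step.
#'
#' @param Hf,Hg dense step-size matrices (either may be \code{NULL} to skip
#'   that block).
#' @param A_dense,B_dense dense constraint matrices.
#' @param Sigma dense penalty matrix (or positive diagonal vector).
#' @param hessian_fd,hessian_gd functions returning the dense Hessian of the
#'   smooth parts at a point (may be \code{NULL}).
#' @param probe_points_x,probe_points_y lists of probe points.
#' @param tol flag threshold on eigenvalues.
#' @return An object of class \code{"step_condition_report"} with one row per
#'   check and an overall \code{ok} flag.
#' @export
verify_step_conditions <- function(Hf = NULL, Hg = NULL, A_dense = NULL,
                                   B_dense = NULL, Sigma = NULL,
                                   hessian_fd = NULL, hessian_gd = NULL,
                                   probe_points_x = list(),
                                   probe_points_y = list(), tol = 1e-8) {
  if (is.vector(Sigma)) Sigma <- diag(Sigma, nrow = length(Sigma))
  min_eig <- function(M) min(eigen((M + t(M)) / 2, symmetric = TRUE,
                                   only.values = TRUE)$values)
  rows <- list()
  add <- function(check, value) rows[[length(rows) + 1L]] <<-
    data.frame(check = check, min_eigenvalue = value, ok = value >= -tol)
  block <- function(H, Mat, hess, probes, label) {
    if (is.null(H)) return()
    add(paste0(label, " >= 0"), min_eig(H))
    if (!is.null(Mat) && !is.null(Sigma)) {
      D <- H + t(Mat) %*% Sigma %*% Mat
      v <- min_eig(D)
      rows[[length(rows) + 1L]] <<-
        data.frame(check = paste0(label, " + M'SM > 0"),
                   min_eigenvalue = v, ok = v > tol)
    }
    if (!is.null(hess))
      for (i in seq_along(probes))
        add(sprintf("%s - Hess at probe %d", label, i),
            min_eig(H - hess(probes[[i]])))
  }
  block(Hf, A_dense, hessian_fd, probe_points_x, "Hf")
  block(Hg, B_dense, hessian_gd, probe_points_y, "Hg")
  tab <- do.call(rbind, rows)
  structure(list(table = tab, ok = all(tab$ok), tol = tol),
            class = "step_condition_report")
}

#' @export
print.step_condition_report <- function(x, ...) {
  cat("Step-size condition report",
      if (x$ok) "(all checks passed)" else "(VIOLATIONS FLAGGED)", "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
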