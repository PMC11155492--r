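#' Squared spectral norm by power iteration
#'
#' Estimates \code{||Phi||_2^2} (the largest eigenvalue of \code{Phi' Phi})
#' by power iteration, then inflates by a factor \code{1 + 1e-10} so that
#' \code{gamma * I - Phi' Phi} is positive semidefinite under floating point.
#'
#' @param Phi numeric matrix.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @return Scalar upper estimate of the squared spectral norm.
#' @export
spectral_norm_sq <- function(Phi, tol = 1e-8, max_iter = 500) {
  old <- local_seed(7L)
  on.exit(restore_seed(old))
  v <- stats::rnorm(ncol(Phi))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(max_iter)) {
    z <- crossprod(Phi, Phi %*% v)
    lam_new <- sqrt(sum(z^2))
    if (lam_new == 0) return(0)
    v <- as.numeric(z) / lam_new
    if (abs(lam_new - lam) <= tol * lam_new) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  lam * (1 + 1e-10)
}

#' Penalized quantile regression objective
#'
#' Evaluates
#' \deqn{\mathrm{Loss}(x) = \frac1n \sum_i \ell_q(w_i - \phi_i^\top x)
#'   + \lambda \sum_j \beta \log(1 + |x_j|/\beta),}
#' the check loss of the linear fit plus the (possibly nonconvex) log
#' penalty. \code{beta = Inf} gives the l1-penalized convex case.
#'
#' @param x coefficient vector.
#' @param Phi n-by-d design matrix.
#' @param w response vector.
#' @param q quantile level in (0, 1).
#' @param lam penalty weight.
#' @param beta penalty shape (\code{Inf} for the l1 norm).
#' @return Scalar objective value.
#' @export
qr_objective <- function(x, Phi, w, q, lam, beta = Inf) {
  mean(quantile_loss(w - as.numeric(Phi %*% x), q)) +
    log_penalty_value(x, lam, beta)
}

#' Penalty weight on the theoretical scale
#'
#' Convenience default \code{const * sqrt(log(d) / n)}, the rate at which the
#' penalty must grow with dimension for consistent sparse recovery. The rate
#' fixes only the scaling; the constant must keep the penalty cost of the
#' true support below the loss gap between the null fit and the truth, or
#' the zero vector becomes the global optimum. The default 0.75 preserves
#' that balance at moderate sparsity levels (around 2-3\% nonzeros).
#'
#' @param n sample size.
#' @param d dimension.
#' @param const leading constant.
#' @return Scalar penalty weight.
#' @export
qr_lambda <- function(n, d, const = 0.75) const * sqrt(log(d) / n)

#' Assemble the split problem for sparse quantile regression
#'
#' Recasts the penalized quantile regression as
#' \code{min fc(x) + fd(x) + gc(y)} subject to \code{Phi x = y}, with
#' \itemize{
#'   \item \code{fc(x) = lam ||x||_1} plus the indicator of the l2 ball of
#'     radius \code{R} (prox: soft-threshold then ball projection),
#'   \item \code{fd(x) = lam * sum(beta log(1 + |x|/beta) - |x|)}, the smooth
#'     concave remainder of the log penalty, linearized each sweep,
#'   \item \code{gc(y) = mean(quantile_loss(w - y, q))} with a closed-form
#'     per-coordinate prox.
#' }
#' The constraint maps are \code{A = Phi}, \code{B = -I}, \code{c = 0} with
#' penalty \code{Sigma = sigma I_n}. The x step-size matrix is
#' \code{Hf = sigma (gamma I - Phi'Phi)} with \code{gamma} at least the
#' squared spectral norm of \code{Phi}, so the combined x metric
#' \code{Df = sigma gamma I} is diagonal and every update has a closed form.
#'
#' @inheritParams qr_objective
#' @param R l2-ball radius constraint on x (default \code{Inf}: inactive).
#' @param sigma positive constraint-penalty parameter.
#' @param gamma optional squared-spectral-norm bound (computed by power
#'   iteration when \code{NULL}); values below the squared spectral norm are
#'   a configuration error (\code{Hf} would be indefinite).
#' @return List with the \code{split_problem}, the \code{step_config}, and
#'   \code{gamma}.
#' @export
assemble_qr_problem <- function(Phi, w, q = 0.5, lam, beta = Inf, R = Inf,
                                sigma, gamma = NULL) {
  n <- nrow(Phi); d <- ncol(Phi)
  stopifnot(length(w) == n, sigma > 0, lam >= 0)
  if (is.null(gamma)) {
    gamma <- spectral_norm_sq(Phi)
  } else {
    top <- spectral_norm_sq(Phi)
    if (gamma < top / (1 + 1e-6))
      stop("assemble_qr_problem: 'gamma' is below the squared spectral norm of Phi; Hf would be indefinite",
           call. = FALSE)
  }
  R_tol <- if (is.finite(R)) R * (1 + 1e-10) else Inf
  problem <- split_problem(
    A = linear_map_dense(Phi),
    B = linear_map_identity(n, scale = -1),
    c_vec = numeric(n),
    fc_prox = function(v, metric) prox_l1_ball(v, lam / metric, R),
    fc_value = function(x) {
      if (sqrt(sum(x^2)) > R_tol) Inf else lam * sum(abs(x))
    },
    fd_value = function(x) log_penalty_smooth_value(x, lam, beta),
    fd_grad = function(x) log_penalty_smooth_grad(x, lam, beta),
    gc_prox = function(v, metric) prox_quantile(v, w, q, a = 1 / n, rho = metric),
    gc_value = function(y) mean(quantile_loss(w - y, q)))
  cfg <- step_config(sigma = sigma, Df = sigma * gamma, Eg = sigma,
                     dim_x = d, dim_y = n, dim_c = n)
  list(problem = problem, cfg = cfg, gamma = gamma)
}

#' Sparse quantile regression via linearized nonconvex ADMM
#'
#' Fits the penalized quantile regression model of [qr_objective()] by
#' running the linearized ADMM engine on the split assembled by
#' [assemble_qr_problem()]. Every update is closed form, so each sweep costs
#' two multiplications by \code{Phi}. The returned estimate is the running
#' average of the iterates (the quantity the convergence guarantee is stated
#' for); the final iterate is also kept.
#'
#' @inheritParams assemble_qr_problem
#' @param iters number of ADMM sweeps (default 1000).
#' @param truth optional true coefficient vector; enables RMSE logging
#'   \code{sqrt(sum((x - truth)^2) / d)}.
#' @param init optional list \code{(x, y, u)} (default zeros).
#' @return An object of class \code{"sqr_fit"} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{fitted},
#'   \code{residuals}, and \code{plot}. Per-iteration loss curves for the
#'   iterate and its running average are in \code{$run$log} (columns
#'   \code{loss_x}, \code{loss_xbar}).
#' @examples
#' dat <- generate_qr_data(n = 60, d = 20, s_star = 3, noise = "t5", seed = 1)
#' fit <- sqr(dat$Phi, dat$w, q = 0.5, lam = 0.2, beta = 0.5,
#'            sigma = 0.005, iters = 200, truth = dat$x_true)
#' head(sort(abs(coef(fit)), decreasing = TRUE))
#' @export
sqr <- function(Phi, w, q = 0.5, lam = qr_lambda(nrow(Phi), ncol(Phi)),
                beta = Inf, R = Inf, sigma, gamma = NULL, iters = 1000,
                truth = NULL, init = NULL) {
  asm <- assemble_qr_problem(Phi, w, q, lam, beta, R, sigma, gamma)
  cb <- function(t, x_prev, y_prev, u_prev, x, y, u, xbar, ybar) {
    c(loss_x = qr_objective(x, Phi, w, q, lam, beta),
      loss_xbar = qr_objective(xbar, Phi, w, q, lam, beta))
  }
  run <- run_admm(asm$problem, asm$cfg, iters = iters, init = init,
                  truth = if (!is.null(truth)) list(x = truth) else NULL,
                  rmse_denom = sqrt(ncol(Phi)), callback = cb)
  structure(list(run = run, Phi = Phi, w = w, q = q, lam = lam, beta = beta,
                 R = R, sigma = sigma, gamma = asm$gamma,
                 coefficients = run$xbar, x_final = run$x,
                 call = match.call()),
            class = "sqr_fit")
}

#' @export
coef.sqr_fit <- function(object, type = c("average", "final"), ...) {
  switch(match.arg(type), average = object$coefficients,
         final = object$x_final)
}

#' @export
predict.sqr_fit <- function(object, newx = NULL, ...) {
  X <- if (is.null(newx)) object$Phi else newx
  as.numeric(X %*% coef(object))
}

#' @export
fitted.sqr_fit <- function(object, ...) predict(object)

#' @export
residuals.sqr_fit <- function(object, ...) object$w - fitted(object)

#' @export
print.sqr_fit <- function(x, ...) {
  cat("Sparse quantile regression (linearized nonconvex ADMM)\n")
  cat(sprintf("  n = %d, d = %d, q = %g, lambda = %.4g, beta = %g, sigma = %g\n",
              nrow(x$Phi), ncol(x$Phi), x$q, x$lam, x$beta, x$sigma))
  cat(sprintf("  sweeps: %d;  final penalized loss (averaged iterate): %.6g\n",
              x$run$iters, x$run$log$loss_xbar[x$run$iters]))
  nz <- sum(abs(coef(x)) > 1e-6)
  cat(sprintf("  nonzero coefficients (|x| > 1e-6): %d\n", nz))
  invisible(x)
}

#' @export
summary.sqr_fit <- function(object, ...) {
  lg <- object$run$log
  top <- order(abs(coef(object)), decreasing = TRUE)
  out <- list(fit = object,
              loss_final = lg$loss_xbar[nrow(lg)],
              rmse_final = lg$rmse_xbar[nrow(lg)],
              top_coef = utils::head(data.frame(index = top,
                                                value = coef(object)[top]), 10))
  class(out) <- "summary.sqr_fit"
  out
}

#' @export
print.summary.sqr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$rmse_final))
    cat(sprintf("  final RMSE vs truth (averaged iterate): %.4g\n",
                x$rmse_final))
  cat("  largest-magnitude coefficients:\n")
  print(x$top_coef, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sqr_fit <- function(x, ...) {
  lg <- x$run$log
  has_rmse <- !all(is.na(lg$rmse_xbar))
  old <- graphics::par(mfrow = c(1, 1 + has_rmse))
  on.exit(graphics::par(old))
  graphics::plot(lg$t, lg$loss_x, type = "l", log = "xy", col = "grey50",
                 xlab = "iteration", ylab = "penalized loss", ...)
  graphics::lines(lg$t, lg$loss_xbar, col = "black")
  graphics::legend("topright", c("iterate", "running average"),
                   col = c("grey50", "black"), lty = 1, bty = "n")
  if (has_rmse) {
    graphics::plot(lg$t, lg$rmse_x, type = "l", log = "xy", col = "grey50",
                   xlab = "iteration", ylab = "RMSE", ...)
    graphics::lines(lg$t, lg$rmse_xbar, col = "black")
  }
  invisible(x)
}
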