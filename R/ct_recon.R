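#' Quadratically-continued exponential
#'
#' \code{qexp(t)} equals \code{exp(t)} for \code{t <= 0} and its second-order
#' Taylor continuation \code{1 + t + t^2/2} for \code{t >= 0}. It is strictly
#' positive, convex, twice continuously differentiable, and has bounded
#' second derivative on the right half-line — which is what keeps the
#' reconstruction objective's curvature controlled when intermediate iterates
#' produce negative path lengths. \code{qexp_d1} and \code{qexp_d2} are its
#' first and second derivatives (\code{exp(t)} / \code{1 + t} and
#' \code{exp(t)} / \code{1} on the two branches); all three are continuous at
#' 0 with value 1.
#'
#' @param t numeric vector.
#' @return Numeric vector.
#' @export
qexp <- function(t) ifelse(t <= 0, exp(pmin(t, 0)), 1 + t + 0.5 * t^2)

#' @rdname qexp
#' @export
qexp_d1 <- function(t) ifelse(t <= 0, exp(pmin(t, 0)), 1 + t)

#' @rdname qexp
#' @export
qexp_d2 <- function(t) ifelse(t <= 0, exp(pmin(t, 0)), 1)

# Per-window-and-ray means under the surrogate model:
# Lambda[w, l] = sum_i S[w, i] * qexp(-sum_m mu[m, i] * y[l, m]) * s_ray[l]
ct_lambda <- function(y, spectrum, mu) {
  Q0 <- qexp(-(as.matrix(y) %*% as.matrix(mu)))   # n_rays x ni
  lam <- spectrum$S %*% t(Q0)                     # nw x n_rays
  if (!is.null(spectrum$s_ray)) lam <- sweep(lam, 2, spectrum$s_ray, "*")
  as.matrix(lam)
}

ct_check_domain <- function(lam, counts) {
  if (any(lam[counts > 0] <= 0))
    stop("ct_loss: nonpositive window mean with a positive count (domain error)",
         call. = FALSE)
}

#' Spectral CT reconstruction loss
#'
#' The negative Poisson log-likelihood (up to the count-factorial constant) of
#' the windowed photon-count model, with the exponential replaced by its
#' quadratic continuation [qexp()]:
#' \deqn{\mathrm{Loss}(y) = \sum_{wl}\Big[\Lambda_{wl}(y)
#'   - C_{wl}\log \Lambda_{wl}(y)\Big], \quad
#'   \Lambda_{wl}(y)=\sum_i S_{wli}\,\mathrm{qexp}\{-\sum_m \mu_{mi} y_{lm}\}.}
#' The first (convex) term is \code{gc}; the count-weighted log term is the
#' smooth part \code{gd}, linearized by the solver. Wherever all path lengths
#' are nonnegative the surrogate coincides with the exact likelihood.
#'
#' @param y \code{n_rays x nm} matrix of material path lengths.
#' @param spectrum a \code{spectral_model}.
#' @param mu \code{nm x ni} attenuation table.
#' @param counts \code{nw x n_rays} photon counts (zero counts contribute
#'   only through \code{gc}).
#' @return Scalar loss \code{gc(y) + gd(y)}.
#' @export
ct_loss <- function(y, spectrum, mu, counts) {
  lam <- ct_lambda(y, spectrum, mu)
  ct_check_domain(lam, counts)
  lg <- ifelse(counts > 0, counts * log(pmax(lam, .Machine$double.xmin)), 0)
  sum(lam) - sum(lg)
}

#' @rdname ct_loss
#' @export
ct_gc_value <- function(y, spectrum, mu) sum(ct_lambda(y, spectrum, mu))

#' @rdname ct_loss
#' @export
ct_gd_value <- function(y, spectrum, mu, counts) {
  lam <- ct_lambda(y, spectrum, mu)
  ct_check_domain(lam, counts)
  -sum(ifelse(counts > 0, counts * log(pmax(lam, .Machine$double.xmin)), 0))
}

#' Analytic gradients of the reconstruction loss
#'
#' \code{ct_grad_gc} is the gradient of the convex surrogate-mean term;
#' \code{ct_grad_gd} the gradient of the count-weighted log term; their sum is
#' the full loss gradient \code{grad g(y)}, an \code{n_rays x nm} matrix.
#'
#' @inheritParams ct_loss
#' @return \code{n_rays x nm} gradient matrix.
#' @export
ct_grad_gc <- function(y, spectrum, mu) {
  mu <- as.matrix(mu)
  sbar <- colSums(spectrum$S)
  Q1 <- qexp_d1(-(as.matrix(y) %*% mu))
  G <- -(sweep(Q1, 2, sbar, "*") %*% t(mu))
  if (!is.null(spectrum$s_ray)) G <- G * spectrum$s_ray
  unname(as.matrix(G))
}

#' @rdname ct_grad_gc
#' @export
ct_grad_gd <- function(y, spectrum, mu, counts) {
  mu <- as.matrix(mu)
  lam <- ct_lambda(y, spectrum, mu)
  ct_check_domain(lam, counts)
  Rt <- ifelse(counts > 0, counts / lam, 0)        # nw x n_rays
  W <- t(Rt) %*% spectrum$S                        # n_rays x ni
  if (!is.null(spectrum$s_ray)) W <- W * spectrum$s_ray
  Q1 <- qexp_d1(-(as.matrix(y) %*% mu))
  unname(as.matrix((W * Q1) %*% t(mu)))
}

#' Diagonal preconditioners from the projection matrix
#'
#' The matched diagonal pair
#' \code{Qf[k] = sigma * sum_l P[l, k]} (the x-step metric, column sums) and
#' \code{SigmaTilde[l] = sigma / sum_k P[l, k]} (the per-ray penalty,
#' reciprocal row sums). For a nonnegative matrix,
#' \code{P' diag(1/rowsums) P <= diag(colsums)} elementwise-convexly
#' (Jensen across each ray's pixels), so the induced x step-size matrix
#' \code{Hf = Qf - P' SigmaTilde P} (per material block) is positive
#' semidefinite for every \code{sigma} — the scalar cancels from the
#' condition. Pixels untouched by any ray (or rays missing the grid) get
#' their entries floored/capped so they are frozen rather than divided by
#' zero.
#'
#' @param P projection matrix.
#' @param sigma positive scalar penalty parameter.
#' @return List with \code{Qf_diag} (length nk) and \code{SigmaTilde_diag}
#'   (length n_rays).
#' @export
build_preconditioners <- function(P, sigma) {
  stopifnot(sigma > 0)
  colsum <- as.numeric(Matrix::colSums(P))
  rowsum <- as.numeric(Matrix::rowSums(P))
  m <- max(colsum)
  if (m <= 0) stop("build_preconditioners: P is identically zero", call. = FALSE)
  # untouched pixels: frozen; rays missing the grid: negligible penalty
  qf <- sigma * pmax(colsum, 1e-12 * m)
  st <- sigma / pmax(rowsum, 1e-12 * max(rowsum))
  list(Qf_diag = qf, SigmaTilde_diag = st)
}

#' Closed-form x step for CT reconstruction
#'
#' With \code{f == 0} and the diagonal metric \code{Qf}, the linearized x
#' subproblem has the closed-form minimizer
#' \deqn{x_{t+1} = x_t - Q_f^{-1} P^\top\big(u_t + \tilde\Sigma (P x_t - y_t)\big),}
#' applied per material column.
#'
#' @param x_t \code{nk x nm} current image.
#' @param y_t \code{n_rays x nm} current projection variable.
#' @param u_t \code{n_rays x nm} dual variable.
#' @param P projection matrix.
#' @param pre preconditioners from [build_preconditioners()].
#' @return Updated \code{nk x nm} image.
#' @export
ct_x_update <- function(x_t, y_t, u_t, P, pre) {
  if (any(pre$Qf_diag <= 0)) stop("ct_x_update: zero Qf entry", call. = FALSE)
  r <- as.matrix(P %*% x_t) - y_t
  g <- as.matrix(Matrix::crossprod(P, u_t + pre$SigmaTilde_diag * r))
  x_t - g / pre$Qf_diag
}

# Batched solve of per-ray symmetric positive-definite systems H[l] d = g[l].
# H is given by its unique entries as an n x (nm*(nm+1)/2) matrix in
# column-major upper-triangle order; closed-form inverses for nm <= 3,
# per-row solve() otherwise.
solve_spd_batch <- function(Hu, G) {
  nm <- ncol(G)
  if (nm == 1L) return(G / Hu)
  if (nm == 2L) {
    a <- Hu[, 1]; b <- Hu[, 2]; cc <- Hu[, 3]   # [a b; b c]
    det <- a * cc - b^2
    cbind((cc * G[, 1] - b * G[, 2]) / det,
          (-b * G[, 1] + a * G[, 2]) / det)
  } else if (nm == 3L) {
    h11 <- Hu[, 1]; h12 <- Hu[, 2]; h22 <- Hu[, 3]
    h13 <- Hu[, 4]; h23 <- Hu[, 5]; h33 <- Hu[, 6]
    A11 <- h22 * h33 - h23^2; A12 <- h13 * h23 - h12 * h33
    A13 <- h12 * h23 - h13 * h22
    A22 <- h11 * h33 - h13^2; A23 <- h12 * h13 - h11 * h23
    A33 <- h11 * h22 - h12^2
    det <- h11 * A11 + h12 * A12 + h13 * A13
    cbind((A11 * G[, 1] + A12 * G[, 2] + A13 * G[, 3]) / det,
          (A12 * G[, 1] + A22 * G[, 2] + A23 * G[, 3]) / det,
          (A13 * G[, 1] + A23 * G[, 2] + A33 * G[, 3]) / det)
  } else {
    out <- G
    ut <- upper.tri(diag(nm), diag = TRUE)
    for (l in seq_len(nrow(G))) {
      H <- matrix(0, nm, nm); H[ut] <- Hu[l, ]; H <- H + t(H) - diag(diag(H))
      out[l, ] <- solve(H, G[l, ])
    }
    out
  }
}

#' Per-ray Newton y step for CT reconstruction
#'
#' With \code{Hg = 0} and the per-ray penalty \code{SigmaTilde}, the y
#' subproblem separates across rays: each ray solves the smooth, strictly
#' convex nm-dimensional problem
#' \deqn{\min_{y_l}\; g_{c,l}(y_l) + \langle y_l, d_l\rangle
#'   + \tfrac{\tilde\Sigma_{ll}}2 \|y_l - (P x_{t+1})_l\|^2,}
#' where \code{d_l = (grad gd(y_t))_l - u_l}. All rays are driven jointly by
#' damped Newton (step halving, at most 30 backtracks per step) started at
#' the previous \code{y_l}, until every ray's subproblem gradient norm is at
#' most \code{newton_tol}. The gradient is a sum of large near-cancelling
#' terms (photon-count scale), so its evaluation carries an absolute noise
#' floor of a few machine epsilons times those term magnitudes; a ray that
#' can no longer improve at any step size is accepted once its residual is
#' below that per-ray floor, and is an error otherwise. The returned matrix
#' carries the attained maximum residual as attribute \code{"max_residual"}
#' and the count of positive surrogate-exponent arguments as
#' \code{"n_pos_exponent"}.
#'
#' @inheritParams ct_x_update
#' @param x_next updated image (the x block of the current sweep).
#' @param spectrum a \code{spectral_model}.
#' @param mu attenuation table.
#' @param counts photon counts.
#' @param newton_tol gradient-norm tolerance (default 1e-10).
#' @param newton_max_iter Newton iteration cap (default 50); non-convergence
#'   raises an error naming the worst ray.
#' @return Updated \code{n_rays x nm} matrix.
#' @export
ct_y_update <- function(y_t, x_next, u_t, P, spectrum, mu, counts, pre,
                        newton_tol = 1e-10, newton_max_iter = 50L) {
  mu <- as.matrix(mu)
  nm <- ncol(y_t); nl <- nrow(y_t)
  sbar <- colSums(spectrum$S)
  srow <- if (is.null(spectrum$s_ray)) rep(1, nl) else spectrum$s_ray
  st <- pre$SigmaTilde_diag
  p <- as.matrix(P %*% x_next)
  D <- ct_grad_gd(y_t, spectrum, mu, counts) - u_t

  # upper-triangle index pairs for the Hessian entries, column-major
  ut <- which(upper.tri(diag(nm), diag = TRUE), arr.ind = TRUE)
  mu_pair <- mu[ut[, 1], , drop = FALSE] * mu[ut[, 2], , drop = FALSE]

  n_pos <- 0L
  obj_fn <- function(Y) {
    A <- -(Y %*% mu)
    n_pos <<- max(n_pos, sum(A > 0))
    gcv <- srow * as.numeric(qexp(A) %*% sbar)
    gcv + rowSums(Y * D) + 0.5 * st * rowSums((Y - p)^2)
  }
  grad_fn <- function(Y) {
    Q1 <- qexp_d1(-(Y %*% mu))
    -srow * (sweep(Q1, 2, sbar, "*") %*% t(mu)) + D + st * (Y - p)
  }

  # absolute noise floor of the gradient evaluation for each ray: a small
  # multiple of machine epsilon times the magnitudes of its summed terms
  noise_floor <- function(Y) {
    Q1 <- qexp_d1(-(Y %*% mu))
    Aabs <- srow * (sweep(Q1, 2, sbar, "*") %*% t(abs(mu))) + abs(D) +
      st * abs(Y - p)
    8 * .Machine$double.eps * sqrt(rowSums(Aabs^2))
  }

  Y <- y_t
  obj <- obj_fn(Y)
  G <- grad_fn(Y)
  gn2 <- rowSums(G^2)
  tol2 <- newton_tol^2
  frozen <- rep(FALSE, nl)
  iter <- 0L
  while (any(gn2 > tol2 & !frozen)) {
    if (iter >= newton_max_iter) {
      worst <- which.max(ifelse(frozen, -Inf, gn2))
      stop(sprintf("ct_y_update: Newton failed to converge for ray %d (residual %.3g)",
                   worst, sqrt(gn2[worst])), call. = FALSE)
    }
    iter <- iter + 1L
    frozen <- frozen | (sqrt(gn2) <= noise_floor(Y))
    act <- which(gn2 > tol2 & !frozen)
    if (length(act) == 0L) break
    Ya <- Y[act, , drop = FALSE]
    W2 <- sweep(qexp_d2(-(Ya %*% mu)), 2, sbar, "*") * srow[act]
    Hu <- W2 %*% t(mu_pair)                      # |act| x n_pairs
    diag_cols <- which(ut[, 1] == ut[, 2])
    Hu[, diag_cols] <- Hu[, diag_cols] + st[act]
    delta <- solve_spd_batch(Hu, -G[act, , drop = FALSE])
    # Step-halving line search. A trial step on a ray is accepted when it
    # decreases either its subproblem objective or its gradient norm; near
    # the optimum the objective comparison is dominated by rounding while
    # the full Newton step still contracts the gradient quadratically.
    step <- rep(1, length(act))
    pending <- seq_along(act)
    for (bt in 0:30) {
      Ytrial <- Y
      Ytrial[act[pending], ] <- Ya[pending, , drop = FALSE] +
        step[pending] * delta[pending, , drop = FALSE]
      obj_t <- obj_fn(Ytrial)
      gn2_t <- rowSums(grad_fn(Ytrial)^2)
      rows <- act[pending]
      good <- (obj_t[rows] <= obj[rows] + 1e-12 * (1 + abs(obj[rows]))) |
        (gn2_t[rows] < gn2[rows])
      if (any(good)) {
        Y[rows[good], ] <- Ytrial[rows[good], , drop = FALSE]
        pending <- pending[!good]
      }
      if (length(pending) == 0L || bt == 30L) break
      step[pending] <- step[pending] / 2
    }
    if (length(pending) > 0L) {
      # complete stagnation: the subproblem is convex, so a descent step
      # exists unless the evaluation is resolution-limited
      rows <- act[pending]
      floor_r <- noise_floor(Y)[rows]
      stuck_ok <- sqrt(gn2[rows]) <= floor_r
      if (!all(stuck_ok)) {
        worst <- rows[which.max(gn2[rows])]
        stop(sprintf("ct_y_update: Newton stagnated for ray %d above the numerical noise floor (residual %.3g)",
                     worst, sqrt(gn2[worst])), call. = FALSE)
      }
      frozen[rows] <- TRUE
    }
    obj <- obj_fn(Y)
    G <- grad_fn(Y)
    gn2 <- rowSums(G^2)
  }
  structure(Y, max_residual = sqrt(max(gn2)), newton_iters = iter,
            n_pos_exponent = n_pos)
}

#' Spectral CT reconstruction via linearized nonconvex ADMM
#'
#' Reconstructs the material images \code{x} (nk pixels by nm materials) from
#' windowed photon counts by minimizing [ct_loss()] of the projected image
#' subject to \code{P x = y}, i.e. the split \code{f(x) = 0},
#' \code{g(y) = gc(y) + gd(y)}. The Kronecker-structured operators
#' (\code{A = P} per material block, diagonal penalty \code{SigmaTilde} per
#' ray) are applied column-wise and never materialized. The x step is closed
#' form ([ct_x_update()]); the y step is per-ray Newton ([ct_y_update()]);
#' the dual step is exact.
#'
#' When \code{truth} is supplied, the log gains the RMSE columns
#' (\code{sqrt(sum((x - truth)^2)) / sqrt(nk)}) and the per-iteration
#' restricted-strong-convexity statistic \code{alpha_t} (see
#' [rsc_alpha_series()]).
#'
#' @param P projection matrix (\code{n_rays x nk}).
#' @param spectrum a \code{spectral_model}.
#' @param mu \code{nm x ni} attenuation table.
#' @param counts \code{nw x n_rays} photon counts.
#' @param sigma positive penalty parameter.
#' @param iters number of sweeps (default 1000).
#' @param newton_tol,newton_max_iter y-step Newton controls.
#' @param truth optional true \code{nk x nm} phantom image.
#' @param keep_history store \code{(x_{t+1}, y_t)} snapshots (needed to
#'   recompute diagnostics afterwards); stride \code{history_every}.
#' @param history_every snapshot stride.
#' @param init optional list \code{(x, y, u)} of shaped matrices.
#' @return An object of class \code{"ct_fit"}: the reconstruction
#'   \code{$image} (averaged iterate; \code{$image_final} is the last
#'   iterate), the underlying \code{$run}, preconditioners, and inputs. The
#'   log has columns \code{loss_x} (loss of \code{P x_t}),
#'   \code{max_newton_residual}, \code{pos_exponent}, and — given truth —
#'   \code{alpha_t}.
#' @export
ct_recon <- function(P, spectrum, mu, counts, sigma, iters = 1000,
                     newton_tol = 1e-10, newton_max_iter = 50L, truth = NULL,
                     keep_history = FALSE, history_every = 10L, init = NULL) {
  stopifnot(sigma > 0, newton_tol > 0)
  nk <- ncol(P); nl <- nrow(P); nm <- nrow(as.matrix(mu))
  pre <- build_preconditioners(P, sigma)
  diag_env <- new.env(parent = emptyenv())
  diag_env$max_res <- 0; diag_env$n_pos <- 0L

  problem <- split_problem(
    A = linear_map(function(x) as.matrix(P %*% x),
                   function(yy) as.matrix(Matrix::crossprod(P, yy)),
                   n_in = nk * nm, n_out = nl * nm),
    B = linear_map(function(y) -y, function(u) -u, nl * nm, nl * nm),
    c_vec = matrix(0, nl, nm),
    gc_value = function(y) ct_gc_value(y, spectrum, mu),
    gd_value = function(y) ct_gd_value(y, spectrum, mu, counts),
    gd_grad = function(y) ct_grad_gd(y, spectrum, mu, counts),
    y_subproblem_solver = function(y_t, x_next, u_t, problem, cfg) {
      out <- ct_y_update(y_t, x_next, u_t, P, spectrum, mu, counts, pre,
                         newton_tol, newton_max_iter)
      diag_env$max_res <- attr(out, "max_residual")
      diag_env$n_pos <- attr(out, "n_pos_exponent")
      attributes(out) <- list(dim = dim(out))
      out
    })
  sig_mat <- matrix(pre$SigmaTilde_diag, nl, nm)
  cfg <- step_config(sigma = sig_mat, Df = matrix(pre$Qf_diag, nk, nm),
                     Eg = sig_mat)

  truth_y <- if (!is.null(truth)) as.matrix(P %*% truth) else NULL
  grad_truth <- if (!is.null(truth))
    ct_grad_gc(truth_y, spectrum, mu) +
      ct_grad_gd(truth_y, spectrum, mu, counts) else NULL

  cb <- function(t, x_prev, y_prev, u_prev, x, y, u, xbar, ybar) {
    out <- c(loss_x = ct_loss(as.matrix(P %*% x), spectrum, mu, counts),
             max_newton_residual = diag_env$max_res,
             pos_exponent = as.numeric(diag_env$n_pos))
    if (!is.null(truth_y)) {
      dy <- y_prev - truth_y
      den <- sum(dy^2)
      alpha <- if (den > 1e-12^2) {
        gy <- ct_grad_gc(y_prev, spectrum, mu) +
          ct_grad_gd(y_prev, spectrum, mu, counts)
        r <- as.matrix(P %*% x) - y_prev
        (sum(dy * (gy - grad_truth)) +
           0.5 * sum(sig_mat * r^2)) / den
      } else NA_real_
      out <- c(out, alpha_t = alpha)
    }
    out
  }

  if (is.null(init))
    init <- list(x = matrix(0, nk, nm), y = matrix(0, nl, nm),
                 u = matrix(0, nl, nm))
  run <- run_admm(problem, cfg, iters = iters, init = init,
                  truth = if (!is.null(truth)) list(x = truth) else NULL,
                  rmse_denom = sqrt(nk), callback = cb,
                  keep_history = keep_history, history_every = history_every)
  if (any(run$log$pos_exponent > 0))
    warning(sprintf("positive surrogate-exponent arguments occurred in %d of %d sweeps (outside the region where the likelihood's smooth part is concave)",
                    sum(run$log$pos_exponent > 0), run$iters), call. = FALSE)
  structure(list(run = run, image = run$xbar, image_final = run$x,
                 P = P, spectrum = spectrum, mu = mu, counts = counts,
                 sigma = sigma, pre = pre, truth = truth,
                 call = match.call()),
            class = "ct_fit")
}

#' @export
coef.ct_fit <- function(object, type = c("average", "final"), ...) {
  switch(match.arg(type), average = object$image, final = object$image_final)
}

#' @export
print.ct_fit <- function(x, ...) {
  cat("Spectral CT reconstruction (linearized nonconvex ADMM)\n")
  cat(sprintf("  %d pixels x %d materials, %d rays, %d windows; sigma = %g\n",
              ncol(x$P), ncol(x$image), nrow(x$P), nrow(x$counts), x$sigma))
  lg <- x$run$log
  cat(sprintf("  sweeps: %d;  final loss(P x_t): %.8g\n",
              x$run$iters, lg$loss_x[nrow(lg)]))
  cat(sprintf("  max per-ray Newton residual: %.3g\n",
              max(lg$max_newton_residual)))
  if (!all(is.na(lg$rmse_x)))
    cat(sprintf("  final RMSE vs truth: %.4g (iterate), %.4g (averaged)\n",
                lg$rmse_x[nrow(lg)], lg$rmse_xbar[nrow(lg)]))
  invisible(x)
}

#' @export
summary.ct_fit <- function(object, ...) {
  lg <- object$run$log
  out <- list(fit = object,
              loss_final = lg$loss_x[nrow(lg)],
              rmse_final = lg$rmse_x[nrow(lg)],
              alpha_min = if ("alpha_t" %in% names(lg))
                min(lg$alpha_t, na.rm = TRUE) else NA_real_,
              max_newton_residual = max(lg$max_newton_residual))
  class(out) <- "summary.ct_fit"
  out
}

#' @export
print.summary.ct_fit <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$alpha_min))
    cat(sprintf("  min alpha_t (empirical restricted strong convexity): %.4g\n",
                x$alpha_min))
  invisible(x)
}

#' @export
plot.ct_fit <- function(x, grid = NULL, material = NULL, ...) {
  img <- coef(x)
  nm <- ncol(img)
  mats <- if (is.null(material)) seq_len(nm) else material
  Nx <- if (!is.null(grid)) grid$Nx else round(sqrt(nrow(img)))
  Ny <- nrow(img) / Nx
  old <- graphics::par(mfrow = c(1, length(mats)))
  on.exit(graphics::par(old))
  for (m in mats)
    graphics::image(matrix(img[, m], Nx, Ny), asp = Ny / Nx, axes = FALSE,
                    main = paste("material", m), ...)
  invisible(x)
}

#' Empirical restricted-strong-convexity series from run snapshots
#'
#' Recomputes, for each stored snapshot pair \code{(x_{t+1}, y_t)},
#' \deqn{\alpha_t = \frac{\langle y_t - \tilde y,\; \nabla g(y_t) -
#'   \nabla g(\tilde y)\rangle + \tfrac12\|P x_{t+1} - y_t\|_\Sigma^2}
#'   {\|y_t - \tilde y\|_2^2},}
#' the curvature-along-the-path statistic whose positivity certifies the
#' restricted-strong-convexity surrogate empirically. Entries with
#' \code{||y_t - y~|| <= 1e-12} are returned as \code{NA} (undefined) and
#' excluded from summaries.
#'
#' @param history list of snapshots, each \code{list(t, x_next, y_prev)} (as
#'   stored by [run_admm()] with \code{keep_history = TRUE}).
#' @param truth_y the true projection \code{P x~} (\code{n_rays x nm}).
#' @param grad_g function mapping y to the full loss gradient.
#' @param apply_A function mapping x to \code{P x} (per material column).
#' @param Sigma_diag per-entry penalty weights, conformable with y.
#' @return Data frame with columns \code{t} and \code{alpha}.
#' @export
rsc_alpha_series <- function(history, truth_y, grad_g, apply_A, Sigma_diag) {
  g_truth <- grad_g(truth_y)
  rows <- lapply(history, function(h) {
    dy <- h$y_prev - truth_y
    den <- sum(dy^2)
    alpha <- if (den > 1e-12^2) {
      r <- apply_A(h$x_next) - h$y_prev
      (sum(dy * (grad_g(h$y_prev) - g_truth)) +
         0.5 * sum(Sigma_diag * r^2)) / den
    } else NA_real_
    data.frame(t = h$t, alpha = alpha)
  })
  do.call(rbind, rows)
}

#' First-order-stationarity gradient ratio
#'
#' Compares the loss gradient at the true projection to the gradient at the
#' zero image: \code{||grad g(y~)||_2 / ||grad g(0)||_2}, with
#' \code{g = gc + gd} evaluated on the observed counts. A small ratio
#' certifies that the truth is an approximate first-order stationary point of
#' the reconstruction objective; with counts replaced by their exact means
#' the ratio is zero up to floating point.
#'
#' @param truth_y true projection \code{P x~}.
#' @param spectrum a \code{spectral_model}.
#' @param mu attenuation table.
#' @param counts observed (or expected) counts; real values permitted.
#' @return Nonnegative scalar ratio.
#' @export
fosp_gradient_ratio <- function(truth_y, spectrum, mu, counts) {
  g <- function(y) ct_grad_gc(y, spectrum, mu) +
    ct_grad_gd(y, spectrum, mu, counts)
  denom <- sqrt(sum(g(truth_y * 0)^2))
  if (denom == 0) stop("fosp_gradient_ratio: zero gradient at y = 0", call. = FALSE)
  sqrt(sum(g(truth_y)^2)) / denom
}
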