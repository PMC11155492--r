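#' Quantile (check) loss
#'
#' The asymmetric piecewise-linear loss
#' \deqn{\ell_q(t) = q \max(t, 0) + (1 - q)\max(-t, 0),}
#' whose population minimizer is the q-th conditional quantile. For
#' \code{q = 0.5} it equals \code{abs(t) / 2} (median regression).
#'
#' @param t numeric vector of residuals.
#' @param q quantile level, strictly between 0 and 1.
#' @return Numeric vector of nonnegative losses, same length as \code{t}.
#' @examples
#' quantile_loss(c(-2, 2), 0.5)  # both 1
#' quantile_loss(-1, 0.9)        # 0.1
#' @export
quantile_loss <- function(t, q) {
  check_quantile_level(q)
  q * pmax(t, 0) + (1 - q) * pmax(-t, 0)
}

check_quantile_level <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop("quantile level 'q' must be a single number in (0, 1)", call. = FALSE)
  invisible(q)
}

#' Elementwise soft-thresholding
#'
#' Proximal operator of the weighted l1 norm: component j returns
#' \code{sign(v_j) * max(abs(v_j) - tau_j, 0)}. This is the exact minimizer of
#' \code{tau_j |x| + (x - v_j)^2 / 2} per coordinate; \code{sign(0)} is 0.
#'
#' @param v numeric vector.
#' @param tau nonnegative threshold(s), scalar or conformable with \code{v}.
#' @return Thresholded vector.
#' @export
soft_threshold <- function(v, tau) {
  if (any(tau < 0)) stop("soft_threshold: 'tau' must be nonnegative", call. = FALSE)
  sign(v) * pmax(abs(v) - tau, 0)
}

#' Euclidean projection onto the l2 ball
#'
#' Returns \code{v} unchanged when \code{sqrt(sum(v^2)) <= R}, otherwise
#' rescales it onto the sphere of radius \code{R}. \code{R = Inf} is the
#' identity.
#'
#' @param v numeric vector.
#' @param R positive radius (may be \code{Inf}).
#' @return Projected vector with norm at most \code{R}.
#' @export
project_l2_ball <- function(v, R) {
  if (R <= 0) stop("project_l2_ball: 'R' must be positive", call. = FALSE)
  if (is.infinite(R)) return(v)
  nv <- sqrt(sum(v^2))
  if (nv <= R) v else v * (R / nv)
}

#' Prox of the l1 norm plus an l2-ball indicator
#'
#' Exact proximal operator of \code{h(x) = sum(tau * |x|) + I(||x||_2 <= R)}
#' in the Euclidean metric: soft-threshold first, then project onto the ball.
#' This composition order is exact (the reverse is not): the ball projection
#' only rescales, which preserves the sign pattern and relative magnitudes
#' produced by the thresholding step.
#'
#' @param v numeric vector.
#' @param tau nonnegative threshold(s).
#' @param R positive ball radius; \code{Inf} recovers pure soft-thresholding.
#' @return Prox point, with norm at most \code{R}.
#' @export
prox_l1_ball <- function(v, tau, R = Inf) {
  project_l2_ball(soft_threshold(v, tau), R)
}

#' Scalar prox of a weighted quantile loss
#'
#' Unique minimizer over y of \code{a * quantile_loss(w - y, q) +
#' (rho / 2) * (y - v)^2}. The solution clips \code{v} into the flat region of
#' the check loss: it equals \code{w} when \code{w - v} lies in
#' \code{[-a(1-q)/rho, a q / rho]}, and otherwise moves \code{v} by the
#' appropriate one-sided slope.
#'
#' All arguments are vectorized elementwise over \code{v} and \code{w}.
#'
#' @param v prox center(s).
#' @param w observed response value(s).
#' @param q quantile level in (0, 1).
#' @param a nonnegative loss weight (e.g. \code{1/n}).
#' @param rho positive quadratic weight.
#' @return The prox point(s).
#' @export
prox_quantile <- function(v, w, q, a, rho) {
  check_quantile_level(q)
  if (any(a < 0)) stop("prox_quantile: 'a' must be nonnegative", call. = FALSE)
  if (any(rho <= 0)) stop("prox_quantile: 'rho' must be positive", call. = FALSE)
  r <- w - v
  hi <- a * q / rho          # slope bound for w - v > 0 (y < w side)
  lo <- a * (1 - q) / rho    # slope bound for w - v < 0
  out <- w
  out[r > hi] <- (v + hi)[r > hi]
  out[r < -lo] <- (v - lo)[r < -lo]
  out
}

#' Nonconvex log penalty and its smooth part
#'
#' \code{log_penalty_value} evaluates the sparsity-promoting penalty
#' \deqn{\lambda \sum_j \beta \log(1 + |x_j| / \beta),}
#' which interpolates between the l1 norm (\code{beta = Inf}) and an
#' increasingly concave, less-shrinking penalty as \code{beta} decreases.
#'
#' The penalty splits as \code{lam * ||x||_1 + fd(x)} with the smooth concave
#' remainder \code{fd(x) = lam * sum(beta * log(1 + |x|/beta) - |x|)};
#' \code{log_penalty_smooth_value} and \code{log_penalty_smooth_grad} evaluate
#' that remainder and its gradient, with components
#' \code{-lam * x_j / (beta + |x_j|)}. The gradient is continuous everywhere
#' (including 0), bounded by \code{lam}, and its Jacobian is bounded below by
#' \code{-lam / beta} times the identity, so the concavity of the remainder is
#' controlled by \code{beta}. \code{beta = Inf} gives a remainder identically
#' zero (handled exactly, no overflow).
#'
#' @param x numeric vector.
#' @param lam nonnegative penalty weight.
#' @param beta positive shape parameter, possibly \code{Inf}.
#' @return Scalar penalty value, scalar remainder value, or gradient vector.
#' @export
log_penalty_value <- function(x, lam, beta) {
  if (beta <= 0) stop("log_penalty_value: 'beta' must be positive", call. = FALSE)
  if (is.infinite(beta)) return(lam * sum(abs(x)))
  lam * beta * sum(log1p(abs(x) / beta))
}

#' @rdname log_penalty_value
#' @export
log_penalty_smooth_value <- function(x, lam, beta) {
  if (beta <= 0) stop("log_penalty_smooth_value: 'beta' must be positive", call. = FALSE)
  if (is.infinite(beta)) return(0)
  lam * sum(beta * log1p(abs(x) / beta) - abs(x))
}

#' @rdname log_penalty_value
#' @export
log_penalty_smooth_grad <- function(x, lam, beta) {
  if (beta <= 0) stop("log_penalty_smooth_grad: 'beta' must be positive", call. = FALSE)
  if (is.infinite(beta)) return(numeric(length(x)) * x)  # keeps dim attributes
  -lam * x / (beta + abs(x))
}
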