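# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: golden-section search for 1-D proxes, dense KKT
# solves for quadratic programs, finite differences for gradients, and an
# edge-intersection chord formula for the ray tracer.

golden_section <- function(f, lo, hi, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

finite_diff_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Random equality-constrained convex QP:
#   min 1/2 x'Qx + q'x + 1/2 y'Ry + r'y  s.t.  Ax + By = c
# with its exact KKT solution, wrapped as a split problem for the engine.
random_qp <- function(seed, dx = 4, dy = 3, dc = 3, sigma = 1) {
  set.seed(seed)
  Qm <- crossprod(matrix(rnorm(dx * dx), dx)) + diag(dx)
  Rm <- crossprod(matrix(rnorm(dy * dy), dy)) + diag(dy)
  qv <- rnorm(dx); rv <- rnorm(dy)
  A <- matrix(rnorm(dc * dx), dc, dx)
  B <- matrix(rnorm(dc * dy), dc, dy)
  cc <- rnorm(dc)
  KKT <- rbind(cbind(Qm, matrix(0, dx, dy), t(A)),
               cbind(matrix(0, dy, dx), Rm, t(B)),
               cbind(A, B, matrix(0, dc, dc)))
  sol <- solve(KKT, c(-qv, -rv, cc))
  xs <- sol[1:dx]; ys <- sol[dx + 1:dy]

  fc_prox <- function(v, metric) solve(Qm + diag(metric, dx), metric * v - qv)
  gc_prox <- function(v, metric) solve(Rm + diag(metric, dy), metric * v - rv)
  problem <- split_problem(
    A = linear_map_dense(A), B = linear_map_dense(B), c_vec = cc,
    fc_prox = fc_prox,
    fc_value = function(x) 0.5 * sum(x * (Qm %*% x)) + sum(qv * x),
    gc_prox = gc_prox,
    gc_value = function(y) 0.5 * sum(y * (Rm %*% y)) + sum(rv * y))
  Df <- rep(sigma * (norm(A, "2")^2 + 1), dx)
  Eg <- rep(sigma * (norm(B, "2")^2 + 1), dy)
  cfg <- step_config(sigma = rep(sigma, dc), Df = Df, Eg = Eg)
  list(problem = problem, cfg = cfg, x_star = xs, y_star = ys,
       Q = Qm, R = Rm, q = qv, r = rv, A = A, B = B, c = cc)
}

# Chord length of the line {offset * (-sin, cos) + t (cos, sin)} through the
# centered square of half-side `half`, via explicit edge intersections.
chord_length_oracle <- function(theta, offset, half) {
  d <- c(cos(theta), sin(theta)); o <- offset * c(-sin(theta), cos(theta))
  pts <- list()
  for (s in c(-half, half)) {
    if (abs(d[1]) > 1e-14) {       # vertical edge x = s
      t <- (s - o[1]) / d[1]; yy <- o[2] + t * d[2]
      if (abs(yy) <= half + 1e-12) pts[[length(pts) + 1]] <- c(s, yy)
    }
    if (abs(d[2]) > 1e-14) {       # horizontal edge y = s
      t <- (s - o[2]) / d[2]; xx <- o[1] + t * d[1]
      if (abs(xx) <= half + 1e-12) pts[[length(pts) + 1]] <- c(xx, s)
    }
  }
  if (length(pts) < 2) return(0)
  P <- unique(do.call(rbind, lapply(pts, round, digits = 10)))
  if (nrow(P) < 2) return(0)
  max(stats::dist(P))
}

# Tiny spectral CT fixture shared by reconstruction tests.
tiny_ct_fixture <- function(seed = 1, Nx = 8, n_angles = 12, n_cells = 12,
                            ni = 10, photons = 1e5) {
  grid <- image_grid(Nx, Nx, 10)
  geom <- scan_geometry(n_angles, n_cells, grid)
  P <- build_projection_matrix(grid, geom)
  spectrum <- generate_spectrum(ni = ni, nw = 3, total_photons = photons)
  mu <- builtin_attenuation(energies = spectrum$energies)
  phantom <- generate_phantom(grid, 3, list(
    list(shape = "disk", center = c(0, 0), size = 3.5, material = 1, fraction = 1),
    list(shape = "disk", center = c(-1.2, 0.8), size = 1, material = 2, fraction = 1),
    list(shape = "disk", center = c(1.2, -0.8), size = 1, material = 3, fraction = 1)))
  y_true <- forward_project(P, phantom)
  mean0 <- expected_counts(y_true, spectrum, mu)
  counts <- simulate_counts(mean0, seed)
  list(grid = grid, geom = geom, P = P, spectrum = spectrum, mu = mu,
       phantom = phantom, y_true = y_true, mean0 = mean0, counts = counts)
}
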