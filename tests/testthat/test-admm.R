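test_that("linear maps verify the adjoint identity and catch broken adjoints", {
  set.seed(1)
  M <- matrix(rnorm(12), 3, 4)
  expect_silent(check_adjoint(linear_map_dense(M)))
  broken <- linear_map(function(v) as.numeric(M %*% v),
                       function(u) as.numeric(t(M) %*% u) * 1.01, 4, 3)
  expect_error(check_adjoint(broken), "adjoint identity")
  expect_equal(linear_map_identity(3, -1)$forward(c(1, 2, 3)), c(-1, -2, -3))
})

test_that("step config validates positivity of the combined metrics", {
  expect_error(step_config(sigma = 1, Df = c(1, 0), Eg = 1), "Df")
  expect_error(step_config(sigma = -1, Df = 1, Eg = 1), "sigma")
  expect_error(step_config(sigma = 1, Df = 1, Eg = -2), "Eg")
  cfg <- step_config(sigma = 2, Df = 3, Eg = 4, dim_x = 2, dim_y = 2, dim_c = 2)
  expect_equal(cfg$sigma_diag, c(2, 2))
  expect_error(step_config(sigma = 1, Df = 1, Eg = 1,
                           sigma_dense = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

make_identity_problem <- function(fc_prox = NULL, fc_value = function(x) 0) {
  split_problem(A = linear_map_identity(2), B = linear_map_identity(2, -1),
                c_vec = c(0, 0), fc_prox = fc_prox, fc_value = fc_value)
}

test_that("x update is stationary at a subproblem optimum and soft-thresholds l1", {
  prob <- make_identity_problem()
  cfg <- step_config(sigma = c(1, 1), Df = c(1, 1), Eg = c(1, 1))
  st <- list(x = c(1, 1), y = c(1, 1), u = c(0, 0))
  expect_equal(x_update(st, prob, cfg), c(1, 1))
  # fc = |.|_1: with zero residual and zero dual, v = x and the update is a
  # plain soft threshold at 1
  prob_l1 <- make_identity_problem(
    fc_prox = function(v, metric) soft_threshold(v, 1 / metric),
    fc_value = function(x) sum(abs(x)))
  st <- list(x = c(2, -0.5), y = c(2, -0.5), u = c(0, 0))
  expect_equal(x_update(st, prob_l1, cfg), c(1, 0))
})

test_that("x update solves the linearized subproblem exactly for quadratics", {
  qp <- random_qp(11, dx = 5, dy = 4, dc = 4)
  st <- list(x = rnorm(5), y = rnorm(4), u = rnorm(4))
  x1 <- x_update(st, qp$problem, qp$cfg)
  # dense KKT oracle: minimize fc(x) + <x, A'u> + 1/2|Ax + By - c|_S^2
  #                   + 1/2 |x - x_t|^2_Hf  with Hf = Df - A'SA
  S <- diag(qp$cfg$sigma_diag)
  Df <- diag(qp$cfg$Df_diag)
  Hf <- Df - t(qp$A) %*% S %*% qp$A
  Hmat <- qp$Q + t(qp$A) %*% S %*% qp$A + Hf
  rhs <- -(qp$q + t(qp$A) %*% st$u +
             t(qp$A) %*% S %*% (qp$B %*% st$y - qp$c)) + Hf %*% st$x
  expect_equal(x1, as.numeric(solve(Hmat, rhs)), tolerance = 1e-8)
  # the update weakly decreases its own subproblem objective
  subobj <- function(x) qp$problem$fc_value(x) + sum(x * (t(qp$A) %*% st$u)) +
    0.5 * sum((qp$A %*% x + qp$B %*% st$y - qp$c)^2 * qp$cfg$sigma_diag) +
    0.5 * sum((x - st$x) * (Hf %*% (x - st$x)))
  expect_lte(subobj(x1), subobj(st$x) + 1e-10)
})

test_that("y update is stationary when feasible and matches per-coordinate search", {
  # gc = gd = 0, B = -I: y already equal to A x_next is a fixed point
  prob <- make_identity_problem()
  cfg <- step_config(sigma = c(3, 3), Df = c(3, 3), Eg = c(3, 3))
  st <- list(x = c(1, 2), y = c(0.5, -1), u = c(0, 0))
  xn <- c(0.5, -1)
  expect_equal(y_update(st, xn, prob, cfg), c(0.5, -1))
  # separable gc: weighted l1 prox vs golden-section per coordinate
  wts <- c(0.7, 1.3)
  prob2 <- split_problem(
    A = linear_map_identity(2), B = linear_map_identity(2, -1), c_vec = c(0, 0),
    gc_prox = function(v, metric) soft_threshold(v, wts / metric),
    gc_value = function(y) sum(wts * abs(y)))
  set.seed(12)
  st <- list(x = rnorm(2), y = rnorm(2), u = rnorm(2))
  xn <- rnorm(2)
  y1 <- y_update(st, xn, prob2, cfg)
  for (j in 1:2) {
    # per-coordinate subproblem objective (gd = 0, B = -I)
    f <- function(yj) wts[j] * abs(yj) - yj * st$u[j] +
      0.5 * cfg$sigma_diag[j] * (xn[j] - yj)^2 +
      0.5 * (cfg$Eg_diag[j] - cfg$sigma_diag[j]) * (yj - st$y[j])^2
    ref <- golden_section(f, -5, 5)
    expect_equal(y1[j], ref, tolerance = 1e-6)
  }
})

test_that("dual update follows the exact ascent formula", {
  prob <- make_identity_problem()
  cfg <- step_config(sigma = c(2, 2), Df = c(2, 2), Eg = c(2, 2))
  st <- list(x = c(0, 0), y = c(0, 0), u = c(0, 0))
  expect_equal(u_update(st, c(1, 0), c(0, 1), prob, cfg), c(2, -2))
  # feasible pair leaves u unchanged
  expect_equal(u_update(list(u = c(5, -3)), c(1, 2), c(1, 2), prob, cfg),
               c(5, -3))
  # dense Sigma vs explicit matrix product
  Sm <- matrix(c(2, 0.5, 0.5, 1), 2)
  cfg_d <- step_config(sigma = c(1, 1), Df = c(4, 4), Eg = c(4, 4),
                       sigma_dense = Sm)
  r <- c(1, -1)
  expect_equal(u_update(list(u = c(0, 0)), r, c(0, 0), prob, cfg_d),
               as.numeric(Sm %*% r))
})

test_that("augmented Lagrangian and primal residual evaluate exactly", {
  qp <- random_qp(21)
  # feasible pair: aug Lagrangian equals the plain objective for any u
  xs <- qp$x_star; ys <- qp$y_star
  f_plus_g <- qp$problem$fc_value(xs) + qp$problem$gc_value(ys)
  expect_equal(augmented_lagrangian(xs, ys, rnorm(3), qp$problem, qp$cfg),
               f_plus_g, tolerance = 1e-8)
  expect_lt(primal_residual(xs, ys, qp$problem, qp$cfg), 1e-8)
  # f = g = 0, Sigma = I: <u, r> + |r|^2/2
  prob0 <- make_identity_problem()
  cfg0 <- step_config(sigma = c(1, 1), Df = c(1, 1), Eg = c(1, 1))
  x <- c(1, 0); y <- c(0, 1); u <- c(2, -1)
  r <- x - y
  expect_equal(augmented_lagrangian(x, y, u, prob0, cfg0),
               sum(u * r) + 0.5 * sum(r^2))
  # Sigma = 4I, residual (3,4): weighted norm 10
  cfg4 <- step_config(sigma = c(4, 4), Df = c(4, 4), Eg = c(4, 4))
  expect_equal(primal_residual(c(3, 4), c(0, 0), prob0, cfg4), 10)
  # random instance vs term-by-term recomputation
  st <- list(x = rnorm(4), y = rnorm(3), u = rnorm(3))
  ref <- qp$problem$fc_value(st$x) + qp$problem$gc_value(st$y)
  rr <- qp$A %*% st$x + qp$B %*% st$y - qp$c
  ref <- ref + sum(st$u * rr) + 0.5 * sum(rr^2 * qp$cfg$sigma_diag)
  expect_equal(augmented_lagrangian(st$x, st$y, st$u, qp$problem, qp$cfg),
               as.numeric(ref))
})

test_that("domain violations make the augmented Lagrangian infinite", {
  prob <- split_problem(A = linear_map_identity(1), B = linear_map_identity(1, -1),
                        c_vec = 0,
                        fc_value = function(x) if (abs(x) > 1) Inf else 0)
  cfg <- step_config(sigma = 1, Df = 1, Eg = 1)
  expect_equal(augmented_lagrangian(2, 0, 0, prob, cfg), Inf)
  expect_lt(augmented_lagrangian(0.5, 0, 0, prob, cfg), Inf)
})

test_that("the engine preserves the dual identity and averages exactly", {
  qp <- random_qp(31)
  run <- run_admm(qp$problem, qp$cfg, iters = 50)
  expect_equal(nrow(run$log), 50)
  # re-run tracking iterates to check the dual identity at machine precision
  st <- list(x = numeric(4), y = numeric(3), u = numeric(3))
  xs <- list(); ys <- list()
  for (t in 1:50) {
    xn <- x_update(st, qp$problem, qp$cfg)
    yn <- y_update(st, xn, qp$problem, qp$cfg)
    un <- u_update(st, xn, yn, qp$problem, qp$cfg)
    r <- qp$A %*% xn + qp$B %*% yn - qp$c
    expect_lt(max(abs((un - st$u) - as.numeric(r * qp$cfg$sigma_diag))), 1e-13)
    xs[[t]] <- xn; ys[[t]] <- yn
    st <- list(x = xn, y = yn, u = un)
  }
  expect_equal(run$x, st$x)
  expect_equal(run$xbar, Reduce(`+`, xs) / 50, tolerance = 1e-12)
  expect_equal(run$ybar, Reduce(`+`, ys) / 50, tolerance = 1e-12)
})

test_that("a first-order-optimal feasible triple is a fixed point of a sweep", {
  # min |x| + (y - 2)^2 / 2 s.t. x = y: optimum x = y = 1, u = -1
  prob <- split_problem(
    A = linear_map_identity(1), B = linear_map_identity(1, -1), c_vec = 0,
    fc_prox = function(v, metric) soft_threshold(v, 1 / metric),
    fc_value = function(x) abs(x),
    gc_prox = function(v, metric) (metric * v + 2) / (metric + 1),
    gc_value = function(y) 0.5 * (y - 2)^2)
  cfg <- step_config(sigma = 1.7, Df = 1.7, Eg = 2.7)
  st <- list(x = 1, y = 1, u = -1)
  xn <- x_update(st, prob, cfg)
  yn <- y_update(st, xn, prob, cfg)
  un <- u_update(st, xn, yn, prob, cfg)
  expect_lt(abs(xn - 1) + abs(yn - 1) + abs(un + 1), 1e-10)
})

test_that("averaged iterates of a strongly convex toy contract to the optimum", {
  # f = x^2/2, g = y^2/2, x = y: unique minimizer at the origin
  prob <- split_problem(
    A = linear_map_identity(1), B = linear_map_identity(1, -1), c_vec = 0,
    fc_prox = function(v, metric) metric * v / (metric + 1),
    fc_value = function(x) 0.5 * x^2,
    gc_prox = function(v, metric) metric * v / (metric + 1),
    gc_value = function(y) 0.5 * y^2)
  cfg <- step_config(sigma = 1, Df = 1, Eg = 1)
  run <- run_admm(prob, cfg, iters = 500, init = list(x = 5, y = -3, u = 2))
  expect_lt(abs(run$xbar), 0.05)
  expect_lt(abs(run$x), 1e-3)
})

test_that("a small lasso recast reaches the proximal-gradient optimum", {
  set.seed(41)
  n <- 12; d <- 5
  Phi <- matrix(rnorm(n * d), n, d)
  w <- as.numeric(Phi %*% c(1.5, -1, 0, 0, 0)) + 0.1 * rnorm(n)
  lam <- 0.3
  # split: f = lam|x|_1, g = |w - y|^2/2, y = Phi x
  prob <- split_problem(
    A = linear_map_dense(Phi), B = linear_map_identity(n, -1),
    c_vec = numeric(n),
    fc_prox = function(v, metric) soft_threshold(v, lam / metric),
    fc_value = function(x) lam * sum(abs(x)),
    gc_prox = function(v, metric) (metric * v + w) / (metric + 1),
    gc_value = function(y) 0.5 * sum((w - y)^2))
  gam <- norm(Phi, "2")^2 * (1 + 1e-10)
  sig <- 1
  cfg <- step_config(sigma = rep(sig, n), Df = rep(sig * gam, d), Eg = rep(sig, n))
  run <- run_admm(prob, cfg, iters = 3000)
  # proximal-gradient oracle on lam|x|_1 + |w - Phi x|^2/2
  L <- gam
  xo <- numeric(d)
  for (k in 1:20000)
    xo <- soft_threshold(xo - crossprod(Phi, Phi %*% xo - w) / L, lam / L)
  obj <- function(x) lam * sum(abs(x)) + 0.5 * sum((w - Phi %*% x)^2)
  expect_lt(obj(run$x) - obj(xo), 1e-5)
})

test_that("oracle failures carry the iteration index", {
  calls <- 0
  prob <- split_problem(
    A = linear_map_identity(1), B = linear_map_identity(1, -1), c_vec = 0,
    fc_prox = function(v, metric) {
      calls <<- calls + 1
      if (calls >= 3) stop("prox oracle exploded")
      v
    })
  cfg <- step_config(sigma = 1, Df = 1, Eg = 1)
  expect_error(run_admm(prob, cfg, iters = 5, init = list(x = 2, y = 0, u = 0)),
               "x update failed at iteration 3: prox oracle exploded")
})

test_that("early stopping truncates the log only when enabled", {
  qp <- random_qp(51)
  run_full <- run_admm(qp$problem, qp$cfg, iters = 400)
  expect_equal(nrow(run_full$log), 400)
  run_stop <- run_admm(qp$problem, qp$cfg, iters = 400,
                       early_stop = list(primal = 1e-9, change = 1e-9))
  expect_lt(nrow(run_stop$log), 400)
  expect_lt(sum((run_stop$x - qp$x_star)^2), 1e-10)
})

test_that("step-size condition checks flag violations and pass valid configs", {
  # Hf = I dominates a quadratic with Hessian I/2
  rep1 <- verify_step_conditions(
    Hf = diag(2), A_dense = diag(2), Sigma = c(1, 1),
    hessian_fd = function(x) diag(2) / 2, probe_points_x = list(c(0, 0)))
  expect_true(rep1$ok)
  # Hf = 0 cannot dominate a positive-definite Hessian
  rep2 <- verify_step_conditions(
    Hf = matrix(0, 2, 2), A_dense = diag(2), Sigma = c(1, 1),
    hessian_fd = function(x) diag(2), probe_points_x = list(c(1, 1)))
  expect_false(rep2$ok)
  expect_true(any(grepl("Hess", rep2$table$check) & !rep2$table$ok))
  # quantile-style Hf = sigma (gamma I - Phi'Phi) dominates the log-penalty
  # Hessian, which is bounded below by -lam/beta
  set.seed(61)
  Phi <- matrix(rnorm(30 * 20), 30, 20)
  sig <- 0.01; lam <- 0.1; beta <- 0.5
  gam <- norm(Phi, "2")^2 * (1 + 1e-10)
  Hf <- sig * (gam * diag(20) - crossprod(Phi))
  hess_fd <- function(x) diag(-lam * beta / (beta + abs(x))^2)
  rep3 <- verify_step_conditions(
    Hf = Hf, A_dense = Phi, Sigma = rep(sig, 30), hessian_fd = hess_fd,
    probe_points_x = list(numeric(20), rnorm(20)))
  expect_true(rep3$ok)
})
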