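# ncadmm

Linearized ADMM for composite optimization problems

```
minimize  f(x) + g(y)   subject to   A x + B y = c
```

where **both** `f = fc + fd` and `g = gc + gd` may be nonsmooth and
nonconvex — `fc`, `gc` convex (possibly nondifferentiable, prox-friendly),
`fd`, `gd` differentiable (possibly nonconvex) and linearized at each sweep.
Each iteration is

```
x_{t+1} = argmin_x  fc(x) + <x, ∇fd(x_t) + Aᵀu_t> + ½‖Ax + By_t − c‖²_Σ + ½‖x − x_t‖²_Hf
y_{t+1} = argmin_y  gc(y) + <y, ∇gd(y_t) + Bᵀu_t> + ½‖Ax_{t+1} + By − c‖²_Σ + ½‖y − y_t‖²_Hg
u_{t+1} = u_t + Σ(Ax_{t+1} + By_{t+1} − c)
```

with step-size matrices `Hf`, `Hg` chosen so that `Df = Hf + AᵀΣA` and
`Eg = Hg + BᵀΣB` are diagonal, making every update a cheap proximal map.
The quantity the theory controls is the running average
`x̄_T = (1/T) Σ_t x_t`, whose squared error decays like `C/T` (plus a
statistical floor) under a restricted strong convexity condition; the
package returns both the averages and the final iterates and logs
objective, augmented Lagrangian, constraint residual, and RMSE against a
known truth at every sweep.

The package is for numerical statisticians and imaging scientists who need
a splitting solver whose guarantees do not require either block of the
objective to be smooth. It ships two complete applications:

* **Sparse quantile regression** (`sqr()`): check loss `ℓ_q` plus the
  nonconvex log penalty `λ Σ_j β log(1 + |x_j|/β)`, split as `y = Φx` with
  closed-form soft-threshold/ball and quantile-clipping proxes.
* **Spectral photon-counting CT reconstruction** (`ct_recon()`): Poisson
  maximum likelihood for energy-windowed counts
  `C_{wl} ~ Poisson(Σ_i S_{wli} exp{−Σ_m μ_{mi}(Px)_{lm}})`, with a
  Siddon-style ray tracer for `P`, a quadratically-continued exponential for
  bounded curvature, closed-form x steps and per-ray Newton y steps, and
  empirical diagnostics for restricted strong convexity (`α_t`) and
  first-order stationarity of the truth.

Seeded generators build every input in code: regression designs, phantoms,
X-ray spectra with blurry window responses, and synthetic attenuation
curves (including a gadolinium K-edge).

## Worked example

Recover a 5-sparse signal from 200 heavy-tailed observations in 250
dimensions by penalized median regression:

```r
library(ncadmm)

dat <- generate_qr_data(n = 200, d = 250, s_star = 5, noise = "t5", seed = 1)
fit <- sqr(dat$Phi, dat$w, q = 0.5, lam = qr_lambda(200, 250), beta = 0.5,
           sigma = 1e-3, iters = 1000, truth = dat$x_true)
summary(fit)
#> Sparse quantile regression (linearized nonconvex ADMM)
#>   n = 200, d = 250, q = 0.5, lambda = 0.1246, beta = 0.5, sigma = 0.001
#>   sweeps: 1000;  final penalized loss (averaged iterate): 0.794217
#>   nonzero coefficients (|x| > 1e-6): 6
#>   final RMSE vs truth (averaged iterate): 0.02392
#>   largest-magnitude coefficients:
#>  index        value
#>      4 1.033231e+00
#>      3 1.008748e+00
#>      2 9.336504e-01
#>      1 7.429159e-01
#>      5 7.327712e-01
#>      8 3.590617e-05
#>      ...
```

The five largest coefficients are exactly the true support (indices 1–5,
true value 1); the small nonconvexity parameter `beta = 0.5` keeps their
estimates near 1 instead of shrinking them as the plain lasso would. The
final RMSE `(1/√d)‖x̄_T − x̃‖ ≈ 0.024` is the statistical noise floor, not
an optimization gap. `plot(fit)` draws the loss and RMSE trajectories for
the iterate and its running average.

A CT reconstruction works the same way from a preset:

```r
ps  <- ct_preset("small")
P   <- build_projection_matrix(ps$grid, ps$geom)
cnt <- simulate_counts(expected_counts(forward_project(P, ps$phantom),
                                       ps$spectrum, ps$mu), seed = 1)
rec <- ct_recon(P, ps$spectrum, ps$mu, cnt, sigma = 10, iters = 300,
                truth = ps$phantom)
```

`rec$run$log` then holds per-sweep loss, the curvature statistic `alpha_t`,
and the maximum per-ray Newton residual; `plot(rec, grid = ps$grid)` shows
the per-material images. A command-line interface with the same
functionality (subcommands `qr-sim`, `ct-sim`, `ct-recon`, `diagnose-rsc`)
is installed at `inst/cli/admmct.R`.

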