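#' Image grid for tomographic reconstruction
#'
#' A square field of view of physical side \code{side_cm}, centered at the
#' origin and discretized into \code{Nx * Ny} pixels. Pixels are indexed
#' row-major with the x index fastest: pixel \code{k = (iy - 1) * Nx + ix}
#' has center \code{(-side/2 + (ix - 0.5) * hx, -side/2 + (iy - 0.5) * hy)}.
#'
#' @param Nx,Ny pixel counts along x and y.
#' @param side_cm physical side length in cm.
#' @return Object of class \code{"image_grid"} with pixel sizes \code{hx},
#'   \code{hy} and total pixel count \code{nk}.
#' @export
image_grid <- function(Nx, Ny = Nx, side_cm = 10) {
  stopifnot(Nx >= 1, Ny >= 1, side_cm > 0)
  structure(list(Nx = as.integer(Nx), Ny = as.integer(Ny),
                 side_cm = side_cm, hx = side_cm / Nx, hy = side_cm / Ny,
                 nk = as.integer(Nx * Ny)), class = "image_grid")
}

#' Parallel-beam scan geometry
#'
#' View angles are spaced evenly over \code{[0, 2*pi)}; each view has
#' \code{n_cells} detector cells spanning the image diagonal, so every ray
#' can traverse the field of view at every angle. Ray \code{l} for angle
#' index a and cell index j is \code{l = (a - 1) * n_cells + j}; it runs in
#' direction \code{(cos theta, sin theta)} through the point
#' \code{offset * (-sin theta, cos theta)}.
#'
#' @param n_angles number of view angles.
#' @param n_cells detector cells per view.
#' @param grid the \code{image_grid} (fixes the detector extent).
#' @return Object of class \code{"scan_geometry"}.
#' @export
scan_geometry <- function(n_angles, n_cells, grid) {
  stopifnot(n_angles >= 1, n_cells >= 1, inherits(grid, "image_grid"))
  extent <- grid$side_cm * sqrt(2)
  offsets <- -extent / 2 + (seq_len(n_cells) - 0.5) * extent / n_cells
  structure(list(n_angles = as.integer(n_angles),
                 n_cells = as.integer(n_cells),
                 angles = 2 * pi * (seq_len(n_angles) - 1) / n_angles,
                 offsets = offsets, extent = extent,
                 n_rays = as.integer(n_angles * n_cells)),
            class = "scan_geometry")
}

#' Siddon-style projection matrix
#'
#' Computes the sparse matrix P with \code{P[l, k]} equal to the exact length
#' (in cm) of the intersection between ray l and pixel k, by walking the
#' sorted grid-line crossing parameters of each ray (the incremental
#' ray-tracing construction). Intersection lengths below 1e-12 cm are dropped
#' as numerical noise. Deterministic given the geometry.
#'
#' @param grid an \code{image_grid}.
#' @param geom a \code{scan_geometry} built on the same grid.
#' @return A \code{dgCMatrix} of dimension \code{n_rays x nk}.
#' @export
build_projection_matrix <- function(grid, geom) {
  stopifnot(inherits(grid, "image_grid"), inherits(geom, "scan_geometry"))
  half <- grid$side_cm / 2
  xlines <- seq(-half, half, length.out = grid$Nx + 1L)
  ylines <- seq(-half, half, length.out = grid$Ny + 1L)
  eps_dir <- 1e-14
  ri <- list(); ki <- list(); vi <- list(); idx <- 0L
  for (a in seq_len(geom$n_angles)) {
    th <- geom$angles[a]
    d <- c(cos(th), sin(th)); nv <- c(-sin(th), cos(th))
    for (j in seq_len(geom$n_cells)) {
      o <- geom$offsets[j] * nv
      # clip ray to the bounding box
      tmin <- -Inf; tmax <- Inf; miss <- FALSE
      for (ax in 1:2) {
        if (abs(d[ax]) > eps_dir) {
          t1 <- (-half - o[ax]) / d[ax]; t2 <- (half - o[ax]) / d[ax]
          tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
        } else if (o[ax] <= -half || o[ax] >= half) {
          miss <- TRUE; break
        }
      }
      if (miss || tmax - tmin <= 1e-12) next
      tx <- if (abs(d[1]) > eps_dir) (xlines - o[1]) / d[1] else numeric(0)
      ty <- if (abs(d[2]) > eps_dir) (ylines - o[2]) / d[2] else numeric(0)
      ts <- c(tmin, tx[tx > tmin & tx < tmax], ty[ty > tmin & ty < tmax], tmax)
      ts <- sort(ts)
      keep <- c(TRUE, diff(ts) > 1e-12)
      ts <- ts[keep]
      if (length(ts) < 2L) next
      lens <- diff(ts)
      mids <- (ts[-1L] + ts[-length(ts)]) / 2
      px <- o[1] + mids * d[1]; py <- o[2] + mids * d[2]
      ix <- pmin(pmax(floor((px + half) / grid$hx) + 1, 1), grid$Nx)
      iy <- pmin(pmax(floor((py + half) / grid$hy) + 1, 1), grid$Ny)
      ok <- lens > 1e-12
      if (!any(ok)) next
      idx <- idx + 1L
      ri[[idx]] <- rep.int((a - 1L) * geom$n_cells + j, sum(ok))
      ki[[idx]] <- (iy[ok] - 1L) * grid$Nx + ix[ok]
      vi[[idx]] <- lens[ok]
    }
  }
  Matrix::sparseMatrix(i = unlist(ri), j = unlist(ki), x = unlist(vi),
                       dims = c(geom$n_rays, grid$nk))
}

#' Forward projection of a material image
#'
#' \code{y = P x}: for each ray and material, the total path length (cm of
#' pure material) traversed, applied per material column.
#'
#' @param P projection matrix (\code{n_rays x nk}).
#' @param x phantom image, \code{nk x nm} matrix of material fractions.
#' @return Dense \code{n_rays x nm} matrix.
#' @export
forward_project <- function(P, x) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(P))
    stop("forward_project: pixel count of image does not match P", call. = FALSE)
  as.matrix(P %*% x)
}

#' Spectral model of the beam and windowed detector response
#'
#' Bundles the energy grid (keV), the \code{nw x ni} matrix \code{S} of
#' incident photon counts per detector window and energy bin (shared across
#' rays), and optional per-ray sensitivity multipliers.
#'
#' @param energies energy-bin centers in keV.
#' @param S nonnegative \code{nw x ni} matrix of photon counts.
#' @param s_ray optional per-ray sensitivity multipliers (default all 1).
#' @return Object of class \code{"spectral_model"}.
#' @export
spectral_model <- function(energies, S, s_ray = NULL) {
  S <- as.matrix(S)
  stopifnot(ncol(S) == length(energies), all(S >= 0))
  structure(list(energies = energies, S = S, s_ray = s_ray,
                 nw = nrow(S), ni = ncol(S), total = sum(S)),
            class = "spectral_model")
}

#' Expected spectral photon counts
#'
#' Mean of the Poisson count model for windowed photon-counting detectors:
#' \deqn{E[C_{wl}] = \sum_i S_{wli} \exp\{-\sum_m \mu_{mi} y_{lm}\},}
#' using the true exponential (this is the physical forward model; the
#' quadratically-continued surrogate is used only inside the reconstruction
#' objective).
#'
#' @param y \code{n_rays x nm} matrix of material path lengths (cm).
#' @param spectrum a \code{spectral_model}.
#' @param mu \code{nm x ni} attenuation table (1/cm).
#' @return \code{nw x n_rays} matrix of expected counts.
#' @export
expected_counts <- function(y, spectrum, mu) {
  y <- as.matrix(y); mu <- as.matrix(mu)
  stopifnot(ncol(y) == nrow(mu), ncol(mu) == spectrum$ni)
  E <- exp(-(y %*% mu))                      # n_rays x ni
  mean_c <- spectrum$S %*% t(E)              # nw x n_rays
  if (!is.null(spectrum$s_ray))
    mean_c <- sweep(mean_c, 2, spectrum$s_ray, "*")
  unname(as.matrix(mean_c))
}

#' Simulate Poisson photon counts
#'
#' Independent Poisson draws per (window, ray) cell, reproducible given the
#' seed.
#'
#' @param mean_counts nonnegative matrix of expected counts.
#' @param seed integer seed.
#' @return Integer matrix of the same shape.
#' @export
simulate_counts <- function(mean_counts, seed) {
  if (any(mean_counts < 0))
    stop("simulate_counts: negative mean", call. = FALSE)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  matrix(stats::rpois(length(mean_counts), as.numeric(mean_counts)),
         nrow(mean_counts), ncol(mean_counts))
}
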