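#' Synthetic sparse quantile-regression data
#'
#' Generates a design with i.i.d. standard normal entries and responses
#' \code{w = Phi x_true + z}, where the true signal has \code{s_star} leading
#' entries equal to 1 and the rest zero. The default noise is Student t with
#' 5 degrees of freedom — heavy-tailed, the regime in which quantile
#' regression outperforms least squares; \code{"gaussian"} and \code{"none"}
#' are available for comparisons and exact-interpolation checks.
#'
#' @param n sample size.
#' @param d dimension.
#' @param s_star number of nonzero (unit) signal entries, \code{0 <= s_star
#'   <= d}.
#' @param noise one of \code{"t5"}, \code{"gaussian"}, \code{"none"}.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with \code{Phi}, \code{w}, \code{x_true}, \code{noise},
#'   \code{seed}.
#' @export
generate_qr_data <- function(n, d, s_star, noise = c("t5", "gaussian", "none"),
                             seed = 1L) {
  noise <- match.arg(noise)
  if (s_star < 0 || s_star > d) stop("generate_qr_data: need 0 <= s_star <= d",
                                     call. = FALSE)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  Phi <- matrix(stats::rnorm(n * d), n, d)
  x_true <- c(rep(1, s_star), rep(0, d - s_star))
  z <- switch(noise,
              t5 = stats::rt(n, df = 5),
              gaussian = stats::rnorm(n),
              none = numeric(n))
  list(Phi = Phi, w = as.numeric(Phi %*% x_true) + z, x_true = x_true,
       noise = noise, seed = seed)
}

#' Rasterize a phantom from geometric inserts
#'
#' Builds an \code{nk x nm} material-fraction image by pixel-center
#' membership: the background insert is applied first, then each insert in
#' order. An insert with \code{replace = TRUE} (the default) overwrites all
#' material fractions of the pixels it covers; with \code{replace = FALSE}
#' its fraction is added, and any pixel whose fractions then exceed 1 is a
#' validation error.
#'
#' @param grid an \code{image_grid}.
#' @param n_materials number of material channels.
#' @param inserts list of inserts, each a list with \code{shape}
#'   (\code{"disk"} or \code{"rectangle"}), \code{center = c(x, y)} in cm,
#'   \code{size} (radius, or \code{c(width, height)}), \code{material}
#'   (index), \code{fraction} in [0, 1], and optional \code{replace}.
#' @return \code{nk x nm} matrix with entries in [0, 1] and per-pixel row
#'   sums at most 1.
#' @export
generate_phantom <- function(grid, n_materials, inserts = list()) {
  stopifnot(inherits(grid, "image_grid"), n_materials >= 1)
  half <- grid$side_cm / 2
  cx <- -half + (rep(seq_len(grid$Nx), times = grid$Ny) - 0.5) * grid$hx
  cy <- -half + (rep(seq_len(grid$Ny), each = grid$Nx) - 0.5) * grid$hy
  x <- matrix(0, grid$nk, n_materials)
  for (ins in inserts) {
    if (ins$fraction < 0 || ins$fraction > 1)
      stop("generate_phantom: insert fraction must lie in [0, 1]", call. = FALSE)
    member <- switch(ins$shape,
      disk = (cx - ins$center[1])^2 + (cy - ins$center[2])^2 <= ins$size[1]^2,
      rectangle = abs(cx - ins$center[1]) <= ins$size[1] / 2 &
                  abs(cy - ins$center[2]) <= ins$size[2] / 2,
      stop("generate_phantom: unknown insert shape ", ins$shape, call. = FALSE))
    replace <- if (is.null(ins$replace)) TRUE else ins$replace
    if (replace) x[member, ] <- 0
    x[member, ins$material] <- x[member, ins$material] + ins$fraction
  }
  if (any(x < 0) || any(x > 1) || any(rowSums(x) > 1 + 1e-12))
    stop("generate_phantom: overlapping inserts push a pixel's material sum above 1",
         call. = FALSE)
  x
}

#' Synthetic X-ray beam spectrum with blurry window responses
#'
#' The beam density is a smooth unimodal bump (a Beta(2, 3) profile over the
#' energy range, peaking in the lower-middle of the spectrum as filtered
#' tube spectra do), discretized to \code{ni} bin centers and normalized to
#' \code{total_photons}. Detector windows are a logistic-blurred partition of
#' the range at the given thresholds: the per-energy window responses are
#' nonnegative and sum to exactly 1 at every energy, so summing the window
#' rows recovers the beam density and the total photon budget is conserved.
#' \code{blur_keV = 0} gives a hard partition.
#'
#' @param ni number of energy bins.
#' @param nw number of windows (must equal \code{length(thresholds_keV) + 1}).
#' @param total_photons total incident photon count across windows and
#'   energies.
#' @param energy_range_keV length-2 range.
#' @param thresholds_keV increasing window thresholds inside the range.
#' @param blur_keV logistic blur scale at the thresholds (keV).
#' @return A \code{spectral_model}.
#' @export
generate_spectrum <- function(ni = 60, nw = 3, total_photons = 1e6,
                              energy_range_keV = c(20, 120),
                              thresholds_keV = c(50, 80), blur_keV = 3) {
  stopifnot(ni >= 1, nw == length(thresholds_keV) + 1)
  lo <- energy_range_keV[1]; hi <- energy_range_keV[2]
  if (any(thresholds_keV <= lo) || any(thresholds_keV >= hi) ||
      is.unsorted(thresholds_keV, strictly = TRUE))
    stop("generate_spectrum: thresholds must be strictly increasing inside the energy range",
         call. = FALSE)
  energies <- lo + (seq_len(ni) - 0.5) * (hi - lo) / ni
  uu <- (energies - lo) / (hi - lo)
  density <- stats::dbeta(uu, 2, 3)
  density <- density / sum(density) * total_photons
  # cumulative logistic edges; s[w] = P(detected in window >= w)
  edge <- function(th) {
    if (blur_keV <= 0) as.numeric(energies >= th)
    else stats::plogis((energies - th) / blur_keV)
  }
  s_list <- c(list(rep(1, ni)), lapply(thresholds_keV, edge), list(rep(0, ni)))
  S <- matrix(0, nw, ni)
  for (w in seq_len(nw)) S[w, ] <- (s_list[[w]] - s_list[[w + 1]]) * density
  spectral_model(energies, S)
}

#' Embedded synthetic attenuation curves
#'
#' Smooth parametric stand-ins (units 1/cm) with the qualitative features the
#' reconstruction algorithm exercises: PMMA (a plastic) low and strictly
#' decreasing in energy, aluminum higher and strictly decreasing, and
#' gadolinium decreasing with a discontinuous upward K-edge jump at
#' 50.2 keV — the signature that makes it usable as a contrast material.
#' These are synthetic curves, not physical reference data; the algorithm's
#' behavior depends only on their qualitative shape.
#'
#' @param materials character vector from \code{c("pmma", "aluminum",
#'   "gadolinium")}.
#' @param energies energy grid in keV.
#' @return \code{length(materials) x length(energies)} matrix with rownames.
#' @export
builtin_attenuation <- function(materials = c("pmma", "aluminum", "gadolinium"),
                                energies) {
  curve <- function(mat) {
    switch(mat,
      pmma = 0.15 + 1.1 * (20 / energies)^1.6,
      aluminum = 0.35 + 5.5 * (20 / energies)^2.1,
      gadolinium = {
        base <- 0.25 + 9 * (20 / energies)^2.4
        base * (1 + 3.5 * (energies >= 50.2))
      },
      stop("builtin_attenuation: unknown material '", mat, "'", call. = FALSE))
  }
  mu <- do.call(rbind, lapply(materials, curve))
  rownames(mu) <- materials
  mu
}

#' Named CT simulation presets
#'
#' Bundles a grid, scan geometry, spectrum, attenuation table, and phantom
#' into a ready-to-scan configuration. \code{"paper-like"} is the full-size
#' reference setting (25 x 25 grid over 10 cm, 3 materials, 50 angles x 50
#' cells, 60 energy bins, 3 windows, 1e6 photons); \code{"small"} is a
#' scaled-down version (16 x 16 grid, 24 x 24 rays, 20 bins, 1e5 photons)
#' sized for fast simulation studies. The phantom is a PMMA background disk
#' (radius 4 cm) with one aluminum and one gadolinium disk insert (radius
#' 1 cm) replacing the background where they sit.
#'
#' @param name \code{"paper-like"} or \code{"small"}.
#' @return List with \code{grid}, \code{geom}, \code{spectrum}, \code{mu},
#'   \code{phantom}, \code{materials}, and \code{name}.
#' @export
ct_preset <- function(name = c("paper-like", "small")) {
  name <- match.arg(name)
  p <- switch(name,
    "paper-like" = list(Nx = 25, n_angles = 50, n_cells = 50, ni = 60,
                        photons = 1e6),
    "small" = list(Nx = 16, n_angles = 24, n_cells = 24, ni = 20,
                   photons = 1e5))
  grid <- image_grid(p$Nx, p$Nx, side_cm = 10)
  geom <- scan_geometry(p$n_angles, p$n_cells, grid)
  spectrum <- generate_spectrum(ni = p$ni, nw = 3, total_photons = p$photons)
  materials <- c("pmma", "aluminum", "gadolinium")
  mu <- builtin_attenuation(materials, spectrum$energies)
  phantom <- generate_phantom(grid, 3, inserts = list(
    list(shape = "disk", center = c(0, 0), size = 4, material = 1,
         fraction = 1),
    list(shape = "disk", center = c(-1.8, 0.8), size = 1, material = 2,
         fraction = 1),
    list(shape = "disk", center = c(1.8, -0.8), size = 1, material = 3,
         fraction = 1)))
  list(grid = grid, geom = geom, spectrum = spectrum, mu = mu,
       phantom = phantom, materials = materials, name = name)
}
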