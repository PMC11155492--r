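#' Read and write scan components in plain-text formats
#'
#' The projection matrix is serialized as MatrixMarket coordinate format;
#' phantoms, spectra, attenuation tables, counts, and images as CSV with
#' documented headers:
#' \itemize{
#'   \item phantom / image: column \code{pixel} then one \code{material_*}
#'     column per material (nk rows);
#'   \item spectrum: \code{energy_keV} then one \code{window_*} column per
#'     window (photon counts per bin);
#'   \item attenuation: \code{energy_keV} then one column per material name
#'     (1/cm);
#'   \item counts: long format with columns \code{window}, \code{ray},
#'     \code{count}.
#' }
#'
#' @param P,x,spectrum,mu,counts the objects to serialize.
#' @param path file path.
#' @param materials material names for attenuation columns.
#' @name ct_io
NULL

#' @rdname ct_io
#' @export
write_projection_matrix <- function(P, path) {
  Matrix::writeMM(methods::as(methods::as(P, "generalMatrix"), "TsparseMatrix"),
                  path)
  invisible(path)
}

#' @rdname ct_io
#' @export
read_projection_matrix <- function(path) {
  methods::as(Matrix::readMM(path), "CsparseMatrix")
}

#' @rdname ct_io
#' @export
write_phantom_csv <- function(x, path) {
  x <- as.matrix(x)
  df <- data.frame(pixel = seq_len(nrow(x)), x)
  names(df)[-1] <- paste0("material_", seq_len(ncol(x)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ct_io
#' @export
read_phantom_csv <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, -1, drop = FALSE])
}

#' @rdname ct_io
#' @export
write_spectrum_csv <- function(spectrum, path) {
  df <- data.frame(energy_keV = spectrum$energies, t(spectrum$S))
  names(df)[-1] <- paste0("window_", seq_len(spectrum$nw))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ct_io
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  spectral_model(df$energy_keV, t(as.matrix(df[, -1, drop = FALSE])))
}

#' @rdname ct_io
#' @export
write_attenuation_csv <- function(mu, path, materials = rownames(mu),
                                  energies = seq_len(ncol(mu))) {
  df <- data.frame(energy_keV = energies, t(mu))
  if (!is.null(materials)) names(df)[-1] <- materials
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ct_io
#' @param energies optional energy grid to attach when reading.
#' @export
read_attenuation_csv <- function(path, energies = NULL) {
  df <- utils::read.csv(path)
  mu <- t(as.matrix(df[, -1, drop = FALSE]))
  rownames(mu) <- names(df)[-1]
  mu
}

#' @rdname ct_io
#' @export
write_counts_csv <- function(counts, path) {
  df <- data.frame(window = rep(seq_len(nrow(counts)), times = ncol(counts)),
                   ray = rep(seq_len(ncol(counts)), each = nrow(counts)),
                   count = as.integer(counts))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ct_io
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path)
  nw <- max(df$window); nl <- max(df$ray)
  counts <- matrix(0L, nw, nl)
  counts[cbind(df$window, df$ray)] <- as.integer(df$count)
  counts
}
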