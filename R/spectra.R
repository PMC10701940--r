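#' The fixed UV wavelength grid
#'
#' 361 points from 230.0 to 266.0 nm in 0.1 nm steps.  Points are computed
#' by index (`230 + j * 0.1`), never by floating-point accumulation, so the
#' grid endpoints are exact to within one representation error.
#'
#' @return Numeric vector of length 361 (nm).
#' @export
#' @examples
#' g <- wavelength_grid()
#' c(g[1], g[361])
wavelength_grid <- function() {
  230 + (0:360) * 0.1
}

#' Build a pure-component spectrum from Gaussian bands
#'
#' The sensitivity (absorbance per ug/mL at 1 cm path) at wavelength
#' lambda is the sum over bands of `height * exp(-(lambda - center)^2 /
#' (2 * width^2))`, evaluated on the standard grid.
#'
#' @param bands A list of bands, each `c(center, width, height)` (nm, nm,
#'   absorbance mL/ug), or a 3-column matrix / data frame with those
#'   columns.
#' @param analyte Optional analyte name.
#' @return An object of class `pure_spectrum`: list with `analyte`,
#'   `sensitivity` (length-361 non-negative vector) and `bands`.
#' @export
#' @examples
#' ps <- gaussian_pure_spectrum(list(c(248, 6, 0.1)), "X")
#' which.max(ps$sensitivity)   # grid point at 248.0 nm
gaussian_pure_spectrum <- function(bands, analyte = NA_character_) {
  if (is.data.frame(bands) || is.matrix(bands)) {
    bands <- lapply(seq_len(nrow(bands)), function(i) as.numeric(bands[i, 1:3]))
  }
  if (length(bands) == 0) stop("at least one band is required")
  grid <- wavelength_grid()
  sens <- numeric(length(grid))
  for (b in bands) {
    b <- as.numeric(b)
    if (length(b) != 3) stop("each band must be c(center, width, height)")
    if (b[1] < 200 || b[1] > 400) stop("band center must lie in [200, 400] nm")
    if (b[2] <= 0) stop("band width must be positive")
    if (b[3] < 0) stop("band height must be non-negative")
    sens <- sens + b[3] * exp(-(grid - b[1])^2 / (2 * b[2]^2))
  }
  structure(list(analyte = analyte, sensitivity = sens, bands = bands),
            class = "pure_spectrum")
}

# Frozen band parameters of the default six-component library.
# Each analyte: a narrow signature band in-window plus a weak shared-shape
# end-absorption band centred below the window (214 nm) whose tail enters
# at the 230 nm edge.  The signature bands are spaced ~5.4 nm apart so each
# analyte retains a near-selective channel; see the methods vignette.
.default_library_bands <- list(
  PAR = list(sens = 0.090, center = 243.2, width = 1.7, tail = 0.70),
  HYO = list(sens = 0.012, center = 254.0, width = 1.7, tail = 0.50),
  PNP = list(sens = 0.115, center = 237.8, width = 1.6, tail = 0.90),
  PCA = list(sens = 0.130, center = 248.6, width = 1.7, tail = 0.55),
  TRO = list(sens = 0.016, center = 259.4, width = 1.7, tail = 0.40),
  PAP = list(sens = 0.105, center = 264.8, width = 1.6, tail = 0.65)
)

#' Default six-component pure-spectrum library
#'
#' A fixed, reproducible synthetic stand-in for measured pure UV spectra of
#' PAR, HYO, PNP, PCA, TRO and PAP on the 230.0-266.0 nm grid.  Every
#' analyte has (i) a narrow signature band at a distinct wavelength, so
#' curve-resolution methods can recover the profiles, and (ii) a weak
#' end-absorption tail (band centred at 214 nm) entering at the short-
#' wavelength edge, so every channel carries more than one component.
#' Sensitivities span 0.012-0.13 A mL/ug, mimicking the large difference
#' between strong chromophores (PAR, PNP, PCA, PAP) and weak ones
#' (HYO, TRO).
#'
#' @return Named list of six [gaussian_pure_spectrum()] objects in the
#'   analyte order PAR, HYO, PNP, PCA, TRO, PAP.
#' @export
#' @examples
#' lib <- pure_spectra_library()
#' sapply(lib, function(p) max(p$sensitivity))
pure_spectra_library <- function() {
  out <- lapply(names(.default_library_bands), function(a) {
    p <- .default_library_bands[[a]]
    gaussian_pure_spectrum(list(c(214, 9, p$sens * p$tail),
                                c(p$center, p$width, p$sens)), analyte = a)
  })
  names(out) <- names(.default_library_bands)
  out
}

# 361 x k sensitivity matrix from a library (list of pure_spectrum).
library_matrix <- function(library) {
  S <- vapply(library, function(p) p$sensitivity, numeric(361))
  if (is.null(colnames(S))) colnames(S) <- names(library)
  S
}

#' Simulate mixture spectra under the bilinear Beer-Lambert model
#'
#' Generates `A = C S' + E` where `C` are the design concentrations
#' (ug/mL), `S` the pure-component sensitivities, and `E` iid Gaussian
#' measurement noise with standard deviation `noise_sd` absorbance units.
#'
#' @param design A [concentration_design] or a samples x analytes
#'   concentration matrix with column names matching the library.
#' @param library Named list of [gaussian_pure_spectrum()] objects, default
#'   [pure_spectra_library()].
#' @param noise_sd Additive noise standard deviation (absorbance units);
#'   default 0.002, a typical UV photometric repeatability.
#' @param seed Optional integer seed; with a seed the result is
#'   reproducible and the caller's RNG state is untouched.
#' @return An object of class `spectra_matrix`: list with `absorbance`
#'   (n x 361 matrix), `wavelength`, and `sample_ids`.
#' @export
#' @examples
#' d <- default_design()
#' sp <- simulate_spectra(d, noise_sd = 0.002, seed = 42)
#' dim(sp$absorbance)
simulate_spectra <- function(design, library = pure_spectra_library(),
                             noise_sd = 0.002, seed = NULL) {
  conc <- if (inherits(design, "concentration_design")) design$concentrations
          else as.matrix(design)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  S <- library_matrix(library)
  if (ncol(conc) != ncol(S))
    stop("design has ", ncol(conc), " analytes but library has ", ncol(S))
  if (!is.null(colnames(conc)) && !identical(colnames(conc), colnames(S)))
    stop("design analyte order (", paste(colnames(conc), collapse = ","),
         ") does not match library order (", paste(colnames(S), collapse = ","), ")")
  A <- conc %*% t(S)
  if (noise_sd > 0) {
    noise <- function() matrix(rnorm(length(A), 0, noise_sd), nrow = nrow(A))
    E <- if (is.null(seed)) noise() else with_seed(seed, noise())
    A <- A + E
  }
  ids <- rownames(conc)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  structure(list(absorbance = A, wavelength = wavelength_grid(),
                 sample_ids = ids),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("Spectra matrix: %d samples x %d wavelengths (%.1f-%.1f nm)\n",
              nrow(x$absorbance), ncol(x$absorbance),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

# Coerce spectra_matrix or plain matrix to the n x 361 absorbance matrix.
absorbance_matrix <- function(x) {
  if (inherits(x, "spectra_matrix")) return(x$absorbance)
  as.matrix(x)
}

#' Write / read spectra as CSV
#'
#' Layout: first column `wavelength_nm` (361 rows, one decimal place),
#' then one column per sample holding absorbances at full double
#' precision.
#'
#' @param spectra A `spectra_matrix`.
#' @param path File path.
#' @return `write_spectra_csv` returns `path` invisibly;
#'   `read_spectra_csv` returns a `spectra_matrix`.
#' @export
write_spectra_csv <- function(spectra, path) {
  A <- absorbance_matrix(spectra)
  df <- data.frame(wavelength_nm = sprintf("%.1f", wavelength_grid()))
  ids <- if (inherits(spectra, "spectra_matrix")) spectra$sample_ids
         else as.character(seq_len(nrow(A)))
  for (i in seq_len(nrow(A))) df[[paste0("s", ids[i])]] <- A[i, ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  A <- t(as.matrix(df[, -1, drop = FALSE]))
  ids <- sub("^s", "", rownames(A))
  dimnames(A) <- NULL
  structure(list(absorbance = A, wavelength = wavelength_grid(),
                 sample_ids = ids),
            class = "spectra_matrix")
}
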