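#' @importFrom stats coef cor lm pf pt qf qt predict rnorm sd var setNames
#' @importFrom utils read.csv write.csv head
NULL

# Analyte order used throughout: columns of every design / spectra object.
ANALYTES <- c("PAR", "HYO", "PNP", "PCA", "TRO", "PAP")

#' Factor specifications for the six-analyte calibration design
#'
#' Each analyte enters the multilevel design as a factor with five coded
#' levels (-2, -1, 0, +1, +2).  A factor is described by the concentration
#' at the centre level (level 0) and the increment per coded unit, so that
#' `conc = center + level * step` (all in ug/mL).  The defaults give the
#' calibration ranges 4.00-8.00 (PAR), 16.00-24.00 (HYO), 1.00-5.00 (PNP),
#' 0.40-0.80 (PCA), 4.00-12.00 (TRO) and 2.00-6.00 (PAP) ug/mL.
#'
#' @param analyte Character vector of analyte names.
#' @param center Concentrations at coded level 0 (ug/mL).
#' @param step Concentration increment per coded unit (ug/mL).
#' @return A data frame with columns `analyte`, `center`, `step`.
#' @export
#' @examples
#' factor_specs()
factor_specs <- function(analyte = ANALYTES,
                         center = c(6, 20, 3, 0.6, 8, 4),
                         step = c(1, 2, 1, 0.1, 2, 1)) {
  if (length(analyte) != length(center) || length(center) != length(step))
    stop("'analyte', 'center' and 'step' must have equal length")
  if (any(step <= 0)) stop("all steps must be positive")
  if (any(center - 2 * step <= 0))
    stop("center - 2*step must be positive: all design concentrations must be > 0")
  data.frame(analyte = analyte, center = center, step = step,
             stringsAsFactors = FALSE)
}

#' Cyclic generator of the 25-run calibration design
#'
#' The length-24 coded-level sequence that generates runs 2-25 of the
#' five-level, six-factor design: column k of the design (runs 2-25) is
#' this sequence cyclically rotated by k-1 positions, and run 1 is the
#' all-centre point.  Each nonzero level occurs five times and zero four
#' times, so that together with the centre run every level occurs exactly
#' five times in every column.
#'
#' @format Integer vector of length 24 with entries in -2..2.
#' @export
design_generator <- c(0L, -2L, -2L, 2L, -1L, 2L, 0L, -1L, -1L, 1L, 2L, 1L,
                      0L, 2L, 2L, -2L, 1L, -2L, 0L, 1L, 1L, -1L, -2L, -1L)

#' Default validation-set run indices
#'
#' The eight mixtures held out as the external validation set; the
#' remaining seventeen form the calibration (training) set.
#'
#' @format Integer vector of length 8.
#' @export
default_validation_ids <- c(5L, 8L, 10L, 11L, 14L, 15L, 17L, 22L)

#' Build the coded five-level six-factor design
#'
#' Constructs the 25 x 6 matrix of coded levels: run 1 is the centre point
#' (all zeros) and for runs 2-25 column k equals the generator rotated by
#' k-1 positions, i.e. `levels[i, k] = generator[(i - 2 + k - 1) mod 24 + 1]`.
#'
#' @param generator Integer vector of length 24 with entries in -2..2.  The
#'   default is [design_generator].
#' @param n_factors Number of factor columns (default 6).
#' @param permissive If `TRUE`, skip the level-balance check (each nonzero
#'   level five times, zero four times); useful for degenerate designs such
#'   as an all-zero generator.
#' @return An object of class `coded_design`: a list with `levels` (25 x 6
#'   integer matrix) and `generator`.
#' @export
#' @examples
#' cd <- coded_design()
#' cd$levels[5, ]   # coded row of run 5
coded_design <- function(generator = design_generator, n_factors = 6,
                         permissive = FALSE) {
  generator <- as.integer(generator)
  if (length(generator) != 24)
    stop("generator must have length 24, got ", length(generator))
  if (any(generator < -2L | generator > 2L))
    stop("generator entries must lie in -2..2")
  if (!permissive) {
    tab <- table(factor(generator, levels = -2:2))
    if (!all(tab == c(5L, 5L, 4L, 5L, 5L)))
      stop("unbalanced generator: each nonzero level must occur 5 times and 0 must occur 4 times")
  }
  lev <- matrix(0L, nrow = 25, ncol = n_factors)
  for (i in 2:25) {
    for (k in seq_len(n_factors)) {
      lev[i, k] <- generator[((i - 2 + k - 1) %% 24) + 1]
    }
  }
  structure(list(levels = lev, generator = generator), class = "coded_design")
}

#' Map a coded design to concentrations
#'
#' Applies the affine level-to-concentration map `conc = center + level *
#' step` factor by factor.  Concentrations are stored rounded to 2 decimal
#' places (ug/mL), the precision at which designs are prepared and printed.
#'
#' @param coded A [coded_design].
#' @param factors Factor specification data frame, see [factor_specs()].
#'   Column order must match the analyte order of the design.
#' @return An object of class `concentration_design`: list with
#'   `concentrations` (25 x 6 named matrix, ug/mL), `coded`, `factors`, and
#'   (once [split_design()] has been applied) `calibration_ids` /
#'   `validation_ids`.
#' @export
#' @examples
#' d <- concentration_design(coded_design(), factor_specs())
#' d$concentrations[12, ]
concentration_design <- function(coded = coded_design(), factors = factor_specs()) {
  if (!inherits(coded, "coded_design")) stop("'coded' must be a coded_design")
  lev <- coded$levels
  if (ncol(lev) != nrow(factors))
    stop("design has ", ncol(lev), " factors but ", nrow(factors), " specs given")
  conc <- sweep(sweep(lev, 2, factors$step, `*`), 2, factors$center, `+`)
  if (any(conc <= 0)) stop("design produces non-positive concentrations")
  conc <- round(conc, 2)
  dimnames(conc) <- list(seq_len(nrow(conc)), factors$analyte)
  structure(list(concentrations = conc, coded = coded, factors = factors,
                 calibration_ids = NULL, validation_ids = NULL),
            class = "concentration_design")
}

#' Split a design into calibration and validation sets
#'
#' Either a fixed set of validation run indices is supplied (the default is
#' the eight held-out mixtures in [default_validation_ids]) or, with
#' `seed`, eight runs are drawn at random without replacement.
#'
#' @param design A [concentration_design].
#' @param validation_ids Integer vector of 8 distinct run indices in 1..25,
#'   or `NULL` to draw at random.
#' @param seed Integer seed for the random draw (ignored when
#'   `validation_ids` is given).
#' @param n_validation Size of the random validation draw (default 8).
#' @return The design with `calibration_ids` (17 runs) and
#'   `validation_ids` (8 runs) filled in.
#' @export
split_design <- function(design, validation_ids = default_validation_ids,
                         seed = NULL, n_validation = 8) {
  n <- nrow(design$concentrations)
  if (is.null(validation_ids)) {
    if (!is.null(seed)) {
      validation_ids <- with_seed(seed, sample.int(n, n_validation))
    } else {
      validation_ids <- sample.int(n, n_validation)
    }
  }
  validation_ids <- as.integer(validation_ids)
  if (anyDuplicated(validation_ids)) stop("duplicate validation ids")
  if (any(validation_ids < 1L | validation_ids > n))
    stop("validation ids out of range 1..", n)
  design$validation_ids <- sort(validation_ids)
  design$calibration_ids <- setdiff(seq_len(n), design$validation_ids)
  design
}

#' @export
print.concentration_design <- function(x, ...) {
  cat("Multilevel multifactor concentration design\n")
  cat(sprintf("  %d mixtures x %d analytes (%s)\n",
              nrow(x$concentrations), ncol(x$concentrations),
              paste(colnames(x$concentrations), collapse = ", ")))
  if (!is.null(x$validation_ids))
    cat(sprintf("  calibration: %d runs; validation: runs %s\n",
                length(x$calibration_ids),
                paste(x$validation_ids, collapse = ", ")))
  invisible(x)
}

#' Calibration / validation subsets of a design
#'
#' @param design A split [concentration_design].
#' @return Concentration matrix of the requested subset (ug/mL).
#' @export
calibration_set <- function(design) {
  if (is.null(design$calibration_ids)) stop("design has not been split")
  design$concentrations[design$calibration_ids, , drop = FALSE]
}

#' @rdname calibration_set
#' @export
validation_set <- function(design) {
  if (is.null(design$validation_ids)) stop("design has not been split")
  design$concentrations[design$validation_ids, , drop = FALSE]
}

#' The full 25-mixture design, split as used for model building
#'
#' Convenience wrapper: generator-built coded design, default factor
#' specifications, default 17/8 calibration/validation split.
#'
#' @return A split [concentration_design].
#' @export
#' @examples
#' d <- default_design()
#' head(calibration_set(d))
default_design <- function() {
  split_design(concentration_design(coded_design(), factor_specs()))
}

#' Write / read a concentration design as CSV
#'
#' Columns: `mix_no`, one column per analyte (2-decimal fixed point,
#' ug/mL) and `set` (`cal` or `val`).
#'
#' @param design A split [concentration_design].
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `concentration_design` (without coded levels).
#' @export
write_design_csv <- function(design, path) {
  conc <- design$concentrations
  set <- rep("cal", nrow(conc))
  if (!is.null(design$validation_ids)) set[design$validation_ids] <- "val"
  df <- data.frame(mix_no = seq_len(nrow(conc)))
  for (j in colnames(conc)) df[[j]] <- sprintf("%.2f", conc[, j])
  df$set <- set
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  analytes <- setdiff(names(df), c("mix_no", "set"))
  conc <- as.matrix(df[analytes])
  dimnames(conc) <- list(df$mix_no, analytes)
  d <- structure(list(concentrations = conc, coded = NULL, factors = NULL,
                      calibration_ids = which(df$set == "cal"),
                      validation_ids = which(df$set == "val")),
                 class = "concentration_design")
  d
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
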