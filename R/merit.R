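#' Root mean square error
#'
#' `sqrt(sum((pred - truth)^2) / n)`.  Applied to calibration rows this is
#' the RMSEC, to external validation rows the RMSEP.
#'
#' @param pred,truth Equal-length concentration vectors (ug/mL).
#' @return Non-negative scalar.
#' @export
#' @examples
#' rmse(c(5, 6, 7), c(4, 6, 8))   # sqrt(2/3)
rmse <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop("pred and truth must be non-empty vectors of equal length")
  sqrt(mean((pred - truth)^2))
}

#' Recovery statistics
#'
#' Per-sample recovery `100 * pred / truth` (percent), their mean, and the
#' relative standard deviation `100 * sd / mean` (sample sd, n - 1).
#'
#' @param pred,truth Concentration vectors; `truth` strictly positive.
#' @return List with `recovery` (percent, per sample), `mean`, `rsd`.
#' @export
#' @examples
#' recovery_stats(c(0.98, 1.00, 1.02), c(1, 1, 1))
recovery_stats <- function(pred, truth) {
  if (any(truth <= 0)) stop("truth must be strictly positive")
  if (length(pred) != length(truth)) stop("length mismatch")
  rec <- 100 * pred / truth
  m <- mean(rec)
  rsd <- if (length(rec) > 1) 100 * sd(rec) / m else 0
  list(recovery = rec, mean = m, rsd = rsd)
}

#' Predicted-versus-actual regression diagnostics
#'
#' Ordinary least-squares line of predicted on actual concentrations: the
#' slope S and residual standard deviation s feed the detection and
#' quantitation limits ([lod_loq]).
#'
#' @param pred,truth Concentration vectors, n >= 3.
#' @return Object of class `regression_merit`: `slope`, `intercept`, `r`
#'   (Pearson), `residual_sd` (`sqrt(sum(res^2) / (n - 2))`), `n`.
#' @export
predicted_vs_actual <- function(pred, truth) {
  n <- length(pred)
  if (n < 3) stop("need at least 3 points for the regression")
  if (n != length(truth)) stop("length mismatch")
  fit <- lm(pred ~ truth)
  res <- residuals(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = cor(pred, truth),
                 residual_sd = sqrt(sum(res^2) / (n - 2)),
                 n = n),
            class = "regression_merit")
}

#' Limits of detection and quantitation
#'
#' `LOD = 3.3 * s / S` and `LOQ = 10 * s / S`, with s a standard deviation
#' of the response and S the calibration slope.  By default s is the
#' residual standard deviation of the predicted-versus-actual line; the
#' standard error of its intercept may be used instead.
#'
#' @param merit A [predicted_vs_actual()] result, or a list with `slope`
#'   and `residual_sd`.
#' @param s Optional explicit response standard deviation overriding the
#'   one in `merit`.
#' @return List with `lod` and `loq` (ug/mL); their ratio is 10/3.3 by
#'   construction.
#' @export
#' @examples
#' lod_loq(list(slope = 1, residual_sd = 0.1))
lod_loq <- function(merit, s = NULL) {
  S <- merit$slope
  if (is.null(S) || S == 0) stop("zero or missing slope")
  if (is.null(s)) s <- merit$residual_sd
  list(lod = 3.3 * s / S, loq = 10 * s / S)
}

#' Figures of merit for a fitted calibration model
#'
#' Computes, per analyte: RMSEC (calibration rows), RMSEP (validation
#' rows), per-sample validation recoveries with mean and RSD, the
#' predicted-versus-actual regression on the calibration set, and
#' LOD/LOQ.
#'
#' @param model A [calibrate()] fit (or any object with a `predict`
#'   method returning a samples x analytes matrix).
#' @param X_cal,Y_cal Calibration spectra and known concentrations.
#' @param X_val,Y_val Validation spectra and known concentrations.
#' @return Object of class `merit_report`: a list with `table` (one row
#'   per analyte: rmsec, rmsep, mean_recovery, rsd, slope, intercept, r,
#'   residual_sd, lod, loq) and `recoveries` (validation samples x
#'   analytes, percent).
#' @export
merit_report <- function(model, X_cal, Y_cal, X_val, Y_val) {
  Y_cal <- as.matrix(Y_cal); Y_val <- as.matrix(Y_val)
  pred_cal <- predict(model, X_cal)
  pred_val <- predict(model, X_val)
  analytes <- colnames(Y_cal)
  rows <- lapply(seq_len(ncol(Y_cal)), function(k) {
    reg <- predicted_vs_actual(pred_cal[, k], Y_cal[, k])
    lim <- lod_loq(reg)
    rec <- recovery_stats(pred_val[, k], Y_val[, k])
    data.frame(analyte = analytes[k],
               rmsec = rmse(pred_cal[, k], Y_cal[, k]),
               rmsep = rmse(pred_val[, k], Y_val[, k]),
               mean_recovery = rec$mean, rsd = rec$rsd,
               slope = reg$slope, intercept = reg$intercept, r = reg$r,
               residual_sd = reg$residual_sd,
               lod = lim$lod, loq = lim$loq)
  })
  recoveries <- 100 * pred_val / Y_val
  dimnames(recoveries) <- list(NULL, analytes)
  structure(list(table = do.call(rbind, rows), recoveries = recoveries),
            class = "merit_report")
}

#' @export
print.merit_report <- function(x, ...) {
  cat("Figures of merit (validation recoveries in %, concentrations in ug/mL)\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) round(v, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialise / restore a merit report as JSON
#'
#' Full double precision (lossless round trip).
#'
#' @param report A [merit_report()] result.
#' @param path File path.
#' @return `write_merit_json` returns `path` invisibly; `read_merit_json`
#'   the restored `merit_report`.
#' @export
write_merit_json <- function(report, path) {
  obj <- list(table = report$table,
              recoveries = as.vector(report$recoveries),
              n_val = nrow(report$recoveries),
              analytes = colnames(report$recoveries))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_merit_json
#' @export
read_merit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- matrix(obj$recoveries, nrow = obj$n_val,
                dimnames = list(NULL, obj$analytes))
  structure(list(table = as.data.frame(obj$table), recoveries = rec),
            class = "merit_report")
}
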