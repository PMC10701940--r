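#' Fit a multivariate calibration model
#'
#' Inverse calibration of analyte concentrations on mixture spectra by one
#' of three methods:
#'
#' * `"pcr"` -- principal component regression: regress the responses on
#'   the first `ncomp` principal-component scores of the mean-centred
#'   spectra (components ordered by decreasing singular value);
#' * `"pls"` -- partial least squares, NIPALS PLS2: one joint model for
#'   all responses;
#' * `"ann"` -- a linear ("purelin-purelin") feed-forward network,
#'   361 inputs, `n_hidden` hidden and 6 output neurons, trained by
#'   full-batch gradient descent on the mean squared error.
#'
#' All methods mean-centre spectra and responses; the centring vectors are
#' stored with the model and re-applied at prediction time, so
#' `predict(fit, x) = (x - x_mean) B + y_mean`.
#'
#' @param X Calibration spectra: a `spectra_matrix` or an n x p matrix.
#' @param Y Calibration concentrations: n x q matrix (ug/mL).
#' @param method `"pcr"`, `"pls"` or `"ann"`.
#' @param ncomp Number of latent variables for PCR/PLS (default 8).
#' @param n_hidden Hidden-layer size for the network (default 6).
#' @param epochs Training epochs for the network (default 100).  Gradient
#'   descent is a first-order method: reaching the affine optimum to tight
#'   tolerance typically takes a few thousand epochs, see the vignette.
#' @param learning_rate Step size for the network; `"auto"` (default) uses
#'   1 / (largest eigenvalue of the centred spectral Gram matrix), halved
#'   whenever a step would increase the training error.
#' @param seed Seed for the network's random weight initialisation.
#' @return An object of class `chemocal`: list with `method`, `coefficients`
#'   (p x q matrix B), `x_mean`, `y_mean`, `fitted`, `residuals` and
#'   method-specific fields (`scores`, `loadings` for PCR/PLS;
#'   `weights`, `mse_history` for the network).
#' @seealso [predict.chemocal()], [select_ncomp()], [merit_report()]
#' @export
#' @examples
#' d <- default_design()
#' sp <- simulate_spectra(d, noise_sd = 0, seed = 1)
#' fit <- calibrate(sp$absorbance[d$calibration_ids, ],
#'                  calibration_set(d), method = "pls", ncomp = 6)
#' fit
calibrate <- function(X, Y, method = c("pcr", "pls", "ann"), ncomp = 8,
                      n_hidden = 6, epochs = 100, learning_rate = "auto",
                      seed = 1) {
  method <- match.arg(method)
  X <- absorbance_matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)

  fit <- switch(method,
    pcr = fit_pcr_centered(Xc, Yc, ncomp),
    pls = fit_pls_centered(Xc, Yc, ncomp),
    ann = fit_ann_centered(Xc, Yc, n_hidden, epochs, learning_rate, seed))

  fit$method <- method
  fit$x_mean <- x_mean
  fit$y_mean <- y_mean
  fit$fitted <- sweep(Xc %*% fit$coefficients, 2, y_mean, `+`)
  fit$residuals <- Y - fit$fitted
  fit$analytes <- colnames(Y)
  colnames(fit$coefficients) <- colnames(Y)
  class(fit) <- "chemocal"
  fit
}

# PCR on centred data: regression of Yc on the first ncomp PC scores.
fit_pcr_centered <- function(Xc, Yc, ncomp) {
  sv <- svd(Xc)
  r <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  if (ncomp < 1) stop("ncomp must be >= 1")
  if (ncomp > r) stop("ncomp (", ncomp, ") exceeds the rank of X (", r, ")")
  if (nrow(Xc) < ncomp + 1) stop("need at least ncomp + 1 calibration samples")
  U <- sv$u[, 1:ncomp, drop = FALSE]
  D <- sv$d[1:ncomp]
  V <- sv$v[, 1:ncomp, drop = FALSE]
  # B = V D^-1 U' Yc ; scores T = U D
  B <- V %*% (crossprod(U, Yc) / D)
  list(coefficients = B, ncomp = ncomp,
       scores = U %*% diag(D, ncomp), loadings = V,
       singular_values = sv$d)
}

# NIPALS PLS2 on centred data.
fit_pls_centered <- function(Xc, Yc, ncomp, max_inner = 500, tol = 1e-12) {
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  if (ncomp < 1) stop("ncomp must be >= 1")
  r <- qr(Xc)$rank
  if (ncomp > r) stop("ncomp (", ncomp, ") exceeds the rank of X (", r, ")")
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); TT <- matrix(0, n, ncomp)
  if (max(apply(Yc, 2, var)) == 0) {
    # constant responses: nothing to model, B = 0
    return(list(coefficients = matrix(0, p, q), ncomp = ncomp, scores = TT,
                loadings = P, weights = W, y_loadings = Q))
  }
  Xw <- Xc; Yw <- Yc
  for (h in seq_len(ncomp)) {
    u <- Yw[, which.max(apply(Yw, 2, var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_inner)) {
      w <- crossprod(Xw, u)
      w <- w / sqrt(sum(w^2))
      t <- Xw %*% w
      qv <- crossprod(Yw, t) / sum(t^2)
      u <- Yw %*% qv / sum(qv^2)
      if (sum((t - t_old)^2) / max(sum(t^2), .Machine$double.xmin) < tol) break
      t_old <- t
    }
    if (it == max_inner)
      stop("NIPALS inner loop failed to converge for component ", h,
           " after ", max_inner, " iterations")
    p_load <- crossprod(Xw, t) / sum(t^2)
    Xw <- Xw - t %*% t(p_load)
    Yw <- Yw - t %*% t(qv)
    W[, h] <- w; P[, h] <- p_load; Q[, h] <- qv; TT[, h] <- t
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  list(coefficients = B, ncomp = ncomp, scores = TT,
       loadings = P, weights = W, y_loadings = Q)
}

# Linear two-layer network trained by full-batch gradient descent on the
# centred data.  The composed map is affine, so the optimum coincides with
# least squares; GD from small random weights approaches the minimum-norm
# solution.
fit_ann_centered <- function(Xc, Yc, n_hidden, epochs, learning_rate, seed) {
  if (epochs < 1) stop("epochs must be >= 1")
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  W1 <- with_seed(seed, matrix(rnorm(n_hidden * p, 0, 0.01), n_hidden, p))
  W2 <- with_seed(seed + 1L, matrix(rnorm(q * n_hidden, 0, 0.01), q, n_hidden))
  auto_rate <- identical(learning_rate, "auto")
  if (auto_rate) {
    d1 <- svd(Xc, nu = 0, nv = 0)$d[1]
    lr <- 1 / (d1^2 / n)
  } else {
    lr <- as.numeric(learning_rate)
    if (!is.finite(lr) || lr <= 0) stop("learning_rate must be positive")
  }
  mse_history <- numeric(epochs)
  mse <- function(W1, W2) {
    R <- Xc %*% t(W1) %*% t(W2) - Yc
    mean(R^2)
  }
  cur <- mse(W1, W2)
  for (e in seq_len(epochs)) {
    H <- Xc %*% t(W1)            # n x h
    R <- H %*% t(W2) - Yc        # n x q residual
    G2 <- 2 * crossprod(R, H) / (n * q)            # dMSE/dW2
    G1 <- 2 * t(W2) %*% crossprod(R, Xc) / (n * q) # dMSE/dW1
    repeat {
      W1n <- W1 - lr * G1
      W2n <- W2 - lr * G2
      new <- mse(W1n, W2n)
      if (!is.finite(new)) {
        if (!auto_rate)
          stop("network training diverged (MSE not finite); use a smaller learning_rate")
        lr <- lr / 2
        next
      }
      if (new <= cur || !auto_rate || lr < 1e-300) break
      lr <- lr / 2
    }
    if (!is.finite(new))
      stop("network training diverged (MSE not finite); use a smaller learning_rate")
    W1 <- W1n; W2 <- W2n; cur <- new
    mse_history[e] <- cur
  }
  list(coefficients = t(W2 %*% W1), n_hidden = n_hidden, epochs = epochs,
       weights = list(W1 = W1, W2 = W2), mse_history = mse_history,
       learning_rate = lr)
}

#' Predict concentrations from spectra
#'
#' @param object A fitted [calibrate()] model.
#' @param newdata A `spectra_matrix`, a matrix of spectra (rows =
#'   samples), or a single spectrum vector.
#' @param ... Unused.
#' @return Matrix of predicted concentrations (ug/mL), one row per sample.
#' @export
predict.chemocal <- function(object, newdata, ...) {
  X <- absorbance_matrix(if (is.null(dim(newdata)) && !inherits(newdata, "spectra_matrix"))
    matrix(newdata, nrow = 1) else newdata)
  pred <- sweep(X, 2, object$x_mean) %*% object$coefficients
  sweep(pred, 2, object$y_mean, `+`)
}

#' @export
print.chemocal <- function(x, ...) {
  lab <- switch(x$method,
                pcr = sprintf("PCR (%d latent variables)", x$ncomp),
                pls = sprintf("PLS2 (%d latent variables)", x$ncomp),
                ann = sprintf("linear feed-forward network (%d hidden neurons, %d epochs)",
                              x$n_hidden, x$epochs))
  cat("Multivariate calibration model:", lab, "\n")
  cat(sprintf("  %d wavelengths -> %d analytes; calibration RMSE %.4g ug/mL\n",
              nrow(x$coefficients), ncol(x$coefficients),
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
summary.chemocal <- function(object, ...) {
  rmsec <- sqrt(colMeans(object$residuals^2))
  out <- list(method = object$method, rmsec = rmsec,
              ncomp = object$ncomp, n_hidden = object$n_hidden,
              epochs = object$epochs)
  class(out) <- "summary.chemocal"
  out
}

#' @export
print.summary.chemocal <- function(x, ...) {
  cat("Calibration model (", x$method, ")\n", sep = "")
  cat("Per-analyte calibration RMSE (ug/mL):\n")
  print(round(x$rmsec, 4))
  invisible(x)
}

#' @export
coef.chemocal <- function(object, ...) {
  object$coefficients
}

#' @export
residuals.chemocal <- function(object, ...) object$residuals

#' @export
fitted.chemocal <- function(object, ...) object$fitted

#' Choose the number of latent variables by leave-one-out cross-validation
#'
#' For every candidate count h = 1..`max_ncomp`, each calibration sample is
#' left out in turn, the model is refitted and the left-out sample
#' predicted.  The pooled root mean square error of cross-validation is
#' `RMSECV(h) = sqrt(sum((yhat - y)^2) / (n * q))` over all samples and
#' analytes; the chosen h is the smallest one attaining the minimum.
#'
#' @param X,Y Calibration spectra and concentrations (as in [calibrate()]).
#' @param max_ncomp Largest latent-variable count to try; must be at most
#'   n - 2 so that every leave-one-out fit is defined.
#' @param method `"pcr"` or `"pls"`.
#' @return Object of class `lv_selection`: list with `rmsecv` (vector over
#'   h), `per_analyte` (max_ncomp x q matrix), `chosen` and `method`.
#' @export
#' @examples
#' d <- default_design()
#' sp <- simulate_spectra(d, noise_sd = 0, seed = 1)
#' sel <- select_ncomp(sp$absorbance[d$calibration_ids, ],
#'                     calibration_set(d), max_ncomp = 8, method = "pls")
#' sel$chosen
select_ncomp <- function(X, Y, max_ncomp, method = c("pcr", "pls")) {
  method <- match.arg(method)
  X <- absorbance_matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); q <- ncol(Y)
  if (max_ncomp < 1) stop("max_ncomp must be >= 1")
  if (max_ncomp > n - 2) stop("max_ncomp must be <= n - 2 for leave-one-out")
  sq_err <- array(0, dim = c(max_ncomp, n, q))
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; Yi <- Y[-i, , drop = FALSE]
    xm <- colMeans(Xi); ym <- colMeans(Yi)
    Xc <- sweep(Xi, 2, xm); Yc <- sweep(Yi, 2, ym)
    xo <- X[i, ] - xm
    if (method == "pcr") {
      sv <- svd(Xc)
      for (h in seq_len(max_ncomp)) {
        B <- sv$v[, 1:h, drop = FALSE] %*%
          (crossprod(sv$u[, 1:h, drop = FALSE], Yc) / sv$d[1:h])
        sq_err[h, i, ] <- (drop(xo %*% B) + ym - Y[i, ])^2
      }
    } else {
      fit <- fit_pls_centered(Xc, Yc, max_ncomp)
      # sequential NIPALS components: prediction with h factors uses the
      # first h columns of W, P, Q
      for (h in seq_len(max_ncomp)) {
        Wh <- fit$weights[, 1:h, drop = FALSE]
        Ph <- fit$loadings[, 1:h, drop = FALSE]
        Qh <- fit$y_loadings[, 1:h, drop = FALSE]
        B <- Wh %*% solve(crossprod(Ph, Wh), t(Qh))
        sq_err[h, i, ] <- (drop(xo %*% B) + ym - Y[i, ])^2
      }
    }
  }
  rmsecv <- sqrt(apply(sq_err, 1, sum) / (n * q))
  per_analyte <- sqrt(apply(sq_err, c(1, 3), mean))
  colnames(per_analyte) <- colnames(Y)
  structure(list(rmsecv = rmsecv, per_analyte = per_analyte,
                 chosen = which.min(rmsecv), method = method),
            class = "lv_selection")
}

#' @export
print.lv_selection <- function(x, ...) {
  cat(sprintf("Leave-one-out RMSECV (%s): chosen %d latent variables\n",
              x$method, x$chosen))
  print(round(setNames(x$rmsecv, seq_along(x$rmsecv)), 5))
  invisible(x)
}

#' @export
plot.lv_selection <- function(x, ...) {
  plot(seq_along(x$rmsecv), x$rmsecv, type = "b", pch = 16,
       xlab = "Latent variables", ylab = "RMSECV (ug/mL)",
       main = sprintf("Leave-one-out cross-validation (%s)", toupper(x$method)),
       ...)
  points(x$chosen, x$rmsecv[x$chosen], col = 2, pch = 19, cex = 1.4)
  invisible(x)
}

#' Save / load a calibration model as JSON
#'
#' Serialises kind, latent structure, centring vectors and coefficient
#' matrix (row-major) so a model can be stored with results.
#'
#' @param model A [calibrate()] fit.
#' @param path File path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   a `chemocal` model limited to what prediction needs.
#' @export
write_model_json <- function(model, path) {
  obj <- list(method = model$method,
              ncomp = model$ncomp,
              n_hidden = model$n_hidden,
              epochs = model$epochs,
              analytes = model$analytes,
              x_mean = model$x_mean,
              y_mean = model$y_mean,
              coefficients = as.vector(t(model$coefficients)),
              n_wavelengths = nrow(model$coefficients))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  B <- matrix(obj$coefficients, nrow = obj$n_wavelengths, byrow = TRUE)
  colnames(B) <- obj$analytes
  structure(list(method = obj$method, ncomp = obj$ncomp,
                 n_hidden = obj$n_hidden, epochs = obj$epochs,
                 analytes = obj$analytes,
                 x_mean = obj$x_mean, y_mean = obj$y_mean,
                 coefficients = B),
            class = "chemocal")
}
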