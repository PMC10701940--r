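# Hand-entered 25-mixture concentration design (ug/mL) used as an
# independent regression fixture for the generator-built design.
reference_concentrations <- matrix(c(
  6, 20, 3, 0.60,  8, 4,
  6, 16, 1, 0.80,  6, 6,
  4, 16, 5, 0.50, 12, 4,
  4, 24, 2, 0.80,  8, 3,
  8, 18, 5, 0.60,  6, 3,
  5, 24, 3, 0.50,  6, 5,
  8, 20, 2, 0.50, 10, 6,
  6, 18, 2, 0.70, 12, 5,
  5, 18, 4, 0.80, 10, 4,
  5, 22, 5, 0.70,  8, 6,
  7, 24, 4, 0.60, 12, 6,
  8, 22, 3, 0.80, 12, 2,
  7, 20, 5, 0.80,  4, 5,
  6, 24, 5, 0.40, 10, 2,
  8, 24, 1, 0.70,  4, 4,
  8, 16, 4, 0.40,  8, 5,
  4, 22, 1, 0.60, 10, 5,
  7, 16, 3, 0.70, 10, 3,
  4, 20, 4, 0.70,  6, 2,
  6, 22, 4, 0.50,  4, 3,
  7, 22, 2, 0.40,  6, 4,
  7, 18, 1, 0.50,  8, 2,
  5, 16, 2, 0.60,  4, 2,
  4, 18, 3, 0.40,  4, 6,
  5, 20, 1, 0.40, 12, 3), nrow = 25, byrow = TRUE,
  dimnames = list(1:25, c("PAR", "HYO", "PNP", "PCA", "TRO", "PAP")))

reference_validation_ids <- c(5L, 8L, 10L, 11L, 14L, 15L, 17L, 22L)

# Small full-column-rank regression instance for least-squares oracles.
small_instance <- function(seed = 42, n = 12, p = 5, q = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(p * q), p, q)
  Y <- X %*% B + matrix(rnorm(n * q, 0, 0.05), n, q)
  list(X = X, Y = Y)
}

# Ordinary least squares on centred data: the oracle all latent-variable
# models must match at full rank.
ols_predictions <- function(X, Y, Xnew) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  B <- solve(crossprod(Xc), crossprod(Xc, Yc))
  sweep(sweep(Xnew, 2, xm) %*% B, 2, ym, `+`)
}

# Brute-force non-negative least squares by enumeration of all active sets.
brute_force_nnls <- function(Z, b) {
  p <- ncol(Z)
  best <- NULL; best_obj <- Inf
  for (mask in 0:(2^p - 1)) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))
    x <- numeric(p)
    if (any(on)) {
      sol <- tryCatch(qr.solve(Z[, on, drop = FALSE], b),
                      error = function(e) NULL)
      if (is.null(sol) || any(sol < 0)) next
      x[on] <- sol
    }
    obj <- sum((Z %*% x - b)^2)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- x }
  }
  list(x = best, objective = best_obj)
}
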