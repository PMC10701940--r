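#' @importFrom graphics plot points matplot legend
NULL

#' Fast non-negativity-constrained least squares
#'
#' Solves `min || Z x - b ||^2` subject to `x >= 0` by the active-set
#' algorithm of Bro and De Jong, which works on the Gram matrix `Z'Z` and
#' `Z'b` so repeated right-hand sides are cheap.  The returned solution
#' satisfies the Karush-Kuhn-Tucker conditions to the given tolerance.
#'
#' @param Z Design matrix (m x n).
#' @param b Target vector (length m).
#' @param tol Dual-feasibility tolerance (default 1e-10).
#' @return Non-negative solution vector of length n.
#' @export
#' @examples
#' fnnls(diag(3), c(1, -2, 3))   # c(1, 0, 3)
fnnls <- function(Z, b, tol = 1e-10) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z)) || !all(is.finite(b))) stop("inputs must be finite")
  fnnls_gram(crossprod(Z), crossprod(Z, b), tol)
}

# Bro & De Jong fnnls core on precomputed Z'Z and Z'b.
fnnls_gram <- function(ZtZ, Ztb, tol = 1e-10) {
  n <- ncol(ZtZ)
  P <- rep(FALSE, n)
  x <- numeric(n)
  w <- Ztb - ZtZ %*% x
  iter <- 0
  max_iter <- 30 * n
  while (any(!P) && max(w[!P]) > tol && iter < max_iter) {
    iter <- iter + 1
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- solve(ZtZ[P, P, drop = FALSE], Ztb[P])
      if (all(s[P] > tol)) break
      qs <- which(P & s <= tol)
      alpha <- min(x[qs] / (x[qs] - s[qs]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    x <- s
    w <- Ztb - ZtZ %*% x
  }
  x[x < 0] <- 0
  drop(x)
}

# Columnwise non-negative least squares min ||Z X - B||, X >= 0.
# Fast path: unconstrained solve first; fnnls only for columns that come
# out negative.  Falls back to a ridge-stabilised solve if Z'Z is singular
# (collapsed component).
nnls_columns <- function(Z, B, nonneg = TRUE) {
  ZtZ <- crossprod(Z)
  ZtB <- crossprod(Z, B)
  X <- tryCatch(solve(ZtZ, ZtB), error = function(e) {
    solve(ZtZ + diag(1e-12 * max(diag(ZtZ)), ncol(ZtZ)), ZtB)
  })
  if (!nonneg) return(X)
  bad <- which(apply(X < -1e-12, 2, any))
  for (j in bad) X[, j] <- fnnls_gram(ZtZ, ZtB[, j])
  X[X < 0] <- 0
  X
}

#' SIMPLISMA initial spectral estimates
#'
#' Selects the n purest wavelengths of a mixture data matrix by the
#' SIMPLISMA purity criterion.  The first purity of channel j is
#' `sigma_j / (mu_j + alpha)` with `alpha = noise_allowance * max(mu)`;
#' subsequent selections are weighted by the determinant of the
#' correlation-around-origin submatrix of the already-selected channels,
#' which suppresses channels collinear with earlier picks.  The initial
#' spectral profiles are the least-squares spectra obtained by regressing
#' the data on the intensity vectors at the selected channels (negative
#' entries clipped to zero).
#'
#' @param A Mixture spectra: `spectra_matrix` or n x p matrix.
#' @param n_components Number of components to extract.
#' @param noise_allowance Noise-offset fraction alpha (default 0.05, i.e.
#'   5 percent of the largest channel mean).
#' @return List with `S0` (p x n_components initial spectra), `wavelengths`
#'   (selected channels, nm), `indices` and `purity` (first-pass purity
#'   spectrum).
#' @export
simplisma <- function(A, n_components, noise_allowance = 0.05) {
  A <- absorbance_matrix(A)
  if (n_components > min(dim(A)))
    stop("n_components exceeds min(n_samples, n_wavelengths)")
  mu <- colMeans(A)
  sg <- sqrt(colMeans(sweep(A, 2, mu)^2))
  if (max(sg) == 0 || max(mu) == 0)
    stop("degenerate data matrix: no spectral variation")
  alpha <- noise_allowance * max(mu)
  purity1 <- sg / (mu + alpha)
  Zs <- sweep(A, 2, sqrt(mu^2 + (sg + alpha)^2), `/`) / sqrt(nrow(A))
  COO <- crossprod(Zs)
  sel <- integer(0)
  for (s in seq_len(n_components)) {
    wdet <- vapply(seq_along(mu), function(j) {
      det(COO[c(j, sel), c(j, sel), drop = FALSE])
    }, numeric(1))
    p <- wdet * purity1
    if (length(sel)) p[sel] <- -Inf
    sel <- c(sel, which.max(p))
  }
  W <- A[, sel, drop = FALSE]
  S0 <- t(qr.solve(W, A))
  S0[S0 < 0] <- 0
  grid <- wavelength_grid()
  wl <- if (ncol(A) == length(grid)) grid[sel] else sel
  list(S0 = S0, wavelengths = wl, indices = sel, purity = purity1)
}

#' Multivariate curve resolution by alternating least squares
#'
#' Decomposes a mixture spectra matrix as `A = C S' + E` with non-negative
#' concentration profiles `C` (n x k) and spectral profiles `S` (p x k).
#' Each iteration solves the two conditional least-squares problems with
#' the fast non-negative least squares solver ([fnnls]), then rescales the
#' columns of `S` to unit Euclidean norm (moving the scale into `C`) to fix
#' the bilinear scale ambiguity.  Iteration stops when the relative change
#' in the percent lack of fit,
#' `lof = 100 * sqrt(sum(E^2) / sum(A^2))`,
#' falls below `tol`, when the fit is exact, or at `max_iter`.  The
#' explained variance is reported as `r2 = 100 * (1 - (lof/100)^2)`.
#'
#' @param A Mixture spectra: `spectra_matrix` or n x p matrix.
#' @param n_components Number of components (default 6).
#' @param S0 Initial spectral profiles (p x k); default SIMPLISMA
#'   estimates with 5 percent noise allowance.
#' @param nonneg_C,nonneg_S Toggle the non-negativity constraint on each
#'   profile matrix (both default `TRUE`).
#' @param tol Relative lack-of-fit change threshold (default 0.001, the
#'   usual 0.1 percent rule).
#' @param max_iter Iteration cap (default 100).
#' @param noise_allowance Passed to [simplisma()] when `S0` is missing.
#' @return Object of class `mcr_als`: `C`, `S`, `residuals`, `lof_percent`,
#'   `r2_percent`, `lof_history`, `n_iterations`, `converged`, `collapsed`.
#' @export
#' @examples
#' d <- default_design()
#' sp <- simulate_spectra(d, noise_sd = 0, seed = 1)
#' dec <- mcr_als(sp, n_components = 6)
#' dec
mcr_als <- function(A, n_components = 6, S0 = NULL,
                    nonneg_C = TRUE, nonneg_S = TRUE,
                    tol = 0.001, max_iter = 100, noise_allowance = 0.05) {
  A <- absorbance_matrix(A)
  if (tol <= 0) stop("tol must be positive")
  if (n_components < 1) stop("n_components must be >= 1")
  if (is.null(S0)) S0 <- simplisma(A, n_components, noise_allowance)$S0
  S0 <- as.matrix(S0)
  if (ncol(S0) != n_components)
    stop("S0 must have n_components = ", n_components, " columns")
  ssA <- sum(A^2)
  S <- S0
  lof_prev <- Inf
  lof_history <- numeric(0)
  converged <- FALSE
  Cm <- NULL
  for (it in seq_len(max_iter)) {
    Cm <- t(nnls_columns(S, t(A), nonneg = nonneg_C))
    S <- t(nnls_columns(Cm, A, nonneg = nonneg_S))
    nrm <- sqrt(colSums(S^2))
    zero <- nrm == 0
    nrm[zero] <- 1
    S <- sweep(S, 2, nrm, `/`)
    Cm <- sweep(Cm, 2, nrm, `*`)
    E <- A - tcrossprod(Cm, S)
    lof <- 100 * sqrt(sum(E^2) / ssA)
    lof_history <- c(lof_history, lof)
    if (lof == 0 ||
        (is.finite(lof_prev) && abs(lof - lof_prev) / lof_prev < tol)) {
      converged <- TRUE
      break
    }
    lof_prev <- lof
  }
  collapsed <- any(colSums(S) == 0) || any(colSums(abs(Cm)) == 0)
  if (collapsed)
    warning("component collapse: a concentration or spectral profile is identically zero")
  out <- list(C = Cm, S = S, residuals = E,
              lof_percent = lof,
              r2_percent = 100 * (1 - (lof / 100)^2),
              lof_history = lof_history,
              n_iterations = length(lof_history),
              converged = converged, collapsed = collapsed,
              n_components = n_components)
  class(out) <- "mcr_als"
  out
}

#' @export
print.mcr_als <- function(x, ...) {
  cat(sprintf("MCR-ALS decomposition: %d components, %d iterations%s\n",
              x$n_components, x$n_iterations,
              if (x$converged) " (converged)" else ""))
  cat(sprintf("  lack of fit %.4g %%, explained variance %.6g %%\n",
              x$lof_percent, x$r2_percent))
  if (x$collapsed) cat("  WARNING: collapsed component present\n")
  invisible(x)
}

#' @export
plot.mcr_als <- function(x, ...) {
  matplot(wavelength_grid()[seq_len(nrow(x$S))], x$S, type = "l", lty = 1,
          xlab = "Wavelength (nm)", ylab = "Resolved spectral profile",
          main = "MCR-ALS resolved spectra", ...)
  invisible(x)
}

#' Quantify analytes from resolved MCR-ALS profiles
#'
#' The decomposition is computed on the augmented matrix (calibration and
#' unknown samples together).  Components are aligned to analytes by
#' maximum absolute correlation between the resolved concentration
#' profiles (calibration rows) and the known concentrations; each analyte
#' then gets a pseudo-univariate straight line (resolved value vs known
#' concentration, least squares on the calibration rows), which is
#' inverted to predict the unknown rows.
#'
#' @param decomposition An [mcr_als()] fit of the augmented matrix.
#' @param cal_ids Row indices of the calibration samples.
#' @param Y_cal Known calibration concentrations (length(cal_ids) x q).
#' @return List with `assignment` (component index per analyte), `lines`
#'   (per-analyte slope/intercept/r), `predictions` (all rows x q) and
#'   `unknown_ids`.
#' @export
mcr_quantify <- function(decomposition, cal_ids, Y_cal) {
  Cm <- decomposition$C
  Y_cal <- as.matrix(Y_cal)
  if (length(cal_ids) != nrow(Y_cal))
    stop("cal_ids and Y_cal disagree in length")
  cc <- cor(Cm[cal_ids, , drop = FALSE], Y_cal)
  assignment <- apply(abs(cc), 2, which.max)
  if (anyDuplicated(assignment))
    stop("ambiguous alignment: two analytes map to the same resolved component")
  q <- ncol(Y_cal)
  lines <- data.frame(analyte = colnames(Y_cal), slope = NA_real_,
                      intercept = NA_real_, r = NA_real_)
  pred <- matrix(NA_real_, nrow(Cm), q,
                 dimnames = list(NULL, colnames(Y_cal)))
  for (k in seq_len(q)) {
    resolved <- Cm[, assignment[k]]
    fit <- lm(resolved[cal_ids] ~ Y_cal[, k])
    a <- coef(fit)[1]; b <- coef(fit)[2]
    lines$slope[k] <- b
    lines$intercept[k] <- a
    lines$r[k] <- cor(resolved[cal_ids], Y_cal[, k])
    pred[, k] <- (resolved - a) / b
  }
  unknown <- setdiff(seq_len(nrow(Cm)), cal_ids)
  list(assignment = assignment, lines = lines, predictions = pred,
       unknown_ids = unknown)
}

#' Align resolved components to reference spectra
#'
#' Best-correlation assignment between resolved and reference spectral
#' profiles; used to assess rotational/permutation ambiguity.
#'
#' @param S_resolved,S_reference p x k spectral matrices.
#' @return List with `order` (reference column matched by each resolved
#'   column position: `order[k]` is the resolved column assigned to
#'   reference k) and `correlation` (per reference column, absolute).
#' @export
align_components <- function(S_resolved, S_reference) {
  cc <- abs(cor(S_resolved, S_reference))
  k <- ncol(S_reference)
  ord <- integer(k)
  work <- cc
  # greedy best-pair assignment: take the global best remaining pair
  for (step in seq_len(k)) {
    best <- which(work == max(work), arr.ind = TRUE)[1, ]
    ord[best[2]] <- best[1]
    work[best[1], ] <- -Inf
    work[, best[2]] <- -Inf
  }
  cc2 <- cc
  list(order = ord,
       correlation = vapply(seq_len(k), function(j) cc2[ord[j], j], 0))
}
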