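#' Principal component analysis with varimax rotation and regression scores
#'
#' Correlation-matrix PCA; components with eigenvalue strictly greater
#' than `eigen_threshold` are retained and varimax-rotated (normalized
#' rotation, i.e. Kaiser row normalization). Factor scores are computed by
#' the regression method: standardized data times `solve(R) %*% L`, with
#' `R` the correlation matrix and `L` the rotated loadings. Loadings with
#' absolute value above `loading_threshold` are flagged as salient.
#' Component signs are fixed so the largest-magnitude loading of each
#' component is positive.
#'
#' @param x Numeric matrix or data frame (participants x variables).
#' @param eigen_threshold Retain components with eigenvalue `>` this
#'   (default 1, the Kaiser criterion; the bound is strict).
#' @param loading_threshold Salience threshold for loadings (default 0.6).
#' @return Object of class `pca_varimax`: list with `eigenvalues`,
#'   `n_retained`, `loadings` (unrotated), `rotated` (varimax loadings),
#'   `rotation_matrix`, `variance_explained` (per rotated component,
#'   proportion of total variance), `scores` (regression-method factor
#'   scores), `salient` (logical matrix), `communalities`,
#'   `loading_threshold`.
#' @export
pca_varimax <- function(x, eigen_threshold = 1, loading_threshold = 0.6) {
  X <- as.matrix(x)
  if (ncol(X) < 2L) stop("need at least 2 variables")
  keep <- complete.cases(X)
  X <- X[keep, , drop = FALSE]
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (nrow(X) <= ncol(X))
    warning("fewer observations than variables + 1; PCA is unstable")
  R <- cor(X)
  ei <- eigen(R, symmetric = TRUE)
  ev <- ei$values
  m <- sum(ev > eigen_threshold)
  if (m < 1L) m <- 1L
  L <- ei$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(m)]), m)
  dimnames(L) <- list(colnames(X), paste0("RC", seq_len(m)))
  if (m > 1L) {
    vm <- stats::varimax(L, normalize = TRUE)
    Lr <- L %*% vm$rotmat
    rot <- vm$rotmat
    # order rotated components by explained variance, descending
    ord <- order(colSums(Lr^2), decreasing = TRUE)
    Lr <- Lr[, ord, drop = FALSE]
    rot <- rot[, ord, drop = FALSE]
  } else {
    Lr <- L
    rot <- diag(1)
  }
  # deterministic sign: dominant loading positive
  sgn <- apply(Lr, 2L, function(v) sign(v[which.max(abs(v))]))
  sgn[sgn == 0] <- 1
  Lr <- sweep(Lr, 2L, sgn, "*")
  rot <- sweep(rot, 2L, sgn, "*")
  colnames(Lr) <- paste0("RC", seq_len(m))
  Z <- scale(X)
  # regression-method weights; pseudo-inverse when R is singular (n <= p)
  W <- tryCatch(solve(R, Lr), error = function(e) {
    ok <- ev > max(ev) * 1e-10
    ei$vectors[, ok, drop = FALSE] %*%
      (crossprod(ei$vectors[, ok, drop = FALSE], Lr) / ev[ok])
  })
  scores <- Z %*% W
  colnames(scores) <- colnames(Lr)
  structure(list(
    eigenvalues = ev,
    n_retained = m,
    loadings = L,
    rotated = Lr,
    rotation_matrix = rot,
    variance_explained = colSums(Lr^2) / ncol(X),
    scores = scores,
    salient = abs(Lr) > loading_threshold,
    communalities = rowSums(Lr^2),
    loading_threshold = loading_threshold),
    class = "pca_varimax")
}

#' @export
print.pca_varimax <- function(x, ...) {
  cat("PCA (correlation matrix):", x$n_retained, "component(s) retained;",
      sprintf("%.0f%% of variance explained\n",
              100 * sum(x$variance_explained)))
  print(round(x$rotated, 2))
  invisible(x)
}
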