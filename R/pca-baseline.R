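#' Gram-matrix PCA with features embedded
#'
#' In contrast to the usual PCA over samples, the features are embedded:
#' scores \eqn{u_k} are eigenvectors of the gram matrix
#' \eqn{G = XX^T} (one entry per feature), eigenvalues are ordered
#' non-increasingly, and loadings are the sample-space images
#' \eqn{v_k = X^T u_k}, eigenvectors of the covariance matrix
#' \eqn{X^T X} with \eqn{\|v_k\|^2 = \lambda_k}.
#'
#' Computed through the SVD of `X` rather than an explicit `N x N`
#' eigendecomposition, for stability and memory; the two agree because
#' the left singular vectors of `X` are the eigenvectors of \eqn{XX^T}
#' with eigenvalues the squared singular values. The sign convention of
#' [hosvd()] (largest-magnitude score entry positive) is applied.
#'
#' @param X a [ViewMatrix-class] (or matrix), normally standardized with
#'   [standardizeView()] first.
#' @param nComponents number of components, at most `min(N, M)`.
#'
#' @return A [PCAResult-class].
#' @export
pcaDecompose <- function(X, nComponents = NULL) {
  if (is(X, "ViewMatrix")) X <- X@values
  X <- as.matrix(X)
  kmax <- min(dim(X))
  if (is.null(nComponents)) nComponents <- min(10L, kmax)
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L || nComponents > kmax)
    stop("'nComponents' must be in 1..min(N, M) = ", kmax)
  s <- svd(X, nu = nComponents, nv = 0)
  u <- .fixSigns(s$u)
  lambda <- s$d[seq_len(nComponents)]^2
  v <- crossprod(X, u)                       # v_k = X^T u_k
  cn <- paste0("comp", seq_len(nComponents))
  dimnames(u) <- list(rownames(X), cn)
  dimnames(v) <- list(colnames(X), cn)
  new("PCAResult", scores = u, loadings = v, eigenvalues = lambda)
}

#' PCA-based unsupervised feature extraction
#'
#' The matrix-based baseline: gram-matrix PCA on one view, an optional
#' screen that keeps only components whose loadings show significant
#' sample-class dependence (categorical regression, P < `screenAlpha`),
#' then chi-squared/BH outlier selection on the surviving score columns
#' via [selectOutliers()].
#'
#' @param X a [ViewMatrix-class] or matrix; standardized per
#'   [standardizeView()] conventions by the caller.
#' @param screenLabels optional class label per sample; when given,
#'   components whose loadings fail the categorical-regression screen are
#'   dropped before selection.
#' @param components candidate component indices (default 1..5).
#' @param alpha BH threshold for selection (default 0.01).
#' @param screenAlpha screen threshold on the loading regression
#'   (default 0.05).
#'
#' @return A [SelectionResult-class]. When the screen removes every
#'   component the result is explicitly empty: no feature selected and
#'   `components` of length zero.
#' @export
pcaUnsupervisedFE <- function(X, screenLabels = NULL,
                              components = seq_len(5L), alpha = 0.01,
                              screenAlpha = 0.05) {
  if (is(X, "ViewMatrix")) X <- X@values
  X <- as.matrix(X)
  components <- as.integer(components)
  res <- pcaDecompose(X, nComponents = max(components))
  keep <- components
  if (!is.null(screenLabels)) {
    pass <- vapply(components, function(k)
      categoricalRegressionTest(res@loadings[, k], screenLabels)$p <
        screenAlpha, logical(1))
    keep <- components[pass]
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(X)))
  if (length(keep) == 0L) {
    tab <- data.frame(feature_id = ids, score = NA_real_, df = 0L,
                      p = NA_real_, p_adj = NA_real_, selected = FALSE,
                      stringsAsFactors = FALSE)
    return(new("SelectionResult", table = tab, alpha = alpha,
               components = integer(0)))
  }
  selectOutliers(res@scores, components = keep, alpha = alpha,
                 featureIds = ids)
}
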