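#' Chi-squared outlier scores and P-values on factor columns
#'
#' Each feature is scored by summing its squared standardized entries over
#' the chosen singular-value-vector (or PC-score) columns,
#' \deqn{s_i = \sum_{\ell} \left(\frac{u_{\ell i}}{\sigma_\ell}\right)^2,}
#' where \eqn{\sigma_\ell} is the standard deviation of column \eqn{\ell}
#' over all features. Under the null that a column's entries are Gaussian,
#' \eqn{s_i} follows a chi-squared distribution with as many degrees of
#' freedom as there are columns, and the reported P-value is its upper
#' tail at \eqn{s_i}. \eqn{\sigma_\ell} is computed about the column mean
#' with denominator `n - 1`; singular value vectors are near zero-mean
#' unit-norm, so this is numerically indistinguishable from the
#' uncentered convention.
#'
#' @param U numeric matrix, features in rows, components in columns (a
#'   factor matrix from [hosvd()] or scores from [pcaDecompose()]).
#' @param components indices of the columns to use (default: first 5 or
#'   all, whichever is smaller).
#'
#' @return A list with `score`, `p` (raw upper-tail P, exact zeros coded
#'   as the smallest positive double so BH stays well-defined), and `df`.
#' @seealso [selectOutliers()]
#' @export
chi2Pvalues <- function(U, components = seq_len(min(5L, ncol(U)))) {
  U <- as.matrix(U)
  components <- as.integer(components)
  if (length(components) == 0L)
    stop("'components' must name at least one column")
  if (any(components < 1L) || any(components > ncol(U)))
    stop("'components' out of range 1..", ncol(U))
  V <- U[, components, drop = FALSE]
  sigma <- apply(V, 2L, stats::sd)
  if (any(sigma <= 0))
    stop("zero-variance factor column(s): ",
         paste(components[sigma <= 0], collapse = ", "))
  score <- rowSums(sweep(V, 2L, sigma, "/")^2)
  p <- stats::pchisq(score, df = length(components), lower.tail = FALSE)
  p[p == 0] <- .Machine$double.xmin
  list(score = score, p = p, df = length(components))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order and
#' capped at 1. Thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of raw P-values in `[0, 1]`.
#' @return Adjusted P-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("'p' must be numeric P-values in [0, 1] without NAs")
  stats::p.adjust(p, method = "BH")
}

#' Select chi-squared outlier features
#'
#' Runs [chi2Pvalues()] on the chosen components, applies [bhAdjust()],
#' and flags features with adjusted P below `alpha` (default 0.01). This
#' is the unsupervised feature-extraction step: features whose factor
#' entries are too large to be Gaussian noise are the ones driving the
#' selected singular value vectors.
#'
#' @inheritParams chi2Pvalues
#' @param alpha BH-adjusted P-value threshold in `(0, 1]`.
#' @param featureIds optional feature IDs; defaults to `rownames(U)` or
#'   `f1, f2, ...`.
#'
#' @return A [SelectionResult-class].
#' @examples
#' U <- matrix(rnorm(400), 200, 2)
#' U[1:5, ] <- 6           # planted outliers
#' selectedFeatures(selectOutliers(U, 1:2))
#' @export
selectOutliers <- function(U, components = seq_len(min(5L, ncol(U))),
                           alpha = 0.01, featureIds = rownames(U)) {
  U <- as.matrix(U)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must be a single value in (0, 1]")
  if (is.null(featureIds)) featureIds <- paste0("f", seq_len(nrow(U)))
  ch <- chi2Pvalues(U, components)
  padj <- bhAdjust(ch$p)
  tab <- data.frame(feature_id = as.character(featureIds),
                    score = ch$score, df = ch$df, p = ch$p, p_adj = padj,
                    selected = padj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  new("SelectionResult", table = tab, alpha = alpha,
      components = as.integer(components))
}

#' Intersect selections across runs
#'
#' IDs of the features selected in every one of the given results, e.g.
#' features extracted independently from several views or sample groups.
#'
#' @param results a list of [SelectionResult-class] objects (a single
#'   result is also accepted).
#' @return Character vector of feature IDs.
#' @export
intersectSelections <- function(results) {
  if (is(results, "SelectionResult")) results <- list(results)
  if (length(results) < 1L) stop("need at least one SelectionResult")
  sets <- lapply(results, selectedFeatures)
  Reduce(intersect, sets)
}
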