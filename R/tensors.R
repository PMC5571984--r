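#' Standardize a view per sample column
#'
#' Centers and rescales every sample column so that
#' \eqn{\sum_i x_{ij} = 0} and \eqn{\sum_i x_{ij}^2 = N} (the number of
#' features). This is the conventional preprocessing for expression
#' profiles before decomposition; it is equivalent to requiring zero mean
#' and unit mean square per column. Idempotent.
#'
#' @param X a [ViewMatrix-class] (or plain matrix with dimnames).
#'
#' @return A [ViewMatrix-class] with standardized values.
#' @examples
#' vm <- ViewMatrix(cbind(a = c(0, 2), b = c(1, -1)),
#'                  featureIds = c("f1", "f2"))
#' viewValues(standardizeView(vm))
#' @export
standardizeView <- function(X) {
  if (!is(X, "ViewMatrix")) X <- ViewMatrix(as.matrix(X))
  v <- X@values
  n <- nrow(v)
  mu <- colMeans(v)
  centered <- sweep(v, 2L, mu)
  ss <- colSums(centered^2)
  bad <- ss <= 0
  if (any(bad))
    stop("cannot standardize constant sample column(s): ",
         paste(colnames(v)[bad], collapse = ", "))
  out <- sweep(centered, 2L, sqrt(ss / n), "/")
  dimnames(out) <- dimnames(v)
  new("ViewMatrix", values = out, name = X@name)
}

## Orient views so the shared axis is always the column axis: Case I views
## are used as stored (features x shared samples); Case II views are
## transposed (samples x shared features).
.sharedAsColumns <- function(set) {
  if (set@case == "shared_samples") {
    list(mats = lapply(set@views, function(v) v@values),
         modeIds = lapply(set@views, function(v) rownames(v@values)),
         sharedIds = colnames(set@views[[1L]]@values),
         sharedLabel = "sample")
  } else {
    list(mats = lapply(set@views, function(v) t(v@values)),
         modeIds = lapply(set@views, function(v) colnames(v@values)),
         sharedIds = rownames(set@views[[1L]]@values),
         sharedLabel = "feature")
  }
}

#' Build a Type I product tensor
#'
#' For `m` views sharing their samples (Case I), the Type I tensor is the
#' `(m+1)`-mode array of entry-wise products
#' \deqn{x_{i_1,\dots,i_m,j} = \prod_k x^{(k)}_{i_k, j},}
#' with the shared (sample) mode last. Case II swaps the roles of features
#' and samples. Each new entry combines exactly one feature from each view,
#' so no cross-view weighting is needed.
#'
#' Storage is dense and grows as the product of the per-view mode sizes
#' times the shared-mode size; `elementCap` guards against accidental
#' memory exhaustion and the error recommends the Type II tensor, which
#' contracts the shared mode away.
#'
#' @param set a [MultiViewSet-class].
#' @param elementCap maximum number of tensor elements (default `2e8`).
#'
#' @return A [MultiwayArray-class] with `tensorType = "type1"`.
#' @seealso [buildTypeIITensor()]
#' @examples
#' s <- MultiViewSet(list(A = matrix(1:2, 1, 2, dimnames = list("f", c("s1","s2"))),
#'                        B = matrix(3:4, 1, 2, dimnames = list("f", c("s1","s2")))))
#' tensorValues(buildTypeITensor(s))
#' @export
buildTypeITensor <- function(set, elementCap = 2e8) {
  stopifnot(is(set, "MultiViewSet"))
  or <- .sharedAsColumns(set)
  sizes <- vapply(or$mats, nrow, integer(1))
  M <- length(or$sharedIds)
  nElem <- prod(c(as.double(sizes), M))
  if (nElem > elementCap)
    stop("Type I tensor would hold ", format(nElem, scientific = TRUE),
         " elements (cap ", format(elementCap, scientific = TRUE),
         "); consider the Type II tensor (buildTypeIITensor), which sums ",
         "over the shared mode")
  flat <- matrix(0, prod(sizes), M)
  for (j in seq_len(M)) {
    cols <- lapply(or$mats, function(m) m[, j])
    flat[, j] <- as.vector(Reduce(outer, cols))
  }
  arr <- array(flat, dim = c(sizes, M),
               dimnames = c(or$modeIds, list(or$sharedIds)))
  new("MultiwayArray", data = arr,
      modeLabels = c(vapply(set@views, viewName, character(1)),
                     or$sharedLabel),
      tensorType = "type1", case = set@case)
}

#' Build a Type II product tensor
#'
#' The Type II tensor contracts the Type I tensor over the shared mode:
#' \deqn{\tilde x_{i_1,\dots,i_m} = \sum_j \prod_k x^{(k)}_{i_k, j}}
#' (Case I; Case II sums over the shared features instead). It has one mode
#' per view and needs a factor `1/M` (Case I) less memory than Type I. For
#' two views in Case I it equals the matrix product
#' \eqn{X^{(1)} (X^{(2)})^T}. The Type I tensor is never materialized.
#'
#' @inheritParams buildTypeITensor
#' @return A [MultiwayArray-class] with `tensorType = "type2"`.
#' @examples
#' s <- MultiViewSet(list(A = matrix(1:2, 1, 2, dimnames = list("f", c("s1","s2"))),
#'                        B = matrix(3:4, 1, 2, dimnames = list("f", c("s1","s2")))))
#' tensorValues(buildTypeIITensor(s))   # 1*3 + 2*4 = 11
#' @export
buildTypeIITensor <- function(set) {
  stopifnot(is(set, "MultiViewSet"))
  or <- .sharedAsColumns(set)
  sizes <- vapply(or$mats, nrow, integer(1))
  m <- length(or$mats)
  if (m == 2L) {
    arr <- or$mats[[1L]] %*% t(or$mats[[2L]])
    dim(arr) <- sizes
  } else {
    acc <- numeric(prod(sizes))
    for (j in seq_along(or$sharedIds)) {
      cols <- lapply(or$mats, function(mm) mm[, j])
      acc <- acc + as.vector(Reduce(outer, cols))
    }
    arr <- array(acc, dim = sizes)
  }
  dimnames(arr) <- or$modeIds
  new("MultiwayArray", data = arr,
      modeLabels = vapply(set@views, viewName, character(1)),
      tensorType = "type2", case = set@case)
}
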