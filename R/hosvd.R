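#' Mode-k unfolding of a tensor
#'
#' Matricizes a dense array with the mode-`k` fibers as rows and the
#' remaining modes in cyclic order `k+1, ..., m, 1, ..., k-1` along the
#' columns. The convention is fixed and is the one under which the
#' reconstruction identity of [hosvd()] is verified.
#'
#' @param a dense numeric array (or [MultiwayArray-class]).
#' @param mode mode index, 1-based.
#'
#' @return A matrix with `dim(a)[mode]` rows.
#' @export
unfoldTensor <- function(a, mode) {
  if (is(a, "MultiwayArray")) a <- a@data
  d <- dim(a)
  m <- length(d)
  if (mode < 1L || mode > m) stop("'mode' must be in 1..", m)
  perm <- c(mode, setdiff(seq_len(m), mode)[
    order((setdiff(seq_len(m), mode) - mode) %% m)])
  matrix(aperm(a, perm), nrow = d[mode])
}

## n-mode (tensor x matrix) product along 'mode'; M is r x d[mode]
.modeProduct <- function(a, M, mode) {
  d <- dim(a)
  m <- length(d)
  others <- seq_len(m)[-mode]
  perm <- c(mode, others)
  u <- matrix(aperm(a, perm), nrow = d[mode])
  arr <- array(M %*% u, dim = c(nrow(M), d[others]))
  aperm(arr, order(perm))
}

## Deterministic sign convention: the entry of largest absolute value in
## each column is made positive (ties broken by the first such index).
.fixSigns <- function(U) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  U
}

## Leading left singular vectors of A, economical for wide unfoldings.
.leadingLSV <- function(A, rank) {
  if (ncol(A) > max(4L * nrow(A), 512L)) {
    # wide: work with the n x n gram matrix instead of the full SVD
    es <- eigen(tcrossprod(A), symmetric = TRUE)
    es$vectors[, seq_len(rank), drop = FALSE]
  } else {
    svd(A, nu = rank, nv = 0)$u
  }
}

#' Higher-order singular value decomposition
#'
#' Plain HOSVD (no iterative refinement): each mode's factor matrix holds
#' the leading left singular vectors of that mode's unfolding, and the
#' core is the tensor contracted with every transposed factor,
#' \deqn{G = T \times_1 U_1^T \times_2 U_2^T \cdots \times_m U_m^T.}
#' At full ranks the factors reconstruct the tensor exactly and
#' \eqn{\|G\|_F = \|T\|_F}; with truncation \eqn{\|G\|_F \le \|T\|_F}.
#' Components within each mode are ordered by decreasing mode singular
#' value, and a deterministic sign convention (largest-magnitude entry of
#' each factor column made positive) keeps results reproducible.
#'
#' For a 2-mode tensor this is the ordinary SVD (factors equal the left
#' and right singular vectors, the core is diagonal up to the sign
#' convention).
#'
#' @param x a [MultiwayArray-class] or a plain dense array.
#' @param ranks per-mode truncation ranks; a single value is recycled.
#'   Defaults to `min(10, mode size)` per mode. Must not exceed the mode
#'   sizes.
#'
#' @return An [HOSVDResult-class].
#' @examples
#' a <- array(rnorm(24), c(2, 3, 4))
#' h <- hosvd(a)
#' norm(coreTensor(h), "F") - sqrt(sum(a^2))  # ~0 at full ranks
#' @export
setGeneric("hosvd", function(x, ranks = NULL) standardGeneric("hosvd"))

#' @rdname hosvd
setMethod("hosvd", "array", function(x, ranks = NULL) {
  ma <- new("MultiwayArray", data = x,
            modeLabels = paste0("mode", seq_along(dim(x))),
            tensorType = "type2", case = "shared_samples")
  hosvd(ma, ranks = ranks)
})

#' @rdname hosvd
setMethod("hosvd", "MultiwayArray", function(x, ranks = NULL) {
  d <- dim(x@data)
  m <- length(d)
  if (is.null(ranks)) ranks <- pmin(10L, d)
  if (length(ranks) == 1L) ranks <- rep(ranks, m)
  ranks <- as.integer(ranks)
  if (length(ranks) != m)
    stop("'ranks' must have one entry per mode (", m, ")")
  if (any(ranks < 1L) || any(ranks > d))
    stop("each rank must be a positive integer not exceeding its mode ",
         "size (", paste(d, collapse = ", "), ")")
  factors <- vector("list", m)
  for (k in seq_len(m)) {
    U <- .fixSigns(.leadingLSV(unfoldTensor(x@data, k), ranks[k]))
    dimnames(U) <- list(dimnames(x@data)[[k]],
                        paste0("comp", seq_len(ranks[k])))
    factors[[k]] <- U
  }
  core <- x@data
  for (k in seq_len(m)) core <- .modeProduct(core, t(factors[[k]]), k)
  new("HOSVDResult", core = core, factors = factors, ranks = ranks,
      modeLabels = x@modeLabels, tensorType = x@tensorType, case = x@case)
})

#' Reconstruct a tensor from an HOSVD
#'
#' Multiplies the core back through every factor matrix. At full ranks this
#' reproduces the decomposed tensor to numerical precision.
#'
#' @param res an [HOSVDResult-class].
#' @return A dense array of the original dimensions.
#' @export
reconstructTensor <- function(res) {
  stopifnot(is(res, "HOSVDResult"))
  out <- res@core
  for (k in seq_along(res@factors))
    out <- .modeProduct(out, res@factors[[k]], k)
  out
}

#' Rank core-tensor entries by absolute value
#'
#' Core entries \eqn{G(\ell_1, \dots, \ell_m)} with larger absolute value
#' couple their singular value vectors more strongly, so the top-ranked
#' entries identify which per-mode components belong together across
#' views. Ties are broken by lexicographic index order and indices are
#' reported 1-based.
#'
#' @param res an [HOSVDResult-class].
#' @param topN number of entries to report (clipped to the core size).
#'
#' @return A data.frame with one index column per mode (named after the
#'   mode labels), a `value` column, and a `rank` column, sorted by
#'   decreasing `|value|`.
#' @export
rankCore <- function(res, topN = 10L) {
  stopifnot(is(res, "HOSVDResult"))
  topN <- max(1L, as.integer(topN))
  vals <- as.vector(res@core)
  idx <- arrayInd(seq_along(vals), dim(res@core))
  ord <- do.call(order,
                 c(list(-abs(vals)),
                   lapply(seq_len(ncol(idx)), function(k) idx[, k])))
  keep <- ord[seq_len(min(topN, length(vals)))]
  out <- as.data.frame(idx[keep, , drop = FALSE])
  colnames(out) <- paste0("l_", res@modeLabels)
  out$value <- vals[keep]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Project singular value vectors onto the missing mode of a Type II tensor
#'
#' A Type II tensor lacks the shared mode, so the HOSVD yields no factor
#' for it. Each view `k` nevertheless induces shared-mode singular value
#' vectors by projecting its factor through its own data:
#' \deqn{\tilde x^{(k)}_{\ell, j} = \sum_{i} \tilde x^{(k)}_{\ell, i}\,
#'   x^{(k)}_{i, j}} (Case I; Case II swaps the feature and sample roles).
#' This yields `m` sets of sample (Case I) or feature (Case II) vectors,
#' one per view, whose cross-view correlations expose latent
#' correspondence between the views.
#'
#' @param res an [HOSVDResult-class] obtained from a Type II tensor of
#'   `set`.
#' @param set the [MultiViewSet-class] the tensor was built from.
#'
#' @return A [ProjectedVectors-class] holding, per view, a
#'   components-by-shared-index matrix.
#' @export
projectMissingMode <- function(res, set) {
  stopifnot(is(res, "HOSVDResult"), is(set, "MultiViewSet"))
  if (res@tensorType != "type2")
    stop("missing-mode projection applies to Type II tensors only; a ",
         "Type I tensor already carries the shared-mode factor")
  if (res@case != set@case)
    stop("'res' and 'set' disagree on the multi-view case")
  if (length(res@factors) != length(set@views))
    stop("number of factors does not match the number of views")
  or <- .sharedAsColumns(set)
  vectors <- vector("list", length(set@views))
  for (k in seq_along(set@views)) {
    U <- res@factors[[k]]
    Xk <- or$mats[[k]]                 # non-shared x shared
    if (nrow(U) != nrow(Xk))
      stop("factor for mode ", k, " does not match view '",
           viewName(set@views[[k]]), "'")
    P <- t(U) %*% Xk                   # components x shared
    rownames(P) <- colnames(U)
    colnames(P) <- or$sharedIds
    vectors[[k]] <- P
  }
  names(vectors) <- vapply(set@views, viewName, character(1))
  new("ProjectedVectors", vectors = vectors, case = set@case,
      derivation = paste0("per-view factor projected through its view (",
                          or$sharedLabel, " mode)"))
}
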