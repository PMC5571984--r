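#' @import methods
NULL

#' ViewMatrix: one view of a multi-view dataset
#'
#' A `ViewMatrix` holds a single data modality (a "view", e.g. mRNA or
#' miRNA expression) as a numeric features-by-samples matrix together with
#' unique feature and sample identifiers and a view name. All entries must
#' be finite; identity is carried by IDs, never by position.
#'
#' @slot values numeric matrix, features in rows and samples in columns;
#'   the dimnames hold the feature and sample IDs.
#' @slot name single string naming the view.
#'
#' @seealso [ViewMatrix()] for the constructor, [standardizeView()],
#'   [MultiViewSet-class]
#' @aliases ViewMatrix-class
#' @exportClass ViewMatrix
setClass("ViewMatrix",
         representation(values = "matrix", name = "character"))

setValidity("ViewMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v))
    return("'values' must be a numeric matrix")
  if (any(!is.finite(v)))
    return("'values' must not contain missing or non-finite entries")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("'values' must carry feature IDs (rownames) and sample IDs (colnames)")
  if (anyDuplicated(rownames(v)))
    return("feature IDs must be unique")
  if (anyDuplicated(colnames(v)))
    return("sample IDs must be unique")
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  TRUE
})

#' Construct a ViewMatrix
#'
#' @param values numeric matrix (features x samples).
#' @param featureIds character vector of unique feature IDs; defaults to
#'   `rownames(values)`.
#' @param sampleIds character vector of unique sample IDs; defaults to
#'   `colnames(values)`.
#' @param name name of the view (single string).
#'
#' @return A [ViewMatrix-class] object.
#' @examples
#' vm <- ViewMatrix(matrix(rnorm(6), 3, 2), paste0("g", 1:3),
#'                  c("s1", "s2"), name = "mRNA")
#' featureIds(vm)
#' @export
ViewMatrix <- function(values, featureIds = rownames(values),
                       sampleIds = colnames(values), name = "view") {
  values <- as.matrix(values)
  if (is.null(featureIds))
    featureIds <- paste0("f", seq_len(nrow(values)))
  if (is.null(sampleIds))
    sampleIds <- paste0("s", seq_len(ncol(values)))
  if (length(featureIds) != nrow(values))
    stop("length of 'featureIds' (", length(featureIds),
         ") does not match the number of rows (", nrow(values), ")")
  if (length(sampleIds) != ncol(values))
    stop("length of 'sampleIds' (", length(sampleIds),
         ") does not match the number of columns (", ncol(values), ")")
  dimnames(values) <- list(as.character(featureIds), as.character(sampleIds))
  new("ViewMatrix", values = values, name = as.character(name))
}

#' MultiViewSet: an ordered collection of views
#'
#' Views either share their samples across views (Case I, e.g. mRNA and
#' miRNA measured on the same specimens) or share their features (Case II,
#' e.g. the same genes measured under different treatments). The shared
#' axis must carry identical ID sequences in every view.
#'
#' @slot views list of [ViewMatrix-class] objects with unique names.
#' @slot case either `"shared_samples"` (Case I) or `"shared_features"`
#'   (Case II).
#'
#' @aliases MultiViewSet-class
#' @exportClass MultiViewSet
setClass("MultiViewSet",
         representation(views = "list", case = "character"))

setValidity("MultiViewSet", function(object) {
  if (length(object@views) < 2L)
    return("a MultiViewSet needs at least two views")
  if (!all(vapply(object@views, is, logical(1), "ViewMatrix")))
    return("'views' must be a list of ViewMatrix objects")
  if (!object@case %in% c("shared_samples", "shared_features"))
    return("'case' must be \"shared_samples\" or \"shared_features\"")
  nms <- vapply(object@views, function(v) v@name, character(1))
  if (anyDuplicated(nms))
    return("view names must be unique")
  ref <- object@views[[1L]]
  for (v in object@views[-1L]) {
    if (object@case == "shared_samples") {
      if (!identical(colnames(v@values), colnames(ref@values)))
        return("Case I requires identical sample ID sequences across views")
    } else {
      if (!identical(rownames(v@values), rownames(ref@values)))
        return("Case II requires identical feature ID sequences across views")
    }
  }
  TRUE
})

#' Construct a MultiViewSet
#'
#' @param views list of [ViewMatrix-class] objects (or plain matrices with
#'   dimnames, which are promoted).
#' @param case `"shared_samples"` (Case I) or `"shared_features"` (Case II).
#'
#' @return A [MultiViewSet-class] object.
#' @export
MultiViewSet <- function(views, case = c("shared_samples", "shared_features")) {
  case <- match.arg(case)
  views <- lapply(seq_along(views), function(k) {
    v <- views[[k]]
    if (is(v, "ViewMatrix")) return(v)
    nm <- if (!is.null(names(views)) && nzchar(names(views)[k]))
      names(views)[k] else paste0("view", k)
    ViewMatrix(v, name = nm)
  })
  new("MultiViewSet", views = views, case = case)
}

#' MultiwayArray: a dense Type I or Type II product tensor
#'
#' Dense labelled tensor built from a [MultiViewSet-class]. A Type I tensor
#' has one mode per view plus the shared mode (last); a Type II tensor sums
#' over the shared mode and has one mode per view.
#'
#' @slot data dense numeric array; dimnames carry the IDs of each mode.
#' @slot modeLabels one label per mode (view names, plus `"sample"` or
#'   `"feature"` for the shared mode of a Type I tensor).
#' @slot tensorType `"type1"` or `"type2"`.
#' @slot case the layout of the source set (`"shared_samples"` or
#'   `"shared_features"`).
#'
#' @aliases MultiwayArray-class
#' @exportClass MultiwayArray
setClass("MultiwayArray",
         representation(data = "array", modeLabels = "character",
                        tensorType = "character", case = "character"))

setValidity("MultiwayArray", function(object) {
  if (length(dim(object@data)) != length(object@modeLabels))
    return("one mode label per mode is required")
  if (!object@tensorType %in% c("type1", "type2"))
    return("'tensorType' must be \"type1\" or \"type2\"")
  if (!object@case %in% c("shared_samples", "shared_features"))
    return("invalid 'case'")
  TRUE
})

#' HOSVDResult: a higher-order SVD
#'
#' Tucker-format result of [hosvd()]: a (possibly truncated) core tensor
#' and one column-orthonormal factor matrix per mode, whose columns are the
#' singular value vectors of that mode ordered by decreasing mode singular
#' value.
#'
#' @slot core dense numeric array with dimensions equal to the per-mode
#'   ranks.
#' @slot factors list of factor matrices, one per mode; rows are indexed by
#'   the original mode IDs, columns are components.
#' @slot ranks integer vector of per-mode truncation ranks.
#' @slot modeLabels labels inherited from the decomposed tensor.
#' @slot tensorType,case provenance of the decomposed tensor, used to
#'   validate the missing-mode projection.
#'
#' @aliases HOSVDResult-class
#' @exportClass HOSVDResult
setClass("HOSVDResult",
         representation(core = "array", factors = "list", ranks = "integer",
                        modeLabels = "character", tensorType = "character",
                        case = "character"))

setValidity("HOSVDResult", function(object) {
  if (length(object@factors) != length(dim(object@core)))
    return("one factor matrix per core mode is required")
  if (!identical(unname(dim(object@core)), as.integer(object@ranks)))
    return("core dimensions must equal the per-mode ranks")
  for (U in object@factors) {
    g <- crossprod(U)
    if (max(abs(g - diag(ncol(U)))) > 1e-8)
      return("factor columns must be orthonormal (within 1e-8)")
  }
  TRUE
})

#' ProjectedVectors: missing-mode singular value vectors of a Type II tensor
#'
#' A Type II tensor has no mode for the shared axis (samples in Case I,
#' features in Case II), so it yields one set of shared-axis singular value
#' vectors *per view*, obtained by projecting each view's factor matrix
#' through that view's data. See [projectMissingMode()].
#'
#' @slot vectors named list (one entry per view) of component-by-shared-index
#'   matrices.
#' @slot case layout of the source set.
#' @slot derivation human-readable note of which factor was projected
#'   through which view.
#'
#' @aliases ProjectedVectors-class
#' @exportClass ProjectedVectors
setClass("ProjectedVectors",
         representation(vectors = "list", case = "character",
                        derivation = "character"))

#' SelectionResult: chi-squared outlier feature extraction
#'
#' Per-feature scores, raw and BH-adjusted P-values, and selection flags
#' produced by [selectOutliers()] (or [pcaUnsupervisedFE()]).
#'
#' @slot table data.frame with columns `feature_id`, `score`, `df`, `p`,
#'   `p_adj`, `selected`.
#' @slot alpha the BH-adjusted P-value threshold used.
#' @slot components 1-based indices of the singular value vector (or PC
#'   score) columns that entered the score.
#'
#' @aliases SelectionResult-class
#' @exportClass SelectionResult
setClass("SelectionResult",
         representation(table = "data.frame", alpha = "numeric",
                        components = "integer"))

setValidity("SelectionResult", function(object) {
  need <- c("feature_id", "score", "df", "p", "p_adj", "selected")
  if (!all(need %in% colnames(object@table)))
    return(paste("selection table must have columns:",
                 paste(need, collapse = ", ")))
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha > 1)
    return("'alpha' must be a single value in (0, 1]")
  TRUE
})

#' PCAResult: gram-matrix PCA with features embedded
#'
#' Result of [pcaDecompose()]. Scores are per-feature eigenvector entries
#' of the gram matrix \eqn{G = XX^T}; loadings are their sample-space
#' images \eqn{v_k = X^T u_k}, so \eqn{\|v_k\|^2 = \lambda_k}.
#'
#' @slot scores features-by-components matrix of PC scores \eqn{u_k}.
#' @slot loadings samples-by-components matrix of PC loadings \eqn{v_k}.
#' @slot eigenvalues non-increasing eigenvalues \eqn{\lambda_k} of the gram
#'   matrix.
#'
#' @aliases PCAResult-class
#' @exportClass PCAResult
setClass("PCAResult",
         representation(scores = "matrix", loadings = "matrix",
                        eigenvalues = "numeric"))

#' SyntheticDataset: the two-view latent-correspondence benchmark
#'
#' Output of [generateTwoView()]: a Case I [MultiViewSet-class] with two
#' views, the indices of the signal features, and the two deterministic
#' base curves so that recovered components can be checked against ground
#' truth.
#'
#' @slot views Case I [MultiViewSet-class] with views `"view1"`, `"view2"`.
#' @slot signalIndex integer indices (1..N0) of the signal features.
#' @slot baseCurves list with numeric length-M vectors `g1`, `g2`.
#' @slot config the [SyntheticConfig()] list used for generation.
#'
#' @aliases SyntheticDataset-class
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
         representation(views = "MultiViewSet", signalIndex = "integer",
                        baseCurves = "list", config = "list"))
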