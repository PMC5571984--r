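#' Read a view matrix from TSV
#'
#' Expected layout: a header row of sample IDs (with or without a leading
#' cell for the feature-ID column) and one row per feature whose first
#' field is the feature ID followed by tab-separated numeric values. IDs
#' are preserved in file order. Duplicate IDs, ragged rows and
#' non-numeric cells raise errors that name the offending line.
#'
#' @param path path to a TSV file.
#' @param name view name; defaults to the file name without extension.
#'
#' @return A [ViewMatrix-class].
#' @seealso [writeViewMatrix()]
#' @export
readViewMatrix <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("'", path, "' must have a header row and at least one feature row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  widths <- lengths(body)
  nc <- widths[1L]
  if (any(widths != nc))
    stop("ragged row(s) in '", path, "' at line(s) ",
         paste(which(widths != nc)[1L] + 1L, collapse = ", "),
         ": expected ", nc, " fields")
  sampleIds <- if (length(header) == nc) header[-1L]
    else if (length(header) == nc - 1L) header
    else stop("header of '", path, "' has ", length(header),
              " fields but data rows have ", nc)
  featIds <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(featIds))
    stop("duplicate feature ID(s) in '", path, "': ",
         paste(unique(featIds[duplicated(featIds)]), collapse = ", "))
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ID(s) in '", path, "'")
  vals <- matrix(NA_real_, length(body), nc - 1L)
  for (i in seq_along(body)) {
    x <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (any(is.na(x)))
      stop("non-numeric cell in '", path, "' at line ", i + 1L)
    vals[i, ] <- x
  }
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  ViewMatrix(vals, featureIds = featIds, sampleIds = sampleIds, name = name)
}

#' Write a view matrix as TSV
#'
#' @param X a [ViewMatrix-class] (or matrix with dimnames).
#' @param path output path.
#' @export
writeViewMatrix <- function(X, path) {
  if (!is(X, "ViewMatrix")) X <- ViewMatrix(as.matrix(X))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", sampleIds(X)), collapse = "\t"), con)
  v <- X@values
  writeLines(paste(rownames(v),
                   apply(v, 1L, function(r)
                     paste(format(r, digits = 15, trim = TRUE,
                                  scientific = FALSE), collapse = "\t")),
             sep = "\t"), con)
  invisible(path)
}

.writeTable <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param viewPaths character vector of TSV paths (or a named list of
#'   [ViewMatrix-class] objects).
#' @param case `"shared_samples"` or `"shared_features"`.
#' @param tensorType 1 or 2 (Type I product tensor, or Type II contracted
#'   tensor).
#' @param ranks per-mode HOSVD truncation (default `min(10, mode size)`).
#' @param components component indices used for feature selection
#'   (default 1..5, clipped to the available rank).
#' @param alpha BH threshold per view; a single value is recycled.
#' @param standardize standardize views per sample column before building
#'   the tensor (default TRUE, the convention for omics profiles).
#' @param elementCap Type I dense-storage cap (elements).
#' @param seed integer seed recorded in the manifest; the pipeline itself
#'   is deterministic, the seed matters when `viewPaths` is replaced by a
#'   generator.
#' @param outDir output directory.
#'
#' @return A validated config list for [runPipeline()].
#' @export
RunConfig <- function(viewPaths, case = "shared_samples", tensorType = 2L,
                      ranks = NULL, components = seq_len(5L), alpha = 0.01,
                      standardize = TRUE, elementCap = 2e8, seed = 1L,
                      outDir = ".") {
  if (!tensorType %in% c(1L, 2L)) stop("'tensorType' must be 1 or 2")
  if (any(alpha <= 0) || any(alpha > 1)) stop("'alpha' must be in (0, 1]")
  if (is.character(viewPaths)) {
    missing <- !file.exists(viewPaths)
    if (any(missing))
      stop("view file(s) not found: ",
           paste(viewPaths[missing], collapse = ", "))
  }
  list(viewPaths = viewPaths, case = case, tensorType = as.integer(tensorType),
       ranks = ranks, components = as.integer(components), alpha = alpha,
       standardize = isTRUE(standardize), elementCap = elementCap,
       seed = as.integer(seed), outDir = outDir)
}

#' Run the full extraction pipeline
#'
#' Orchestrates the workflow: read (or accept) the views, optionally
#' standardize, build the Type I or Type II tensor, decompose with
#' [hosvd()], rank the core, project the missing-mode vectors (Type II),
#' and select chi-squared outlier features per view. All tables are
#' written as TSV under `config$outDir` together with a JSON manifest
#' (config, seed, package version) sufficient to re-execute the run; the
#' same config and seed give byte-identical selection tables.
#'
#' @param config a [RunConfig()] list.
#'
#' @return Invisibly, a list with the in-memory results (`set`, `tensor`
#'   dimensions, `hosvd`, `coreRanking`, `projected`, `selections`) and
#'   the written file paths.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  vs <- if (is.character(config$viewPaths))
    lapply(config$viewPaths, readViewMatrix)
  else config$viewPaths
  set <- MultiViewSet(vs, case = config$case)
  if (config$standardize)
    set <- MultiViewSet(lapply(views(set), standardizeView),
                        case = config$case)
  tens <- if (config$tensorType == 1L)
    buildTypeITensor(set, elementCap = config$elementCap)
  else buildTypeIITensor(set)
  dec <- hosvd(tens, ranks = config$ranks)

  paths <- list()
  facs <- factorMatrices(dec)
  for (k in seq_along(facs)) {
    d <- data.frame(id = rownames(facs[[k]]), facs[[k]],
                    check.names = FALSE, stringsAsFactors = FALSE)
    paths[[paste0("factor_", names(facs)[k])]] <-
      .writeTable(d, file.path(config$outDir,
                               paste0("factor_", names(facs)[k], ".tsv")))
  }
  ranking <- rankCore(dec, topN = length(coreTensor(dec)))
  paths$core <- .writeTable(ranking, file.path(config$outDir, "core.tsv"))

  projected <- NULL
  if (config$tensorType == 2L) {
    projected <- projectMissingMode(dec, set)
    for (nm in names(projectedVectors(projected))) {
      P <- projectedVectors(projected)[[nm]]
      d <- data.frame(component = seq_len(nrow(P)), P,
                      check.names = FALSE, stringsAsFactors = FALSE)
      paths[[paste0("projected_", nm)]] <-
        .writeTable(d, file.path(config$outDir,
                                 paste0("projected_", nm, ".tsv")))
    }
  }

  alphas <- rep_len(config$alpha, length(set@views))
  selections <- vector("list", length(set@views))
  featureModes <- seq_along(set@views)
  for (k in featureModes) {
    U <- facs[[k]]
    comps <- config$components[config$components <= ncol(U)]
    sel <- selectOutliers(U, components = comps, alpha = alphas[k],
                          featureIds = rownames(U))
    selections[[k]] <- sel
    nm <- viewName(set@views[[k]])
    paths[[paste0("selection_", nm)]] <-
      .writeTable(selectionTable(sel),
                  file.path(config$outDir, paste0("selection_", nm, ".tsv")))
  }
  names(selections) <- vapply(set@views, viewName, character(1))

  manifest <- list(
    config = config[setdiff(names(config), "viewPaths")],
    viewPaths = if (is.character(config$viewPaths)) config$viewPaths
                else paste0("<in-memory:", vapply(vs, viewName, character(1)), ">"),
    seed = config$seed,
    package = as.character(utils::packageVersion("tdfe")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$manifest <- file.path(config$outDir, "manifest.json")

  invisible(list(set = set, tensorDim = dim(tens), hosvd = dec,
                 coreRanking = ranking, projected = projected,
                 selections = selections, paths = paths))
}
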