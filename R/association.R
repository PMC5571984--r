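#' Categorical regression of a sample vector on class labels
#'
#' Least-squares fit of the class-means model
#' \eqn{v_j = C^0 + \sum_S C^1_S \delta_{Sj}} and the F test of that model
#' against the intercept-only model (df1 = classes - 1,
#' df2 = n - classes). Used to ask whether a sample singular value vector
#' (or PC loading) is coincident with known sample classes without having
#' used the classes during decomposition.
#'
#' @param v numeric vector over samples.
#' @param classes class label per sample (factor or coercible); at least
#'   two classes, each non-empty, and `n` must exceed the class count.
#'
#' @return A list with `p` (perfect fits coded as the smallest positive
#'   double), `f`, `r_squared`, `df1`, `df2`.
#' @examples
#' categoricalRegressionTest(c(1, 1, 0, 0), c("A", "A", "B", "B"))$p
#' @export
categoricalRegressionTest <- function(v, classes) {
  v <- as.numeric(v)
  cls <- factor(classes)
  if (length(v) != length(cls))
    stop("'v' and 'classes' must have the same length")
  if (nlevels(cls) < 2L)
    stop("at least two classes are required")
  if (length(v) <= nlevels(cls))
    stop("need more samples (", length(v), ") than classes (",
         nlevels(cls), ") for a residual degree of freedom")
  fit <- stats::lm(v ~ cls)
  # perfect fits trip lm's F-test reliability warning; they are handled
  # explicitly below
  a <- suppressWarnings(stats::anova(fit))
  f <- a[["F value"]][1L]
  p <- a[["Pr(>F)"]][1L]
  rss <- a[["Sum Sq"]][2L]
  tss <- sum(a[["Sum Sq"]])
  r2 <- if (tss > 0) 1 - rss / tss else 0
  df1 <- a[["Df"]][1L]
  df2 <- a[["Df"]][2L]
  if (!is.finite(f)) {            # zero residual variance: perfect fit
    f <- Inf
    p <- 0
  }
  if (tss == 0) { f <- 0; p <- 1; r2 <- 0 }   # constant v: nothing to explain
  if (p == 0) p <- .Machine$double.xmin
  list(p = p, f = f, r_squared = r2, df1 = df1, df2 = df2)
}

#' Correlate a template vector with feature profiles
#'
#' Pearson correlation of each feature's profile with a template (e.g. a
#' sample singular value vector laid out over the concatenated
#' condition/time axis), with raw P from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} and BH adjustment. Features with
#' zero-variance profiles have undefined correlation; they are flagged,
#' reported as `NA`, and excluded from the adjustment.
#'
#' @param template numeric vector.
#' @param profiles features-by-positions matrix, columns aligned with
#'   `template` (at least 3 positions).
#'
#' @return data.frame with `feature_id`, `r`, `p`, `p_adj`, `flagged`.
#' @export
templateCorrelations <- function(template, profiles) {
  template <- as.numeric(template)
  profiles <- as.matrix(profiles)
  n <- length(template)
  if (ncol(profiles) != n)
    stop("'profiles' must have one column per template position")
  if (n < 3L) stop("at least 3 positions are required")
  if (stats::sd(template) == 0) stop("'template' has zero variance")
  sds <- apply(profiles, 1L, stats::sd)
  flagged <- sds == 0
  r <- rep(NA_real_, nrow(profiles))
  r[!flagged] <- as.vector(stats::cor(t(profiles[!flagged, , drop = FALSE]),
                                      template))
  p <- rep(NA_real_, nrow(profiles))
  ok <- !flagged
  r2 <- pmin(r[ok]^2, 1)
  tval <- abs(r[ok]) * sqrt((n - 2) / pmax(1 - r2, 0))
  p[ok] <- 2 * stats::pt(tval, df = n - 2, lower.tail = FALSE)
  p[ok][r2 >= 1] <- .Machine$double.xmin
  padj <- rep(NA_real_, nrow(profiles))
  padj[ok] <- bhAdjust(p[ok])
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(profiles)))
  data.frame(feature_id = ids, r = r, p = p, p_adj = padj,
             flagged = flagged, stringsAsFactors = FALSE, row.names = NULL)
}

#' Scale-and-shift fit of feature profiles to a template
#'
#' Every feature has its own baseline and amplitude, so before profiles
#' can be overdrawn on a common template they are linearly mapped onto it:
#' per feature, least squares of `template = a * profile + b` over the
#' full concatenated condition/time axis, with `a`, `b` shared across
#' conditions. Constant profiles get `a = 0`, `b = mean(template)` and
#' are flagged.
#'
#' @inheritParams templateCorrelations
#' @return A list with `coefficients` (data.frame `feature_id`, `a`, `b`,
#'   `flagged`) and `fitted` (features-by-positions matrix of
#'   `a * profile + b`).
#' @export
scaleShiftFit <- function(template, profiles) {
  template <- as.numeric(template)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != length(template))
    stop("'profiles' must have one column per template position")
  mu <- rowMeans(profiles)
  centered <- profiles - mu
  ssx <- rowSums(centered^2)
  flagged <- ssx == 0
  a <- numeric(nrow(profiles))
  a[!flagged] <- (centered[!flagged, , drop = FALSE] %*%
                    (template - mean(template)))[, 1L] / ssx[!flagged]
  b <- mean(template) - a * mu
  fitted <- profiles * a + b                  # rows recycled per feature
  dimnames(fitted) <- dimnames(profiles)
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(profiles)))
  list(coefficients = data.frame(feature_id = ids, a = a, b = b,
                                 flagged = flagged,
                                 stringsAsFactors = FALSE, row.names = NULL),
       fitted = fitted)
}

#' Group tests per time point on scale-and-shift fitted values
#'
#' At each time point the fitted values of the selected features are
#' compared between treatment groups: a pooled-variance two-sided t test
#' when there are two groups, or the class-means F test
#' ([categoricalRegressionTest()]) when there are three or more.
#'
#' @param fits result of [scaleShiftFit()].
#' @param groups group label per column of the fitted matrix.
#' @param times time point per column of the fitted matrix.
#'
#' @return data.frame with `time`, `statistic` (t or F), `df` (residual
#'   df), `p`.
#' @export
groupwiseTimepointTest <- function(fits, groups, times) {
  fitted <- fits$fitted
  groups <- factor(groups)
  if (length(groups) != ncol(fitted) || length(times) != ncol(fitted))
    stop("'groups' and 'times' must have one entry per fitted column")
  if (nlevels(groups) < 2L) stop("at least two groups are required")
  out <- lapply(unique(times), function(tp) {
    sel <- times == tp
    g <- droplevels(groups[sel])
    if (nlevels(g) < 2L)
      stop("time point '", tp, "' is present in fewer than two groups")
    vals <- lapply(levels(g), function(lv)
      as.vector(fitted[, sel, drop = FALSE][, g == lv, drop = FALSE]))
    if (any(lengths(vals) < 2L))
      stop("time point '", tp, "' has a group with fewer than two values")
    if (nlevels(g) == 2L) {
      if (stats::sd(unlist(vals)) == 0) {
        data.frame(time = tp, statistic = 0,
                   df = length(unlist(vals)) - 2L, p = 1)
      } else {
        tt <- stats::t.test(vals[[1L]], vals[[2L]], var.equal = TRUE)
        data.frame(time = tp, statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
      }
    } else {
      y <- unlist(vals)
      lab <- rep(levels(g), lengths(vals))
      cr <- categoricalRegressionTest(y, lab)
      data.frame(time = tp, statistic = cr$f, df = cr$df2, p = cr$p)
    }
  })
  do.call(rbind, out)
}

#' UPGMA pairing of singular value vectors
#'
#' Average-linkage (UPGMA) hierarchical clustering of labelled sample
#' vectors under the distance \eqn{d(u, v) = -|r(u, v)|} (negative signed
#' absolute Pearson correlation). Duplicated or sign-flipped vectors sit
#' at distance \eqn{-1} and merge first; reading off the singleton pairs
#' reveals which vectors of one view correspond to which of another.
#' Negative distances are legitimate here: average linkage only requires
#' an ordering.
#'
#' @param vectors named list of equal-length numeric vectors, or a matrix
#'   with one column per vector.
#'
#' @return A list with `distance` (the full distance matrix), `tree` (the
#'   `hclust` object), and `pairs` (data.frame of leaves merged directly
#'   with another leaf: `member1`, `member2`, `height`).
#' @export
upgmaPair <- function(vectors) {
  if (is.list(vectors)) {
    if (length(unique(lengths(vectors))) != 1L)
      stop("all vectors must have the same length")
    vectors <- do.call(cbind, vectors)
  }
  vectors <- as.matrix(vectors)
  if (ncol(vectors) < 2L) stop("at least two vectors are required")
  if (is.null(colnames(vectors)))
    colnames(vectors) <- paste0("v", seq_len(ncol(vectors)))
  sds <- apply(vectors, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance vector(s): ",
         paste(colnames(vectors)[sds == 0], collapse = ", "))
  D <- -abs(stats::cor(vectors))
  diag(D) <- 0
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  mg <- tree$merge
  leafPairs <- which(mg[, 1L] < 0 & mg[, 2L] < 0)
  pairs <- data.frame(member1 = tree$labels[-mg[leafPairs, 1L]],
                      member2 = tree$labels[-mg[leafPairs, 2L]],
                      height = tree$height[leafPairs],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(distance = D, tree = tree, pairs = pairs)
}
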