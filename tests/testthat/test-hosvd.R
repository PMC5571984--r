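test_that("rank-1 outer product and diagonal matrix recover trivial factors", {
  a <- array(0, c(3, 4, 3))
  a[1, 2, 1] <- 1                      # e1 (x) e2 (x) e1
  h <- hosvd(a, ranks = c(1, 1, 1))
  expect_equal(abs(as.vector(coreTensor(h))), 1)
  f <- factorMatrices(h)
  expect_equal(abs(f[[1]][, 1]), c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(abs(f[[2]][, 1]), c(0, 1, 0, 0), ignore_attr = TRUE)
  expect_equal(abs(f[[3]][, 1]), c(1, 0, 0), ignore_attr = TRUE)

  d <- diag(c(3, 2))
  h2 <- hosvd(d, ranks = c(2, 2))
  expect_equal(abs(unname(coreTensor(h2))), diag(c(3, 2)), tolerance = 1e-12)
  expect_equal(abs(unname(factorMatrices(h2)[[1]])), diag(2),
               tolerance = 1e-12)
})

test_that("two-mode HOSVD agrees with the plain SVD", {
  set.seed(31)
  X <- matrix(rnorm(35), 5, 7)
  s <- svd(X)
  h2 <- hosvd(array(X, dim(X)), ranks = c(5, 5))
  # singular values appear as the absolute diagonal of the core
  expect_equal(abs(diag(coreTensor(h2))), s$d[1:5], tolerance = 1e-10)
  # factor columns match singular vectors up to sign
  expect_equal(abs(unname(factorMatrices(h2)[[1]])), abs(s$u),
               tolerance = 1e-10)
})

test_that("full-rank HOSVD reconstructs the tensor and preserves energy", {
  set.seed(17)
  a <- array(rnorm(5 * 6 * 7), c(5, 6, 7))
  h <- hosvd(a, ranks = c(5, 6, 7))
  expect_lt(max(abs(reconstructTensor(h) - a)), 1e-8)
  expect_equal(sqrt(sum(coreTensor(h)^2)), sqrt(sum(a^2)),
               tolerance = 1e-10)
  # factor orthonormality
  for (U in factorMatrices(h))
    expect_lt(max(abs(crossprod(U) - diag(ncol(U)))), 1e-8)
  # all-orthogonality: rows of every core unfolding are orthogonal
  for (k in 1:3) {
    G <- unfoldTensor(coreTensor(h), k)
    gram <- tcrossprod(G)
    expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)
  }
  # truncation can only lose energy
  ht <- hosvd(a, ranks = c(2, 3, 2))
  expect_lt(sqrt(sum(coreTensor(ht)^2)), sqrt(sum(a^2)))
})

test_that("component order follows decreasing mode singular values", {
  set.seed(8)
  a <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  h <- hosvd(a, ranks = c(4, 5, 6))
  for (k in 1:3) {
    sv <- svd(unfoldTensor(a, k))$d
    expect_equal(sort(sv, decreasing = TRUE), sv)
    # mode-k core unfolding row norms are the mode singular values
    rn <- sqrt(rowSums(unfoldTensor(coreTensor(h), k)^2))
    expect_equal(rn, sv[seq_along(rn)], tolerance = 1e-8)
  }
})

test_that("invalid ranks are rejected", {
  a <- array(rnorm(24), c(2, 3, 4))
  expect_error(hosvd(a, ranks = c(3, 3, 4)), "rank")
  expect_error(hosvd(a, ranks = c(2, 3)), "per mode")
})

test_that("rankCore sorts by |value| with lexicographic tie-breaking", {
  core <- array(0, c(2, 2, 2))
  core[1, 1, 1] <- 5; core[2, 1, 2] <- -7; core[1, 2, 1] <- 7
  h <- new("HOSVDResult", core = core,
           factors = list(diag(2), diag(2), diag(2)),
           ranks = c(2L, 2L, 2L), modeLabels = c("a", "b", "c"),
           tensorType = "type1", case = "shared_samples")
  r <- rankCore(h, topN = 3)
  expect_equal(r$value, c(7, -7, 5))
  expect_equal(unname(as.matrix(r[1, 1:3])), matrix(c(1L, 2L, 1L), 1))
  expect_equal(unname(as.matrix(r[2, 1:3])), matrix(c(2L, 1L, 2L), 1))
  r1 <- rankCore(h, topN = 1)
  expect_identical(nrow(r1), 1L)
  expect_equal(r1$value, 7)

  # random core agrees with an exhaustive sort oracle
  set.seed(4)
  core <- array(rnorm(27), c(3, 3, 3))
  h@core <- core; h@factors <- list(diag(3), diag(3), diag(3))
  h@ranks <- c(3L, 3L, 3L)
  r <- rankCore(h, topN = 27)
  expect_equal(r$value, as.vector(core)[order(-abs(as.vector(core)))])
})

test_that("missing-mode projection recovers per-view shared-mode vectors", {
  idn <- diag(3); dimnames(idn) <- list(paste0("f", 1:3), paste0("s", 1:3))
  si <- MultiViewSet(list(A = idn, B = idn))
  h <- hosvd(buildTypeIITensor(si), ranks = c(3, 3))
  pv <- projectedVectors(projectMissingMode(h, si))
  for (P in pv) expect_equal(abs(unname(P)), diag(3), tolerance = 1e-10)

  # linearity: scaling a view scales its projected vectors
  s <- randomCaseISet(6, 5, 8, seed = 12)
  h <- hosvd(buildTypeIITensor(s), ranks = c(3, 3))
  p0 <- projectedVectors(projectMissingMode(h, s))
  s2 <- MultiViewSet(list(
    ViewMatrix(2 * viewValues(views(s)$A), name = "A"), views(s)$B))
  p2 <- projectedVectors(projectMissingMode(h, s2))
  expect_equal(p2$A, 2 * p0$A, tolerance = 1e-12)

  # a Type I decomposition already has the shared-mode factor
  h1 <- hosvd(buildTypeITensor(s), ranks = c(3, 3, 3))
  expect_error(projectMissingMode(h1, s), "Type II")
})

test_that("projected components track the generating base curves", {
  d <- generateTwoView(SyntheticConfig(N = 300, seed = 6))
  set <- d@views
  h <- hosvd(buildTypeIITensor(set), ranks = c(3, 3))
  pv <- projectedVectors(projectMissingMode(h, set))
  g <- baseCurves(d)
  r1 <- max(abs(cor(t(pv$view1), g$g1)))
  r2 <- max(abs(cor(t(pv$view2), g$g2)))
  expect_gte(r1, 0.9)
  expect_gte(r2, 0.9)
})

test_that("selection and ranking are invariant under factor sign flips", {
  set.seed(19)
  U <- matrix(rnorm(600), 200, 3)
  U[1:6, ] <- 5
  flip <- U %*% diag(c(-1, 1, -1))
  a <- selectOutliers(U, 1:3, alpha = 0.05)
  b <- selectOutliers(flip, 1:3, alpha = 0.05)
  expect_identical(selectionTable(a)$selected, selectionTable(b)$selected)
  expect_equal(selectionTable(a)$p, selectionTable(b)$p)
})
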