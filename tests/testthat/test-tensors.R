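test_that("standardizeView enforces zero column sums and sum of squares N", {
  vm <- ViewMatrix(cbind(s1 = c(0, 2), s2 = c(1, -1)),
                   featureIds = c("f1", "f2"))
  out <- viewValues(standardizeView(vm))
  expect_equal(unname(out[, "s1"]), c(-1, 1))
  expect_equal(unname(out[, "s2"]), c(1, -1))   # already standardized
  expect_equal(unname(colSums(out)), c(0, 0))
  expect_equal(unname(colSums(out^2)), c(2, 2))

  const <- ViewMatrix(cbind(ok = c(1, 2), flat = c(5, 5)),
                      featureIds = c("f1", "f2"))
  expect_error(standardizeView(const), "flat")
})

test_that("standardizeView is idempotent", {
  vm <- randomView(20, 6, seed = 9)
  once <- standardizeView(vm)
  twice <- standardizeView(once)
  expect_equal(viewValues(once), viewValues(twice), tolerance = 1e-12)
})

test_that("Type I tensor is the entry-wise product over views", {
  s <- MultiViewSet(list(
    A = matrix(c(1, 2), 1, 2, dimnames = list("f", c("s1", "s2"))),
    B = matrix(c(3, 4), 1, 2, dimnames = list("f", c("s1", "s2")))))
  t1 <- buildTypeITensor(s)
  expect_identical(dim(t1), c(1L, 1L, 2L))
  expect_equal(as.vector(tensorValues(t1)), c(3, 8))
  expect_identical(modeLabels(t1), c("A", "B", "sample"))

  # Case II: two shared features, one sample per view
  s2 <- MultiViewSet(list(
    A = matrix(c(1, 2), 2, 1, dimnames = list(c("f1", "f2"), "sA")),
    B = matrix(c(3, 4), 2, 1, dimnames = list(c("f1", "f2"), "sB"))),
    case = "shared_features")
  t2 <- buildTypeITensor(s2)
  expect_identical(dim(t2), c(1L, 1L, 2L))
  expect_equal(as.vector(tensorValues(t2)), c(3, 8))
  expect_identical(modeLabels(t2), c("A", "B", "feature"))

  # an all-zero feature row zeroes its slice
  sz <- randomCaseISet(4, 3, 5, seed = 2)
  vz <- views(sz)$A
  vals <- viewValues(vz); vals[2, ] <- 0
  sz <- MultiViewSet(list(ViewMatrix(vals, name = "A"), views(sz)$B))
  tz <- buildTypeITensor(sz)
  expect_true(all(tensorValues(tz)[2, , ] == 0))
})

test_that("Type II tensor contracts the shared mode of Type I", {
  s <- MultiViewSet(list(
    A = matrix(c(1, 2), 1, 2, dimnames = list("f", c("s1", "s2"))),
    B = matrix(c(3, 4), 1, 2, dimnames = list("f", c("s1", "s2")))))
  expect_equal(as.vector(tensorValues(buildTypeIITensor(s))), 11)

  idn <- diag(3); dimnames(idn) <- list(paste0("f", 1:3), paste0("s", 1:3))
  si <- MultiViewSet(list(A = idn, B = idn))
  expect_equal(unname(tensorValues(buildTypeIITensor(si))), diag(3))

  s43 <- randomCaseISet(4, 3, 5, seed = 7)
  direct <- tensorValues(buildTypeIITensor(s43))
  viaType1 <- contractLastMode(tensorValues(buildTypeITensor(s43)))
  expect_lt(max(abs(direct - unname(viaType1))), 1e-12)
  # m = 2 Case I: equals the matrix product X1 %*% t(X2)
  expect_equal(unname(direct),
               unname(viewValues(views(s43)$A) %*%
                        t(viewValues(views(s43)$B))))
})

test_that("contraction identity also holds for three views", {
  set.seed(13)
  mk <- function(n, nm) ViewMatrix(matrix(rnorm(n * 4), n, 4),
                                   featureIds = paste0(nm, seq_len(n)),
                                   sampleIds = paste0("s", 1:4), name = nm)
  s3 <- MultiViewSet(list(mk(3, "a"), mk(2, "b"), mk(4, "c")))
  t2 <- tensorValues(buildTypeIITensor(s3))
  t1c <- contractLastMode(tensorValues(buildTypeITensor(s3)))
  expect_identical(dim(t2), c(3L, 2L, 4L))
  expect_lt(max(abs(t2 - unname(t1c))), 1e-12)
})

test_that("Type II is linear in each view", {
  s <- randomCaseISet(4, 3, 6, seed = 21)
  base <- tensorValues(buildTypeIITensor(s))
  scaled <- MultiViewSet(list(
    ViewMatrix(2.5 * viewValues(views(s)$A), name = "A"), views(s)$B))
  expect_equal(tensorValues(buildTypeIITensor(scaled)), 2.5 * base)
})

test_that("dense Type I storage is capped with a Type II recommendation", {
  s <- randomCaseISet(40, 40, 10, seed = 3)
  expect_error(buildTypeITensor(s, elementCap = 1000), "Type II")
  expect_silent(buildTypeITensor(s, elementCap = 2e8))
})

test_that("mismatched shared IDs are rejected at set construction", {
  v1 <- ViewMatrix(matrix(1:4, 2, 2), c("f1", "f2"), c("s1", "s2"), "A")
  v2 <- ViewMatrix(matrix(1:4, 2, 2), c("f1", "f2"), c("s1", "sX"), "B")
  expect_error(MultiViewSet(list(v1, v2), case = "shared_samples"),
               "sample ID")
  expect_silent(MultiViewSet(list(v1, v2), case = "shared_features"))
})
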