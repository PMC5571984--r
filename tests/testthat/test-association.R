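test_that("categorical regression detects perfect and absent class structure", {
  perfect <- categoricalRegressionTest(c(1, 1, 0, 0), c("A", "A", "B", "B"))
  expect_equal(perfect$p, .Machine$double.xmin)
  expect_equal(perfect$r_squared, 1)

  none <- categoricalRegressionTest(c(1, -1, 1, -1), c("A", "A", "B", "B"))
  expect_equal(none$f, 0)
  expect_equal(none$p, 1)

  expect_error(categoricalRegressionTest(1:4, rep("A", 4)), "two classes")
  expect_error(categoricalRegressionTest(1:3, c("A", "B", "C")), "classes")
})

test_that("categorical regression is invariant to label names and affine v", {
  set.seed(64)
  v <- rnorm(12)
  cls <- rep(c("x", "y", "z"), each = 4)
  a <- categoricalRegressionTest(v, cls)
  b <- categoricalRegressionTest(v, rep(c("G1", "G2", "G3"), each = 4))
  d <- categoricalRegressionTest(3 * v - 7, cls)
  expect_equal(a$p, b$p)
  expect_equal(a$p, d$p, tolerance = 1e-10)
  expect_equal(a$f, d$f, tolerance = 1e-10)
})

test_that("categorical regression P-values are uniform under the null", {
  set.seed(202)
  cls <- rep(paste0("c", 1:4), each = 10)
  ps <- replicate(2000, categoricalRegressionTest(rnorm(40), cls)$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("template correlations use the t transform and flag degenerates", {
  template <- c(1, 2, 3, 4, 5)
  profiles <- rbind(same = template,
                    close = c(1, 2, 3, 4, 6),
                    flat = rep(2, 5))
  out <- templateCorrelations(template, profiles)
  expect_equal(out$r[1], 1)
  expect_equal(out$p[1], .Machine$double.xmin)
  expect_equal(out$r[2], 12 / sqrt(148))       # direct covariance oracle
  expect_true(out$flagged[3])
  expect_true(is.na(out$r[3]))
  # BH over the usable features only
  expect_equal(out$p_adj[1:2], bhAdjust(out$p[1:2]))

  orth <- templateCorrelations(c(1, -1, 1, -1), rbind(p = c(1, 1, -1, -1)))
  expect_equal(orth$r[1], 0)
  expect_equal(orth$p[1], 1)
})

test_that("template-correlation P-values are calibrated under the null", {
  set.seed(99)
  template <- rnorm(30)
  profiles <- matrix(rnorm(2000 * 30), 2000, 30)
  ps <- templateCorrelations(template, profiles)$p
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("scale-and-shift fitting maps each profile onto the template", {
  template <- c(1, 2, 3, 4, 5)
  profiles <- rbind(ident = template,
                    affine = (template - 3) / 2,
                    flat = rep(7, 5))
  fit <- scaleShiftFit(template, profiles)
  co <- fit$coefficients
  expect_equal(co$a, c(1, 2, 0))
  expect_equal(co$b, c(0, 3, mean(template)))
  expect_identical(co$flagged, c(FALSE, FALSE, TRUE))
  expect_equal(unname(fit$fitted[1, ]), template)
  expect_equal(unname(fit$fitted[2, ]), template)
  expect_equal(unname(fit$fitted[3, ]), rep(3, 5))
})

test_that("group tests per time point reproduce the pooled t oracle", {
  fitted <- rbind(c(1, 2), c(2, 3), c(3, 4))
  fits <- list(fitted = fitted)
  out <- groupwiseTimepointTest(fits, groups = c("ctrl", "trt"),
                                times = c(1, 1))
  expect_equal(out$statistic, -sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(out$df, 4)
  expect_equal(out$p, 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-10)

  same <- list(fitted = cbind(c(1, 2, 3), c(1, 2, 3)))
  o2 <- groupwiseTimepointTest(same, c("a", "b"), c(5, 5))
  expect_equal(o2$statistic, 0)
  expect_equal(o2$p, 1)

  tri <- list(fitted = cbind(c(1, 2), c(1, 2), c(1, 2)))
  o3 <- groupwiseTimepointTest(tri, c("a", "b", "c"), c(1, 1, 1))
  expect_equal(o3$statistic, 0)
  expect_equal(o3$p, 1)
})

test_that("three-group time points fall back to the class-means F test", {
  set.seed(12)
  fitted <- matrix(rnorm(5 * 6), 5, 6)
  groups <- rep(c("P", "D", "NP"), each = 2)
  times <- rep(c(1, 2), times = 3)
  out <- groupwiseTimepointTest(list(fitted = fitted), groups, times)
  expect_identical(nrow(out), 2L)
  # oracle at time 1: categorical regression over the flattened values
  sel <- times == 1
  y <- as.vector(fitted[, sel])
  lab <- rep(groups[sel], each = 5)
  expect_equal(out$p[1], categoricalRegressionTest(y, lab)$p,
               tolerance = 1e-12)
})

test_that("UPGMA pairing merges duplicated or sign-flipped vectors first", {
  set.seed(5)
  v <- rnorm(20)
  out <- upgmaPair(list(a = v, b = rnorm(20), dup = v, c = rnorm(20)))
  expect_equal(min(out$distance[upper.tri(out$distance)]), -1)
  expect_true(any(out$pairs$member1 == "a" & out$pairs$member2 == "dup" |
                    out$pairs$member1 == "dup" & out$pairs$member2 == "a"))
  expect_equal(out$pairs$height[1], -1)

  flip <- upgmaPair(list(u = v, negu = -v, w = rnorm(20)))
  expect_equal(flip$distance["u", "negu"], -1)

  expect_error(upgmaPair(list(a = rep(1, 5), b = rnorm(5))),
               "zero-variance")
})

test_that("UPGMA merges agree with a brute-force average-linkage oracle", {
  set.seed(71)
  vecs <- matrix(rnorm(4 * 25), 25, 4,
                 dimnames = list(NULL, paste0("v", 1:4)))
  out <- upgmaPair(vecs)
  oracle <- bruteUPGMA(out$distance)
  expect_equal(out$tree$height, oracle$heights, tolerance = 1e-12)
  # final two-way split matches
  memb <- cutree(out$tree, 2)
  split1 <- sort(unname(which(memb == memb[1])))
  oracleSplit <- oracle$partitions[[2]]
  expect_true(any(vapply(oracleSplit, identical, logical(1), split1)))
})

test_that("UPGMA output is invariant under vector sign flips", {
  set.seed(30)
  vecs <- matrix(rnorm(5 * 15), 15, 5,
                 dimnames = list(NULL, paste0("v", 1:5)))
  a <- upgmaPair(vecs)
  flipped <- vecs %*% diag(c(1, -1, 1, -1, -1))
  colnames(flipped) <- colnames(vecs)
  b <- upgmaPair(flipped)
  expect_equal(a$distance, b$distance)
  expect_equal(a$tree$merge, b$tree$merge)
})
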