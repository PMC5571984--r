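# Independent brute-force oracles used to check the package's fast paths.

# Literal Benjamini-Hochberg step-up: sort, multiply by n/rank, enforce
# monotonicity from the largest P downwards, cap at 1, restore input order.
bruteStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Naive average-linkage (UPGMA) agglomeration on a distance matrix:
# returns the merge heights and the cluster membership after each merge.
bruteUPGMA <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  D <- as.matrix(D)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  dmat <- matrix(NA_real_, n + (n - 1), n + (n - 1))
  dmat[seq_len(n), seq_len(n)] <- D
  diag(dmat) <- NA
  sizes <- c(rep(1, n), rep(NA, n - 1))
  alive <- seq_len(n)
  for (step in seq_len(n - 1)) {
    sub <- dmat[alive, alive, drop = FALSE]
    k <- which(sub == min(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    i <- alive[k[1]]; j <- alive[k[2]]
    heights[step] <- dmat[i, j]
    newid <- n + step
    clusters[[newid]] <- c(clusters[[i]], clusters[[j]])
    sizes[newid] <- sizes[i] + sizes[j]
    rest <- setdiff(alive, c(i, j))
    for (r in rest)
      dmat[newid, r] <- dmat[r, newid] <-
        (sizes[i] * dmat[i, r] + sizes[j] * dmat[j, r]) / sizes[newid]
    alive <- c(rest, newid)
    partitions[[step]] <- lapply(alive, function(a) sort(clusters[[a]]))
  }
  list(heights = heights, partitions = partitions)
}

# Dense contraction of a Type I tensor over its (last) shared mode.
contractLastMode <- function(arr) {
  d <- dim(arr)
  m <- length(d)
  apply(arr, seq_len(m - 1L), sum)
}

# Small random ViewMatrix with reproducible content.
randomView <- function(n, m, name = "v", seed = 1, prefix = name) {
  set.seed(seed)
  ViewMatrix(matrix(rnorm(n * m), n, m),
             featureIds = paste0(prefix, "_f", seq_len(n)),
             sampleIds = paste0("s", seq_len(m)), name = name)
}

# A Case I pair of views with matched sample IDs.
randomCaseISet <- function(n1, n2, m, seed = 1) {
  set.seed(seed)
  v1 <- ViewMatrix(matrix(rnorm(n1 * m), n1, m),
                   featureIds = paste0("a_f", seq_len(n1)),
                   sampleIds = paste0("s", seq_len(m)), name = "A")
  v2 <- ViewMatrix(matrix(rnorm(n2 * m), n2, m),
                   featureIds = paste0("b_f", seq_len(n2)),
                   sampleIds = paste0("s", seq_len(m)), name = "B")
  MultiViewSet(list(v1, v2), case = "shared_samples")
}
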