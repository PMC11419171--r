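test_that("affinity matrix is block-diagonal for separated duplicate groups", {
  X <- rbind(matrix(0, 6, 8), matrix(1, 6, 8))
  A <- affinity_matrix(X, neighbors = 3)
  A <- as.matrix(A)
  expect_true(isSymmetric(A))
  expect_true(all(A[1:6, 7:12] == 0))
  expect_true(all(diag(crossprod(A)) > 0))  # nobody isolated
  # complete graph at k = n - 1
  Afull <- as.matrix(affinity_matrix(X, neighbors = nrow(X) - 1))
  expect_true(all(Afull[upper.tri(Afull)] == 1))
})

test_that("affinity is equivariant under consistent row permutation", {
  set.seed(3)
  X <- matrix(rbinom(20 * 6, 1, 0.4), 20, 6)
  perm <- sample(nrow(X))
  A <- as.matrix(affinity_matrix(X, neighbors = 4))
  Ap <- as.matrix(affinity_matrix(X[perm, ], neighbors = 4))
  expect_equal(Ap, A[perm, perm], ignore_attr = TRUE)
})

test_that("spectral labels equal graph connected components when components == K", {
  # random block graphs; brute-force component oracle from igraph
  for (seed in 1:20) {
    withr::with_seed(seed, {
      K <- sample(2:5, 1)
      sizes <- sample(5:15, K, replace = TRUE)
      n <- sum(sizes)
      comp <- rep(seq_len(K), times = sizes)
      A <- matrix(0, n, n)
      for (k in seq_len(K)) {
        idx <- which(comp == k)
        block <- matrix(rbinom(length(idx)^2, 1, 0.6), length(idx))
        block <- 1 * ((block + t(block)) > 0)
        diag(block) <- 0
        # ensure connectivity within the block via a path
        for (i in seq_along(idx)[-1]) block[i - 1, i] <- block[i, i - 1] <- 1
        A[idx, idx] <- block
      }
    })
    fit <- suppressWarnings(
      spectral_cluster(matrix(0, n, 2), K, affinity = Matrix::Matrix(A, sparse = TRUE)))
    oracle <- igraph::components(
      igraph::graph_from_adjacency_matrix(A, mode = "undirected"))$membership
    expect_equal(ari_oracle(fit$labels, oracle), 1)
  }
})

test_that("duplicated rows stay co-members and planted subtypes are recovered", {
  pf <- planted_features(60, K = 3, J = 12, seed = 11)
  fit <- spectral_cluster(pf$X, 3, neighbors = 10)
  expect_gt(ari_oracle(fit$labels, pf$labels), 0.9)
  expect_equal(ncol(fit$embedding), 3)
  # duplicate every row: duplicates must share a label
  Xd <- pf$X[rep(seq_len(nrow(pf$X)), each = 2), ]
  fit_d <- spectral_cluster(Xd, 3, neighbors = 10)
  odd <- fit_d$labels[seq(1, length(fit_d$labels), 2)]
  even <- fit_d$labels[seq(2, length(fit_d$labels), 2)]
  expect_gt(mean(odd == even), 0.99)
  expect_error(spectral_cluster(pf$X, nrow(pf$X) + 1), "exceeds")
})

test_that("k-means finds the exact split of two separated masses with minimal SSE", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
               matrix(rnorm(40, 10, 0.1), 20, 2))
  })
  fit <- baseline_cluster(X, "kmeans", K = 2, seed = 1)
  truth <- rep(1:2, each = 20)
  expect_equal(ari_oracle(fit$labels, truth), 1)
  # SSE equals the within-mass SSE of the true partition
  sse_true <- distortion_score(X, truth)
  expect_equal(distortion_score(X, fit$labels), sse_true, tolerance = 1e-8)
})

test_that("hierarchical clustering at K = n gives singletons with zero distortion", {
  set.seed(2)
  X <- matrix(rbinom(60, 1, 0.5), 12, 5)
  X <- X[!duplicated(X), , drop = FALSE]
  fit <- baseline_cluster(X, "hierarchical", K = nrow(X))
  expect_equal(fit$n_clusters_found, nrow(X))
  expect_equal(distortion_score(X, fit$labels), 0)
})

test_that("dbscan clusters a tight mass without noise and degrades to 0 clusters", {
  X <- matrix(0, 10, 4)  # identical points: one dense cluster
  fit <- baseline_cluster(X, "dbscan", eps = 0.5, min_samples = 3)
  expect_equal(fit$n_clusters_found, 1)
  expect_true(all(fit$labels == 1))
  # two distant masses
  X2 <- rbind(matrix(0, 8, 4), matrix(1, 8, 4))
  fit2 <- baseline_cluster(X2, "dbscan", eps = 0.5, min_samples = 3)
  expect_equal(fit2$n_clusters_found, 2)
  # eps too small for sparse unique points -> all noise, no exception
  X3 <- diag(8) * 5
  fit3 <- baseline_cluster(X3, "dbscan", eps = 0.5, min_samples = 3)
  expect_equal(fit3$n_clusters_found, 0)
  expect_true(all(fit3$labels == -1))
})

test_that("silhouette matches a brute-force hand computation and its boundaries", {
  # perfect separation of duplicated points: a = 0 everywhere -> score 1
  X <- rbind(matrix(0, 4, 3), matrix(5, 4, 3))
  lab <- rep(1:2, each = 4)
  expect_equal(silhouette_score(X, lab), 1)
  # 6-point hand-checkable configuration
  X6 <- matrix(c(0, 0, 1, 0, 0, 1, 4, 4, 5, 4, 4, 5), 6, 2, byrow = TRUE)
  lab6 <- rep(1:2, each = 3)
  D6 <- as.matrix(dist(X6, method = "manhattan"))
  expect_equal(silhouette_score(X6, lab6), silhouette_oracle(D6, lab6),
               tolerance = 1e-12)
  # random labels on exchangeable data hover near zero
  withr::with_seed(8, {
    Xr <- matrix(rbinom(200 * 6, 1, 0.5), 200, 6)
    labr <- sample(1:2, 200, replace = TRUE)
  })
  expect_lt(abs(silhouette_score(Xr, labr)), 0.05)
  expect_error(silhouette_score(X, rep(1, 8)), "undefined")
})

test_that("distortion and evenness follow their closed forms", {
  expect_equal(distortion_score(matrix(c(0, 1)), c(1, 1)), 0.5)  # centroid 0.5
  expect_equal(distortion_score(matrix(c(0, 1)), c(1, 2)), 0)    # singletons
  expect_equal(evenness_score(rep(1:4, each = 5)), 0)
  # reference cluster sizes 441/686/1151/796/1004: (1151-441)/4078
  sizes <- c(441, 686, 1151, 796, 1004)
  expect_equal(evenness_score(rep(1:5, times = sizes)), (1151 - 441) / 4078,
               tolerance = 1e-12)
  expect_equal(evenness_score(rep(1, 10)), 0)  # K = 1 boundary
})

test_that("metrics are invariant to cluster relabeling and row permutation", {
  pf <- planted_features(25, K = 3, J = 8, seed = 13)
  lab <- pf$labels
  relab <- c(3L, 1L, 2L)[lab]
  perm <- withr::with_seed(1, sample(length(lab)))
  for (f in list(silhouette_score, distortion_score)) {
    expect_equal(f(pf$X, lab), f(pf$X, relab), tolerance = 1e-12)
    expect_equal(f(pf$X, lab), f(pf$X[perm, ], lab[perm]), tolerance = 1e-12)
  }
  expect_equal(evenness_score(lab), evenness_score(relab))
})

test_that("k-means best-of-restarts distortion is non-increasing in K", {
  pf <- planted_features(30, K = 3, J = 10, seed = 17)
  d <- vapply(2:8, function(K)
    distortion_score(pf$X, baseline_cluster(pf$X, "kmeans", K = K,
                                            n_restarts = 10, seed = K)$labels),
    numeric(1))
  expect_true(all(diff(d) <= 1e-8))
})
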