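#' Symmetrized k-nearest-neighbour affinity matrix
#'
#' Connectivity graph under Manhattan distance: an edge joins `i` and `j`
#' iff `i` is among the `neighbors` nearest points of `j` or vice versa.
#' Duplicated rows are at distance zero and always end up connected.
#' Manhattan distance on 0/1 feature vectors equals the Hamming count, so
#' the same metric serves the affinity, silhouette and KNN-transfer steps.
#'
#' @param X numeric matrix (subjects x features), or a precomputed
#'   symmetric distance matrix via `dist_matrix`.
#' @param neighbors neighbourhood size (default 25); `nrow(X) - 1` gives
#'   the complete graph.
#' @param dist_matrix optional precomputed Manhattan distance matrix.
#' @return sparse symmetric 0/1 affinity matrix (`Matrix::dgCMatrix`).
#' @export
affinity_matrix <- function(X, neighbors = 25, dist_matrix = NULL) {
  D <- dist_matrix %||% manhattan_matrix(X)
  n <- nrow(D)
  if (n < 2) stop("affinity needs at least 2 subjects", call. = FALSE)
  k <- min(neighbors, n - 1)
  diag(D) <- Inf
  # all points tied with the k-th distance are included, so the graph does
  # not depend on row order (exact ties are common on binary features)
  nbr <- lapply(seq_len(n), function(i) {
    kth <- sort(D[i, ], partial = k)[k]
    which(D[i, ] <= kth)
  })
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), lengths(nbr)),
                            j = unlist(nbr), x = 1, dims = c(n, n))
  A <- A + Matrix::t(A)
  A@x[] <- 1
  A
}

spectral_embedding <- function(A, K, seed = 1) {
  n <- nrow(A)
  d <- pmax(Matrix::rowSums(A), 1e-12)
  M <- Matrix::Diagonal(x = 1 / sqrt(d)) %*% A %*% Matrix::Diagonal(x = 1 / sqrt(d))
  if (n <= 400 || K >= n - 2) {
    e <- eigen(as.matrix(M), symmetric = TRUE)
    U <- e$vectors[, seq_len(K), drop = FALSE]
  } else {
    f <- function(x, extra) as.numeric(extra %*% x)
    # ARPACK draws its start vector from the R RNG; seed it for determinism
    r <- with_seed(seed, igraph::arpack(
      f, extra = M, sym = TRUE,
      options = list(n = n, nev = K, ncv = min(n, max(3 * K + 10, 30)),
                     which = "LA", maxiter = 10000)))
    V <- r$vectors
    if (is.null(dim(V))) V <- matrix(V, ncol = 1)
    U <- V[, order(r$values, decreasing = TRUE)[seq_len(K)], drop = FALSE]
  }
  U / pmax(sqrt(rowSums(U^2)), 1e-12)
}

# Column-pivoted-QR cluster assignment in eigenvector space.
# Picks K maximally independent rows as cluster representatives, rotates
# the embedding onto them, and assigns each point to its dominant column.
qr_assign <- function(U) {
  K <- ncol(U)
  piv <- qr(t(U), LAPACK = TRUE)$pivot[seq_len(K)]
  R <- t(U[piv, , drop = FALSE])
  if (rcond(R) < 1e-10) return(NULL)  # ill-conditioned; caller falls back
  s <- svd(R)
  max.col(abs(U %*% (s$u %*% t(s$v))), ties.method = "first")
}

#' Spectral clustering of a binary phenotype matrix
#'
#' Symmetric normalized Laplacian of the kNN affinity graph; the `K`
#' eigenvectors of smallest Laplacian eigenvalue form the embedding, rows
#' are normalized to unit length, and clusters are assigned in eigenspace
#' by column-pivoted QR, with a seeded k-means fallback when the QR
#' representative system is ill-conditioned.
#'
#' @param X binary phenotype matrix.
#' @param K number of clusters (>= 2).
#' @param neighbors affinity neighbourhood size.
#' @param seed seed for the k-means fallback.
#' @param affinity optional precomputed affinity matrix.
#' @return object of class `endo_clustering`: list with `method`, `K`,
#'   `labels` (integer vector), `n_clusters_found`, `embedding`.
#' @export
spectral_cluster <- function(X, K, neighbors = 25, seed = 1, affinity = NULL) {
  if (K < 2) stop("spectral clustering needs K >= 2", call. = FALSE)
  if (K > nrow(X)) stop("K exceeds number of subjects", call. = FALSE)
  A <- affinity %||% affinity_matrix(X, neighbors)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected"))
  if (comp$no > K)
    warning(sprintf("affinity graph has %d components > K = %d; labels still returned",
                    comp$no, K))
  U <- spectral_embedding(A, K, seed = seed)
  labels <- qr_assign(U)
  if (is.null(labels)) {
    labels <- with_seed(seed, kmeans(U, centers = K, nstart = 10,
                                     iter.max = 100)$cluster)
  }
  structure(list(method = "spectral", K = K, labels = as.integer(labels),
                 n_clusters_found = length(unique(labels)),
                 embedding = U),
            class = "endo_clustering")
}

# k-means++ seeding (stats::kmeans has none); distances in Euclidean space
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- numeric(K)
  centers[1] <- sample.int(n, 1)
  d2 <- colSums((t(X) - X[centers[1], ])^2)
  for (k in seq_len(K - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[k + 1] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, colSums((t(X) - X[centers[k + 1], ])^2))
  }
  X[centers, , drop = FALSE]
}

#' Baseline clustering methods
#'
#' The three comparison methods run against spectral clustering:
#' * `kmeans`: k-means++ initialisation, `n_restarts` restarts, best SSE kept;
#' * `hierarchical`: agglomerative clustering cut at `K` (`average` and
#'   `complete` linkage use Manhattan distance, `ward` uses Euclidean);
#' * `dbscan`: standard density reachability; `K` is ignored and the number
#'   of clusters is inferred. Noise points get label `-1` and are excluded
#'   from quality metrics. An `eps` too small for any core point yields
#'   `n_clusters_found = 0`, not an error.
#'
#' @param X phenotype matrix.
#' @param method one of `"kmeans"`, `"hierarchical"`, `"dbscan"`.
#' @param K target cluster count (ignored by dbscan).
#' @param linkage hierarchical linkage (`average`, `complete`, `ward`).
#' @param eps,min_samples dbscan radius (Manhattan) and core-point minimum.
#' @param n_restarts k-means restarts.
#' @param seed seed for k-means initialisation.
#' @param dist_matrix optional precomputed Manhattan distance matrix.
#' @return an `endo_clustering` object.
#' @export
baseline_cluster <- function(X, method = c("kmeans", "hierarchical", "dbscan"),
                             K = 2, linkage = "average", eps = 2, min_samples = 5,
                             n_restarts = 10, seed = 1, dist_matrix = NULL) {
  method <- match.arg(method)
  labels <- switch(method,
    kmeans = {
      if (K > nrow(X)) stop("K exceeds number of subjects", call. = FALSE)
      with_seed(seed, {
        best <- NULL
        for (r in seq_len(n_restarts)) {
          fit <- suppressWarnings(
            kmeans(X, centers = kmeanspp_centers(X, K), iter.max = 100))
          if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
        }
        # stable relabeling: clusters numbered by first appearance
        match(best$cluster, unique(best$cluster))
      })
    },
    hierarchical = {
      if (linkage == "ward") {
        hc <- hclust(dist(X, method = "euclidean"), method = "ward.D2")
      } else {
        D <- dist_matrix %||% manhattan_matrix(X)
        hc <- hclust(stats::as.dist(D), method = linkage)
      }
      as.integer(cutree(hc, k = min(K, nrow(X))))
    },
    dbscan = dbscan_labels(dist_matrix %||% manhattan_matrix(X), eps, min_samples)
  )
  found <- length(setdiff(unique(labels), -1L))
  structure(list(method = method, K = if (method == "dbscan") found else K,
                 labels = as.integer(labels), n_clusters_found = found,
                 embedding = NULL),
            class = "endo_clustering")
}

# Classic DBSCAN on a precomputed distance matrix. Noise = -1.
dbscan_labels <- function(D, eps, min_samples) {
  stopifnot(eps > 0, min_samples >= 1)
  n <- nrow(D)
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))  # includes self
  core <- vapply(nbr, length, 1L) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbr[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nbr[[j]][labels[nbr[[j]]] == -1L])
      }
    }
  }
  labels
}

#' Clustering quality metrics
#'
#' `silhouette_score()` is the mean silhouette width `(b - a)/max(a, b)`
#' under Manhattan distance; `distortion_score()` is the within-cluster sum
#' of squared Euclidean errors about each centroid; `evenness_score()` is
#' the fractional difference between the largest and smallest cluster
#' sizes, `(max - min)/n`, minimized at perfectly balanced clusters.
#' DBSCAN noise points (label `-1`) are excluded throughout.
#'
#' @param X phenotype matrix (or embedding).
#' @param labels integer cluster labels.
#' @param dist_matrix optional precomputed Manhattan distance matrix.
#' @return a single numeric score.
#' @export
silhouette_score <- function(X, labels, dist_matrix = NULL) {
  keep <- labels != -1L
  labels <- labels[keep]
  if (length(unique(labels)) < 2)
    stop("silhouette undefined for fewer than 2 clusters", call. = FALSE)
  D <- dist_matrix %||% manhattan_matrix(X)
  D <- D[keep, keep, drop = FALSE]
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = D)
  mean(sil[, "sil_width"])
}

#' @rdname silhouette_score
#' @export
distortion_score <- function(X, labels) {
  keep <- labels != -1L
  X <- as.matrix(X)[keep, , drop = FALSE]
  labels <- labels[keep]
  sum(vapply(split(seq_along(labels), labels), function(ix) {
    ctr <- colMeans(X[ix, , drop = FALSE])
    sum(sweep(X[ix, , drop = FALSE], 2, ctr)^2)
  }, numeric(1)))
}

#' @rdname silhouette_score
#' @export
evenness_score <- function(labels) {
  labels <- labels[labels != -1L]
  if (!length(labels)) stop("no clustered points", call. = FALSE)
  sizes <- table(labels)
  as.numeric((max(sizes) - min(sizes)) / length(labels))
}

#' Cluster size summary
#'
#' Counts and percentage shares per cluster, formatted as in cohort
#' reports, e.g. `"441 (10.8%)"`.
#'
#' @param labels cluster labels.
#' @return data.frame (`cluster`, `n`, `pct`, `formatted`).
#' @export
cluster_size_table <- function(labels) {
  labels <- labels[labels != -1L]
  sizes <- table(labels)
  pct <- 100 * as.numeric(sizes) / length(labels)
  data.frame(cluster = names(sizes), n = as.integer(sizes), pct = pct,
             formatted = sprintf("%s (%.1f%%)",
                                 formatC(as.integer(sizes), big.mark = ","),
                                 pct))
}
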