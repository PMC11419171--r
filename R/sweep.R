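#' Model-selection sweep over clustering methods and K
#'
#' Runs each requested method across `K_range` (DBSCAN contributes a single
#' row with its inferred cluster count) and records the three selection
#' metrics: Manhattan silhouette, distortion (SSE on the feature matrix)
#' and evenness. Individual run failures are recorded as missing metrics
#' and the sweep continues. Deterministic under a fixed seed; the Manhattan
#' distance matrix and the spectral eigendecomposition are computed once
#' and shared across K.
#'
#' @param X binary phenotype matrix.
#' @param methods subset of `c("spectral", "kmeans", "hierarchical", "dbscan")`.
#' @param K_range integer vector of cluster counts (default 2:20).
#' @param seed integer seed.
#' @param neighbors spectral affinity neighbourhood size.
#' @param linkage hierarchical linkage.
#' @param eps,min_samples dbscan parameters.
#' @param n_restarts k-means restarts.
#' @return data.frame of class `endo_sweep` with columns `method`, `K`,
#'   `n_clusters_found`, `silhouette`, `distortion`, `evenness`.
#' @export
model_sweep <- function(X, methods = c("spectral", "kmeans", "hierarchical", "dbscan"),
                        K_range = 2:20, seed = 1, neighbors = 25,
                        linkage = "average", eps = 2, min_samples = 5,
                        n_restarts = 10) {
  stopifnot(nrow(X) > 1)
  D <- manhattan_matrix(X)
  A <- if ("spectral" %in% methods) affinity_matrix(X, neighbors, dist_matrix = D)
  Umax <- if ("spectral" %in% methods)
    spectral_embedding(A, min(max(K_range), nrow(X) - 1), seed = seed)
  rows <- list()
  score_run <- function(method, K, labels, found) {
    sil <- tryCatch(silhouette_score(X, labels, dist_matrix = D),
                    error = function(e) NA_real_)
    data.frame(method = method, K = K, n_clusters_found = found,
               silhouette = sil,
               distortion = tryCatch(distortion_score(X, labels),
                                     error = function(e) NA_real_),
               evenness = tryCatch(evenness_score(labels),
                                   error = function(e) NA_real_))
  }
  for (method in methods) {
    if (method == "dbscan") {
      run <- tryCatch(baseline_cluster(X, "dbscan", eps = eps,
                                       min_samples = min_samples,
                                       dist_matrix = D),
                      error = function(e) NULL)
      if (!is.null(run))
        rows[[length(rows) + 1]] <-
          score_run("dbscan", run$n_clusters_found, run$labels, run$n_clusters_found)
      next
    }
    for (K in K_range) {
      labels <- tryCatch({
        if (method == "spectral") {
          U <- Umax[, seq_len(K), drop = FALSE]
          U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
          lab <- qr_assign(U)
          if (is.null(lab))
            lab <- with_seed(seed + K, kmeans(U, centers = K, nstart = 10,
                                              iter.max = 100)$cluster)
          lab
        } else if (method == "kmeans") {
          baseline_cluster(X, "kmeans", K = K, n_restarts = n_restarts,
                           seed = seed + K)$labels
        } else {
          baseline_cluster(X, "hierarchical", K = K, linkage = linkage,
                           dist_matrix = D)$labels
        }
      }, error = function(e) NULL)
      rows[[length(rows) + 1]] <- if (is.null(labels)) {
        data.frame(method = method, K = K, n_clusters_found = NA_integer_,
                   silhouette = NA_real_, distortion = NA_real_,
                   evenness = NA_real_)
      } else {
        score_run(method, K, labels, length(setdiff(unique(labels), -1L)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("endo_sweep", "data.frame")
  out
}

# Strict interior local minima of y over an ordered grid, keeping only
# minima whose depth below both neighbours exceeds rel_tol * range(y).
prominent_local_minima <- function(K, y, rel_tol) {
  ok <- is.finite(y)
  K <- K[ok]; y <- y[ok]
  if (length(y) < 3) return(integer(0))
  o <- order(K); K <- K[o]; y <- y[o]
  rng <- diff(range(y))
  if (rng == 0) return(integer(0))
  i <- 2:(length(y) - 1)
  depth <- pmin(y[i - 1], y[i + 1]) - y[i]
  K[i][y[i] < y[i - 1] & y[i] < y[i + 1] & depth >= rel_tol * rng]
}

#' Select a clustering model from a sweep table
#'
#' Codifies the empirical selection procedure:
#' 1. exclude methods whose inferred cluster count exceeds
#'    `max_clusters` (catches DBSCAN blow-ups) or that never produced a
#'    valid multi-cluster run;
#' 2. rank the surviving methods by mean evenness (balanced clusters
#'    preferred);
#' 3. walk methods in that order and pick the first with a *prominent*
#'    strict interior local minimum of distortion over K (depth at least
#'    `prominence` of the curve's range — a "clear" minimum rather than
#'    sampling jitter);
#' 4. if no method shows one, fall back to the (method, K) with maximal
#'    silhouette.
#'
#' @param sweep an `endo_sweep` table.
#' @param max_clusters exclusion bound on inferred cluster count (default 20).
#' @param prominence relative depth a distortion local minimum must have
#'   (default 0.05 of the curve range).
#' @return list with `method`, `K`, `rule` (`"distortion_local_minimum"` or
#'   `"max_silhouette"`), and a human-readable `trace` of decisions.
#' @export
select_model <- function(sweep, max_clusters = 20, prominence = 0.05) {
  stopifnot(nrow(sweep) > 0)
  trace <- character(0)
  keep <- character(0)
  for (m in unique(sweep$method)) {
    rows <- sweep[sweep$method == m, ]
    kf <- rows$n_clusters_found
    if (all(is.na(kf)) || max(kf, na.rm = TRUE) < 2) {
      trace <- c(trace, sprintf("excluded %s: no valid multi-cluster run", m))
    } else if (any(kf > max_clusters, na.rm = TRUE)) {
      trace <- c(trace, sprintf(
        "excluded %s: inferred %d clusters > bound %d",
        m, max(kf, na.rm = TRUE), max_clusters))
    } else keep <- c(keep, m)
  }
  if (!length(keep))
    stop("no clustering method survives exclusions:\n",
         paste(trace, collapse = "\n"), call. = FALSE)
  ev <- vapply(keep, function(m)
    mean(sweep$evenness[sweep$method == m], na.rm = TRUE), numeric(1))
  keep <- keep[order(ev)]
  trace <- c(trace, sprintf("evenness ranking: %s",
                            paste(sprintf("%s=%.3f", keep, sort(ev)), collapse = ", ")))
  for (m in keep) {
    rows <- sweep[sweep$method == m & !is.na(sweep$K), ]
    if (nrow(rows) < 3) next
    mins <- prominent_local_minima(rows$K, rows$distortion, prominence)
    if (length(mins)) {
      Ksel <- mins[1]
      trace <- c(trace, sprintf(
        "%s shows a prominent distortion local minimum at K=%d", m, Ksel))
      return(list(method = m, K = as.integer(Ksel),
                  rule = "distortion_local_minimum", trace = trace))
    }
    trace <- c(trace, sprintf("%s: no prominent distortion local minimum", m))
  }
  cand <- sweep[sweep$method %in% keep & is.finite(sweep$silhouette), ]
  if (!nrow(cand))
    stop("no candidate with a finite silhouette:\n",
         paste(trace, collapse = "\n"), call. = FALSE)
  best <- cand[which.max(cand$silhouette), ]
  trace <- c(trace, sprintf(
    "fallback: max silhouette %.3f at %s K=%d", best$silhouette,
    best$method, best$K))
  list(method = best$method, K = as.integer(best$K),
       rule = "max_silhouette", trace = trace)
}
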