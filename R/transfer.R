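#' K-nearest-neighbour cluster label transfer
#'
#' `knn_model()` freezes the derivation cohort's feature matrix and cluster
#' labels; `knn_assign()` labels new endometriosis cases by majority vote
#' among the `k` nearest training points under Manhattan distance (equal to
#' the Hamming count on binary features).
#'
#' Tie rules (binary features make exact ties common, so they are explicit):
#' the neighbour set includes *all* training points tied with the k-th
#' distance; a tied majority vote falls back to the label of the single
#' nearest neighbour, with residual exact-distance ties broken toward the
#' smallest cluster label so results do not depend on training row order.
#'
#' @param X training feature matrix (e.g. the 17 clustering features).
#' @param labels training cluster labels.
#' @param k neighbour count (default 3).
#' @return object of class `endo_knn`.
#' @export
knn_model <- function(X, labels, k = 3) {
  stopifnot(k >= 1, nrow(X) == length(labels), !is.null(colnames(X)))
  structure(list(X = as.matrix(X), labels = as.integer(labels), k = as.integer(k),
                 metric = "manhattan"),
            class = "endo_knn")
}

#' @rdname knn_model
#' @param model an `endo_knn` model.
#' @param newX feature matrix for subjects to label; columns must match the
#'   training features by name and order.
#' @return data.frame (`subject_id`, `cluster`, `n_votes`,
#'   `mean_neighbor_distance`), one row per row of `newX`.
#' @export
knn_assign <- function(model, newX) {
  stopifnot(inherits(model, "endo_knn"))
  newX <- as.matrix(newX)
  if (is.null(colnames(newX)) || !identical(colnames(newX), colnames(model$X))) {
    unmatched <- union(setdiff(colnames(newX), colnames(model$X)),
                       setdiff(colnames(model$X), colnames(newX)))
    stop("feature columns do not match training features; unmatched: ",
         paste(if (length(unmatched)) unmatched else "(column order differs)",
               collapse = ", "), call. = FALSE)
  }
  D <- manhattan_matrix(newX, model$X)
  out <- data.frame(subject_id = rownames(newX) %||% seq_len(nrow(newX)),
                    cluster = NA_integer_, n_votes = NA_integer_,
                    mean_neighbor_distance = NA_real_)
  for (i in seq_len(nrow(newX))) {
    d <- D[i, ]
    kth <- sort(d, partial = model$k)[model$k]
    nb <- which(d <= kth)  # all points tied with the k-th distance included
    votes <- table(model$labels[nb])
    top <- as.integer(names(votes)[votes == max(votes)])
    cl <- if (length(top) == 1) top else {
      nearest_labels <- model$labels[nb[d[nb] == min(d[nb])]]
      cand <- intersect(sort(unique(nearest_labels)), top)
      if (length(cand)) cand[1] else min(nearest_labels)
    }
    out$cluster[i] <- cl
    out$n_votes[i] <- as.integer(votes[as.character(cl)])
    out$mean_neighbor_distance[i] <- mean(d[nb])
  }
  out
}
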