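# Deterministic k-nearest-neighbour prediction from a distance matrix.
# Distance ties resolve to the lowest column index; vote ties resolve by
# tie_order (default: factor level order). D is n_query x n_train.
knn_from_dist <- function(D, labels_train, k, tie_order = NULL) {
  D <- as.matrix(D)
  nq <- nrow(D)
  k <- min(k, ncol(D))
  lv <- levels(labels_train)
  if (is.null(tie_order)) tie_order <- lv
  if (!setequal(tie_order, lv)) stop("tie_order must permute the class levels")
  votes <- matrix(0L, nq, length(lv))
  Dw <- D
  rows <- seq_len(nq)
  for (s in seq_len(k)) {
    j <- max.col(-Dw, ties.method = "first")
    lab <- as.integer(labels_train[j])
    idx <- cbind(rows, lab)
    votes[idx] <- votes[idx] + 1L
    Dw[cbind(rows, j)] <- Inf
  }
  # subtract a sub-vote priority so earlier tie_order entries win ties
  priority <- match(lv, tie_order) * 1e-6
  win <- max.col(sweep(votes, 2L, priority, "-"), ties.method = "first")
  factor(lv[win], levels = lv)
}

# Leave-one-out knn error restricted to a selection of instances.
# D_full: precomputed full distance matrix; sel: integer indices.
loo_knn_error <- function(D_full, labels, sel, k) {
  D <- D_full[sel, sel, drop = FALSE]
  diag(D) <- Inf
  pred <- knn_from_dist(D, droplevels(labels[sel]), k)
  mean(pred != droplevels(labels[sel]))
}

# Error of the knn classifier induced by the selection, over ALL candidates:
# each candidate is classified by its k nearest selected instances, itself
# excluded when it is selected (so the selected rows are scored
# leave-one-out and the unselected rows as held-out points).
induced_knn_error <- function(D_full, labels, sel, k) {
  D <- D_full[, sel, drop = FALSE]
  self <- match(seq_len(nrow(D_full)), sel)
  hit <- which(!is.na(self))
  D[cbind(hit, self[hit])] <- Inf
  pred <- knn_from_dist(D, droplevels(labels[sel]), k)
  mean(as.character(pred) != as.character(labels))
}
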