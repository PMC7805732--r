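# Minimal CART decision tree (Gini impurity, axis-aligned splits), the
# comparison classifier for the k-NN grader. Fully deterministic: candidate
# thresholds are midpoints between consecutive distinct feature values, and
# equally good splits are resolved by lowest feature index, then lowest
# threshold.

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) {
    return(0)
  }
  1 - sum((counts / n)^2)
}

best_split <- function(x, y_int, n_classes) {
  n <- length(y_int)
  parent_counts <- tabulate(y_int, n_classes)
  parent_gini <- gini_impurity(parent_counts)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xv <- x[ord, j]
    yv <- y_int[ord]
    if (xv[1] == xv[n]) {
      next
    }
    # Cumulative class counts left of each cut position.
    left <- matrix(0, n, n_classes)
    left[cbind(seq_len(n), yv)] <- 1
    left <- apply(left, 2, cumsum)
    cuts <- which(xv[-n] < xv[-1]) # split between positions i and i+1
    for (i in cuts) {
      lc <- left[i, ]
      rc <- parent_counts - lc
      w_gini <- (i * gini_impurity(lc) + (n - i) * gini_impurity(rc)) / n
      gain <- parent_gini - w_gini
      thr <- (xv[i] + xv[i + 1]) / 2
      if (gain > 1e-12 &&
          (is.null(best) || gain > best$gain + 1e-12 ||
           (abs(gain - best$gain) <= 1e-12 &&
            (j < best$feature ||
             (j == best$feature && thr < best$threshold))))) {
        best <- list(feature = j, threshold = thr, gain = gain)
      }
    }
  }
  best
}

leaf_label <- function(y_int, n_classes) {
  counts <- tabulate(y_int, n_classes)
  which(counts == max(counts))[1] # tie: lowest ordinal grade
}

grow_tree <- function(x, y_int, depth, max_depth, min_split, n_classes) {
  if (length(unique(y_int)) == 1L || length(y_int) < min_split ||
      depth >= max_depth) {
    return(list(leaf = TRUE, label = leaf_label(y_int, n_classes),
                n = length(y_int)))
  }
  sp <- best_split(x, y_int, n_classes)
  if (is.null(sp)) {
    return(list(leaf = TRUE, label = leaf_label(y_int, n_classes),
                n = length(y_int)))
  }
  go_left <- x[, sp$feature] <= sp$threshold
  list(
    leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
    n = length(y_int),
    left = grow_tree(x[go_left, , drop = FALSE], y_int[go_left],
                     depth + 1L, max_depth, min_split, n_classes),
    right = grow_tree(x[!go_left, , drop = FALSE], y_int[!go_left],
                      depth + 1L, max_depth, min_split, n_classes)
  )
}

tree_depth <- function(node) {
  if (node$leaf) {
    return(0L)
  }
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' Fit a CART decision tree on Hu features
#'
#' Binary CART with Gini impurity and axis-aligned splits at feature
#' midpoints, depth-limited. Deterministic given the input order: split
#' ties go to the lowest feature index, then the lowest threshold; leaf
#' label ties go to the lowest ordinal grade.
#'
#' @inheritParams knn_fit
#' @param max_depth Maximum tree depth (default 8).
#' @param min_split Minimum node size to attempt a split (default 2).
#' @return An object of class `kl_tree`.
#' @export
decision_tree_fit <- function(train, labels = NULL, max_depth = 8L,
                              min_split = 2L) {
  x <- as_feature_matrix(train)
  y <- extract_labels(train, labels)
  if (length(y) != nrow(x)) {
    stop_invalid("number of labels must match number of feature rows")
  }
  if (nrow(x) < 2) {
    stop_invalid("need at least 2 training samples")
  }
  if (max_depth < 1 || max_depth != round(max_depth)) {
    stop_invalid("`max_depth` must be a positive integer")
  }
  root <- grow_tree(x, as.integer(y), 0L, as.integer(max_depth),
                    as.integer(min_split), length(kl_grades()))
  structure(
    list(root = root, max_depth = as.integer(max_depth),
         depth = tree_depth(root), n = nrow(x)),
    class = "kl_tree"
  )
}

#' @export
print.kl_tree <- function(x, ...) {
  cat(sprintf("<kl_tree> n = %d, depth = %d (max %d)\n",
              x$n, x$depth, x$max_depth))
  invisible(x)
}

#' Predict KL grades with a fitted decision tree
#'
#' @param model A [decision_tree_fit()] model.
#' @param query Data frame / matrix of feature rows, or one named feature
#'   vector.
#' @return Ordered factor of predicted KL grades.
#' @export
tree_predict <- function(model, query) {
  if (!inherits(model, "kl_tree")) {
    stop_invalid("`model` must be a kl_tree")
  }
  q <- as_feature_matrix(query)
  lv <- kl_grades()
  out <- integer(nrow(q))
  for (i in seq_len(nrow(q))) {
    node <- model$root
    while (!node$leaf) {
      node <- if (q[i, node$feature] <= node$threshold) node$left
              else node$right
    }
    out[i] <- node$label
  }
  kl_grade(lv[out])
}
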