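# k-nearest-neighbour grading of Hu feature vectors.
#
# Distances, neighbour selection and all tie-breaks are explicit contracts
# so predictions are reproducible and checkable against an exhaustive
# brute-force oracle: neighbours are ordered by (distance, training-row
# index); vote ties are broken by the smallest summed neighbour distance,
# then by the lowest ordinal grade.

feature_cols <- function() paste0("phi", 1:7)

# Accepts a tibble/data.frame with phi1..phi7 columns, a numeric matrix, or
# a single named feature vector; returns an n x 7 matrix.
as_feature_matrix <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  }
  if (is.data.frame(x)) {
    cols <- intersect(feature_cols(), names(x))
    if (length(cols) != 7L) {
      stop_invalid("feature data must contain columns phi1 ... phi7")
    }
    x <- as.matrix(x[, feature_cols()])
  }
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 7L) {
    stop_invalid("features must form an n x 7 numeric matrix (phi1..phi7)")
  }
  if (any(!is.finite(x))) {
    stop_invalid("feature matrix contains non-finite values")
  }
  colnames(x) <- feature_cols()
  x
}

extract_labels <- function(data, labels) {
  if (is.null(labels)) {
    if (!is.data.frame(data) || !"grade" %in% names(data)) {
      stop_invalid("supply `labels` or a data frame with a `grade` column")
    }
    labels <- data$grade
  }
  kl_grade(labels)
}

#' Fit a k-nearest-neighbour KL grading model
#'
#' Stores the (optionally per-feature standardised) training feature matrix
#' and labels. Standardisation is on by default because the seven Hu
#' invariants span several orders of magnitude, and an unstandardised
#' Euclidean distance would be dominated by `phi1`.
#'
#' @param train Data frame with columns `phi1` ... `phi7` and `grade`, or
#'   an n x 7 numeric matrix (then supply `labels`).
#' @param labels KL grade labels, if `train` is a matrix.
#' @param k Number of neighbours (default 3).
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @param standardize Standardise each feature to zero mean / unit variance
#'   using the training data (default `TRUE`).
#' @return An object of class `knn_model`.
#' @export
#' @examples
#' feats <- generate_feature_dataset(n_per_grade = 3, seed = 1)
#' model <- knn_fit(feats, k = 1)
#' knn_predict(model, feats[1, ])
knn_fit <- function(train, labels = NULL, k = 3L,
                    metric = c("euclidean", "manhattan"),
                    standardize = TRUE) {
  metric <- match.arg(metric)
  x <- as_feature_matrix(train)
  y <- extract_labels(train, labels)
  if (length(y) != nrow(x)) {
    stop_invalid("number of labels must match number of feature rows")
  }
  if (k < 1 || k != round(k)) {
    stop_invalid("`k` must be a positive integer")
  }
  if (k > nrow(x)) {
    stop_invalid("`k` cannot exceed the number of training samples")
  }
  center <- rep(0, 7)
  scale <- rep(1, 7)
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale, "/")
  }
  structure(
    list(x = x, y = y, k = as.integer(k), metric = metric,
         standardize = standardize, center = center, scale = scale),
    class = "knn_model"
  )
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> n = %d, k = %d, metric = %s, standardized = %s\n",
              nrow(x$x), x$k, x$metric, x$standardize))
  invisible(x)
}

knn_distances <- function(model, q) {
  d <- sweep(model$x, 2, q)
  switch(model$metric,
    euclidean = sqrt(rowSums(d^2)),
    manhattan = rowSums(abs(d))
  )
}

#' Predict KL grades with a fitted k-NN model
#'
#' Majority vote among the `k` nearest training samples. Neighbours are
#' ordered by distance with training-row index as the stable tie-break;
#' vote ties are resolved by the smallest summed neighbour distance, then
#' by the lowest ordinal grade.
#'
#' @param model A [knn_fit()] model.
#' @param query Data frame / matrix of feature rows, or one named feature
#'   vector.
#' @return Ordered factor of predicted KL grades, one per query row.
#' @export
knn_predict <- function(model, query) {
  if (!inherits(model, "knn_model")) {
    stop_invalid("`model` must be a knn_model")
  }
  q <- as_feature_matrix(query)
  if (model$standardize) {
    q <- sweep(sweep(q, 2, model$center), 2, model$scale, "/")
  }
  lv <- kl_grades()
  out <- character(nrow(q))
  for (i in seq_len(nrow(q))) {
    d <- knn_distances(model, q[i, ])
    nb <- order(d)[seq_len(model$k)] # order() is a stable sort: index ties
    votes <- table(factor(as.character(model$y[nb]), levels = lv))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(g) {
        sum(d[nb][as.character(model$y[nb]) == g])
      }, numeric(1))
      top <- top[sums == min(sums)]
      # Remaining ties: lowest ordinal grade (levels are severity-ordered).
      top <- top[which.min(match(top, lv))]
    }
    out[i] <- top
  }
  kl_grade(out)
}
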