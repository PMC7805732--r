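# Stratified two-fold cross-validation of the KL grading classifiers.

#' Two-fold cross-validated grading
#'
#' Splits the labelled feature set into two stratified random halves
#' (seeded), predicts each half with a model trained on the other, and
#' pools the predictions into one 5x5 confusion matrix (rows = predicted,
#' columns = expert truth).
#'
#' @param data Data frame with columns `phi1` ... `phi7` and `grade`
#'   (optionally `image_id`).
#' @param classifier `"knn"` (default) or `"tree"`.
#' @param k,metric,standardize k-NN configuration, see [knn_fit()].
#' @param max_depth Tree depth cap, see [decision_tree_fit()].
#' @param seed Integer seed for the stratified split.
#' @return An object of class `kl_cv`: list with `confusion`
#'   ([as_kl_confusion()]), `accuracy`, `predictions` (tibble with `fold`,
#'   `truth`, `pred`), `classifier`, `config` and `seed`.
#' @export
#' @examples
#' feats <- generate_feature_dataset(n_per_grade = 4, seed = 3)
#' cv <- two_fold_cv(feats, seed = 1)
#' cv$accuracy
two_fold_cv <- function(data, classifier = c("knn", "tree"), k = 3L,
                        metric = "euclidean", standardize = TRUE,
                        max_depth = 8L, seed = 1L) {
  classifier <- match.arg(classifier)
  x <- as_feature_matrix(data)
  y <- extract_labels(data, NULL)
  counts <- table(y)
  if (any(counts < 2)) {
    stop_invalid(paste0(
      "every grade needs >= 2 samples for 2-fold CV; short: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (g in kl_grades()) {
      idx <- which(as.character(y) == g)
      idx <- idx[sample.int(length(idx))]
      half <- ceiling(length(idx) / 2)
      fold[idx[seq_len(half)]] <- 1L
      fold[idx[-seq_len(half)]] <- 2L
    }
  })
  pred <- character(length(y))
  for (f in 1:2) {
    train_i <- fold != f
    test_i <- fold == f
    if (classifier == "knn") {
      model <- knn_fit(x[train_i, , drop = FALSE], labels = y[train_i],
                       k = k, metric = metric, standardize = standardize)
      pred[test_i] <- as.character(knn_predict(model,
                                               x[test_i, , drop = FALSE]))
    } else {
      model <- decision_tree_fit(x[train_i, , drop = FALSE],
                                 labels = y[train_i], max_depth = max_depth)
      pred[test_i] <- as.character(tree_predict(model,
                                                x[test_i, , drop = FALSE]))
    }
  }
  cm <- confusion_from_predictions(pred, y)
  config <- if (classifier == "knn") {
    list(k = k, metric = metric, standardize = standardize)
  } else {
    list(max_depth = max_depth)
  }
  structure(
    list(confusion = cm,
         accuracy = overall_accuracy(cm),
         predictions = tibble::tibble(
           fold = fold, truth = y, pred = kl_grade(pred)
         ),
         classifier = classifier, config = config, seed = as.integer(seed)),
    class = "kl_cv"
  )
}

#' @export
print.kl_cv <- function(x, ...) {
  cat(sprintf("<kl_cv> %s, n = %d, pooled accuracy = %.4f (seed %d)\n",
              x$classifier, sum(x$confusion), x$accuracy, x$seed))
  print(x$confusion)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x A [two_fold_cv()] result.
#' @param ... Unused.
#' @return Tibble of confusion-matrix cells: `predicted`, `expert`, `n`.
#' @method tidy kl_cv
#' @export
tidy.kl_cv <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x$confusion)))
  names(df) <- c("predicted", "expert", "n")
  tibble::as_tibble(df)
}

#' One-row summary of a cross-validation result
#'
#' @inheritParams tidy.kl_cv
#' @return Tibble with `classifier`, `n`, `accuracy`, `seed`.
#' @method glance kl_cv
#' @export
glance.kl_cv <- function(x, ...) {
  tibble::tibble(
    classifier = x$classifier,
    n = sum(x$confusion),
    accuracy = x$accuracy,
    seed = x$seed
  )
}
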