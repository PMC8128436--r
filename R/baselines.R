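#' Train a baseline regressor on flattened encoder features
#'
#' Baselines operate on the flattened binary tensors (the same matrices the
#' convolutional model consumes, without the spatial interpretation):
#'
#' * `"lasso"`: L1-penalised linear regression with the penalty chosen by
#'   internal cross-validation ([glmnet::cv.glmnet()]).
#' * `"svm"`: support vector regression with radial kernel
#'   ([e1071::svm()]).
#' * `"random_forest"`: [randomForest::randomForest()].
#'
#' @param kind one of `"lasso"`, `"svm"`, `"random_forest"`.
#' @param X encoded feature matrix from [batch_encode()].
#' @param y numeric activity labels.
#' @param seed integer seed (cross-validation folds, forest bootstraps).
#' @param ... passed to the underlying fitting function.
#' @return an `az_model`; predictions via [predict.az_model()].
#' @export
train_baseline <- function(kind = c("lasso", "svm", "random_forest"),
                           X, y, seed = 1L, ...) {
  kind <- match.arg(kind)
  meta <- check_encoded_matrix(X)
  if (nrow(X) != length(y)) {
    az_stop("az_shape_error", "nrow(X) = %d but length(y) = %d", nrow(X), length(y))
  }
  if (any(!is.finite(y))) az_stop("az_label_error", "labels must be finite")
  fit <- with_seed(seed, function() {
    switch(kind,
      lasso = glmnet::cv.glmnet(X, y, alpha = 1, ...),
      # binary features: no column scaling (constant columns are expected)
      svm = e1071::svm(x = X, y = y, kernel = "radial", scale = FALSE, ...),
      random_forest = randomForest::randomForest(x = X, y = y, ...)
    )
  })
  structure(list(kind = kind, fit = fit, meta = meta, seed = seed,
                 history = NULL),
            class = "az_model")
}
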