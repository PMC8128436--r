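# Accuracy metrics, splits, structure-stratified hold-out, and
# flow-cytometry-style normalisation.

#' R-squared between predicted and measured activities
#'
#' Reports both common readings of "R^2": the squared Pearson correlation
#' (`r2_pearson`, invariant to affine rescaling of the predictions) and the
#' coefficient of determination (`r2_cod = 1 - SS_res/SS_tot`, which
#' penalises calibration error). The squared correlation is the headline
#' value.
#'
#' @param predicted,measured numeric vectors of equal length (>= 2).
#' @return list of class `az_eval_report` with `r2_pearson`, `r2_cod`, `n`.
#' @export
r_squared <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(measured) < 2L) {
    az_stop("az_shape_error", "need two equal-length vectors with n >= 2")
  }
  if (any(!is.finite(predicted)) || any(!is.finite(measured))) {
    az_stop("az_label_error", "inputs must be finite")
  }
  if (sd(measured) == 0) {
    az_stop("az_degenerate_data", "measured values have zero variance")
  }
  # constant predictions carry no linear association: report 0, not NaN
  r2p <- if (sd(predicted) == 0) 0 else cor(predicted, measured)^2
  structure(list(
    r2_pearson = r2p,
    r2_cod = 1 - sum((measured - predicted)^2) / sum((measured - mean(measured))^2),
    n = length(measured)
  ), class = "az_eval_report")
}

#' @export
print.az_eval_report <- function(x, ...) {
  cat(sprintf("<az_eval_report> n = %d, R2 (Pearson^2) = %.3f, R2 (CoD) = %.3f\n",
              x$n, x$r2_pearson, x$r2_cod))
  invisible(x)
}

#' Random train/test split
#'
#' Seeded shuffle split; the training size is `round(n * train_frac)`
#' (round-half-up). Returns disjoint, exhaustive index sets.
#'
#' @param n number of records (or a data frame, whose row count is used).
#' @param train_frac fraction assigned to training, strictly in (0, 1).
#' @param seed RNG seed.
#' @return list with integer vectors `train` and `test`.
#' @export
split_train_test <- function(n, train_frac = 0.75, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 2L) az_stop("az_split_error", "need at least 2 records to split")
  if (!(train_frac > 0 && train_frac < 1)) {
    az_stop("az_split_error", "train_frac must be in (0, 1)")
  }
  n_train <- floor(n * train_frac + 0.5)
  n_train <- min(max(n_train, 1L), n - 1L)
  ord <- with_seed(seed, function() sample.int(n))
  list(train = sort(ord[seq_len(n_train)]), test = sort(ord[-seq_len(n_train)]))
}

#' Structural-segment hold-out evaluation
#'
#' Groups records by structural segment (identical structure key), holds
#' each qualifying segment out as a test set in turn, trains on all
#' remaining records, and reports per-segment accuracy. This measures how
#' well a model extrapolates to loop/stem geometries absent from its
#' training data.
#'
#' @param X encoded feature matrix (rows = records).
#' @param y numeric labels.
#' @param keys character vector of structure keys (e.g.
#'   `as.character(structure_key(...))`), one per record.
#' @param fit_fun function `(X_train, y_train) -> model`.
#' @param predict_fun function `(model, X_test) -> predictions` (default
#'   [predict()]).
#' @param min_segment_size segments smaller than this are never used as a
#'   test segment (they still contribute to training).
#' @return data frame with one row per evaluated segment (`segment`, `n`,
#'   `r2_pearson`, `r2_cod`); attribute `"folds"` records the train/test
#'   indices of every fold.
#' @export
segment_holdout <- function(X, y, keys, fit_fun, predict_fun = predict,
                            min_segment_size = 50L) {
  keys <- as.character(keys)
  stopifnot(nrow(X) == length(y), length(keys) == length(y))
  sizes <- table(keys)
  eligible <- names(sizes)[sizes >= min_segment_size]
  if (length(eligible) < 2L || length(unique(keys)) < 2L) {
    az_stop("az_holdout_error",
            "need at least 2 segments (>= %d eligible test segments of size >= %d)",
            2L, min_segment_size)
  }
  meta <- attr(X, "encoder")
  subset_rows <- function(idx) {
    Xs <- X[idx, , drop = FALSE]
    attr(Xs, "encoder") <- meta
    Xs
  }
  folds <- list()
  rows <- lapply(eligible, function(seg) {
    test_idx <- which(keys == seg)
    train_idx <- which(keys != seg)
    folds[[seg]] <<- list(train = train_idx, test = test_idx)
    model <- fit_fun(subset_rows(train_idx), y[train_idx])
    pred <- predict_fun(model, subset_rows(test_idx))
    rep <- r_squared(pred, y[test_idx])
    data.frame(segment = seg, n = rep$n, r2_pearson = rep$r2_pearson,
               r2_cod = rep$r2_cod, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  out
}

#' Normalised switch activities and activation ratio
#'
#' Normalises a switch's GFP/mCherry ratios to those of a non-cleaving
#' control ribozyme measured under the matching condition (uninduced by
#' uninduced control, induced by induced control), expressed in percent,
#' and computes the activation ratio (normalised induced over normalised
#' basal).
#'
#' @param uninduced_ratio,induced_ratio raw GFP/mCherry of the switch
#'   without and with ligand.
#' @param control_uninduced,control_induced raw GFP/mCherry of the inactive
#'   control under the two conditions; must be positive.
#' @return list of class `az_switch_measurement` with `normalized_basal`,
#'   `normalized_induced` (percent of control) and `activation_ratio`.
#' @export
normalize_and_ratio <- function(uninduced_ratio, induced_ratio,
                                control_uninduced, control_induced) {
  if (any(c(control_uninduced, control_induced) <= 0)) {
    az_stop("az_control_error", "control GFP/mCherry values must be positive")
  }
  basal <- 100 * uninduced_ratio / control_uninduced
  induced <- 100 * induced_ratio / control_induced
  structure(list(
    normalized_basal = basal,
    normalized_induced = induced,
    activation_ratio = induced / basal
  ), class = "az_switch_measurement")
}

#' Mean measured activity of the lowest-predicted records
#'
#' Selects the `n` records with the lowest predicted activity (stable order)
#' and averages their measured labels — the summary used to judge whether a
#' ranking enriches genuinely low-activity ribozymes.
#'
#' @param measured,predicted numeric vectors of equal length.
#' @param n how many lowest-predicted records to average (default 10).
#' @return mean measured activity of the selected records.
#' @export
mean_lowest_predicted <- function(measured, predicted, n = 10L) {
  if (length(measured) != length(predicted)) {
    az_stop("az_shape_error", "measured and predicted differ in length")
  }
  if (n > length(measured)) {
    az_stop("az_selection_error", "n = %d exceeds the %d available records",
            n, length(measured))
  }
  mean(measured[order(predicted)[seq_len(n)]])
}
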