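#' Min-max scale the feature columns of a table
#'
#' Maps every feature column linearly onto `[0, 1]` via
#' `(x - min(x)) / (max(x) - min(x))`; constant columns map to 0. Identifier
#' and label columns are left untouched. Scaling the full table once before
#' cross-validation matches the dataset-level normalisation the classifier
#' configurations assume; a strict train-fold-only variant is available in
#' [cross_validate()] for leakage-free comparisons.
#'
#' @param table A feature table (tibble); every numeric column other than
#'   `seed` is treated as a feature.
#' @return The table with scaled feature columns.
#' @export
minmax_scale <- function(table) {
  cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], "seed")
  dplyr::mutate(table, dplyr::across(
    dplyr::all_of(cols),
    function(x) {
      rng <- range(x)
      if (rng[2] - rng[1] < .Machine$double.eps) rep(0, length(x))
      else (x - rng[1]) / (rng[2] - rng[1])
    }
  ))
}

#' k-nearest-neighbour prediction
#'
#' Classifies each query row by majority vote among the `k` training rows
#' with the smallest Euclidean distance. `k` must be odd so that a
#' two-class vote cannot tie; distance ties are broken by the lower training
#' row index, making predictions deterministic.
#'
#' @param train Numeric matrix of training feature vectors (rows).
#' @param labels Vector of training class labels, one per row.
#' @param query Numeric matrix (or single vector) of query feature vectors.
#' @param k Odd neighbour count, at most `nrow(train)`.
#' @return Character vector of predicted labels, one per query row.
#' @export
knn_predict <- function(train, labels, query, k = 5) {
  train <- as.matrix(train)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  query <- as.matrix(query)
  if (nrow(train) == 0) stop("empty training set")
  if (k %% 2 == 0) stop("`k` must be odd to rule out vote ties")
  if (k > nrow(train)) stop("`k` exceeds the number of training rows")
  labels <- as.character(labels)
  # squared Euclidean distances, queries x training rows
  d2 <- outer(rowSums(query^2), rowSums(train^2), `+`) -
    2 * tcrossprod(query, train)
  apply(d2, 1, function(d) {
    nn <- order(d)[seq_len(k)] # stable order(): ties go to the lower index
    votes <- table(labels[nn])
    names(votes)[which.max(votes)]
  })
}

#' Assign rows to cross-validation folds
#'
#' Randomly permutes the rows (seeded) and deals them round-robin into `k`
#' folds, so fold sizes differ by at most one; 69 rows in 23 folds gives
#' folds of exactly 3.
#'
#' @param n Number of rows.
#' @param k Fold count (default 23).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`, length `n`.
#' @export
make_folds <- function(n, k = 23, seed = 1) {
  if (k > n) stop("`k` cannot exceed `n`")
  set.seed(seed)
  fold <- integer(n)
  fold[sample.int(n)] <- rep_len(seq_len(k), n)
  fold
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)` and accuracy
#' `Ac = (TP+TN)/(TP+TN+FP+FN)`, reported as percentages, plus the error
#' rate `theta = 1 - Ac/100` used as the genetic-algorithm fitness. A
#' metric with a zero denominator is reported as `NA`, not 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (positive class = CHF).
#' @return An object of class `hrv_cv`: the counts plus `Se`, `Sp`, `Ac`
#'   (percent) and `theta`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || sum(counts) == 0) stop("invalid confusion counts")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  ac <- 100 * (tp + tn) / sum(counts)
  structure(
    list(
      TP = tp, TN = tn, FP = fp, FN = fn,
      Se = pct(tp, tp + fn),
      Sp = pct(tn, tn + fp),
      Ac = ac,
      theta = 1 - ac / 100
    ),
    class = "hrv_cv"
  )
}

#' @export
print.hrv_cv <- function(x, ...) {
  cat(
    "KNN cross-validation metrics (positive class: CHF)\n",
    sprintf("  Ac = %.2f%%  Se = %.2f%%  Sp = %.2f%%  theta = %.6f\n",
            x$Ac, x$Se, x$Sp, x$theta),
    sprintf("  confusion: TP %d  TN %d  FP %d  FN %d\n",
            x$TP, x$TN, x$FP, x$FN),
    sep = ""
  )
  if (!is.null(x$mask)) {
    cat("  features: ", paste(x$features, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.hrv_cv <- function(x, ...) {
  tibble::tibble(
    metric = c("TP", "TN", "FP", "FN", "Se", "Sp", "Ac", "theta"),
    value = c(x$TP, x$TN, x$FP, x$FN, x$Se, x$Sp, x$Ac, x$theta)
  )
}

#' @export
glance.hrv_cv <- function(x, ...) {
  tibble::tibble(Ac = x$Ac, Se = x$Se, Sp = x$Sp, theta = x$theta,
                 n = x$TP + x$TN + x$FP + x$FN)
}

table_feature_cols <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))], "seed")
}

table_feature_matrix <- function(table) {
  cols <- table_feature_cols(table)
  if (length(cols) == 0) stop("feature table has no numeric feature columns")
  as.matrix(table[, cols])
}

#' k-fold cross-validated KNN performance of a feature subset
#'
#' Trains on `k - 1` folds and predicts the held-out fold, for every fold;
#' all test predictions are pooled into a single confusion matrix (with
#' folds of size 3, per-fold sensitivities are frequently undefined, so
#' pooling is the well-defined reading). CHF is the positive class. The
#' error rate `theta = 1 - correct/total` is the subset's fitness.
#'
#' @param table Feature table with a `label` column (`"NSR"`/`"CHF"`) and
#'   the 16 feature columns; scale it first with [minmax_scale()] for the
#'   standard configuration.
#' @param mask Logical (or 0/1) vector of length 16 selecting features, or
#'   `"all"`.
#' @param k Neighbour count for [knn_predict()] (default 5, odd).
#' @param folds Integer fold assignment from [make_folds()], or a fold
#'   count (a seeded [make_folds()] plan is then built with `seed`).
#' @param seed Seed used only when `folds` is given as a count.
#' @param scale_in_fold If `TRUE`, min-max scaling is re-fit on each
#'   training fold and applied to its test fold (leakage-free variant)
#'   instead of assuming a pre-scaled table.
#' @return An `hrv_cv` object (see [confusion_metrics()]) with the mask and
#'   selected feature names attached.
#' @export
cross_validate <- function(table, mask = "all", k = 5, folds = 23, seed = 1,
                           scale_in_fold = FALSE) {
  feats <- table_feature_cols(table)
  if (identical(mask, "all")) mask <- rep(TRUE, length(feats))
  mask <- as.logical(mask)
  if (length(mask) != length(feats)) {
    stop("`mask` length does not match the number of feature columns")
  }
  if (!any(mask)) stop("`mask` must select at least one feature")
  X <- table_feature_matrix(table)[, mask, drop = FALSE]
  y <- as.character(table$label)
  n <- nrow(X)
  if (length(folds) == 1) folds <- make_folds(n, k = folds, seed = seed)
  if (length(folds) != n) stop("fold assignment length does not match table")

  pred <- character(n)
  for (f in sort(unique(folds))) {
    te <- folds == f
    Xtr <- X[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (scale_in_fold) {
      rng_lo <- apply(Xtr, 2, min)
      rng_w <- apply(Xtr, 2, max) - rng_lo
      rng_w[rng_w < .Machine$double.eps] <- 1
      Xtr <- sweep(sweep(Xtr, 2, rng_lo), 2, rng_w, `/`)
      Xte <- sweep(sweep(Xte, 2, rng_lo), 2, rng_w, `/`)
    }
    pred[te] <- knn_predict(Xtr, y[!te], Xte, k = k)
  }
  out <- confusion_metrics(
    tp = sum(pred == "CHF" & y == "CHF"),
    tn = sum(pred == "NSR" & y == "NSR"),
    fp = sum(pred == "CHF" & y == "NSR"),
    fn = sum(pred == "NSR" & y == "CHF")
  )
  out$mask <- as.integer(mask)
  out$features <- feats[mask]
  out$k <- k
  out
}
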