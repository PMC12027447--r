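#' Stratified k-fold split
#'
#' Shuffles each label class under the seed and deals it round-robin into k
#' folds, so folds are disjoint, exhaustive, and label-balanced to within
#' one observation per class.
#'
#' @param labels 0/1 vector; `k` number of folds (>= 2); `seed` RNG seed.
#' @return list of `k` lists with integer index vectors `train`, `test`.
#' @export
kfold_split <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the dataset size")
  set.seed(as.integer(seed))
  fold_of <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall and F1 from binary predictions. A ratio with
#' a zero denominator is reported as 0 and named in the `"undefined"`
#' attribute rather than propagating NaN.
#'
#' @param y_true,y_pred binary vectors of equal length.
#' @return named list `accuracy`, `precision`, `recall`, `f1`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("inputs must be binary")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  acc <- ratio(tp + tn, tp + tn + fp + fn, "accuracy")
  prec <- ratio(tp, tp + fp, "precision")
  rec <- ratio(tp, tp + fn, "recall")
  f1 <- ratio(2 * prec * rec, prec + rec, "f1")
  out <- list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
  attr(out, "undefined") <- undefined
  out
}

#' Threshold-free metrics: AUC and AUPR
#'
#' AUC is the probability that a random positive outranks a random negative
#' (midranks for ties; equivalently the trapezoidal area under the ROC
#' curve). AUPR integrates precision over recall across the distinct-score
#' thresholds, ties grouped.
#'
#' @param y_true binary labels (both classes required); `y_score` real scores.
#' @return named list `auc`, `aupr`.
#' @export
threshold_free_metrics <- function(y_true, y_score) {
  if (length(y_true) != length(y_score)) stop("length mismatch")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC/AUPR")
  r <- rank(y_score)  # midranks
  auc <- (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # PR curve over distinct thresholds, descending
  ord <- order(-y_score)
  ys <- y_true[ord]; ss <- y_score[ord]
  grp_last <- which(!duplicated(ss, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(ys)[grp_last]
  pp <- grp_last  # predicted positives at each threshold
  prec <- tp / pp
  rec <- tp / n_pos
  aupr <- sum(diff(c(0, rec)) * prec)
  list(auc = auc, aupr = aupr)
}

#' k-fold cross-validated evaluation of the full pipeline
#'
#' Builds a balanced labelled pair dataset, splits it with stratified
#' k-fold, and per fold retrains the model from scratch on the training
#' pairs ([fit_gonnmda()], which rebuilds all association-derived features
#' and the message-passing graph from the training positives only), then
#' scores the held-out pairs. Confusion metrics use the 0.5 threshold.
#'
#' @param data pipeline input list (see [fit_gonnmda()]).
#' @param k number of folds.
#' @param config run configuration.
#' @param seed master seed; negative sampling, the split and each fold's
#'   fit derive their own streams from it.
#' @return list: `folds` (per-fold `y_true`, `y_score`, `metrics`),
#'   `summary` (data.frame of mean and sd per metric), `dataset`.
#' @export
run_cv <- function(data, k = 5L, config = default_config(), seed = 1L) {
  dataset <- build_pair_dataset(data$assoc, data$mirna_ids, data$disease_ids,
                                seed = derive_seed(seed, "negatives"))
  folds <- kfold_split(dataset$label, k, derive_seed(seed, "folds"))
  res <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- dataset[folds[[f]]$train, ]
    te <- dataset[folds[[f]]$test, ]
    model <- fit_gonnmda(data, tr, config, seed = derive_seed(seed, paste0("fold", f)))
    s <- score_pairs(model, te)
    cm <- confusion_metrics(te$label, as.integer(s >= 0.5))
    tf <- threshold_free_metrics(te$label, s)
    res[[f]] <- list(fold_id = f, y_true = te$label, y_score = s,
                     metrics = c(tf, cm))
  }
  met_names <- c("auc", "aupr", "accuracy", "precision", "recall", "f1")
  vals <- sapply(met_names, function(mn)
    vapply(res, function(r) r$metrics[[mn]], numeric(1)))
  vals <- matrix(vals, nrow = k, dimnames = list(NULL, met_names))
  summary <- data.frame(metric = met_names,
                        mean = colMeans(vals),
                        sd = apply(vals, 2L, stats::sd),
                        row.names = NULL)
  list(folds = res, summary = summary, dataset = dataset)
}
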