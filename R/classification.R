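# RBF-kernel SVM with stratified cross-validation, confusion-matrix
# metrics, rank-based AUC, and minimum-redundancy-maximum-relevance
# feature ranking.

#' Classifier configuration
#'
#' Settings of the RBF-kernel support-vector classifier: box constraint
#' (soft-margin cost) 1.7, automatic kernel scale, feature standardization
#' and 12-fold cross-validation by default.
#'
#' @param box_constraint Positive soft-margin cost C (default 1.7).
#' @param kernel_scale `"auto"` (median pairwise Euclidean distance on the
#'   standardized training fold) or a positive scalar s; the RBF kernel is
#'   `exp(-||u - v||^2 / s^2)`.
#' @param standardize Standardize features using training-fold means/SDs
#'   (default `TRUE`).
#' @param n_folds Number of cross-validation folds (default 12).
#' @param positive_class Class treated as positive for
#'   sensitivity/specificity (default `"patient"`).
#' @param group_by_subject If `TRUE`, folds are stratified over subjects
#'   rather than cycles, so no subject appears in both a training and a
#'   validation fold. Default `FALSE` (per-cycle folding, each gait cycle an
#'   independent case).
#' @param seed Seed for the fold assignment.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(box_constraint = 1.7, kernel_scale = "auto",
                              standardize = TRUE, n_folds = 12L,
                              positive_class = c("patient", "healthy"),
                              group_by_subject = FALSE, seed = 1L) {
  stopifnot(box_constraint > 0, n_folds >= 2L)
  if (!identical(kernel_scale, "auto")) {
    stopifnot(is.numeric(kernel_scale), kernel_scale > 0)
  }
  structure(list(
    box_constraint = box_constraint, kernel_scale = kernel_scale,
    standardize = standardize, n_folds = as.integer(n_folds),
    positive_class = match.arg(positive_class),
    group_by_subject = group_by_subject, seed = as.integer(seed)
  ), class = "classifier_config")
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin into folds.
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      ix <- which(y == cl)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  fold
}

#' Cross-validated RBF-SVM classification of gait cycles
#'
#' Trains a Gaussian-RBF support-vector machine on the selected feature
#' subset under stratified k-fold cross-validation. In every fold the
#' features are standardized with the training fold's means and SDs only;
#' `kernel_scale = "auto"` is resolved per fold as the median pairwise
#' Euclidean distance between standardized training samples. Validation
#' predictions are pooled across folds into a single confusion matrix;
#' decision scores are retained for the ROC/AUC.
#'
#' @param table Feature table from [build_feature_table()] (columns `label`
#'   and optionally `subject_id`).
#' @param feature_subset `"set1"`, `"set2"`, `"all"` or a character vector
#'   of feature column names.
#' @param config A [classifier_config()].
#'
#' @return Object of class `classifier_report`: list with pooled `tp`,
#'   `tn`, `fp`, `fn`, `accuracy`, `sensitivity`, `specificity` (percent),
#'   `auc`, `roc` (curve points), `per_fold` (data.frame of fold metrics),
#'   `predictions` (per-sample pooled validation predictions and scores),
#'   `kernel_scales` (resolved per fold) and a `config` echo.
#' @export
train_and_crossvalidate <- function(table, feature_subset = "all",
                                    config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  cols <- if (length(feature_subset) == 1L &&
              feature_subset %in% c("set1", "set2", "all")) {
    feature_set_columns(feature_subset)
  } else {
    feature_subset
  }
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("feature column(s) not in table: ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(table[, cols, drop = FALSE])
  if (!all(is.finite(X))) stop("features must be finite")
  y <- as.character(table$label)
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    stop("classification requires exactly two classes; got: ",
         paste(classes, collapse = ", "))
  }
  pos <- config$positive_class
  if (!pos %in% classes) pos <- classes[1L]
  k <- config$n_folds
  if (min(table(y)) < k) {
    stop("need at least n_folds samples per class; reduce n_folds")
  }

  if (config$group_by_subject) {
    subj <- as.character(table$subject_id)
    us <- unique(subj)
    ug <- y[match(us, subj)]
    sf <- .stratified_folds(ug, k, config$seed)
    fold <- sf[match(subj, us)]
  } else {
    fold <- .stratified_folds(y, k, config$seed)
  }

  pred <- character(length(y))
  score <- numeric(length(y))
  scales <- numeric(k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    if (length(unique(y[tr])) < 2L) {
      stop("a class is absent from a training fold; reduce n_folds")
    }
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (config$standardize) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    ks <- if (identical(config$kernel_scale, "auto")) {
      stats::median(stats::dist(Xtr))
    } else {
      config$kernel_scale
    }
    if (!is.finite(ks) || ks <= 0) ks <- 1
    scales[f] <- ks
    fit <- e1071::svm(Xtr, factor(y[tr], levels = classes),
                      kernel = "radial", cost = config$box_constraint,
                      gamma = 1 / ks^2, scale = FALSE)
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # decision values are signed towards the class named first in the colname
    first <- strsplit(colnames(dv)[1L], "/")[[1L]][1L]
    s <- as.numeric(dv[, 1L])
    if (first != pos) s <- -s
    pred[te] <- as.character(pr)
    score[te] <- s
    cm <- .confusion_counts(as.character(pr), y[te], pos)
    per_fold[[f]] <- data.frame(fold = f, n = sum(te), kernel_scale = ks,
                                accuracy = 100 * (cm["tp"] + cm["tn"]) / sum(te))
  }

  cm <- .confusion_counts(pred, y, pos)
  metrics <- confusion_metrics(cm["tp"], cm["tn"], cm["fp"], cm["fn"])
  roc <- roc_auc(score, y, positive_class = pos)
  structure(list(
    tp = unname(cm["tp"]), tn = unname(cm["tn"]),
    fp = unname(cm["fp"]), fn = unname(cm["fn"]),
    accuracy = metrics$accuracy, sensitivity = metrics$sensitivity,
    specificity = metrics$specificity,
    auc = roc$auc, roc = roc$curve,
    per_fold = do.call(rbind, per_fold),
    predictions = data.frame(label = y, predicted = pred, score = score,
                             fold = fold, stringsAsFactors = FALSE),
    kernel_scales = scales,
    positive_class = pos, classes = classes, features = cols,
    config = config
  ), class = "classifier_report")
}

.confusion_counts <- function(pred, truth, pos) {
  c(tp = sum(pred == pos & truth == pos),
    tn = sum(pred != pos & truth != pos),
    fp = sum(pred == pos & truth != pos),
    fn = sum(pred != pos & truth == pos))
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> %d cycles, positive class '%s'\n  ACC %.1f%%  SEN %.1f%%  SPEC %.1f%%  AUC %.3f\n  confusion: TP %d  TN %d  FP %d  FN %d\n",
    nrow(x$predictions), x$positive_class, x$accuracy, x$sensitivity,
    x$specificity, x$auc, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `ACC = (TN + TP) / (TP + TN + FP + FN) * 100`;
#' `SEN = TP / (TP + FN) * 100`; `SPEC = TN / (TN + FP) * 100`.
#' An empty positive (or negative) margin makes sensitivity (specificity)
#' undefined: `NA` with a flag.
#'
#' @param tp,tn,fp,fn Non-negative counts, total > 0.
#' @return List with `accuracy`, `sensitivity`, `specificity` (percent) and
#'   `undefined` (character vector naming undefined metrics).
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  tp <- unname(tp); tn <- unname(tn); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  undef <- character(0)
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    undef <- c(undef, "sensitivity"); NA_real_
  }
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    undef <- c(undef, "specificity"); NA_real_
  }
  list(accuracy = 100 * (tn + tp) / (tp + tn + fp + fn),
       sensitivity = sen, specificity = spec, undefined = undef)
}

#' ROC curve and AUC from decision scores
#'
#' The AUC is computed with the rank statistic (Mann-Whitney form,
#' equivalent to trapezoidal integration of the ROC curve; ties receive
#' average ranks).
#'
#' @param scores Numeric decision scores, larger = more positive.
#' @param labels Class labels.
#' @param positive_class The positive label.
#' @return List with `auc` and `curve` (data.frame `fpr`, `tpr` over all
#'   score thresholds).
#' @export
roc_auc <- function(scores, labels, positive_class) {
  is_pos <- labels == positive_class
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  rk <- rank(scores)
  auc <- (sum(rk[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  n <- length(ord)
  block_end <- c(s_sorted[-n] != s_sorted[-1L], TRUE)  # last index of each tie block
  curve <- data.frame(
    fpr = c(0, (cumsum(!is_pos[ord]) / n_neg)[block_end]),
    tpr = c(0, (cumsum(is_pos[ord]) / n_pos)[block_end])
  )
  list(auc = auc, curve = curve)
}

# Plug-in mutual information (nats) between two discrete vectors.
.mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

# Equal-frequency discretization into at most n_bins levels.
.discretize <- function(x, n_bins = 10L) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE, type = 7)
  br <- unique(qs)
  if (length(br) < 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Minimum-redundancy-maximum-relevance feature ranking
#'
#' Greedy MRMR with the mutual-information difference criterion: at each
#' step the feature maximizing `I(feature; label) - mean I(feature;
#' selected)` is selected. Continuous features are discretized by
#' equal-frequency binning (default 10 bins) before mutual-information
#' estimation. Constant features have zero relevance and rank last; ties
#' break deterministically by column order.
#'
#' @param table Feature table (or plain data.frame/matrix of features).
#' @param labels Class labels; defaults to `table$label`.
#' @param features Feature columns to rank (default the ten standard ones
#'   present in the table).
#' @param n_bins Number of equal-frequency bins.
#' @return `data.frame` with `rank`, `feature`, `score` (the MRMR criterion
#'   at selection) and `relevance` (`I(feature; label)`).
#' @export
rank_features_mrmr <- function(table, labels = table$label,
                               features = intersect(feature_set_columns("all"),
                                                    colnames(table)),
                               n_bins = 10L) {
  if (length(features) < 1L) stop("no features to rank")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  disc <- lapply(features, function(f) .discretize(table[[f]], n_bins))
  names(disc) <- features
  y <- factor(labels)
  rel <- vapply(features, function(f) .mutual_information(disc[[f]], y), numeric(1))
  # zero-relevance (e.g. constant) features take the trailing ranks
  # deterministically, in column order, and are excluded from the greedy
  flat <- features[rel <= .Machine$double.eps]
  # pairwise redundancy, filled lazily
  red <- matrix(NA_real_, length(features), length(features),
                dimnames = list(features, features))
  selected <- character(0)
  scores <- numeric(0)
  remaining <- setdiff(features, flat)
  while (length(remaining)) {
    crit <- vapply(remaining, function(f) {
      if (!length(selected)) return(rel[[f]])
      for (s in selected) {
        if (is.na(red[f, s])) {
          red[f, s] <<- red[s, f] <<- .mutual_information(disc[[f]], disc[[s]])
        }
      }
      rel[[f]] - mean(red[f, selected])
    }, numeric(1))
    best <- remaining[which.max(crit)]
    selected <- c(selected, best)
    scores <- c(scores, max(crit))
    remaining <- setdiff(remaining, best)
  }
  selected <- c(selected, flat)
  scores <- c(scores, rep(0, length(flat)))
  data.frame(rank = seq_along(selected), feature = selected,
             score = scores, relevance = unname(rel[selected]),
             stringsAsFactors = FALSE)
}
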