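# Build a two-feature classification table with controllable class separation.
blob_table <- function(n_per_class = 100, delta = 6, seed = 1, sd = 1) {
  with_seed <- imugait:::with_seed
  with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(2 * n_per_class, 0, sd), ncol = 2),
               matrix(stats::rnorm(2 * n_per_class, delta * sd, sd), ncol = 2))
    data.frame(f1 = X[, 1], f2 = X[, 2],
               label = rep(c("healthy", "patient"), each = n_per_class),
               subject_id = sprintf("s%03d", seq_len(2 * n_per_class)),
               stringsAsFactors = FALSE)
  })
}

test_that("confusion metrics equal the defining formulas", {
  m <- confusion_metrics(90, 80, 20, 10)
  expect_equal(m$accuracy, 85)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)

  perfect <- confusion_metrics(50, 60, 0, 0)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(100, 100, 100))

  set.seed(3)
  for (i in 1:100) {
    k <- as.list(sample(0:50, 4, replace = TRUE))
    if (sum(unlist(k)) == 0) next
    m <- confusion_metrics(k[[1]], k[[2]], k[[3]], k[[4]])
    o <- oracle_confusion(k[[1]], k[[2]], k[[3]], k[[4]])
    expect_equal(m$accuracy, o$accuracy, tolerance = 1e-12)
    if (k[[1]] + k[[4]] > 0) expect_equal(m$sensitivity, o$sensitivity, tolerance = 1e-12)
    if (k[[2]] + k[[3]] > 0) expect_equal(m$specificity, o$specificity, tolerance = 1e-12)
  }

  und <- confusion_metrics(0, 5, 2, 0)
  expect_true(is.na(und$sensitivity))
  expect_identical(und$undefined, "sensitivity")
})

test_that("AUC equals exhaustive pair counting", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c("h", "h", "p", "p"), positive_class = "p")
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, oracle_auc(c(0.1, 0.4, 0.35, 0.8), c("h", "h", "p", "p"), "p"))

  sep <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(c("h", "p"), each = 3), "p")
  expect_equal(sep$auc, 1)
  expect_equal(sep$curve$tpr[nrow(sep$curve)], 1)
  expect_equal(sep$curve$fpr[nrow(sep$curve)], 1)

  set.seed(8)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    sc <- round(stats::rnorm(n), 1)  # force ties
    lb <- sample(c("h", "p"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb, "p")$auc, oracle_auc(sc, lb, "p"), tolerance = 1e-12)
  }
  aucs <- replicate(40, roc_auc(stats::rnorm(60), rep(c("h", "p"), 30), "p")$auc)
  expect_equal(mean(aucs), 0.5, tolerance = 0.06)
  expect_error(roc_auc(1:4, rep("p", 4), "p"), "both classes")
})

test_that("well-separated classes are classified almost perfectly", {
  for (s in 1:3) {
    tab <- blob_table(n_per_class = 100, delta = 6, seed = s)
    rep <- train_and_crossvalidate(tab, c("f1", "f2"),
                                   classifier_config(n_folds = 12, seed = s))
    expect_gte(rep$accuracy, 99)
    expect_gte(rep$auc, 0.999)
  }
})

test_that("pooled predictions cover every sample exactly once and reproduce deterministically", {
  tab <- blob_table(n_per_class = 60, delta = 2, seed = 4)
  cfg <- classifier_config(n_folds = 6, seed = 9)
  rep1 <- train_and_crossvalidate(tab, c("f1", "f2"), cfg)
  expect_identical(nrow(rep1$predictions), nrow(tab))
  expect_true(all(rep1$predictions$predicted %in% c("healthy", "patient")))
  expect_identical(rep1$tp + rep1$tn + rep1$fp + rep1$fn, nrow(tab))
  expect_identical(sort(unique(rep1$predictions$fold)), 1:6)
  # fold sizes balanced within one per class
  expect_lte(diff(range(table(rep1$predictions$fold))), 2)

  rep2 <- train_and_crossvalidate(tab, c("f1", "f2"), cfg)
  expect_identical(rep1$predictions, rep2$predictions)
  expect_identical(rep1$auc, rep2$auc)

  # Eqs. metrics equal brute-force recounts of the pooled predictions
  p <- rep1$predictions
  tp <- sum(p$predicted == "patient" & p$label == "patient")
  tn <- sum(p$predicted == "healthy" & p$label == "healthy")
  fp <- sum(p$predicted == "patient" & p$label == "healthy")
  fn <- sum(p$predicted == "healthy" & p$label == "patient")
  o <- oracle_confusion(tp, tn, fp, fn)
  expect_equal(rep1$accuracy, o$accuracy, tolerance = 1e-12)
  expect_equal(rep1$sensitivity, o$sensitivity, tolerance = 1e-12)
  expect_equal(rep1$specificity, o$specificity, tolerance = 1e-12)
})

test_that("permuted labels drop accuracy to the majority-class rate", {
  tab <- blob_table(n_per_class = 80, delta = 3, seed = 2)
  accs <- vapply(1:5, function(s) {
    ptab <- tab
    ptab$label <- imugait:::with_seed(s, sample(ptab$label))
    train_and_crossvalidate(ptab, c("f1", "f2"),
                            classifier_config(n_folds = 8, seed = s))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 8)
})

test_that("cross-validation guards against impossible fold structures", {
  tab <- blob_table(n_per_class = 5, seed = 1)
  expect_error(train_and_crossvalidate(tab, c("f1", "f2"),
                                       classifier_config(n_folds = 12)),
               "n_folds")
  one <- blob_table(n_per_class = 30, seed = 1)
  one$label <- "healthy"
  expect_error(train_and_crossvalidate(one, c("f1", "f2")), "two classes")
})

test_that("subject-grouped folding keeps each subject in a single fold", {
  tab <- blob_table(n_per_class = 60, delta = 4, seed = 5)
  tab$subject_id <- rep(sprintf("subj%02d", 1:12), each = 10)
  rep <- train_and_crossvalidate(tab, c("f1", "f2"),
                                 classifier_config(n_folds = 3,
                                                   group_by_subject = TRUE, seed = 2))
  folds_per_subject <- tapply(rep$predictions$fold, tab$subject_id,
                              function(f) length(unique(f)))
  expect_true(all(folds_per_subject == 1L))
})

test_that("MRMR ranks an informative feature first and penalizes redundancy", {
  hits <- 0L
  for (s in 1:20) {
    tab <- imugait:::with_seed(s, {
      y <- rep(c("healthy", "patient"), each = 100)
      d <- as.data.frame(matrix(stats::rnorm(200 * 9), 200, 9))
      names(d) <- sprintf("noise%02d", 1:9)
      d$informative <- ifelse(y == "patient", 2, 0) + stats::rnorm(200, 0, 0.3)
      d$label <- y
      d
    })
    rk <- rank_features_mrmr(tab, features = c(sprintf("noise%02d", 1:9), "informative"))
    hits <- hits + (rk$feature[1] == "informative")
  }
  expect_gte(hits, 19L)

  # single feature trivially first
  single <- data.frame(f = stats::rnorm(50), label = rep(c("a", "b"), 25))
  expect_identical(rank_features_mrmr(single, features = "f")$feature, "f")

  # duplicated informative feature falls below an independent weaker one
  toy <- imugait:::with_seed(3, {
    y <- rep(c(0, 1), each = 150)
    strong <- y * 3 + stats::rnorm(300, 0, 0.4)
    data.frame(strong = strong,
               copy = strong + stats::rnorm(300, 0, 0.01),
               weak = y * 1.2 + stats::rnorm(300, 0, 1),
               label = ifelse(y == 1, "patient", "healthy"))
  })
  rk <- rank_features_mrmr(toy, features = c("strong", "copy", "weak"))
  expect_identical(rk$feature[1], "strong")
  expect_lt(which(rk$feature == "weak"), which(rk$feature == "copy"))

  # constant feature: zero relevance, ranked last
  toy$flat <- 1
  rk2 <- rank_features_mrmr(toy, features = c("strong", "flat", "weak"))
  expect_identical(rk2$feature[nrow(rk2)], "flat")
  expect_equal(rk2$relevance[rk2$feature == "flat"], 0, tolerance = 1e-12)
})
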