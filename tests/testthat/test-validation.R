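test_that("confusion metrics reproduce the accuracy identities", {
  m <- confusion_metrics(list(TP = 3, TN = 1, FP = 1, FN = 0))
  expect_equal(unname(m), c(0.8, 1.0, 0.5))

  # degenerate: no positives at all -> sensitivity is not-a-value
  m2 <- confusion_metrics(list(TP = 0, TN = 12, FP = 0, FN = 0))
  expect_equal(m2[["accuracy"]], 1.0)
  expect_true(is.na(m2[["sensitivity"]]))
  expect_equal(m2[["specificity"]], 1.0)

  expect_equal(unname(confusion_metrics(list(TP = 5, TN = 5, FP = 0,
                                             FN = 0))),
               c(1, 1, 1))
  expect_error(confusion_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "zero")

  cc <- confusion_counts(c("AD", "AD", "CN", "CN"),
                         c("AD", "CN", "CN", "AD"), positive = "AD")
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(1, 1, 1, 1))
})

test_that("the dispersion summary is a population SD (divisor N)", {
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  expect_equal(pop_sd(x), 2)          # hand-computed with divisor N
  expect_gt(stats::sd(x), pop_sd(x))  # and not the sample SD
  expect_equal(pop_sd(rep(3, 5)), 0)
})

test_that("every learner separates an easy toy problem", {
  tab <- toy_feature_table(class_sep = 10, noise = 0.3, seed = 5)
  for (kind in names(all_classifiers())) {
    pred <- fit_predict(classifier_spec(kind), tab, tab, seed = 2)
    expect_equal(as.character(pred), as.character(tab$class),
                 label = kind)
  }
})

test_that("1-NN returns the label of an identical training point", {
  tab <- toy_feature_table(seed = 3)
  one <- tab[7, , drop = FALSE]
  attr(one, "subject_id") <- feature_subjects(tab)[7]
  class(one) <- class(tab)
  pred <- fit_predict(classifier_spec("knn", k = 1), tab, one)
  expect_equal(as.character(pred), as.character(tab$class[7]))
})

test_that("fit_predict is deterministic given a seed and needs two classes", {
  tab <- toy_feature_table(class_sep = 2, noise = 2, seed = 9)
  p1 <- fit_predict(classifier_spec("random_forest"), tab, tab, seed = 42)
  p2 <- fit_predict(classifier_spec("random_forest"), tab, tab, seed = 42)
  expect_identical(p1, p2)
  one_class <- tab[tab$class == "AD", ]
  attr(one_class, "subject_id") <- feature_subjects(tab)[tab$class == "AD"]
  class(one_class) <- class(tab)
  expect_error(fit_predict(classifier_spec("knn"), one_class, tab),
               "both classes")
})

test_that("pooled k-fold is stratified, seeded and exact on separable data", {
  tab <- toy_feature_table(n_subj_per_class = 3, epochs_per_subj = 20,
                           class_sep = 10, noise = 0.3, seed = 6)
  s <- pooled_kfold_cv(tab, classifier_spec("decision_tree"), k = 10,
                       seed = 1)
  expect_equal(s$mean_accuracy, 1.0)
  expect_equal(s$n_iterations, 10L)

  s2 <- pooled_kfold_cv(tab, classifier_spec("decision_tree"), k = 10,
                        seed = 1)
  expect_identical(s$folds, s2$folds)
})

test_that("k-fold accuracy on label-free data is at chance", {
  # labels carry no information: permuted independently of the features
  set.seed(13)
  tab <- toy_feature_table(n_subj_per_class = 2, epochs_per_subj = 50,
                           class_sep = 0, subject_sep = 0, noise = 1,
                           seed = 13)
  tab$class <- sample(tab$class)
  s <- pooled_kfold_cv(tab, classifier_spec("knn"), k = 10, seed = 2)
  # binomial null: 200 draws at p = 0.5 -> 3 SE ~ 0.106
  expect_lt(abs(s$mean_accuracy - 0.5), 3 * sqrt(0.25 / nrow(tab)) + 0.02)
})

test_that("LOPO iterations hold out one subject per class, reusing the smaller class", {
  groups <- c(AD01 = "AD", AD02 = "AD", AD03 = "AD",
              CN01 = "CN", CN02 = "CN")
  plan <- lopo_iterations(groups)
  expect_length(plan, 3L)  # larger class size
  for (held in plan) {
    expect_length(held, 2L)
    expect_setequal(unname(groups[held]), c("AD", "CN"))
  }
  # every subject held out at least once
  expect_setequal(unique(unlist(plan)), names(groups))
  # smaller class reused round-robin
  expect_equal(unname(vapply(plan, `[[`, character(1), "CN")),
               c("CN01", "CN02", "CN01"))
  expect_error(lopo_iterations(c(A1 = "AD", C1 = "CN", C2 = "CN")),
               "at least two subjects")
})

test_that("LOPO train and test subjects are disjoint at every iteration", {
  tab <- toy_feature_table(n_subj_per_class = 3, epochs_per_subj = 8,
                           class_sep = 6, subject_sep = 1, seed = 10)
  subjects <- feature_subjects(tab)
  s <- lopo_cv(tab, clf = classifier_spec("decision_tree"), seed = 1)
  expect_equal(s$n_iterations, 3L)
  tested <- character(0)
  for (i in seq_len(nrow(s$folds))) {
    held <- strsplit(s$folds$held_out[i], "+", fixed = TRUE)[[1]]
    tested <- c(tested, held)
    # the evaluated epochs are exactly the held-out subjects' epochs,
    # so the training set is their complement
    expect_equal(s$folds$TP[i] + s$folds$TN[i] + s$folds$FP[i] +
                   s$folds$FN[i],
                 sum(subjects %in% held))
    expect_length(intersect(held, setdiff(unique(subjects), held)), 0L)
  }
  expect_setequal(unique(tested), unique(subjects))
})

test_that("fold metrics are recomputable from their confusion counts", {
  tab <- toy_feature_table(n_subj_per_class = 2, epochs_per_subj = 10,
                           class_sep = 1, noise = 2, seed = 20)
  s <- pooled_kfold_cv(tab, classifier_spec("naive_bayes"), k = 5, seed = 3)
  for (i in seq_len(nrow(s$folds))) {
    m <- confusion_metrics(as.list(s$folds[i, c("TP", "TN", "FP", "FN")]))
    expect_equal(s$folds$accuracy[i], m[["accuracy"]])
    expect_equal(s$folds$sensitivity[i], m[["sensitivity"]])
    expect_equal(s$folds$specificity[i], m[["specificity"]])
  }
  expect_equal(s$mean_accuracy, mean(s$folds$accuracy))
  expect_equal(s$sd_accuracy, pop_sd(s$folds$accuracy))
  expect_true(s$mean_accuracy >= min(s$folds$accuracy) &&
                s$mean_accuracy <= max(s$folds$accuracy))
})

test_that("cross-validation summaries serialise to JSON and CSV", {
  tab <- toy_feature_table(seed = 2)
  s <- pooled_kfold_cv(tab, classifier_spec("decision_tree"), k = 4,
                       seed = 1)
  jp <- tempfile(fileext = ".json")
  cp <- tempfile(fileext = ".csv")
  cv_summary_json(s, jp)
  cv_folds_csv(s, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$scheme, "kfold")
  expect_equal(back$mean_accuracy, s$mean_accuracy)
  expect_equal(nrow(back$folds), s$n_iterations)
  expect_equal(nrow(utils::read.csv(cp)), s$n_iterations)
})
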