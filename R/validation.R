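#' Confusion counts for a binary problem
#'
#' The positive class is the patient class (AD against CN, FTD against CN;
#' AD is taken as positive for AD versus FTD).
#'
#' @param truth,pred Factors or character vectors of true and predicted
#'   labels (epoch-level).
#' @param positive Label counted as positive.
#' @return An object of class `confusion_counts` with integer fields `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  structure(
    list(TP = sum(truth == positive & pred == positive),
         TN = sum(truth != positive & pred != positive),
         FP = sum(truth != positive & pred == positive),
         FN = sum(truth == positive & pred != positive),
         positive = positive),
    class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy is `(TP + TN) / (TP + TN + FP + FN)`, sensitivity
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)`. A metric whose
#' denominator is zero is reported as `NA` (not-a-value), never silently 0.
#'
#' @param counts A [confusion_counts()] object, or a list with fields
#'   `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) {
    stop("all confusion counts are zero", call. = FALSE)
  }
  c(accuracy = (tp + tn) / total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Population standard deviation (divisor N)
#'
#' Dispersion of per-iteration cross-validation metrics, computed with
#' divisor `N` rather than `N - 1`.
#'
#' @param x Numeric vector.
#' @return Non-negative scalar.
#' @export
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Specify a classifier
#'
#' @param type One of `"decision_tree"`, `"random_forest"`, `"mlp"`,
#'   `"svm"`, `"naive_bayes"`, `"knn"`.
#' @param ... Type-specific hyperparameters. Recognised: `cp`, `minsplit`
#'   (decision_tree); `ntree`, `mtry` (random_forest); `size`, `decay`,
#'   `maxit` (mlp); `cost` (svm, linear kernel); `k` (knn).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(type = c("decision_tree", "random_forest", "mlp",
                                     "svm", "naive_bayes", "knn"), ...) {
  kind <- match.arg(type)
  defaults <- switch(kind,
    decision_tree = list(cp = 0.01, minsplit = 20),
    random_forest = list(ntree = 100, mtry = NULL),
    mlp = list(size = 10, decay = 0.1, maxit = 200),
    svm = list(cost = 1),
    naive_bayes = list(),
    knn = list(k = 1))
  extra <- list(...)
  bad <- setdiff(names(extra), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s", kind,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  defaults[names(extra)] <- extra
  structure(list(kind = kind, hyper = defaults), class = "classifier_spec")
}

#' All six classifier specifications
#'
#' @return Named list of [classifier_spec()] objects for the six supported
#'   learners.
#' @export
all_classifiers <- function() {
  kinds <- c("decision_tree", "random_forest", "mlp", "svm", "naive_bayes",
             "knn")
  stats::setNames(lapply(kinds, classifier_spec), kinds)
}

# Standardise columns with training-fold statistics only (constant columns
# get unit scale). Used for the distance/margin/gradient learners.
standardize_pair <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(train = sweep(sweep(train_x, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(test_x, 2L, mu), 2L, sdv, "/"))
}

predictor_matrix <- function(table) {
  as.matrix(table[, setdiff(names(table), "class"), drop = FALSE])
}

#' Fit a classifier on a training table and predict a test table
#'
#' Predictors are every feature column; the class column is the response
#' and the subject id (attribute metadata) is never an input. Features are
#' standardised with training-fold statistics for the MLP, SVM and kNN
#' learners; trees, forests and naive Bayes consume raw features.
#' Stochastic learners (random forest, MLP) are seeded.
#'
#' @param clf A [classifier_spec()].
#' @param train,test `feature_table`s; `train` must contain both classes.
#' @param seed Integer seed for stochastic learners.
#' @return Factor of predicted labels, one per test row, with the training
#'   class levels.
#' @export
fit_predict <- function(clf, train, test, seed = 1L) {
  stopifnot(inherits(clf, "classifier_spec"))
  y <- droplevels(factor(train$class))
  if (nlevels(y) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  train_x <- predictor_matrix(train)
  test_x <- predictor_matrix(test)
  h <- clf$hyper
  pred <- switch(clf$kind,
    decision_tree = {
      df <- data.frame(train_x, .y = y, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df,
                          method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(
                            cp = h$cp, minsplit = h$minsplit, xval = 0))
      predict(fit, newdata = data.frame(test_x, check.names = FALSE),
              type = "class")
    },
    random_forest = {
      set.seed(seed)
      mtry <- if (is.null(h$mtry)) max(1L, floor(sqrt(ncol(train_x)))) else h$mtry
      fit <- randomForest::randomForest(x = train_x, y = y,
                                        ntree = h$ntree, mtry = mtry)
      predict(fit, newdata = test_x)
    },
    mlp = {
      set.seed(seed)
      sp <- standardize_pair(train_x, test_x)
      fit <- nnet::nnet(x = sp$train, y = stats::model.matrix(~ y - 1),
                        size = h$size, decay = h$decay, maxit = h$maxit,
                        softmax = TRUE, trace = FALSE,
                        MaxNWts = 10000 + h$size * ncol(train_x))
      factor(levels(y)[max.col(predict(fit, sp$test))], levels = levels(y))
    },
    svm = {
      sp <- standardize_pair(train_x, test_x)
      fit <- e1071::svm(x = sp$train, y = y, kernel = "linear",
                        cost = h$cost, scale = FALSE)
      predict(fit, newdata = sp$test)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x = train_x, y = y)
      predict(fit, newdata = test_x)
    },
    knn = {
      sp <- standardize_pair(train_x, test_x)
      class::knn(sp$train, sp$test, cl = y, k = h$k)
    })
  factor(as.character(pred), levels = levels(y))
}

make_cv_summary <- function(scheme, clf, folds) {
  structure(
    list(scheme = scheme, classifier = clf$kind, folds = folds,
         mean_accuracy = mean(folds$accuracy),
         sd_accuracy = pop_sd(folds$accuracy),
         mean_sensitivity = mean(folds$sensitivity, na.rm = TRUE),
         sd_sensitivity = pop_sd(folds$sensitivity[!is.na(folds$sensitivity)]),
         mean_specificity = mean(folds$specificity, na.rm = TRUE),
         sd_specificity = pop_sd(folds$specificity[!is.na(folds$specificity)]),
         n_iterations = nrow(folds)),
    class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> %s / %s: accuracy %.3f (SD %.3f), sensitivity %.3f, specificity %.3f over %d iteration(s)\n",
              x$scheme, x$classifier, x$mean_accuracy, x$sd_accuracy,
              x$mean_sensitivity, x$mean_specificity, x$n_iterations))
  invisible(x)
}

fold_row <- function(id, counts, held_out = NA_character_) {
  m <- confusion_metrics(counts)
  data.frame(fold = id, held_out = held_out,
             TP = counts$TP, TN = counts$TN, FP = counts$FP, FN = counts$FN,
             accuracy = m[["accuracy"]], sensitivity = m[["sensitivity"]],
             specificity = m[["specificity"]],
             stringsAsFactors = FALSE)
}

#' Pooled stratified k-fold cross-validation over epochs
#'
#' Epochs are shuffled (seeded) and dealt into `k` folds stratified by
#' class while deliberately ignoring subject identity, so different epochs
#' of one subject routinely land on both sides of a split. This is the
#' leakage-prone scheme whose optimism the package quantifies; compare
#' [lopo_cv()].
#'
#' @param table A two-class `feature_table`.
#' @param clf A [classifier_spec()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle and any stochastic learner.
#' @param positive Positive-class label; defaults to the patient class
#'   present (AD, else FTD).
#' @return A `cv_summary` over the `k` folds (folds whose training split
#'   lost a class are skipped with a warning).
#' @export
pooled_kfold_cv <- function(table, clf, k = 10L, seed = 1L,
                            positive = NULL) {
  stopifnot(k >= 2L, nrow(table) >= k)
  y <- droplevels(factor(table$class))
  if (nlevels(y) != 2L) {
    stop("pooled_kfold_cv expects exactly two classes", call. = FALSE)
  }
  positive <- positive %||% default_positive(levels(y))
  set.seed(seed)
  fold_id <- integer(nrow(table))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds <- list()
  for (f in seq_len(k)) {
    tr <- ft_rows(table, fold_id != f)
    te <- ft_rows(table, fold_id == f)
    if (nlevels(droplevels(factor(tr$class))) < 2L) {
      warning(sprintf("fold %d skipped: a class is absent from training", f))
      next
    }
    pred <- fit_predict(clf, tr, te, seed = seed + f)
    counts <- confusion_counts(te$class, pred, positive)
    folds[[length(folds) + 1L]] <- fold_row(f, counts)
  }
  make_cv_summary("kfold", clf, do.call(rbind, folds))
}

default_positive <- function(labels) {
  if ("AD" %in% labels) "AD" else if ("FTD" %in% labels) "FTD" else labels[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-subject-per-class-out cross-validation
#'
#' At each iteration the complete epoch set of one subject from each class
#' is withheld as the test set and the classifier is trained on all other
#' subjects' epochs, so no subject contributes to both sides of any split.
#' The number of iterations is the larger class's subject count; subjects
#' of the smaller class are reused round-robin so that every subject is
#' held out at least once. Mean and population-SD (divisor N) summaries are
#' reported over iterations.
#'
#' @param table A two-class `feature_table`.
#' @param groups Named character vector mapping subject id to class, or
#'   `NULL` to derive it from the table's subject metadata.
#' @param clf A [classifier_spec()].
#' @param seed Seed forwarded to stochastic learners.
#' @param positive Positive-class label (defaults to the patient class).
#' @return A `cv_summary` with one row per iteration; `held_out` records
#'   the withheld subject ids.
#' @export
lopo_cv <- function(table, groups = NULL, clf, seed = 1L, positive = NULL) {
  subjects <- feature_subjects(table)
  y <- droplevels(factor(table$class))
  if (nlevels(y) != 2L) {
    stop("lopo_cv expects exactly two classes", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- tapply(as.character(y), subjects, function(v) v[1])
    groups <- stats::setNames(as.character(groups), names(groups))
  }
  positive <- positive %||% default_positive(levels(y))
  plan <- lopo_iterations(groups)
  folds <- list()
  for (i in seq_along(plan)) {
    held <- plan[[i]]
    test_idx <- subjects %in% held
    tr <- ft_rows(table, !test_idx)
    te <- ft_rows(table, test_idx)
    pred <- fit_predict(clf, tr, te, seed = seed + i)
    counts <- confusion_counts(te$class, pred, positive)
    folds[[i]] <- fold_row(i, counts, held_out = paste(held, collapse = "+"))
  }
  make_cv_summary("lopo", clf, do.call(rbind, folds))
}

#' Held-out subject sets for leave-one-subject-per-class-out CV
#'
#' Computes the iteration plan used by [lopo_cv()]: the number of
#' iterations equals the larger class's subject count, subjects are taken
#' in sorted-id order, and the smaller class is reused round-robin so that
#' every subject is held out at least once.
#'
#' @param groups Named character vector mapping subject id to class label
#'   (exactly two classes, each with at least two subjects).
#' @return List of character vectors; element `i` holds the subject ids
#'   (one per class) withheld at iteration `i`.
#' @export
lopo_iterations <- function(groups) {
  cls <- sort(unique(as.character(groups)))
  if (length(cls) != 2L) {
    stop("lopo_iterations expects exactly two classes", call. = FALSE)
  }
  subj_by_class <- lapply(cls, function(cl) sort(names(groups)[groups == cl]))
  names(subj_by_class) <- cls
  n_by_class <- lengths(subj_by_class)
  if (any(n_by_class < 2L)) {
    stop("every class needs at least two subjects for LOPO", call. = FALSE)
  }
  lapply(seq_len(max(n_by_class)), function(i) {
    vapply(cls, function(cl) {
      subj_by_class[[cl]][((i - 1L) %% n_by_class[[cl]]) + 1L]
    }, character(1))
  })
}

#' Serialise a cross-validation summary
#'
#' `cv_summary_json()` writes the scheme, classifier, per-fold metrics and
#' the mean/SD summaries as JSON; `cv_folds_csv()` writes the tidy one-row-
#' per-fold table as CSV.
#'
#' @param summary A `cv_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
cv_summary_json <- function(summary, path) {
  payload <- list(scheme = summary$scheme, classifier = summary$classifier,
                  folds = summary$folds,
                  mean_accuracy = summary$mean_accuracy,
                  sd_accuracy = summary$sd_accuracy,
                  mean_sensitivity = summary$mean_sensitivity,
                  sd_sensitivity = summary$sd_sensitivity,
                  mean_specificity = summary$mean_specificity,
                  sd_specificity = summary$sd_specificity,
                  n_iterations = summary$n_iterations)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname cv_summary_json
#' @export
cv_folds_csv <- function(summary, path) {
  utils::write.csv(summary$folds, path, row.names = FALSE)
  invisible(path)
}
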