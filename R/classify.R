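#' Assemble a labeled feature table
#'
#' Standard container fed to the classifier: one row per image, the 45
#' variance-feature columns, a binary label (`art` / `non_art`, with `art`
#' the positive class), a free-text category tag and an image id.
#'
#' @param features Matrix or data frame of feature columns (rows = images).
#' @param label Character/factor vector, values `art` or `non_art`.
#' @param category Character vector of category tags (e.g. the synthetic
#'   class or an art provenance).
#' @param image_id Optional row identifiers.
#' @return A `data.frame` with columns `image_id`, `label`, `category`,
#'   then the features.
#' @export
labeled_feature_table <- function(features, label, category = label,
                                  image_id = NULL) {
  features <- as.data.frame(features)
  n <- nrow(features)
  stopifnot(length(label) == n, length(category) == n)
  label <- factor(as.character(label), levels = c("art", "non_art"))
  if (anyNA(label)) stop("labels must be 'art' or 'non_art'")
  if (any(table(label) < 2L)) stop("need at least 2 images per class")
  if (anyNA(features)) stop("feature table contains missing values")
  image_id <- image_id %||% sprintf("img_%04d", seq_len(n))
  cbind(data.frame(image_id = as.character(image_id), label = label,
                   category = as.character(category),
                   stringsAsFactors = FALSE),
        features)
}

feature_columns <- function(table) {
  setdiff(colnames(table), c("image_id", "label", "category",
                             "layer", "config_hash", "selfsim"))
}

# Seeded stratified fold assignment; every fold contains both classes.
stratified_folds <- function(label, k = 5L, seed = 1L) {
  label <- as.factor(label)
  if (min(table(label)) < k)
    stop("stratification error: a class has fewer than ", k,
         " members, so some fold would miss it")
  fold <- integer(length(label))
  with_seed(seed, {
    for (cl in levels(label)) {
      idx <- sample(which(label == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

svm_grid <- expand.grid(cost = c(0.1, 1, 10, 100),
                        gamma = c(0.01, 0.1, 1, 10))

# Inner 3-fold grid search on the training fold only; ties keep the first
# grid entry (fixed grid order).
tune_rbf <- function(x, y, seed) {
  inner <- stratified_folds(y, 3L, seed)
  acc <- vapply(seq_len(nrow(svm_grid)), function(g) {
    mean(vapply(1:3, function(f) {
      tr <- inner != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = svm_grid$cost[g], gamma = svm_grid$gamma[g],
                        scale = FALSE)
      mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  svm_grid[which.max(acc), ]
}

category_metrics <- function(truth, pred, category, art_cats) {
  do.call(rbind, lapply(c(art_cats, "all combined"), function(cc) {
    keep <- if (cc == "all combined") rep(TRUE, length(truth))
            else (category == cc | truth == "non_art")
    tt <- truth[keep]; pp <- pred[keep]
    tp <- sum(pp == "art" & tt == "art")
    fp <- sum(pp == "art" & tt == "non_art")
    fn <- sum(pp == "non_art" & tt == "art")
    tn <- sum(pp == "non_art" & tt == "non_art")
    data.frame(category = cc,
               accuracy = (tp + tn) / length(tt),
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Cross-validated SVM evaluation of a feature subset
#'
#' Stratified 5-fold cross-validation of an RBF-kernel support vector
#' machine on the named feature subset. Features are z-scored using
#' training-fold statistics only; the test fold never influences
#' standardization or the fitted model. Hyperparameters default to
#' `cost = 1`, `gamma = 1/d`; with `tune = TRUE` an inner 3-fold grid search
#' over `cost` in \{0.1, 1, 10, 100\} and `gamma` in \{0.01, 0.1, 1, 10\}
#' is run on each training fold.
#'
#' Per-category scores follow the convention of restricting the test
#' predictions to one art category plus all non-art images, with `art` as
#' the positive class; they are averaged over folds.
#'
#' @param table A [labeled_feature_table()].
#' @param subset Character vector of feature column names to use.
#' @param seed Integer seed controlling fold assignment (and tuning).
#' @param folds Number of folds (default 5).
#' @param tune Run the inner grid search? Default `FALSE`.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @return A `cv_result`: mean/SD of test-fold accuracy, per-fold
#'   accuracies, per-category metrics, and the held-out predictions.
#' @export
cv_evaluate <- function(table, subset, seed = 1L, folds = 5L, tune = FALSE,
                        kernel = "radial") {
  if (length(subset) < 1L) stop("feature subset must be non-empty")
  missing_cols <- setdiff(subset, colnames(table))
  if (length(missing_cols))
    stop("features not in table: ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(table[, subset, drop = FALSE])
  if (anyNA(x)) stop("feature table contains missing values")
  y <- factor(as.character(table$label), levels = c("art", "non_art"))
  const <- apply(x, 2, function(v) max(v) - min(v) == 0)
  if (any(const))
    warning("constant feature(s) retained: ",
            paste(subset[const], collapse = ", "))
  fold <- stratified_folds(y, folds, seed)
  art_cats <- sort(unique(table$category[y == "art"]))
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(y))
  fold_acc <- numeric(folds)
  percat <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
    par <- if (tune && kernel == "radial")
      tune_rbf(xs[tr, , drop = FALSE], y[tr], seed + f)
    else data.frame(cost = 1, gamma = 1 / ncol(x))
    fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = kernel,
                      cost = par$cost, gamma = par$gamma, scale = FALSE)
    pf <- predict(fit, xs[!tr, , drop = FALSE])
    pred[!tr] <- pf
    fold_acc[f] <- mean(pf == y[!tr])
    percat[[f]] <- category_metrics(as.character(y[!tr]), as.character(pf),
                                    table$category[!tr], art_cats)
  }
  pc <- percat[[1]][, "category", drop = FALSE]
  for (col in c("accuracy", "precision", "recall")) {
    mm <- sapply(percat, function(d) d[[col]])
    pc[[col]] <- rowMeans(mm, na.rm = TRUE)
    pc[[paste0(col, "_sd")]] <- apply(mm, 1, sd, na.rm = TRUE)
  }
  structure(list(feature_subset = subset,
                 mean_accuracy = mean(fold_acc),
                 sd_accuracy = sd(fold_acc),
                 fold_accuracy = fold_acc,
                 per_category = pc,
                 predictions = data.frame(image_id = table$image_id,
                                          fold = fold,
                                          truth = y, pred = pred,
                                          stringsAsFactors = FALSE),
                 fold_seed = as.integer(seed),
                 folds = folds,
                 kernel = kernel, tuned = tune),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV, %s SVM on {%s}\n", x$folds, x$kernel,
              paste(x$feature_subset, collapse = ", ")))
  cat(sprintf("  accuracy %.3f +/- %.3f SD\n", x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  cat("  per-category (art positive):\n")
  print(object$per_category, row.names = FALSE, digits = 3)
  invisible(object)
}

#' Number of feature subsets of sizes 1..max_size
#'
#' For the full pool of 45 variance features and `max_size = 3` this is
#' `choose(45,1) + choose(45,2) + choose(45,3) = 15225`.
#'
#' @param n_features Pool size.
#' @param max_size Largest subset size.
#' @return Integer count.
#' @export
n_feature_subsets <- function(n_features, max_size = 3L) {
  as.integer(sum(choose(n_features, seq_len(max_size))))
}

#' Exhaustive feature-subset search
#'
#' Evaluates every subset of the feature pool of sizes 1 up to `max_size`
#' (at most 3) with [cv_evaluate()] under a shared fold assignment, and
#' ranks subsets by mean test-fold accuracy (descending), breaking ties by
#' smaller subset size and then lexicographically on the feature names.
#'
#' Note the ranking selects on the same cross-validation scores it reports,
#' so the top score is an optimistic estimate; [nested_subset_estimate()]
#' provides the unbiased companion.
#'
#' @param table A [labeled_feature_table()].
#' @param max_size Largest subset size, 1 to 3.
#' @param seed Fold seed.
#' @param features Feature pool (default: all feature columns).
#' @param folds Number of CV folds.
#' @return A `data.frame` with columns `subset`, `size`, `mean_accuracy`,
#'   `sd_accuracy`, ordered best-first.
#' @export
subset_search <- function(table, max_size = 3L, seed = 1L, features = NULL,
                          folds = 5L) {
  if (max_size < 1L || max_size > 3L)
    stop("max_size must be 1, 2 or 3")
  features <- features %||% feature_columns(table)
  subsets <- unlist(lapply(seq_len(max_size), function(s)
    combn(features, s, simplify = FALSE)), recursive = FALSE)
  res <- lapply(subsets, function(ss)
    cv_evaluate(table, ss, seed = seed, folds = folds))
  out <- data.frame(
    subset = vapply(subsets, function(s) paste(sort(s), collapse = "+"),
                    character(1)),
    size = lengths(subsets),
    mean_accuracy = vapply(res, `[[`, numeric(1), "mean_accuracy"),
    sd_accuracy = vapply(res, `[[`, numeric(1), "sd_accuracy"),
    stringsAsFactors = FALSE)
  out[order(-out$mean_accuracy, out$size, out$subset), , drop = FALSE]
}

#' Nested cross-validation estimate of subset-search performance
#'
#' Outer stratified K-fold loop; within each outer training set, the full
#' subset search is repeated and its top subset is refit on the outer
#' training data and scored on the untouched outer test fold. The mean of
#' the outer-fold accuracies estimates what the searched subset achieves on
#' unseen data, free of the selection optimism of [subset_search()].
#'
#' @inheritParams subset_search
#' @param outer_folds Number of outer folds (default 5).
#' @return List with `mean_accuracy`, `sd_accuracy`, per-outer-fold
#'   `chosen_subset` and `fold_accuracy`.
#' @export
nested_subset_estimate <- function(table, max_size = 2L, seed = 1L,
                                   features = NULL, outer_folds = 5L) {
  features <- features %||% feature_columns(table)
  y <- factor(as.character(table$label), levels = c("art", "non_art"))
  fold <- stratified_folds(y, outer_folds, seed)
  acc <- numeric(outer_folds)
  chosen <- character(outer_folds)
  for (f in seq_len(outer_folds)) {
    tr_tab <- table[fold != f, , drop = FALSE]
    rank <- subset_search(tr_tab, max_size = max_size, seed = seed + f,
                          features = features)
    best <- strsplit(rank$subset[1], "+", fixed = TRUE)[[1]]
    chosen[f] <- rank$subset[1]
    x <- as.matrix(table[, best, drop = FALSE])
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
    fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = 1, gamma = 1 / ncol(x), scale = FALSE)
    acc[f] <- mean(predict(fit, xs[!tr, , drop = FALSE]) == y[!tr])
  }
  list(mean_accuracy = mean(acc), sd_accuracy = sd(acc),
       fold_accuracy = acc, chosen_subset = chosen)
}

#' Linear-SVM baseline on raw, high-dimensional inputs
#'
#' The comparison protocol for the variance features: a linear-kernel SVM
#' under the same stratified 5-fold scheme, applied to flattened raw inputs
#' — either downscaled pixel values (227 x 227 x 3 = 154,587 dimensions) or
#' raw first-layer response maps (96 x 55 x 55 = 290,400 dimensions at the
#' original geometry). Inputs are used unstandardized.
#'
#' @param x Numeric matrix, one row per image (consistent row length).
#' @param label Labels as in [labeled_feature_table()].
#' @param seed Fold seed.
#' @param folds Number of folds.
#' @param cost SVM cost parameter (default 1).
#' @return A `cv_result` (with `feature_subset = "<raw>"`).
#' @export
baseline_raw <- function(x, label, seed = 1L, folds = 5L, cost = 1) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("raw input matrix contains missing values")
  y <- factor(as.character(label), levels = c("art", "non_art"))
  if (anyNA(y)) stop("labels must be 'art' or 'non_art'")
  fold <- stratified_folds(y, folds, seed)
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    fold_acc[f] <- mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
  }
  structure(list(feature_subset = "<raw>",
                 mean_accuracy = mean(fold_acc),
                 sd_accuracy = sd(fold_acc),
                 fold_accuracy = fold_acc,
                 per_category = NULL,
                 predictions = NULL,
                 fold_seed = as.integer(seed),
                 folds = folds,
                 kernel = "linear", tuned = FALSE,
                 input_dim = ncol(x)),
            class = "cv_result")
}

#' Accuracy of always guessing the majority class
#'
#' The guessing floor against which classification accuracies are read:
#' `max(class counts) / total`. For a corpus of 2,090 art and 2,199 non-art
#' images this is 2199/4289, about 0.513.
#'
#' @param counts Named or unnamed vector of per-class image counts.
#' @return The majority-class accuracy.
#' @examples
#' majority_class_accuracy(c(art = 2090, non_art = 2199))
#' @export
majority_class_accuracy <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  max(counts) / sum(counts)
}
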