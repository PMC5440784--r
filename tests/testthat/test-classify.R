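test_that("well-separated clusters are classified near-perfectly, matching a centroid oracle", {
  tab <- gaussian_table(n = 200, sep = 10)
  cv <- cv_evaluate(tab, c("f1", "f2"), seed = 3)
  expect_gte(cv$mean_accuracy, 0.99)
  # independent oracle: nearest class centroid separates by construction
  x <- as.matrix(tab[, c("f1", "f2")])
  cen <- rbind(colMeans(x[tab$label == "art", ]),
               colMeans(x[tab$label == "non_art", ]))
  oracle <- c("art", "non_art")[apply(x, 1, function(r)
    which.min(colSums((t(cen) - r)^2)))]
  expect_gte(mean(oracle == as.character(tab$label)), 0.99)
})

test_that("permuted labels fall to the binomial guessing level", {
  tab <- gaussian_table(n = 200, sep = 10)
  set.seed(21)
  tab$label <- sample(tab$label)
  cv <- cv_evaluate(tab, c("f1", "f2"), seed = 3)
  expect_gt(cv$mean_accuracy, 0.5 - 0.08)
  expect_lt(cv$mean_accuracy, 0.5 + 0.08)
})

test_that("cross-validation is deterministic given the seed", {
  tab <- gaussian_table(n = 120, sep = 3)
  a <- cv_evaluate(tab, c("f1", "f2"), seed = 11)
  b <- cv_evaluate(tab, c("f1", "f2"), seed = 11)
  expect_identical(a$fold_accuracy, b$fold_accuracy)
  expect_identical(a$predictions, b$predictions)
  c <- cv_evaluate(tab, c("f1", "f2"), seed = 12)
  expect_false(identical(a$predictions$fold, c$predictions$fold))
})

test_that("test folds never leak into standardization or training", {
  tab <- gaussian_table(n = 100, sep = 2.5, seed = 9)
  base <- cv_evaluate(tab, c("f1", "f2"), seed = 2)
  victim <- 7L
  vfold <- base$predictions$fold[victim]
  poisoned <- tab
  poisoned[victim, c("f1", "f2")] <- poisoned[victim, c("f1", "f2")] * 1e6
  after <- cv_evaluate(poisoned, c("f1", "f2"), seed = 2)
  expect_identical(base$predictions$fold, after$predictions$fold)
  # all other predictions in the victim's own test fold are untouched
  same_fold <- which(base$predictions$fold == vfold)
  same_fold <- setdiff(same_fold, victim)
  expect_identical(as.character(base$predictions$pred[same_fold]),
                   as.character(after$predictions$pred[same_fold]))
})

test_that("degenerate inputs raise the documented conditions", {
  tab <- gaussian_table(n = 40)
  expect_error(cv_evaluate(tab, character(0), seed = 1), "non-empty")
  expect_error(cv_evaluate(tab, "nope", seed = 1), "nope")
  tab$const <- 1
  expect_warning(cv_evaluate(tab, c("f1", "const"), seed = 1), "constant")
  tiny <- gaussian_table(n = 8)
  expect_error(cv_evaluate(tiny, "f1", seed = 1), "stratification")
})

test_that("per-category metrics score each art category against all non-art", {
  tab <- gaussian_table(n = 200, sep = 10)
  half <- sum(tab$label == "art")
  tab$category[seq_len(half)] <- rep(c("west", "east"), length.out = half)
  cv <- cv_evaluate(tab, c("f1", "f2"), seed = 4)
  pc <- cv$per_category
  expect_setequal(pc$category, c("east", "west", "all combined"))
  expect_true(all(pc$accuracy >= 0 & pc$accuracy <= 1))
  expect_true(all(pc$precision >= 0.9, pc$recall >= 0.9))
})

test_that("subset enumeration counts and ranking contract hold", {
  expect_identical(n_feature_subsets(45, 3), 15225L)
  expect_identical(n_feature_subsets(45, 1), 45L)
  expect_identical(n_feature_subsets(45, 2), 45L + 990L)
  tab <- gaussian_table(n = 80, sep = 8, n_noise = 4)
  r1 <- subset_search(tab, max_size = 1, seed = 5)
  expect_identical(nrow(r1), 6L) # 2 informative + 4 noise singletons
  r2 <- subset_search(tab, max_size = 2, seed = 5)
  expect_identical(nrow(r2), n_feature_subsets(6, 2))
  # ranking: descending accuracy, ties to smaller then lexicographic
  expect_true(all(diff(r2$mean_accuracy) <= 1e-12))
  ties <- r2[abs(r2$mean_accuracy - r2$mean_accuracy[1]) < 1e-12, ]
  expect_identical(ties$size, sort(ties$size))
  expect_error(subset_search(tab, max_size = 4), "max_size")
})

test_that("the informative pair is recovered from noise distractors", {
  tab <- gaussian_table(n = 120, sep = 6, seed = 13, n_noise = 6)
  ranked <- subset_search(tab, max_size = 2, seed = 7)
  best_pair <- ranked$subset[ranked$size == 2][1]
  expect_identical(best_pair, "f1+f2")
})

test_that("nested search gives an honest (not higher) estimate on noise-only data", {
  set.seed(33)
  x <- matrix(rnorm(120 * 5), 120)
  colnames(x) <- paste0("n", 1:5)
  tab <- labeled_feature_table(x, rep(c("art", "non_art"), each = 60))
  optimistic <- subset_search(tab, max_size = 1, seed = 2)$mean_accuracy[1]
  nested <- nested_subset_estimate(tab, max_size = 1, seed = 2)
  expect_lte(nested$mean_accuracy, optimistic + 0.05)
  expect_lt(abs(nested$mean_accuracy - 0.5), 0.2)
})

test_that("linear baseline handles raw high-dimensional rows and reports dimensionality", {
  set.seed(17)
  n <- 40
  x <- rbind(matrix(rnorm(n / 2 * 300), n / 2),
             matrix(rnorm(n / 2 * 300, mean = 1.5), n / 2))
  lab <- rep(c("art", "non_art"), each = n / 2)
  cv <- baseline_raw(x, lab, seed = 1)
  expect_gte(cv$mean_accuracy, 0.99)
  expect_identical(cv$input_dim, 300L)
  expect_identical(cv$kernel, "linear")
})

test_that("majority-class accuracy reproduces the printed guessing floor", {
  expect_equal(round(majority_class_accuracy(c(art = 2090, non_art = 2199)), 3),
               0.513)
  expect_equal(majority_class_accuracy(c(1, 1)), 0.5)
})
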