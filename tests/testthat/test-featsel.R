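# small, fast random forests for the pipeline tests
test_rf <- function() rf_classifier(num_trees = 100)

test_that("balanced accuracy is the mean of per-class recalls", {
  truth <- c("a", "a", "a", "a", "b", "b")
  pred <- c("a", "a", "a", "b", "b", "a")
  expect_equal(balanced_accuracy(truth, pred), mean(c(3 / 4, 1 / 2)))
  expect_equal(balanced_accuracy(truth, truth), 1)
})

test_that("stratified holdout is proportional, disjoint and deterministic", {
  y <- rep(c("case", "control"), each = 100)
  s <- stratified_holdout(y, 0.2, seed = 1)
  expect_length(s$validation, 40)
  expect_equal(as.vector(table(y[s$validation])), c(20, 20))
  expect_length(intersect(s$train, s$validation), 0)
  expect_setequal(c(s$train, s$validation), seq_along(y))
  expect_identical(s, stratified_holdout(y, 0.2, seed = 1))
  expect_false(identical(s, stratified_holdout(y, 0.2, seed = 2)))
})

test_that("holdout allocation rounds up per class", {
  y <- c(rep("a", 7), rep("b", 3))
  s <- stratified_holdout(y, 0.2, seed = 1)
  expect_equal(as.vector(table(y[s$validation])), c(2, 1))
  expect_error(stratified_holdout(c("a", "b", "b"), 0.2), "fewer than 2")
})

test_that("a perfectly separating feature gets the maximal importance", {
  set.seed(60)
  n <- 40
  y <- rep(c("case", "control"), each = n / 2)
  x <- cbind(sep = ifelse(y == "case", 1, 0) + rnorm(n, sd = 0.05),
             n1 = rnorm(n), n2 = rnorm(n))
  imp <- mean_permutation_importance(x, y, classifier = test_rf(),
                                     cv_splits = 3, cv_repeats = 1,
                                     n_permutations = 10, seed = 1)
  expect_identical(names(which.max(imp)), "sep")
  expect_gt(imp["sep"], 5 * max(imp[c("n1", "n2")]))
})

test_that("labels independent of the features leave importances near zero", {
  fx <- classification_fixture(n = 40, d = 5, informative = 0, seed = 61)
  imp <- mean_permutation_importance(fx$x, fx$y, classifier = test_rf(),
                                     cv_splits = 3, cv_repeats = 1,
                                     n_permutations = 10, seed = 2)
  expect_true(all(imp >= 0))     # clamped for cABC admissibility
  expect_lt(max(imp), 0.15)
})

test_that("planted informative features rank at the top", {
  fx <- classification_fixture(n = 80, d = 12, informative = 2,
                               effect = 2, seed = 62)
  imp <- mean_permutation_importance(fx$x, fx$y, classifier = test_rf(),
                                     cv_splits = 3, cv_repeats = 2,
                                     n_permutations = 5, seed = 3)
  top5 <- names(sort(imp, decreasing = TRUE))[1:5]
  expect_true(all(fx$informative %in% top5))
})

test_that("accuracy interval is the median with 2.5/97.5 percentiles", {
  ci <- balanced_accuracy_ci(c(0.6, 0.7, 0.8))
  expect_equal(ci$median, 0.7)
  ci1 <- balanced_accuracy_ci(rep(1, 50))
  expect_equal(unlist(ci1), c(median = 1, lower = 1, upper = 1))
  v <- seq(0, 1, length.out = 1001)
  ci2 <- balanced_accuracy_ci(v)
  expect_equal(ci2$lower, 0.025, tolerance = 1e-6)
  expect_equal(ci2$upper, 0.975, tolerance = 1e-6)
  expect_true(ci2$lower <= ci2$median && ci2$median <= ci2$upper)
})

test_that("the held-out part cannot influence the selected sets", {
  fx <- classification_fixture(n = 60, d = 8, informative = 2,
                               effect = 2, seed = 63)
  s <- stratified_holdout(fx$y, 0.2, seed = 4)
  args <- list(x_train = fx$x[s$train, ], y_train = fx$y[s$train],
               x_val = fx$x[s$validation, ],
               classifier = test_rf(), cv_splits = 3, cv_repeats = 1,
               n_permutations = 5, eval_draws = 20, seed = 5)
  r1 <- do.call(select_features_on_split,
                c(args, list(y_val = fx$y[s$validation])))
  r2 <- do.call(select_features_on_split,
                c(args, list(y_val = sample(fx$y[s$validation]))))
  expect_identical(r1$features, r2$features)
  expect_identical(r1$importances, r2$importances)
  expect_identical(lapply(r1$trace$levels, `[[`, "labels"),
                   lapply(r2$trace$levels, `[[`, "labels"))
})

test_that("the selection report has coherent structure", {
  fx <- classification_fixture(n = 60, d = 8, informative = 2,
                               effect = 2.5, seed = 64)
  rep <- select_features(fx$x, fx$y, classifier = test_rf(),
                         cv_splits = 3, cv_repeats = 1,
                         n_permutations = 5, eval_draws = 30,
                         control = TRUE, seed = 6)
  lv <- rep$levels
  expect_true(all(diff(lv$n_features) < 0))           # strictly decreasing
  expect_true(all(lv$ci_lower <= lv$median_bacc + 1e-12))
  expect_true(all(lv$median_bacc <= lv$ci_upper + 1e-12))
  expect_equal(lv$n_features[1], 8)
  expect_equal(lv$pct_features[1], 100)
  expect_true(rep$recommended %in% lv$depth)
  expect_false(is.null(rep$control))
  expect_output(print(rep), "recommended level")
  # signal datasets classify clearly above chance on the full set
  expect_gt(lv$median_bacc[1], 0.7)
})

test_that("the selection pipeline is reproducible under its seed", {
  fx <- classification_fixture(n = 50, d = 6, informative = 1,
                               effect = 2, seed = 65)
  r1 <- select_features(fx$x, fx$y, classifier = test_rf(),
                        cv_splits = 3, cv_repeats = 1, n_permutations = 3,
                        eval_draws = 10, control = FALSE, seed = 7)
  r2 <- select_features(fx$x, fx$y, classifier = test_rf(),
                        cv_splits = 3, cv_repeats = 1, n_permutations = 3,
                        eval_draws = 10, control = FALSE, seed = 7)
  expect_identical(r1$levels, r2$levels)
  expect_identical(r1$importances, r2$importances)
})
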