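#' Balanced classification accuracy
#'
#' Mean of the per-class recalls over the classes present in `truth`; 0.5
#' is chance level for two balanced classes regardless of class imbalance
#' in the evaluation sample.
#'
#' @param truth vector of true class labels.
#' @param pred vector of predicted labels, same length.
#' @return numeric scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  cls <- unique(truth)
  mean(vapply(cls, function(k) mean(pred[truth == k] == k), numeric(1)))
}

#' Stratified holdout split
#'
#' Sets aside a validation fraction of the cases proportional to the
#' classes. Per class, `ceiling(fraction * n_class)` cases go to the
#' validation part (so every class is represented there and the split is
#' within one case of exact proportionality); the rest form the training
#' part.
#'
#' @param labels vector of class labels, one per case.
#' @param fraction validation fraction, in (0, 0.5).
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with integer index vectors `train` and `validation`
#'   (disjoint, union = all cases).
#' @examples
#' s <- stratified_holdout(rep(c("a", "b"), each = 100), 0.2, seed = 1)
#' length(s$validation)  # 40
#' @export
stratified_holdout <- function(labels, fraction = 0.2, seed = 1) {
  stopifnot(fraction > 0, fraction < 0.5)
  labels <- as.character(labels)
  if (anyNA(labels)) stop("missing class labels", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 2)) {
    stop(sprintf("class '%s' has fewer than 2 cases; cannot stratify",
                 names(tab)[which(tab < 2)[1L]]), call. = FALSE)
  }
  restore <- .with_local_seed(seed)
  on.exit(restore())
  val <- integer(0)
  for (k in names(tab)) {
    idx <- which(labels == k)
    n_val <- ceiling(fraction * length(idx))
    val <- c(val, sample(idx, n_val))
  }
  val <- sort(val)
  list(train = setdiff(seq_along(labels), val), validation = val)
}

#' Random-forest classifier contract
#'
#' The pipeline is classifier-agnostic: any list with `fit(x, y)`
#' returning a model and `predict(model, x)` returning class labels can
#' be plugged in. This default wraps [ranger::ranger()] random forests
#' (the per-fit seed is drawn from R's RNG, so results are reproducible
#' under [set.seed()]).
#'
#' @param num_trees number of trees.
#' @param ... further arguments to [ranger::ranger()].
#' @return list with elements `fit` and `predict`.
#' @export
rf_classifier <- function(num_trees = 500, ...) {
  list(
    fit = function(x, y) {
      ranger::ranger(x = as.data.frame(x), y = factor(y),
                     num.trees = num_trees,
                     seed = sample.int(.Machine$integer.max, 1), ...)
    },
    predict = function(model, x) {
      as.character(stats::predict(model, data = as.data.frame(x))$predictions)
    }
  )
}

# repeated stratified k-fold indices: list of (train, test) index pairs
.stratified_folds <- function(labels, n_splits, n_repeats) {
  labels <- as.character(labels)
  folds <- list()
  for (r in seq_len(n_repeats)) {
    assign_fold <- integer(length(labels))
    for (k in unique(labels)) {
      idx <- sample(which(labels == k))
      assign_fold[idx] <- rep_len(seq_len(n_splits), length(idx))
    }
    for (f in seq_len(n_splits)) {
      test <- which(assign_fold == f)
      if (length(unique(labels[-test])) < 2L || length(test) == 0L) next
      folds[[length(folds) + 1L]] <- list(train = setdiff(seq_along(labels), test),
                                          test = test)
    }
  }
  folds
}

#' Mean permutation importance over repeated cross-validation
#'
#' For each fold of a repeated stratified k-fold scheme, fits the
#' classifier on the fold's training part and measures, per feature, the
#' drop in balanced accuracy on the fold's test part when that feature's
#' column is randomly shuffled (`n_permutations` shuffles, drops
#' averaged). Importances are averaged across folds and floored at 0,
#' making the vector admissible for cABC analysis (a negative importance
#' means "no better than noise", which zero also encodes).
#'
#' @param x numeric feature matrix (cases x features).
#' @param y class labels.
#' @param classifier a classifier contract, see [rf_classifier()].
#' @param cv_splits folds per repeat (default 5).
#' @param cv_repeats repeats (default 20).
#' @param n_permutations shuffles per feature per fold (default 50).
#' @param seed integer seed.
#' @return named numeric vector of mean importances (>= 0), one per
#'   feature.
#' @export
mean_permutation_importance <- function(x, y, classifier = rf_classifier(),
                                        cv_splits = 5, cv_repeats = 20,
                                        n_permutations = 50, seed = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.character(y)
  restore <- .with_local_seed(seed)
  on.exit(restore())
  folds <- .stratified_folds(y, cv_splits, cv_repeats)
  d <- ncol(x)
  imp_sum <- numeric(d)
  for (fd in folds) {
    model <- tryCatch(
      classifier$fit(x[fd$train, , drop = FALSE], y[fd$train]),
      error = function(e) stop(sprintf(
        "classifier failed on a cross-validation fold: %s",
        conditionMessage(e)), call. = FALSE))
    xt <- x[fd$test, , drop = FALSE]
    yt <- y[fd$test]
    m <- nrow(xt)
    base <- balanced_accuracy(yt, classifier$predict(model, xt))
    for (j in seq_len(d)) {
      # stack the shuffled copies so the model scores them in one call
      xp <- xt[rep(seq_len(m), n_permutations), , drop = FALSE]
      perm <- as.vector(vapply(seq_len(n_permutations),
                               function(p) sample(m), integer(m)))
      xp[, j] <- xt[perm, j]
      pred <- classifier$predict(model, xp)
      drops <- vapply(seq_len(n_permutations), function(p) {
        idx <- ((p - 1) * m + 1):(p * m)
        base - balanced_accuracy(yt, pred[idx])
      }, numeric(1))
      imp_sum[j] <- imp_sum[j] + mean(drops)
    }
  }
  imp <- pmax(imp_sum / length(folds), 0)
  names(imp) <- colnames(x)
  imp
}

#' Median and percentile confidence interval of accuracy values
#'
#' Nonparametric summary of per-run balanced accuracies: the median and
#' the 2.5th / 97.5th percentiles (a 95% percentile interval). An
#' interval that includes 0.5 means the classifier cannot be considered
#' better than guessing.
#'
#' @param values numeric vector of per-run balanced accuracies.
#' @return list with `median`, `lower`, `upper`.
#' @examples
#' balanced_accuracy_ci(c(0.6, 0.7, 0.8))$median  # 0.7
#' @export
balanced_accuracy_ci <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  q <- unname(stats::quantile(values, c(0.025, 0.975), type = 7))
  list(median = stats::median(values), lower = q[1L], upper = q[2L])
}

# per-level evaluation: each run retrains the classifier on a stratified
# 80% resample of the training part (emulating the training variability of
# a repeated-CV scenario) and scores it on a random 80% draw of the
# holdout; holdout draws missing a class are redrawn
.holdout_accuracies <- function(classifier, x_train, y_train, x_val, y_val,
                                n_draws = 100, draw_fraction = 0.8) {
  n <- nrow(x_val)
  m <- max(2L, round(draw_fraction * n))
  cls <- unique(y_val)
  vapply(seq_len(n_draws), function(i) {
    tr <- unlist(lapply(unique(y_train), function(k) {
      idx <- which(y_train == k)
      sample(idx, max(2L, round(draw_fraction * length(idx))))
    }))
    model <- classifier$fit(x_train[tr, , drop = FALSE], y_train[tr])
    repeat {
      idx <- sample(n, m)
      if (all(cls %in% y_val[idx])) break
    }
    balanced_accuracy(y_val[idx],
                      classifier$predict(model, x_val[idx, , drop = FALSE]))
  }, numeric(1))
}

#' Feature selection by recursive cABC analysis of permutation importances
#'
#' The end-to-end protocol: (1) set aside a stratified holdout
#' (`holdout_fraction`, untouched during selection); (2) compute mean
#' permutation importances over a repeated stratified cross-validation of
#' the training part ([mean_permutation_importance()]); (3) run
#' [recursive_cabc()] on the mean importances; (4) for the full set and
#' every recursion level, evaluate `eval_draws` training/evaluation runs —
#' each retrains the classifier on a stratified 80% resample of the
#' training part restricted to the level's features and scores balanced
#' accuracy on a random 80% draw of the holdout — and summarise them with
#' [balanced_accuracy_ci()]; (5) optionally
#' rerun the whole pipeline once with the class labels randomly permuted
#' (the permuted-target control — its interval should cover 0.5).
#'
#' The per-level feature sets are a pure function of the training part
#' (the holdout influences neither importances nor cABC boundaries). The
#' classifier-performance termination criterion is applied on top of the
#' computed levels: the `recommended` level is the deepest one whose
#' interval lower bound stays above `performance_floor` and whose median
#' does not drop more than `performance_delta` below the full-feature
#' median.
#'
#' @param x numeric feature matrix (cases x features, >= 3 features).
#' @param y class labels (>= 2 cases per class).
#' @param classifier classifier contract ([rf_classifier()] by default).
#' @param holdout_fraction validation fraction (default 0.2).
#' @param cv_splits,cv_repeats,n_permutations cross-validation scheme for
#'   the importances (defaults 5, 20, 50).
#' @param eval_draws number of 80% holdout draws per evaluation (default
#'   100).
#' @param alpha uniformity-test level of the recursion (default 0.05).
#' @param performance_floor minimal acceptable interval lower bound
#'   (default 0.5 = chance).
#' @param performance_delta maximal acceptable drop of the median below
#'   the full-feature median (default 0.10).
#' @param control logical, run the permuted-target control (default
#'   `TRUE`).
#' @param seed integer seed governing split, folds, shuffles and draws.
#' @param ... passed to [recursive_cabc()].
#' @return object of class `"cabc_selection"`: list with `importances`,
#'   `trace` (the `"recabc"`), `levels` (data frame: depth, set name, KS
#'   p-value of the level's input, feature count and percent, median
#'   balanced accuracy with interval bounds), `features` (list of
#'   per-level feature vectors, element 1 = full set), `recommended`
#'   (depth of the recommended level), `control` (accuracy summary of the
#'   permuted-target run, or `NULL`), `split` (the holdout indices),
#'   `config`.
#' @examples
#' \donttest{
#' fx <- classification_fixture(n = 60, d = 10, informative = 2,
#'                              effect = 2, seed = 1)
#' rep <- select_features(fx$x, fx$y, cv_repeats = 2, n_permutations = 5,
#'                        control = FALSE, seed = 1)
#' rep$levels
#' }
#' @export
select_features <- function(x, y, classifier = rf_classifier(),
                            holdout_fraction = 0.2, cv_splits = 5,
                            cv_repeats = 20, n_permutations = 50,
                            eval_draws = 100, alpha = 0.05,
                            performance_floor = 0.5,
                            performance_delta = 0.10,
                            control = TRUE, seed = 1, ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.character(y)
  stopifnot(nrow(x) == length(y), ncol(x) >= 3)
  cfg <- list(holdout_fraction = holdout_fraction, cv_splits = cv_splits,
              cv_repeats = cv_repeats, n_permutations = n_permutations,
              eval_draws = eval_draws, alpha = alpha,
              performance_floor = performance_floor,
              performance_delta = performance_delta, seed = seed)

  split <- stratified_holdout(y, holdout_fraction, seed = seed)
  main <- select_features_on_split(
    x[split$train, , drop = FALSE], y[split$train],
    x[split$validation, , drop = FALSE], y[split$validation],
    classifier = classifier, cv_splits = cv_splits,
    cv_repeats = cv_repeats, n_permutations = n_permutations,
    eval_draws = eval_draws, alpha = alpha,
    performance_floor = performance_floor,
    performance_delta = performance_delta, seed = seed, ...)

  ctrl <- NULL
  if (control) {
    restore <- .with_local_seed(seed + 104729L)
    y_perm <- sample(y)
    restore()
    csplit <- stratified_holdout(y_perm, holdout_fraction,
                                 seed = seed + 104729L)
    cmain <- select_features_on_split(
      x[csplit$train, , drop = FALSE], y_perm[csplit$train],
      x[csplit$validation, , drop = FALSE], y_perm[csplit$validation],
      classifier = classifier, cv_splits = cv_splits,
      cv_repeats = cv_repeats, n_permutations = n_permutations,
      eval_draws = eval_draws, alpha = alpha,
      performance_floor = performance_floor,
      performance_delta = performance_delta, seed = seed + 104729L, ...)
    # report the control at its innermost computed level
    last <- nrow(cmain$levels)
    ctrl <- list(median = cmain$levels$median_bacc[last],
                 lower = cmain$levels$ci_lower[last],
                 upper = cmain$levels$ci_upper[last],
                 n_features = cmain$levels$n_features[last],
                 levels = cmain$levels)
  }

  structure(
    c(main, list(control = ctrl, split = split, config = cfg)),
    class = "cabc_selection"
  )
}

#' Selection pipeline on a pre-made train/validation split
#'
#' The split-level work-horse behind [select_features()], exposed so a
#' given holdout can be reused or manipulated (e.g. to verify that the
#' validation part cannot leak into the selected sets). Returns the same
#' fields as [select_features()] minus `control`/`split`/`config`.
#'
#' @param x_train,y_train training cases and labels.
#' @param x_val,y_val held-out cases and labels (used only for
#'   evaluation).
#' @inheritParams select_features
#' @return list with `importances`, `trace`, `levels`, `features`,
#'   `recommended`.
#' @export
select_features_on_split <- function(x_train, y_train, x_val, y_val,
                                     classifier = rf_classifier(),
                                     cv_splits = 5, cv_repeats = 20,
                                     n_permutations = 50, eval_draws = 100,
                                     alpha = 0.05, performance_floor = 0.5,
                                     performance_delta = 0.10, seed = 1,
                                     ...) {
  x_train <- as.matrix(x_train)
  x_val <- as.matrix(x_val)
  imp <- mean_permutation_importance(
    x_train, y_train, classifier = classifier, cv_splits = cv_splits,
    cv_repeats = cv_repeats, n_permutations = n_permutations, seed = seed)

  trace <- if (sum(imp) > 0) {
    recursive_cabc(imp, alpha = alpha, ...)
  } else {
    # no feature ever beat its own permutation: nothing to partition,
    # report the full set only
    structure(list(levels = list(), final_set = names(imp),
                   final_name = "full set",
                   stop_reason = "degenerate_importances",
                   stop_p_value = NA_real_, alpha = alpha, input = imp),
              class = "recabc")
  }

  # level 0 = full feature set, then one row per recursion level
  feats <- c(list(colnames(x_train)),
             lapply(trace$levels, function(l) l$fit$a))
  ks_p <- c(ks_uniformity_test(imp)$p_value,
            vapply(trace$levels, function(l) {
              v <- imp[l$fit$a]
              if (length(v) >= 3L) ks_uniformity_test(v)$p_value
              else NA_real_
            }, numeric(1)))

  restore <- .with_local_seed(seed + 15485863L)
  on.exit(restore())
  evals <- lapply(feats, function(fs) {
    acc <- .holdout_accuracies(classifier,
                               x_train[, fs, drop = FALSE], y_train,
                               x_val[, fs, drop = FALSE], y_val,
                               n_draws = eval_draws)
    balanced_accuracy_ci(acc)
  })

  d <- ncol(x_train)
  lv <- data.frame(
    depth = seq_along(feats) - 1L,
    set = c("full", vapply(seq_along(trace$levels), function(k)
      paste(rep("A", k), collapse = ""), "")),
    ks_p = ks_p,
    n_features = vapply(feats, length, 0L),
    pct_features = 100 * vapply(feats, length, 0L) / d,
    median_bacc = vapply(evals, `[[`, 0, "median"),
    ci_lower = vapply(evals, `[[`, 0, "lower"),
    ci_upper = vapply(evals, `[[`, 0, "upper")
  )

  full_median <- lv$median_bacc[1L]
  ok <- lv$ci_lower > performance_floor &
    lv$median_bacc >= full_median - performance_delta
  recommended <- if (any(ok)) max(lv$depth[ok]) else 0L

  list(importances = imp, trace = trace, levels = lv, features = feats,
       recommended = recommended)
}

#' @export
print.cabc_selection <- function(x, ...) {
  cat("Feature selection by recursive computed ABC analysis\n\n")
  lv <- x$levels
  lv$pct_features <- sprintf("%.1f%%", lv$pct_features)
  lv$accuracy <- sprintf("%.3f (%.3f-%.3f)", lv$median_bacc, lv$ci_lower,
                         lv$ci_upper)
  print(lv[, c("depth", "set", "ks_p", "n_features", "pct_features",
               "accuracy")], row.names = FALSE, digits = 3)
  cat(sprintf("\nrecommended level: %d (%d features)\n", x$recommended,
              x$levels$n_features[x$recommended + 1L]))
  if (!is.null(x$control)) {
    cat(sprintf("permuted-target control: %.3f (%.3f-%.3f) with %d features\n",
                x$control$median, x$control$lower, x$control$upper,
                x$control$n_features))
  }
  invisible(x)
}
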