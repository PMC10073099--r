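#' Kolmogorov-Smirnov test against the uniform distribution
#'
#' One-sample KS test of a value set against `Uniform(min(x), max(x))`,
#' the uniformity criterion that terminates recursive cABC analysis: any
#' compact subset of a uniform distribution is again uniform, so the
#' uniform distribution is a fixed point of ABC analysis and further
#' recursion would only ever peel off the next 41% of items.
#'
#' The reference bounds are estimated from the sample itself (its minimum
#' and maximum), which makes the p-value approximate; results of different
#' uniformity tests can disagree when p is close to the significance
#' level, so the stopping decision should be read as a heuristic near the
#' boundary. The identity distribution (all values equal) is *not* uniform
#' — a degenerate spike — and is reported as `p = 0` with
#' `identity = TRUE`.
#'
#' @param x numeric vector, `n >= 3`.
#' @return list with `statistic` (KS D), `p_value`, and logical
#'   `identity`.
#' @examples
#' ks_uniformity_test(seq(2, 7, length.out = 50))$p_value  # near 1
#' @export
ks_uniformity_test <- function(x) {
  x <- as.double(x)
  if (anyNA(x) || length(x) < 3L) {
    stop("uniformity test needs at least 3 non-missing values", call. = FALSE)
  }
  if (max(x) == min(x)) {
    return(list(statistic = 1, p_value = 0, identity = TRUE))
  }
  kt <- suppressWarnings(
    stats::ks.test(x, "punif", min = min(x), max = max(x))
  )
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       identity = FALSE)
}

#' Recursive computed ABC analysis
#'
#' Applies [cabc()] repeatedly to the previous subset "A", producing
#' nested sets "A", "AA", "AAA", ... of increasingly important items,
#' until a termination criterion fires:
#'
#' * `uniform_distribution` — the candidate set's values pass the KS
#'   uniformity test ([ks_uniformity_test()]) at level `alpha`; the
#'   uniform distribution is the fixed point of ABC analysis.
#' * `target_size_reached` — the candidate set is no larger than
#'   `target_size` (a contextual stop; `target_size = "miller"` uses 9,
#'   the upper end of Miller's 7±2 span for human working memory, so
#'   recursion stops once the set is human-graspable).
#' * `max_depth` — the level budget is exhausted.
#' * `too_few_items` — fewer than 3 items remain (no curve can be built).
#' * `no_shrinkage` — a level failed to make "A" strictly smaller.
#'
#' A third, classifier-based criterion (performance must stay above
#' chance) belongs to the feature-selection pipeline, which injects it via
#' `level_callback`: a `function(labels, depth)` called before each
#' split with the candidate item labels; returning `FALSE` stops the
#' recursion with `stop_reason = "callback"`.
#'
#' By default the uniformity test is applied to the candidate input of
#' each level, so an initially uniform vector stops at depth 0 with the
#' full set returned; `check_input = FALSE` defers the first check until
#' after the first split.
#'
#' @param x named numeric vector of non-negative item values.
#' @param alpha significance level of the uniformity stopping test
#'   (default 0.05).
#' @param target_size optional integer stop size, or `"miller"`.
#' @param max_depth optional maximum number of splits.
#' @param check_input logical, test the depth-0 input for uniformity.
#' @param level_callback optional `function(labels, depth) -> logical`.
#' @param ... further arguments passed to [cabc()].
#' @return object of class `"recabc"`: list with `levels` (one entry per
#'   performed split: `depth`, `labels` (input of the split), `fit` (the
#'   `"cabc"` object), `p_value` of the input's uniformity test),
#'   `final_set` (labels of the innermost "A"), `final_name` ("A", "AA",
#'   ...), `stop_reason`, `stop_p_value` (uniformity p of the final set)
#'   and `alpha`.
#' @examples
#' imp <- c(100, 95, 10, 9, 8, rep(0.5, 20))
#' names(imp) <- paste0("f", seq_along(imp))
#' tr <- recursive_cabc(imp)
#' tr$final_set
#' @export
recursive_cabc <- function(x, alpha = 0.05, target_size = NULL,
                           max_depth = NULL, check_input = TRUE,
                           level_callback = NULL, ...) {
  stopifnot(alpha > 0, alpha < 1)
  if (identical(target_size, "miller")) target_size <- 9L
  if (!is.null(target_size)) stopifnot(target_size >= 1)
  xv <- as_item_values(x)

  levels <- list()
  current <- xv
  depth <- 0L
  stop_reason <- NULL
  stop_p <- NA_real_

  repeat {
    if (!is.null(target_size) && length(current) <= target_size) {
      stop_reason <- "target_size_reached"; break
    }
    if (length(current) < 3L) {
      stop_reason <- "too_few_items"; break
    }
    ut <- ks_uniformity_test(current)
    if ((check_input || depth > 0L) && !ut$identity &&
        ut$p_value > alpha) {
      stop_reason <- "uniform_distribution"; stop_p <- ut$p_value; break
    }
    if (!is.null(max_depth) && depth >= max_depth) {
      stop_reason <- "max_depth"; break
    }
    if (!is.null(level_callback) &&
        !isTRUE(level_callback(names(current), depth))) {
      stop_reason <- "callback"; break
    }
    fit <- cabc(current, ...)
    if (length(fit$a) >= length(current)) {
      stop_reason <- "no_shrinkage"; break
    }
    depth <- depth + 1L
    levels[[depth]] <- list(depth = depth, labels = names(current),
                            fit = fit, p_value = ut$p_value)
    current <- current[fit$a]
  }
  if (is.na(stop_p) && length(current) >= 3L) {
    stop_p <- ks_uniformity_test(current)$p_value
  }

  structure(
    list(levels = levels, final_set = names(current),
         final_name = if (depth == 0L) "full set" else
           paste(rep("A", depth), collapse = ""),
         stop_reason = stop_reason, stop_p_value = stop_p,
         alpha = alpha, input = xv),
    class = "recabc"
  )
}

#' @export
print.recabc <- function(x, ...) {
  cat("Recursive computed ABC analysis\n")
  cat(sprintf("  input: %d items; %d level(s); stop: %s\n",
              length(x$input), length(x$levels), x$stop_reason))
  for (lv in x$levels) {
    cat(sprintf("  %s%s: %d -> %d items (KS uniformity p = %.3g)\n",
                strrep(" ", lv$depth),
                paste(rep("A", lv$depth), collapse = ""),
                length(lv$labels), length(lv$fit$a), lv$p_value))
  }
  cat(sprintf("  final set (%s): %d item(s)", x$final_name,
              length(x$final_set)))
  if (length(x$final_set) <= 12) {
    cat(": ", paste(x$final_set, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.recabc <- function(object, ...) {
  lv <- object$levels
  d <- data.frame(
    depth = vapply(lv, `[[`, 0L, "depth"),
    set = vapply(lv, function(l) paste(rep("A", l$depth), collapse = ""),
                 ""),
    n_in = vapply(lv, function(l) length(l$labels), 0L),
    n_out = vapply(lv, function(l) length(l$fit$a), 0L),
    ks_p_input = vapply(lv, `[[`, 0, "p_value")
  )
  structure(list(table = d, stop_reason = object$stop_reason,
                 stop_p_value = object$stop_p_value,
                 final_set = object$final_set),
            class = "summary.recabc")
}

#' @export
print.summary.recabc <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("stopped: %s (final-set uniformity p = %.3g)\n",
              x$stop_reason, x$stop_p_value))
  invisible(x)
}

#' @export
plot.recabc <- function(x, ...) {
  k <- length(x$levels)
  if (k == 0L) {
    stop("no splits were performed; nothing to plot", call. = FALSE)
  }
  old <- graphics::par(mfrow = c(1, k))
  on.exit(graphics::par(old))
  for (lv in x$levels) {
    plot(lv$fit, main = sprintf("level %d (n = %d)", lv$depth,
                                length(lv$labels)), ...)
  }
  invisible(x)
}
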