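#' Synthetic tiered importance vector
#'
#' Generates a right-skewed importance vector from explicit value tiers,
#' the structure typical of classifier feature importances: a few dominant
#' items, a middle band, and a long tail of near-noise values. Each tier
#' draws its values uniformly from the given range.
#'
#' @param tiers list of `list(n = <count>, range = c(lo, hi))`, ordered
#'   from most to least important.
#' @param seed integer seed; identical seeds give identical vectors.
#' @return named numeric vector of length `sum(n)`, labels `t<k>_i<j>`
#'   encoding tier and index.
#' @examples
#' x <- importance_fixture(list(list(n = 2, range = c(90, 100)),
#'                              list(n = 8, range = c(8, 12)),
#'                              list(n = 90, range = c(0, 0.2))), seed = 1)
#' @export
importance_fixture <- function(tiers, seed = 1) {
  stopifnot(is.list(tiers), length(tiers) >= 1)
  restore <- .with_local_seed(seed)
  on.exit(restore())
  vals <- numeric(0)
  for (k in seq_along(tiers)) {
    t <- tiers[[k]]
    stopifnot(t$n >= 1, length(t$range) == 2, all(t$range >= 0))
    v <- stats::runif(t$n, t$range[1L], t$range[2L])
    names(v) <- sprintf("t%d_i%d", k, seq_len(t$n))
    vals <- c(vals, v)
  }
  vals
}

#' Synthetic classification dataset with planted informative features
#'
#' Two-class Gaussian dataset: `informative` features differ between the
#' classes by `effect` standard deviations (the standardized mean
#' difference); the remaining features are pure noise, exchangeable with a
#' permuted-label version of the data. Used to test that the
#' feature-selection pipeline recovers planted structure and reports
#' chance-level accuracy under a permuted-target null.
#'
#' @param n number of cases.
#' @param d number of features (>= `informative`).
#' @param informative number of class-informative features.
#' @param effect standardized mean difference between classes on the
#'   informative features (>= 0; 0 gives a pure null dataset).
#' @param balance fraction of cases in class "case" (default 0.5).
#' @param seed integer seed.
#' @return list with `x` (n x d matrix, informative features first,
#'   columns `inf1.., noise1..`), `y` (character labels "case"/"control"),
#'   `informative` (names of the planted features).
#' @examples
#' fx <- classification_fixture(n = 50, d = 10, informative = 2,
#'                              effect = 1.5, seed = 7)
#' table(fx$y)
#' @export
classification_fixture <- function(n = 100, d = 50, informative = 2,
                                   effect = 1.5, balance = 0.5, seed = 1) {
  stopifnot(informative <= d, effect >= 0, n >= 4, balance > 0,
            balance < 1)
  restore <- .with_local_seed(seed)
  on.exit(restore())
  n_case <- max(2L, round(balance * n))
  y <- c(rep("case", n_case), rep("control", n - n_case))
  x <- matrix(stats::rnorm(n * d), n, d)
  inf_names <- if (informative > 0) paste0("inf", seq_len(informative))
               else character(0)
  colnames(x) <- c(inf_names,
                   paste0("noise", seq_len(d - informative)))
  if (informative > 0) {
    x[y == "case", seq_len(informative)] <-
      x[y == "case", seq_len(informative)] + effect
  }
  list(x = x, y = y, informative = inf_names)
}
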