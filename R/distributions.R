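#' Names of the benchmark distributions
#'
#' The simulation harness draws item values from six laws commonly used to
#' validate ABC-type categorisation: chi-square with 1 df, lognormal with
#' log-mean 0 and log-sd 3, unit-rate exponential, Pareto with shape 1.18
#' (numpy convention, i.e. the Lomax form `U^(-1/alpha) - 1` supported on
#' `[0, Inf)`), uniform on `[0, 100]`, and Gaussian N(5, 1) with the rare
#' negative draws rejected and redrawn (probability about 3e-7 per draw;
#' clipping would create a point mass at zero).
#'
#' @return character vector of distribution identifiers.
#' @export
benchmark_distributions <- function() {
  c("chisq_df1", "lognormal_mu0_sigma3", "exponential_beta1",
    "pareto_alpha1.18", "uniform_0_100", "gaussian_mu5_sigma1")
}

#' Draw one benchmark sample
#'
#' Deterministic given `(seed, replicate)`: each replicate uses the
#' sub-seed `seed + replicate`, so replicates are independent yet
#' reproducible individually.
#'
#' @param distribution one of [benchmark_distributions()].
#' @param n_items sample size (>= 10).
#' @param seed base integer seed.
#' @param replicate replicate index (>= 1).
#' @return named numeric vector (labels `item1..itemN`).
#' @examples
#' x <- sample_distribution("uniform_0_100", 1000, seed = 42, replicate = 1)
#' range(x)
#' @export
sample_distribution <- function(distribution, n_items, seed = 42,
                                replicate = 1L) {
  distribution <- match.arg(distribution, benchmark_distributions())
  stopifnot(n_items >= 10, replicate >= 1)
  rng <- .with_local_seed(seed + as.integer(replicate))
  on.exit(rng())
  x <- switch(distribution,
    chisq_df1            = stats::rchisq(n_items, df = 1),
    lognormal_mu0_sigma3 = stats::rlnorm(n_items, meanlog = 0, sdlog = 3),
    exponential_beta1    = stats::rexp(n_items, rate = 1),
    pareto_alpha1.18     = stats::runif(n_items)^(-1 / 1.18) - 1,
    uniform_0_100        = stats::runif(n_items, 0, 100),
    gaussian_mu5_sigma1  = {
      v <- stats::rnorm(n_items, 5, 1)
      while (any(v < 0)) v[v < 0] <- stats::rnorm(sum(v < 0), 5, 1)
      v
    }
  )
  names(x) <- paste0("item", seq_len(n_items))
  x
}

# set the RNG locally; returns a restore function for on.exit
.with_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Run the subset-"A" size benchmark for one distribution
#'
#' Draws `replicates` samples, runs [cabc()] on each, and aggregates the
#' percentage of items assigned to subset "A". A one-sample Wilcoxon
#' signed-rank test compares the percentages with the 41% fixed point of
#' the uniform distribution.
#'
#' @param distribution one of [benchmark_distributions()].
#' @param n_items sample size per replicate (>= 10).
#' @param replicates number of replicate samples (>= 2, default 20).
#' @param seed base seed.
#' @param ... passed to [cabc()].
#' @return list with `distribution`, `n_items`, `a_percent` (per-replicate
#'   vector), `mean`, `sd`, and `p_vs_41` (signed-rank p against 41).
#' @examples
#' \donttest{
#' run_benchmark("uniform_0_100", 1000, replicates = 5)$mean  # ~41
#' }
#' @export
run_benchmark <- function(distribution, n_items = 1000, replicates = 20,
                          seed = 42, ...) {
  stopifnot(replicates >= 2)
  a_pct <- vapply(seq_len(replicates), function(r) {
    x <- sample_distribution(distribution, n_items, seed = seed,
                             replicate = r)
    100 * cabc(x, ...)$a_fraction
  }, numeric(1))
  p41 <- if (stats::sd(a_pct) == 0) {
    if (all(a_pct == 41)) 1 else 0
  } else {
    suppressWarnings(stats::wilcox.test(a_pct, mu = 41)$p.value)
  }
  list(distribution = distribution, n_items = n_items,
       a_percent = a_pct, mean = mean(a_pct), sd = stats::sd(a_pct),
       p_vs_41 = p41)
}

#' Benchmark grid over distributions and sample sizes
#'
#' Cross product of [run_benchmark()] over sample sizes and distributions,
#' reporting mean and SD of the subset-"A" percentage per cell.
#'
#' @param sizes integer vector of sample sizes.
#' @param distributions character vector of distribution names.
#' @param replicates replicates per cell.
#' @param seed base seed.
#' @param ... passed to [cabc()].
#' @return data frame with columns `distribution`, `n_items`, `mean_a_pct`,
#'   `sd_a_pct`, `p_vs_41`.
#' @export
benchmark_grid <- function(sizes = c(10, 100, 1000, 10000),
                           distributions = benchmark_distributions(),
                           replicates = 20, seed = 42, ...) {
  rows <- list()
  for (d in distributions) {
    for (n in sizes) {
      b <- run_benchmark(d, n_items = n, replicates = replicates,
                         seed = seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        distribution = d, n_items = n, mean_a_pct = b$mean,
        sd_a_pct = b$sd, p_vs_41 = b$p_vs_41
      )
    }
  }
  do.call(rbind, rows)
}
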