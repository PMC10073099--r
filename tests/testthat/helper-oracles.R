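# Independent oracles used across the suite. Each re-derives a quantity by
# a route that shares no code with the implementation it checks.

# Juran point by brute force: dense grid argmin of the distance to (0, 1)
# on an interpolant built here from the raw values.
oracle_juran <- function(values, grid_n = 1e6) {
  xs <- sort(values, decreasing = TRUE)
  n <- length(xs)
  f <- splinefun(c(0, seq_len(n) / n), c(0, cumsum(xs) / sum(xs)),
                 method = "hyman")
  g <- seq(0, 1, length.out = grid_n + 1)
  d2 <- g^2 + (1 - f(g))^2
  g[which.min(d2)]
}

# break-even by a finite-difference scan for the first slope-1 crossing
oracle_break_even <- function(values, from_x = 0, grid_n = 1e6) {
  xs <- sort(values, decreasing = TRUE)
  n <- length(xs)
  f <- splinefun(c(0, seq_len(n) / n), c(0, cumsum(xs) / sum(xs)),
                 method = "hyman")
  g <- seq(from_x, 1, length.out = grid_n + 1)
  h <- (1 - from_x) / grid_n
  slope <- (f(pmin(g + h, 1)) - f(pmax(g - h, 0))) /
    (pmin(g + h, 1) - pmax(g - h, 0))
  i <- which(slope <= 1)[1]
  if (is.na(i)) 1 else g[i]
}

# one-sample KS statistic against Uniform(min, max) from the ECDF distance
oracle_ks_stat <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  Fu <- (xs - min(xs)) / (max(xs) - min(xs))
  max(pmax(seq_len(n) / n - Fu, Fu - (seq_len(n) - 1) / n))
}

# a second, straightforward implementation of the whole partition pipeline:
# own curve, own grid searches, own rank cuts
oracle_partition <- function(values) {
  xs <- sort(values, decreasing = TRUE)
  n <- length(xs)
  f <- splinefun(c(0, seq_len(n) / n), c(0, cumsum(xs) / sum(xs)),
                 method = "hyman")
  g <- seq(0, 1, length.out = 2e5 + 1)
  jx <- g[which.min(g^2 + (1 - f(g))^2)]
  h <- 1 / 2e5
  gg <- g[g >= jx]
  slope <- (f(pmin(gg + h, 1)) - f(pmax(gg - h, 0))) /
    (pmin(gg + h, 1) - pmax(gg - h, 0))
  i <- which(slope <= 1)[1]
  bx <- if (is.na(i)) 1 else gg[i]
  n_a <- max(1, round(jx * n))
  n_ab <- max(n_a, round(bx * n))
  list(a = names(xs)[seq_len(n_a)],
       b = if (n_ab > n_a) names(xs)[(n_a + 1):n_ab] else character(0),
       c = if (n_ab < n) names(xs)[(n_ab + 1):n] else character(0))
}

named <- function(x, prefix = "v") setNames(x, paste0(prefix, seq_along(x)))

# two-stage dense-grid versions reaching 1e-6 resolution cheaply: coarse
# scan, then a fine scan inside the winning cell (still pure brute force)
oracle_juran_fine <- function(values) {
  xs <- sort(values, decreasing = TRUE)
  n <- length(xs)
  f <- splinefun(c(0, seq_len(n) / n), c(0, cumsum(xs) / sum(xs)),
                 method = "hyman")
  d2 <- function(p) p^2 + (1 - f(p))^2
  g <- seq(0, 1, length.out = 8193)
  i <- which.min(d2(g))
  g2 <- seq(g[max(1, i - 1)], g[min(length(g), i + 1)],
            length.out = 8001)
  g2[which.min(d2(g2))]
}

oracle_break_even_fine <- function(values, from_x = 0) {
  xs <- sort(values, decreasing = TRUE)
  n <- length(xs)
  f <- splinefun(c(0, seq_len(n) / n), c(0, cumsum(xs) / sum(xs)),
                 method = "hyman")
  slope <- function(p, h = 5e-8) (f(pmin(p + h, 1)) - f(pmax(p - h, 0))) /
    (pmin(p + h, 1) - pmax(p - h, 0))
  g <- seq(from_x, 1, length.out = 8193)
  s <- slope(g, h = 1e-6)
  i <- which(s <= 1)[1]
  if (is.na(i)) return(1)
  if (i == 1) return(from_x)
  g2 <- seq(g[i - 1], g[i], length.out = 8001)
  s2 <- slope(g2)
  g2[which(s2 <= 1)[1]]
}
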