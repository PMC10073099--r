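#' Computed ABC analysis
#'
#' Partitions a vector of non-negative item values into subsets "A" (the
#' important few), "B" (intermediate) and "C" (the trivial many) with
#' boundaries computed from the ABC curve instead of fixed heuristics such
#' as 80/20. The A|B boundary is the x-coordinate of the Juran point (the
#' curve point nearest the ideal Pareto point (0, 1)); the B|C boundary is
#' the break-even point where the curve slope equals 1, searched to the
#' right of the A|B boundary.
#'
#' Item counts are obtained from boundary fractions as
#' `|A| = max(1, round(Jx * n))` and the B|C cut at `round(Bx * n)`; cuts
#' are made by rank in the stable descending order (ties keep input order),
#' so tied values may straddle a boundary unless `keep_ties = TRUE`, which
#' widens "A" (and "B") to include equal-valued neighbours of the last
#' member. Items with value exactly 0 contribute no yield and are always
#' assigned to "C".
#'
#' The partition is invariant to multiplying all values by any positive
#' constant, but not to translation; `min_to_zero = TRUE` applies the
#' minimum-to-zero normalisation before the curve is built.
#'
#' @param x numeric vector of non-negative item values; names are item
#'   labels.
#' @param method spline interpolation for the curve, `"hyman"` (monotone,
#'   default) or `"natural"`.
#' @param bc one of `"slope"` (default; break-even slope = 1 on the full
#'   interpolant, searched from the A|B boundary) or `"subcurve"` (a
#'   Juran-point search on the re-normalised curve of the items right of
#'   the A|B boundary). The two coincide for concave curves whose slope at
#'   the Juran point exceeds 1.
#' @param keep_ties logical; widen boundary cuts to keep equal values
#'   together (in the higher subset).
#' @param min_to_zero logical; shift values so the minimum is zero first.
#' @param force logical; with fewer than 3 items return the trivial
#'   all-"A" partition instead of an error.
#' @return an object of class `"cabc"`: list with elements `a`, `b`, `c`
#'   (character vectors of labels, decreasing value order), `juran` and
#'   `break_even` (boundary points as returned by [juran_point()] /
#'   [break_even_point()]), `a_fraction` (`|A|/n`), `curve` (the
#'   `"abc_curve"`), `values` (input values, original order) and `call`.
#' @examples
#' imp <- c(gene1 = 40, gene2 = 12, gene3 = 10, gene4 = 3, gene5 = 1,
#'          gene6 = 0.5, gene7 = 0.2, gene8 = 0.1)
#' fit <- cabc(imp)
#' fit$a
#' summary(fit)
#' @references Juran-point/break-even boundary computation for item
#'   categorization on ABC (reversed Lorenz) curves.
#' @export
cabc <- function(x, method = c("hyman", "natural"),
                 bc = c("slope", "subcurve"),
                 keep_ties = FALSE, min_to_zero = FALSE, force = FALSE) {
  method <- match.arg(method)
  bc <- match.arg(bc)
  cl <- match.call()
  xv <- as_item_values(x, min_to_zero = min_to_zero, force = force)
  n <- length(xv)
  if (n < 3L) {  # only reachable with force = TRUE
    out <- list(a = names(xv), b = character(0), c = character(0),
                juran = list(x = 1, y = 1, distance = 1),
                break_even = list(x = 1, y = 1, degenerate = TRUE),
                a_fraction = 1, curve = NULL, values = xv, call = cl)
    return(structure(out, class = "cabc"))
  }
  curve <- abc_curve(xv, method = method)
  jp <- juran_point(curve)
  be <- if (bc == "slope") {
    break_even_point(curve, from_x = jp$x)
  } else {
    .subcurve_juran(curve, jp$x)
  }

  n_a <- max(1L, as.integer(round(jp$x * n)))
  n_ab <- max(n_a, as.integer(round(be$x * n)))
  sorted_labels <- names(curve$values)
  if (keep_ties) {
    n_a <- .widen_for_ties(curve$values, n_a)
    n_ab <- max(n_a, .widen_for_ties(curve$values, n_ab))
  }
  a <- sorted_labels[seq_len(n_a)]
  b <- if (n_ab > n_a) sorted_labels[(n_a + 1L):n_ab] else character(0)
  cc <- if (n_ab < n) sorted_labels[(n_ab + 1L):n] else character(0)

  # zero-valued items yield nothing: force them into C
  zeros <- names(curve$values)[curve$values == 0]
  if (length(zeros)) {
    a <- setdiff(a, zeros)
    b <- setdiff(b, zeros)
    cc <- c(setdiff(cc, zeros), zeros)
    if (!length(a)) {  # cannot happen unless all positive mass is tiny
      a <- cc[1L]; cc <- cc[-1L]
    }
  }

  structure(
    list(a = a, b = b, c = cc, juran = jp, break_even = be,
         a_fraction = length(a) / n, curve = curve, values = xv,
         call = cl),
    class = "cabc"
  )
}

# B|C by a Juran-style search on the sub-curve right of the A|B boundary:
# re-normalise the curve segment [jx, 1] x [Y(jx), 1] to the unit square,
# find its Juran point, and map back.
.subcurve_juran <- function(curve, jx) {
  y0 <- curve$fun(jx)
  if (1 - jx < 1e-9 || 1 - y0 < 1e-9) {
    return(list(x = 1, y = curve$fun(1), degenerate = TRUE))
  }
  f <- function(q) {
    p <- jx + q * (1 - jx)
    yy <- (curve$fun(p) - y0) / (1 - y0)
    q^2 + (1 - yy)^2
  }
  q <- .grid_optimize(f, 0, 1)
  p <- jx + q * (1 - jx)
  list(x = p, y = curve$fun(p), degenerate = FALSE)
}

# extend a rank cut to include all items tied with the last included value
.widen_for_ties <- function(sorted_values, k) {
  if (k >= length(sorted_values)) return(length(sorted_values))
  v <- sorted_values[k]
  while (k < length(sorted_values) && sorted_values[k + 1L] == v) k <- k + 1L
  k
}

#' @export
print.cabc <- function(x, ...) {
  n <- length(x$values)
  cat("Computed ABC analysis\n")
  cat(sprintf("  n = %d items; A: %d (%.1f%%), B: %d, C: %d\n",
              n, length(x$a), 100 * x$a_fraction, length(x$b), length(x$c)))
  cat(sprintf("  A|B boundary (Juran point): x = %.4f, y = %.4f\n",
              x$juran$x, x$juran$y))
  deg <- if (isTRUE(x$break_even$degenerate)) " [degenerate: slope never exceeds 1]" else ""
  cat(sprintf("  B|C boundary (break-even):  x = %.4f, y = %.4f%s\n",
              x$break_even$x, x$break_even$y, deg))
  invisible(x)
}

#' @export
summary.cabc <- function(object, ...) {
  n <- length(object$values)
  memb <- membership(object)
  vals <- object$values[names(memb)]
  tab <- data.frame(
    subset = c("A", "B", "C"),
    n = c(length(object$a), length(object$b), length(object$c)),
    fraction = c(length(object$a), length(object$b), length(object$c)) / n,
    yield = c(sum(vals[memb == "A"]), sum(vals[memb == "B"]),
              sum(vals[memb == "C"])) / sum(vals)
  )
  structure(list(table = tab, juran = object$juran,
                 break_even = object$break_even, n = n),
            class = "summary.cabc")
}

#' @export
print.summary.cabc <- function(x, ...) {
  cat("Computed ABC analysis of", x$n, "items\n\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("\nJuran point (%.4f, %.4f); break-even (%.4f, %.4f)\n",
              x$juran$x, x$juran$y, x$break_even$x, x$break_even$y))
  invisible(x)
}

#' Subset membership of each item
#'
#' @param object a `"cabc"` object.
#' @return a factor (`A`/`B`/`C`) named by item label, in decreasing value
#'   order.
#' @export
membership <- function(object) {
  stopifnot(inherits(object, "cabc"))
  lab <- c(object$a, object$b, object$c)
  factor(c(rep("A", length(object$a)), rep("B", length(object$b)),
           rep("C", length(object$c))),
         levels = c("A", "B", "C")) |>
    stats::setNames(lab)
}

#' Plot an ABC curve with computed boundaries
#'
#' Draws the interpolated ABC curve, its knots, the identity line (the
#' curve of the identity distribution, all values equal), the analytic
#' uniform reference curve `-p^2 + 2p`, and red vertical lines at the
#' computed A|B and B|C boundaries.
#'
#' @param x a `"cabc"` object.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cabc <- function(x, main = "Computed ABC analysis", ...) {
  g <- seq(0, 1, length.out = 512)
  graphics::plot(g, x$curve$fun(g), type = "l", col = "blue", lwd = 2,
                 xlab = "effort (fraction of items)",
                 ylab = "yield (fraction of total value)",
                 main = main, xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, col = "magenta", lty = 2)       # identity dist.
  graphics::lines(g, -g^2 + 2 * g, col = "darkgreen", lty = 3)  # uniform
  graphics::points(x$curve$efforts, x$curve$yields, pch = 16, cex = 0.4,
                   col = "blue")
  graphics::abline(v = x$juran$x, col = "red")
  graphics::abline(v = x$break_even$x, col = "red")
  graphics::legend("bottomright", bty = "n", cex = 0.8,
                   legend = c("ABC curve", "identity", "uniform ref.",
                              "boundaries"),
                   col = c("blue", "magenta", "darkgreen", "red"),
                   lty = c(1, 2, 3, 1))
  invisible(x)
}
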