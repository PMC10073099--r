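#' Construct an ABC curve from item values
#'
#' The ABC curve is the reversed-order Lorenz curve of a set of non-negative
#' values: with the values sorted in decreasing order, the knot for the i-th
#' item is (effort, yield) = (i/n, cumulative sum of the i largest values /
#' total sum), with the origin (0, 0) prepended. The knot polygon is concave
#' and the curve runs from (0,0) to (1,1) on or above the diagonal.
#'
#' The knots are interpolated with a shape-preserving monotone cubic spline
#' (Hyman filtering, [stats::splinefun()] `method = "hyman"`), so the
#' interpolant cannot overshoot and its yield stays monotone — an
#' unconstrained cubic spline can oscillate around steep leading knots of
#' heavy-tailed value sets and break monotonicity. `method = "natural"`
#' switches to the unconstrained natural cubic spline for concordance
#' experiments with implementations that use one.
#'
#' @param x numeric vector of non-negative item values (names = labels).
#' @param method interpolation method, `"hyman"` (default, monotone) or
#'   `"natural"` (unconstrained cubic spline).
#' @param min_to_zero logical, shift values so the minimum is zero before
#'   constructing the curve (see [as_item_values()]).
#' @return an object of class `"abc_curve"`: a list with `efforts`,
#'   `yields` (the knots, origin included), `fun` (the interpolant
#'   `function(p, deriv = 0)`), `n`, `values` (sorted decreasing, named)
#'   and `order` (permutation from input order to sorted order).
#' @examples
#' cv <- abc_curve(c(4, 3, 2, 1))
#' cv$yields            # 0, 0.4, 0.7, 0.9, 1
#' cv$fun(0.5)          # interpolated yield at half the items
#' @seealso [cabc()] for the full partition, [juran_point()] and
#'   [break_even_point()] for the computed boundaries.
#' @export
abc_curve <- function(x, method = c("hyman", "natural"), min_to_zero = FALSE) {
  method <- match.arg(method)
  x <- as_item_values(x, min_to_zero = min_to_zero)
  n <- length(x)
  # stable sort: ties keep input order so boundary cuts are reproducible
  ord <- order(x, decreasing = TRUE)
  xs <- x[ord]
  efforts <- c(0, seq_len(n) / n)
  yields <- c(0, unname(cumsum(xs)) / sum(xs))
  yields[length(yields)] <- 1  # clamp rounding residue
  fn <- splinefun(efforts, yields, method = method)
  structure(
    list(efforts = efforts, yields = yields, fun = fn, n = n,
         values = xs, order = ord, method = method),
    class = "abc_curve"
  )
}

#' Analytic ABC curve of the uniform distribution
#'
#' For values uniformly distributed on `[0, b]` the ABC curve has the closed
#' form `y(p) = -p^2 + 2p` (independent of `b`, by scale invariance). The
#' uniform distribution is the fixed point of ABC analysis — any compact
#' subset of a uniform sample is again uniform — and its Juran point sits at
#' 41% of the items, which is why it serves as the termination reference of
#' recursive cABC analysis.
#'
#' @return an `"abc_curve"`-like object (no knots, `n = NA`) whose `fun`
#'   evaluates the closed form and its derivative.
#' @examples
#' juran_point(uniform_abc_curve())$x  # ~0.4102
#' @export
uniform_abc_curve <- function() {
  fn <- function(x, deriv = 0) {
    if (deriv == 0) -x^2 + 2 * x
    else if (deriv == 1) -2 * x + 2
    else if (deriv == 2) rep(-2, length(x))
    else rep(0, length(x))
  }
  structure(
    list(efforts = NULL, yields = NULL, fun = fn, n = NA_integer_,
         values = NULL, order = NULL, method = "analytic"),
    class = "abc_curve"
  )
}

# Coarse-grid + golden-section style refinement shared by the two boundary
# searches. Returns the argmin of f over [lo, hi] to x-tolerance `tol`.
.grid_optimize <- function(f, lo = 0, hi = 1, grid_n = 4096L, tol = 1e-9) {
  g <- seq(lo, hi, length.out = grid_n + 1L)
  v <- f(g)
  i <- which.min(v)
  bl <- g[max(1L, i - 1L)]
  bh <- g[min(length(g), i + 1L)]
  optimize(f, c(bl, bh), tol = tol)$minimum
}

#' Locate the Juran point of an ABC curve
#'
#' The Pareto point (0, 1) is the ideal of all yield at zero effort. The
#' Juran point is the point on the actual curve with the smallest Euclidean
#' distance to it: the best really attainable effort/yield trade-off. Its
#' x-coordinate defines the boundary between subsets "A" and "B" in computed
#' ABC analysis.
#'
#' The minimiser is found by a 4096-point grid scan followed by golden
#' section/parabolic refinement ([stats::optimize()]) to an x-tolerance
#' below 1e-6. The interpolant is checked for monotonicity on the grid; a
#' non-monotone interpolant (possible with an unconstrained spline on
#' extreme data) is an internal-consistency error.
#'
#' @param curve an `"abc_curve"` object.
#' @return list with `x`, `y` (coordinates) and `distance` to (0, 1).
#' @examples
#' juran_point(uniform_abc_curve())$x         # ~0.41
#' juran_point(abc_curve(c(4, 3, 2, 1)))$x
#' @export
juran_point <- function(curve) {
  stopifnot(inherits(curve, "abc_curve"))
  .check_monotone(curve)
  f <- function(p) p^2 + (1 - curve$fun(p))^2
  px <- .grid_optimize(f, 0, 1)
  list(x = px, y = curve$fun(px), distance = sqrt(f(px)))
}

#' Locate the break-even point of an ABC curve
#'
#' The break-even point is where the curve's slope dY/dE equals 1: beyond
#' it, an additional unit of effort returns less than a unit of yield. Its
#' x-coordinate defines the boundary between subsets "B" and "C". The search
#' starts at `from_x` (by default the origin; passing the Juran x restricts
#' it to the part of the curve right of the A|B boundary, which is
#' equivalent for concave curves whose slope at the Juran point exceeds 1).
#'
#' The smallest root of `slope(p) - 1` on `[from_x, 1]` is found by a grid
#' bracket plus [stats::uniroot()] to an x-tolerance below 1e-6. When the
#' slope never exceeds 1 on the interval — the identity distribution, whose
#' curve is the diagonal — the boundary is returned as `p = 1` with
#' `degenerate = TRUE`.
#'
#' @param curve an `"abc_curve"` object.
#' @param from_x left end of the search interval, in `[0, 1)`.
#' @return list with `x`, `y` and logical `degenerate`.
#' @examples
#' break_even_point(uniform_abc_curve())$x    # 0.5: slope 2 - 2p = 1
#' @export
break_even_point <- function(curve, from_x = 0) {
  stopifnot(inherits(curve, "abc_curve"), from_x >= 0, from_x < 1)
  slope1 <- function(p) curve$fun(p, deriv = 1) - 1
  grid_n <- 4096L
  g <- seq(from_x, 1, length.out = grid_n + 1L)
  s <- slope1(g)
  # smallest p where the slope falls to 1: first sign change + -> -
  below <- which(s <= 0)
  if (!length(below) || all(s <= 1e-12)) {
    # slope never (meaningfully) above 1: flat/diagonal curve
    if (all(abs(s) < 1e-8)) {
      return(list(x = 1, y = curve$fun(1), degenerate = TRUE))
    }
  }
  if (s[1L] <= 0) {
    # slope already at/below 1 at from_x
    return(list(x = from_x, y = curve$fun(from_x), degenerate = FALSE))
  }
  if (!length(below)) {
    return(list(x = 1, y = curve$fun(1), degenerate = TRUE))
  }
  i <- below[1L]
  root <- uniroot(slope1, lower = g[i - 1L], upper = g[i], tol = 1e-9)$root
  list(x = root, y = curve$fun(root), degenerate = FALSE)
}

# The interpolated yield must be nondecreasing; an overshooting spline
# violates this and silently corrupts both boundary searches.
.check_monotone <- function(curve, grid_n = 2048L) {
  g <- seq(0, 1, length.out = grid_n)
  y <- curve$fun(g)
  if (any(diff(y) < -1e-9)) {
    stop(paste0("interpolated ABC curve is not monotone non-decreasing; ",
                "use the shape-preserving interpolant (method = \"hyman\")"),
         call. = FALSE)
  }
  invisible(TRUE)
}
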