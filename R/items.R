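#' Validate and normalise an item-value vector
#'
#' cABC analysis operates on a set of non-negative item values (feature
#' importances, eigenvalues, inventory values). This helper coerces its input
#' to a named numeric vector and enforces the admissibility contract:
#' no negative values, at least one positive value, and at least three items
#' (a curve through fewer knots has no usable shape).
#'
#' Zeros are admitted even though the method is defined for positive values:
#' real importance vectors routinely contain exact zeros, and a zero-valued
#' item carries no yield, so it always belongs to subset "C" (see
#' [cabc()]). Only an all-zero vector is rejected.
#'
#' @param x numeric vector of item values; names are used as item labels,
#'   otherwise labels `item1..itemN` are generated.
#' @param min_to_zero logical; if `TRUE`, subtract `min(x)` from all values
#'   first. ABC curves are scale- but not translation-invariant, and
#'   shifting the minimum to zero maximises the spread the curve can see.
#'   Off by default.
#' @param force logical; allow fewer than 3 items (the partition then
#'   degenerates to all-"A").
#' @return a named numeric vector with attribute `"labels"` removed; an
#'   error if the contract is violated.
#' @keywords internal
as_item_values <- function(x, min_to_zero = FALSE, force = FALSE) {
  if (is.list(x) && !is.data.frame(x)) x <- unlist(x)
  if (!is.numeric(x)) stop("item values must be numeric", call. = FALSE)
  nm <- names(x)
  x <- as.double(x)
  names(x) <- nm
  if (anyNA(x)) stop("item values contain NA", call. = FALSE)
  if (is.null(names(x)) || any(names(x) == "")) {
    names(x) <- paste0("item", seq_along(x))
  }
  if (anyDuplicated(names(x))) {
    stop("item labels must be unique", call. = FALSE)
  }
  neg <- which(x < 0)
  if (length(neg)) {
    stop(sprintf("negative item value for label '%s' (%g); cABC analysis requires non-negative values",
                 names(x)[neg[1L]], x[neg[1L]]), call. = FALSE)
  }
  if (min_to_zero) x <- x - min(x)
  if (sum(x) == 0) {
    stop("degenerate input: all item values are zero", call. = FALSE)
  }
  if (length(x) < 3L && !force) {
    stop(sprintf("too few items (n = %d): at least 3 are required to build an ABC curve",
                 length(x)), call. = FALSE)
  }
  x
}
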