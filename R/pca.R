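#' Eigen-decomposition of a data matrix for component selection
#'
#' Computes the eigenvalue spectrum of a data matrix's feature covariance
#' or correlation matrix, together with everything needed to project and
#' back-transform: loadings, centring vector, and (for the correlation
#' variant) scaling vector.
#'
#' `scale = "covariance"` (default) decomposes the covariance matrix of
#' the centred data. `scale = "correlation"` standardises each column
#' first; columns with zero variance cannot be standardised — they carry
#' no signal — and are excluded from the decomposition, then restored
#' untouched (their constant value) on reconstruction.
#'
#' @param x numeric matrix or data frame, cases in rows, >= 3 features
#'   with non-zero variance.
#' @param scale `"covariance"` or `"correlation"`.
#' @return object of class `"eigen_spectrum"`: list with `eigenvalues`
#'   (descending, floored at 0), `explained` (fractions summing to 1),
#'   `loadings` (columns = components), `center`, `scale` (NULL for
#'   covariance), `kept` (indices of decomposed columns), `d` (total
#'   number of input columns), `mode`.
#' @examples
#' sp <- eigen_spectrum(matrix(rnorm(300), 100, 3))
#' sp$eigenvalues
#' @export
eigen_spectrum <- function(x, scale = c("covariance", "correlation")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("data matrix must be numeric", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (sum(v > 0) < 3L) {
    stop("need at least 3 columns with non-zero variance", call. = FALSE)
  }
  ctr <- colMeans(x)
  if (scale == "correlation") {
    # constant columns cannot be standardised; exclude them and restore
    # them untouched on reconstruction
    kept <- which(v > 0)
    xs <- sweep(sweep(x[, kept, drop = FALSE], 2, ctr[kept]), 2,
                sqrt(v[kept]), "/")
    S <- stats::cov(xs)
    scl <- sqrt(v[kept])
  } else {
    # covariance handles constant columns natively (zero eigenvalue mass)
    kept <- seq_len(ncol(x))
    S <- stats::cov(x)
    scl <- NULL
  }
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  structure(
    list(eigenvalues = ev, explained = ev / sum(ev),
         loadings = e$vectors, center = ctr, scale = scl, kept = kept,
         d = ncol(x), mode = scale),
    class = "eigen_spectrum"
  )
}

#' Kaiser-Guttman component count
#'
#' The conventional retention rule: keep components whose eigenvalue is
#' strictly greater than 1. On a correlation matrix this means "explains
#' more than one original standardised variable"; the rule is also
#' commonly applied to raw covariance spectra, where its meaning depends
#' on the measurement scale.
#'
#' @param spectrum an `"eigen_spectrum"`.
#' @return integer count of eigenvalues > 1.
#' @export
kaiser_guttman_count <- function(spectrum) {
  stopifnot(inherits(spectrum, "eigen_spectrum"))
  sum(spectrum$eigenvalues > 1)
}

#' Select principal components by recursive cABC analysis of eigenvalues
#'
#' Runs [recursive_cabc()] on the eigenvalue vector: level-1 "A" is the
#' computed set of components to retain, level-2 "AA" a further-reduced
#' core, and so on until the remaining eigenvalues are uniformly
#' distributed (or another criterion fires). This replaces heuristic
#' retention rules (Kaiser-Guttman, 95%-variance) with boundaries computed
#' from the eigenvalue distribution itself.
#'
#' @param spectrum an `"eigen_spectrum"`.
#' @param ... passed to [recursive_cabc()] (e.g. `alpha`, `max_depth`).
#' @return list with `kaiser_guttman` (integer count), `levels` (list of
#'   integer index vectors, one per recursion level, components in
#'   decreasing-eigenvalue order), `trace` (the `"recabc"` object),
#'   `spectrum`.
#' @examples
#' sp <- eigen_spectrum(matrix(rnorm(500), 100, 5))
#' sel <- cabc_component_selection(sp)
#' @export
cabc_component_selection <- function(spectrum, ...) {
  stopifnot(inherits(spectrum, "eigen_spectrum"))
  ev <- spectrum$eigenvalues
  names(ev) <- paste0("PC", seq_along(ev))
  tr <- recursive_cabc(ev, ...)
  lv <- lapply(tr$levels, function(l) {
    sort(match(l$fit$a, names(ev)))
  })
  names(lv) <- vapply(seq_along(lv),
                      function(k) paste(rep("A", k), collapse = ""), "")
  list(kaiser_guttman = kaiser_guttman_count(spectrum), levels = lv,
       trace = tr, spectrum = spectrum)
}

#' Reconstruct data from a retained component subset
#'
#' Projects the data onto all components, zeroes the scores of components
#' not in `retained`, and back-transforms into the original data space
#' (undoing any standardisation and restoring excluded zero-variance
#' columns at their constant values). With all components retained this is
#' an identity round-trip up to numerical error.
#'
#' @param x the data matrix the spectrum was computed from (or compatible
#'   new data).
#' @param spectrum an `"eigen_spectrum"` of `x`.
#' @param retained integer vector of component indices to keep (1 = largest
#'   eigenvalue).
#' @return numeric matrix of the same shape as `x`.
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' sp <- eigen_spectrum(x)
#' max(abs(pca_reconstruct(x, sp, 1:3) - x))  # ~1e-15
#' @export
pca_reconstruct <- function(x, spectrum, retained) {
  stopifnot(inherits(spectrum, "eigen_spectrum"))
  if (length(retained) == 0L) {
    stop("retained component set is empty", call. = FALSE)
  }
  k <- length(spectrum$eigenvalues)
  retained <- sort(unique(as.integer(retained)))
  if (any(retained < 1L) || any(retained > k)) {
    stop("retained indices out of range", call. = FALSE)
  }
  x <- as.matrix(x)
  xk <- sweep(x[, spectrum$kept, drop = FALSE], 2,
              spectrum$center[spectrum$kept])
  if (!is.null(spectrum$scale)) xk <- sweep(xk, 2, spectrum$scale, "/")
  scores <- xk %*% spectrum$loadings
  drop_idx <- setdiff(seq_len(k), retained)
  scores[, drop_idx] <- 0
  rec <- scores %*% t(spectrum$loadings)
  if (!is.null(spectrum$scale)) rec <- sweep(rec, 2, spectrum$scale, "*")
  rec <- sweep(rec, 2, spectrum$center[spectrum$kept], "+")
  out <- matrix(rep(spectrum$center, each = nrow(x)), nrow(x),
                spectrum$d, dimnames = dimnames(x))
  out[, spectrum$kept] <- rec
  out
}

#' Handwritten-digits pixel data
#'
#' The 8x8 optical-recognition handwritten-digits data (UCI repository;
#' the same 1797-image set distributed with standard machine-learning
#' libraries): integer pixel grey values 0-16, one image per row, 64 pixel
#' columns, plus the digit labels 0-9. Shipped as a compact text encoding
#' (one base-17 character per pixel) and decoded on load.
#'
#' @return list with `x` (1797 x 64 integer matrix, columns `px1..px64`)
#'   and `labels` (integer vector of digits).
#' @examples
#' d <- load_digits()
#' dim(d$x)
#' @export
load_digits <- function() {
  files <- system.file("extdata",
                       c("digits_pixels_1.txt", "digits_pixels_2.txt"),
                       package = "recabc", mustWork = TRUE)
  lines <- unlist(lapply(files, readLines))
  alphabet <- c(as.character(0:9), LETTERS[1:7])  # values 0..16
  m <- t(vapply(strsplit(lines, ""),
                function(ch) match(ch, alphabet) - 1L,
                integer(nchar(lines[1L]))))
  colnames(m) <- paste0("px", seq_len(ncol(m)))
  lab_file <- system.file("extdata", "digits_labels.txt",
                          package = "recabc", mustWork = TRUE)
  labels <- as.integer(strsplit(readLines(lab_file, n = 1L), "")[[1L]])
  list(x = m, labels = labels)
}
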