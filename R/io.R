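#' Read an item-value vector from a file
#'
#' Accepts a single- or two-column CSV/TSV (a `label` column plus a value
#' column, or one value column whose row order generates labels) or a JSON
#' object mapping labels to values. Negative values are rejected at the
#' parse stage with the offending row named.
#'
#' @param path file path; format inferred from the extension (`.csv`,
#'   `.tsv`/`.txt`, `.json`).
#' @return named numeric vector of item values.
#' @export
read_items <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    x <- unlist(obj)
    if (!is.numeric(x)) stop("JSON items must be numeric", call. = FALSE)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    num_cols <- vapply(df, is.numeric, logical(1))
    if (!any(num_cols)) stop("no numeric value column found", call. = FALSE)
    val_col <- which(num_cols)[1L]
    x <- df[[val_col]]
    lab_col <- which(!num_cols)[1L]
    names(x) <- if (length(lab_col)) as.character(df[[lab_col]])
                else paste0("item", seq_along(x))
  }
  neg <- which(x < 0)
  if (length(neg)) {
    stop(sprintf("negative value in row %d (label '%s'): %g",
                 neg[1L], names(x)[neg[1L]], x[neg[1L]]), call. = FALSE)
  }
  x
}

.schema_version <- "1.0"

#' Write a cABC partition
#'
#' JSON output carries the boundary points, the three label sets, the
#' "A" fraction and a `schema_version` field; CSV output is a flat table
#' with columns `label`, `value`, `rank`, `subset`.
#'
#' @param fit a `"cabc"` object.
#' @param path output path; format from the extension (`.json` or
#'   `.csv`).
#' @return `path`, invisibly.
#' @export
write_partition <- function(fit, path) {
  stopifnot(inherits(fit, "cabc"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- list(
      schema_version = .schema_version,
      juran = c(fit$juran$x, fit$juran$y),
      break_even = c(fit$break_even$x, fit$break_even$y),
      a = fit$a, b = fit$b, c = fit$c,
      a_fraction = fit$a_fraction
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    memb <- membership(fit)
    lab <- names(memb)
    df <- data.frame(label = lab, value = unname(fit$values[lab]),
                     rank = seq_along(lab), subset = as.character(memb))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop("unsupported partition format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a cABC partition written by [write_partition()]
#'
#' @param path a `.json` or `.csv` partition file.
#' @return for JSON, a list mirroring the written object; for CSV, the
#'   flat table as a data frame.
#' @export
read_partition <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    required <- c("schema_version", "juran", "break_even", "a", "c",
                  "a_fraction")
    missing <- setdiff(required, names(obj))
    if (length(missing)) {
      stop("partition file lacks fields: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (s in c("a", "b", "c")) obj[[s]] <- as.character(obj[[s]] %||% character(0))
    obj
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "value", "rank", "subset")
    if (!all(need %in% names(df))) {
      stop("partition CSV lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
    }
    df
  } else {
    stop("unsupported partition format: ", ext, call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recursion trace
#'
#' Serialises a `"recabc"` object to JSON: per level the input labels,
#' the retained "A" labels, boundary coordinates and the uniformity
#' p-value, plus the stop reason and final set; `schema_version` included.
#'
#' @param trace a `"recabc"` object.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "recabc"))
  lv <- lapply(trace$levels, function(l) list(
    depth = l$depth,
    input = l$labels,
    a = l$fit$a,
    juran = c(l$fit$juran$x, l$fit$juran$y),
    break_even = c(l$fit$break_even$x, l$fit$break_even$y),
    ks_p_input = l$p_value
  ))
  obj <- list(schema_version = .schema_version, levels = lv,
              final_set = trace$final_set,
              stop_reason = trace$stop_reason,
              stop_p_value = trace$stop_p_value, alpha = trace$alpha)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recursion trace written by [write_trace()]
#'
#' @param path a `.json` trace file.
#' @return list mirroring the written object.
#' @export
read_trace <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version)) {
    stop("not a recabc trace file (no schema_version)", call. = FALSE)
  }
  obj
}
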