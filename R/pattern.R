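#' Case-control point pattern in a square window
#'
#' A planar point pattern with a binary mark (`"case"` / `"control"`) on each
#' point, observed in a [square_window()]. This is the basic data object
#' consumed by [dhat()], [permutation_null()] and [test_dataset()].
#'
#' @param x,y Numeric coordinate vectors (miles), equal length.
#' @param mark Character (or factor) vector of `"case"` / `"control"`, same
#'   length as `x`.
#' @param window A [square_window()] containing all points.
#' @return An object of class `kdiff_pattern`: a list with `x`, `y`, `mark`
#'   (character) and `window`.
#' @examples
#' w <- square_window(10)
#' p <- labeled_pattern(c(5, 5, 2, 8), c(5, 5.5, 5, 5),
#'                      c("case", "case", "control", "control"), w)
#' p
#' @export
labeled_pattern <- function(x, y, mark, window) {
  stopifnot(inherits(window, "kdiff_window"))
  x <- as.numeric(x); y <- as.numeric(y); mark <- as.character(mark)
  n <- length(x)
  if (length(y) != n || length(mark) != n) {
    stop("`x`, `y` and `mark` must have identical length", call. = FALSE)
  }
  if (n > 0) {
    if (anyNA(x) || anyNA(y) || anyNA(mark)) {
      stop("coordinates and marks must not contain NA", call. = FALSE)
    }
    bad <- setdiff(unique(mark), c("case", "control"))
    if (length(bad)) {
      stop("marks must be 'case' or 'control'; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!all(in_window(window, x, y))) {
      stop("all points must lie inside the window [0, side_length]^2",
           call. = FALSE)
    }
  }
  structure(list(x = x, y = y, mark = mark, window = window),
            class = "kdiff_pattern")
}

#' @export
print.kdiff_pattern <- function(x, ...) {
  cat(sprintf("case-control point pattern: %d points (%d cases, %d controls)\n",
              n_points(x), n_case(x), n_control(x)))
  print(x$window)
  invisible(x)
}

#' @rdname labeled_pattern
#' @param pattern A `kdiff_pattern`.
#' @export
n_points <- function(pattern) length(pattern$x)

#' @rdname labeled_pattern
#' @export
n_case <- function(pattern) sum(pattern$mark == "case")

#' @rdname labeled_pattern
#' @export
n_control <- function(pattern) sum(pattern$mark == "control")

#' Summarize a collection of simulated patterns
#'
#' Reports the sample mean and standard deviation of the total number of
#' points and of the per-dataset proportion of cases, the quantities used to
#' check the generator's calibration (expected total ~30,000 with ~50% cases
#' under the default configuration).
#'
#' @param patterns A non-empty list of `kdiff_pattern` objects, or a
#'   data frame / matrix with columns `n_total` and `n_case` (counts-only
#'   form, as produced by a counts-only simulation).
#' @return A list of class `kdiff_summary`: `n_patterns`, `mean_n`, `sd_n`,
#'   `mean_prop_case`, `sd_prop_case`. Standard deviations are `NA` for a
#'   single pattern (undefined, reported as absent).
#' @export
summarize_patterns <- function(patterns) {
  if (is.data.frame(patterns) || is.matrix(patterns)) {
    counts <- as.data.frame(patterns)
    if (!all(c("n_total", "n_case") %in% names(counts))) {
      stop("counts form requires columns `n_total` and `n_case`", call. = FALSE)
    }
    n_total <- counts$n_total; n_case <- counts$n_case
  } else {
    if (!is.list(patterns) || length(patterns) == 0L) {
      stop("`patterns` must be a non-empty list of patterns", call. = FALSE)
    }
    n_total <- vapply(patterns, n_points, 0L)
    n_case <- vapply(patterns, n_case, 0L)
  }
  if (length(n_total) == 0L) stop("no patterns to summarize", call. = FALSE)
  prop <- ifelse(n_total > 0, n_case / n_total, NA_real_)
  one <- length(n_total) == 1L
  structure(list(
    n_patterns = length(n_total),
    mean_n = mean(n_total),
    sd_n = if (one) NA_real_ else stats::sd(n_total),
    mean_prop_case = mean(prop, na.rm = TRUE),
    sd_prop_case = if (one) NA_real_ else stats::sd(prop, na.rm = TRUE)
  ), class = "kdiff_summary")
}

#' @export
print.kdiff_summary <- function(x, ...) {
  cat(sprintf("%d patterns: n = %.1f (sd %.1f), prop case = %.4f (sd %.4f)\n",
              x$n_patterns, x$mean_n, x$sd_n, x$mean_prop_case,
              x$sd_prop_case))
  invisible(x)
}

#' Read / write pattern CSV
#'
#' The on-disk form is a CSV with header `x,y,mark`, coordinates in decimal
#' miles and `mark` in `{case, control}`, one row per point. The reader
#' validates window containment against the supplied window.
#'
#' @param path File path.
#' @param window A [square_window()] the points must lie in.
#' @return `read_pattern_csv` returns a `kdiff_pattern`;
#'   `write_pattern_csv` invisibly returns `path`.
#' @export
read_pattern_csv <- function(path, window) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "mark")
  if (!all(need %in% names(df))) {
    stop("pattern CSV must have columns x,y,mark", call. = FALSE)
  }
  labeled_pattern(df$x, df$y, df$mark, window)
}

#' @rdname read_pattern_csv
#' @param pattern A `kdiff_pattern` to write.
#' @export
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "kdiff_pattern"))
  utils::write.csv(
    data.frame(x = pattern$x, y = pattern$y, mark = pattern$mark),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
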