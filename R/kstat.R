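#' Equidistant range grid for multi-range testing
#'
#' The distances at which the difference in K functions is evaluated: the
#' interval from 0 to one quarter of the window side, divided into `r`
#' equidistant ranges, i.e. `h_i = i * (side_length / 4) / r` for
#' `i = 1..r` (0 excluded, `side_length / 4` included). Grids are nested:
#' the grid for `r` is contained, bit-for-bit, in the grid for any multiple
#' of `r`.
#'
#' @param side_length Window side in miles, `> 0`.
#' @param r Number of ranges, `>= 1`.
#' @return Object of class `kdiff_grid`: list with `side_length`, `r`, `h`.
#' @examples
#' make_range_grid(sqrt(3e6), 1)$h    # 433.0127
#' make_range_grid(4, 2)$h            # 0.5 1.0
#' @export
make_range_grid <- function(side_length, r) {
  if (!is.numeric(side_length) || length(side_length) != 1L ||
      !is.finite(side_length) || side_length <= 0) {
    stop("invalid `side_length`: must be > 0", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r != round(r)) {
    stop("invalid `r`: number of ranges must be a positive integer",
         call. = FALSE)
  }
  r <- as.integer(r)
  # i/r is a correctly rounded rational, so nested grids coincide exactly
  h <- (side_length / 4) * (seq_len(r) / r)
  structure(list(side_length = as.numeric(side_length), r = r, h = h),
            class = "kdiff_grid")
}

#' @export
print.kdiff_grid <- function(x, ...) {
  cat(sprintf("range grid: r = %d, h in (%.4g, %.4g] mi (side/4 = %.4g)\n",
              x$r, x$h[1], x$h[x$r], x$side_length / 4))
  invisible(x)
}

#' Ripley's K with the border (reduced-sample) edge correction
#'
#' Estimates `K(h) = lambda^-1 E[# further events within distance h of a
#' typical event]` for an unmarked point set in a square window. At each
#' range `h`, only centers strictly farther than `h` from the window
#' boundary are used (so their `h`-discs lie entirely inside the window):
#'
#' `Khat(h) = (|A| / n) * sum over eligible i of #(j != i : d_ij <= h) / n_h`
#'
#' where `n` is the total number of points in the window, `|A|` the window
#' area and `n_h` the number of eligible centers. Neighbors are counted on
#' the closed ball (`d_ij <= h`); eligibility is strict (`bdist_i > h`).
#' When no center is eligible at some range the estimate there is undefined
#' and returned as `NA` with a warning, never as 0. Under complete spatial
#' randomness `E[Khat(h)] ~ pi h^2`.
#'
#' @param x,y Coordinates of the points (all inside `window`); at least 2
#'   points.
#' @param window A [square_window()].
#' @param grid A [make_range_grid()] (its ranges may exceed `side/4`; only
#'   the values in `grid$h` are used).
#' @return Object of class `kdiff_khat`: list with `h`, `khat` (mi^2, `NA`
#'   where undefined) and `n_centers` (eligible centers per range).
#' @export
khat_border <- function(x, y, window, grid) {
  stopifnot(inherits(window, "kdiff_window"), inherits(grid, "kdiff_grid"))
  n <- length(x)
  if (n < 2L) stop("khat_border needs at least 2 points", call. = FALSE)
  if (length(y) != n) stop("`x` and `y` lengths differ", call. = FALSE)
  if (!all(in_window(window, x, y))) {
    stop("all points must lie inside the window", call. = FALSE)
  }
  bd <- boundary_distance(window, x, y)
  r <- grid$r
  cnt <- numeric(r)
  n_centers <- integer(r)
  # blocked over centers so cohort-sized patterns never need the full
  # distance matrix; counts are exact integers, independent of block size
  blk <- max(64L, min(n, as.integer(8e6 / n)))
  for (b0 in seq(1L, n, by = blk)) {
    idx <- b0:min(n, b0 + blk - 1L)
    Db <- sqrt(outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2)
    for (k in seq_len(r)) {
      h <- grid$h[k]
      el <- bd[idx] > h
      if (any(el)) {
        # closed-ball neighbor count; minus the self pair (d_ii = 0) per center
        cnt[k] <- cnt[k] + sum(Db[el, , drop = FALSE] <= h) - sum(el)
      }
      n_centers[k] <- n_centers[k] + sum(el)
    }
  }
  khat <- ifelse(n_centers > 0, (window$area / n) * cnt / n_centers, NA_real_)
  if (anyNA(khat)) {
    warning(sprintf(
      "K undefined at %d range(s): no center farther than h from the boundary",
      sum(is.na(khat))), call. = FALSE)
  }
  structure(list(h = grid$h, khat = khat, n_centers = n_centers),
            class = "kdiff_khat")
}

#' Difference in Ripley's K functions, D(h)
#'
#' `D(h) = Khat_case(h) - Khat_control(h)`, each K estimated by
#' [khat_border()] with its own type's intensity (`n_type / |A|`). Positive
#' values indicate clustering of cases above and beyond the clustering of
#' the controls; under the constant-risk null, `D(h) ~ 0` at every range.
#'
#' @param pattern A `kdiff_pattern` with at least 2 cases and 2 controls.
#' @param grid A [make_range_grid()].
#' @return Object of class `kdiff_dhat`: list with `h`, `dhat` (mi^2, `NA`
#'   where either K is undefined), `khat_case`, `khat_control`,
#'   `n_centers_case`, `n_centers_control`.
#' @examples
#' w <- square_window(10)
#' p <- labeled_pattern(c(5, 5, 2, 8), c(5, 5.5, 5, 5),
#'                      c("case", "case", "control", "control"), w)
#' dhat(p, make_range_grid(10, 1))$dhat   # 50
#' @export
dhat <- function(pattern, grid) {
  stopifnot(inherits(pattern, "kdiff_pattern"), inherits(grid, "kdiff_grid"))
  if (n_case(pattern) < 2L || n_control(pattern) < 2L) {
    stop("dhat needs at least 2 cases and 2 controls", call. = FALSE)
  }
  ic <- pattern$mark == "case"
  kc <- khat_border(pattern$x[ic], pattern$y[ic], pattern$window, grid)
  kk <- khat_border(pattern$x[!ic], pattern$y[!ic], pattern$window, grid)
  structure(list(h = grid$h,
                 dhat = kc$khat - kk$khat,
                 khat_case = kc$khat,
                 khat_control = kk$khat,
                 n_centers_case = kc$n_centers,
                 n_centers_control = kk$n_centers),
            class = "kdiff_dhat")
}

#' @export
print.kdiff_dhat <- function(x, ...) {
  cat(sprintf("difference in K functions at %d range(s):\n", length(x$h)))
  print(utils::head(as.data.frame(unclass(x)), 10))
  if (length(x$h) > 10) cat("...\n")
  invisible(x)
}

#' Write K / D estimates as CSV
#'
#' Columns `h, khat_case, khat_control, dhat, n_centers_case,
#' n_centers_control`, one row per range.
#'
#' @param d A [dhat()] result.
#' @param path Output file path.
#' @export
write_kstat_csv <- function(d, path) {
  stopifnot(inherits(d, "kdiff_dhat"))
  utils::write.csv(data.frame(
    h = d$h, khat_case = d$khat_case, khat_control = d$khat_control,
    dhat = d$dhat, n_centers_case = d$n_centers_case,
    n_centers_control = d$n_centers_control
  ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
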