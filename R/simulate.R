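#' Generate parent events from a homogeneous Poisson process
#'
#' Draws `N ~ Poisson(kappa * area)` parents and places them independently
#' uniformly over the square window.
#'
#' @param window A [square_window()].
#' @param kappa Parent intensity (parents per mi^2), `>= 0`.
#' @param seed Optional: a single integer (seeds a local L'Ecuyer-CMRG
#'   generator) or a `.Random.seed` state vector from [rng_streams()];
#'   `NULL` uses the current RNG state. The caller's RNG state is never
#'   modified when a seed is given.
#' @return A data frame with columns `x`, `y` (one row per parent).
#' @export
generate_parents <- function(window, kappa, seed = NULL) {
  stopifnot(inherits(window, "kdiff_window"))
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa < 0) {
    stop("invalid `kappa`: must be a single finite number >= 0",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- save_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set_rng_seed(seed)
  }
  n <- stats::rpois(1L, kappa * window$area)
  s <- window$side_length
  data.frame(x = stats::runif(n, 0, s), y = stats::runif(n, 0, s))
}

#' Simulate a case-control pattern from the shared-parent cluster process
#'
#' The generative model of the study: parents are homogeneous Poisson with
#' intensity `kappa`; for each parent, the numbers of case and control
#' children are independent Poisson draws with means `lambda_case` and
#' `lambda_control`, and each child is placed uniformly at random in the
#' disc of radius `cluster_radius` centred on its parent (polar sampling
#' with a square-root radial transform). Because case and control children
#' share the same parents, both types are clustered identically and the
#' constant-risk null holds. Children landing outside the window are
#' discarded; at this geometry (15-mi discs in a ~1732-mi window) the
#' clipping loss is well under 1%.
#'
#' @param config A [sim_config()].
#' @inheritParams generate_parents
#' @return A `kdiff_pattern`. Attributes `parents` (data frame of parent
#'   locations) and `parent_id` (index of each retained child's parent) are
#'   attached for diagnostics.
#' @examples
#' cfg <- sim_config(side_length = 200, kappa = 5e-4,
#'                   lambda_case = 10, lambda_control = 10)
#' p <- generate_cox_pattern(cfg, seed = 1)
#' p
#' @export
generate_cox_pattern <- function(config, seed = NULL) {
  stopifnot(inherits(config, "kdiff_simconfig"))
  if (!is.null(seed)) {
    old <- save_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set_rng_seed(seed)
  }
  window <- config$window
  parents <- generate_parents(window, config$kappa)
  np <- nrow(parents)
  if (np == 0L) {
    out <- labeled_pattern(numeric(0), numeric(0), character(0), window)
    attr(out, "parents") <- parents
    attr(out, "parent_id") <- integer(0)
    return(out)
  }
  n_case_kids <- stats::rpois(np, config$lambda_case)
  n_ctrl_kids <- stats::rpois(np, config$lambda_control)
  place <- function(counts) {
    total <- sum(counts)
    pid <- rep.int(seq_len(np), counts)
    r <- config$cluster_radius * sqrt(stats::runif(total))
    th <- stats::runif(total, 0, 2 * pi)
    data.frame(x = parents$x[pid] + r * cos(th),
               y = parents$y[pid] + r * sin(th),
               pid = pid)
  }
  cases <- place(n_case_kids)
  ctrls <- place(n_ctrl_kids)
  kids <- rbind(cases, ctrls)
  mark <- rep(c("case", "control"), c(nrow(cases), nrow(ctrls)))
  keep <- in_window(window, kids$x, kids$y)
  out <- labeled_pattern(kids$x[keep], kids$y[keep], mark[keep], window)
  attr(out, "parents") <- parents
  attr(out, "parent_id") <- kids$pid[keep]
  attr(out, "n_clipped") <- sum(!keep)
  out
}

#' Nadaraya-Watson smoothed case-risk surface
#'
#' Kernel-regression estimate of the probability of being a case as a
#' function of location: at each query point `q`, the estimate is the
#' Gaussian-kernel-weighted fraction of cases,
#' `sum_i w_i 1(mark_i = case) / sum_i w_i` with
#' `w_i = exp(-d(q, i)^2 / (2 bandwidth^2))`. Where the total kernel mass
#' underflows to zero the estimate is undefined and returned as `NA` with a
#' warning (never silently zero). Used for illustrative risk maps of
#' simulated datasets.
#'
#' @param pattern A non-empty `kdiff_pattern`.
#' @param bandwidth Gaussian kernel standard deviation (miles), `> 0`.
#'   There is no canonical choice; a window-adapted rule of thumb such as
#'   `side_length / 20` is a reasonable starting point and the value should
#'   be reported alongside any map.
#' @param grid Optional data frame of query points (columns `x`, `y`);
#'   default a regular `nx` by `nx` lattice of cell centers over the window.
#' @param nx Lattice resolution when `grid` is not given.
#' @return Data frame with columns `x`, `y`, `risk` (fraction in `[0, 1]`,
#'   `NA` where undefined).
#' @export
nadaraya_watson_risk <- function(pattern, bandwidth, grid = NULL, nx = 64) {
  stopifnot(inherits(pattern, "kdiff_pattern"))
  if (n_points(pattern) == 0L) stop("pattern must be non-empty", call. = FALSE)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0) {
    stop("invalid `bandwidth`: must be > 0", call. = FALSE)
  }
  if (is.null(grid)) {
    s <- pattern$window$side_length
    ctr <- (seq_len(nx) - 0.5) * s / nx
    grid <- expand.grid(x = ctr, y = ctr)
  }
  stopifnot(all(c("x", "y") %in% names(grid)))
  is_case <- as.numeric(pattern$mark == "case")
  # m x n squared distances; desk-scale patterns only
  dx <- outer(grid$x, pattern$x, "-")
  dy <- outer(grid$y, pattern$y, "-")
  w <- exp(-(dx^2 + dy^2) / (2 * bandwidth^2))
  tot <- rowSums(w)
  num <- as.vector(w %*% is_case)
  risk <- ifelse(tot > 0, num / tot, NA_real_)
  if (anyNA(risk)) {
    warning(sprintf(
      "risk undefined at %d of %d query points (zero total kernel weight)",
      sum(is.na(risk)), length(risk)), call. = FALSE)
  }
  data.frame(x = grid$x, y = grid$y, risk = risk)
}
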