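#' Generative model configuration
#'
#' Parameters of the shared-parent Poisson cluster (Cox) process used to
#' simulate case-control residential locations. Parents are a homogeneous
#' Poisson process of intensity `kappa` on a square window; each parent
#' independently spawns Poisson(`lambda_case`) case children and
#' Poisson(`lambda_control`) control children, each placed uniformly in the
#' disc of radius `cluster_radius` around the parent. Children falling
#' outside the window are discarded.
#'
#' The defaults are the study conditions: a 3,000,000 mi^2 window,
#' `kappa = 1e-4` parents per mi^2 (300 expected parents),
#' `cluster_radius = 15` mi, and 50 expected children per parent of each
#' type, giving an expected total sample of 30,000 with 50% cases.
#'
#' @param side_length Window side in miles.
#' @param kappa Parent intensity (parents per mi^2), `>= 0`.
#' @param lambda_case,lambda_control Mean children per parent of each type,
#'   `>= 0`.
#' @param cluster_radius Radius (miles) of the disc children are placed in,
#'   `> 0`.
#' @return An object of class `kdiff_simconfig`.
#' @examples
#' sim_config()                       # the default study generator
#' sim_config(side_length = 100, lambda_case = 5, lambda_control = 5)
#' @export
sim_config <- function(side_length = sqrt(3e6),
                       kappa = 1e-4,
                       lambda_case = 50,
                       lambda_control = 50,
                       cluster_radius = 15) {
  window <- square_window(side_length)
  check_scalar <- function(v, name, min = 0, strict = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        (if (strict) v <= min else v < min)) {
      stop(sprintf("invalid `%s`: must be a single finite number %s %s",
                   name, if (strict) ">" else ">=", format(min)),
           call. = FALSE)
    }
    as.numeric(v)
  }
  structure(list(
    window = window,
    kappa = check_scalar(kappa, "kappa"),
    lambda_case = check_scalar(lambda_case, "lambda_case"),
    lambda_control = check_scalar(lambda_control, "lambda_control"),
    cluster_radius = check_scalar(cluster_radius, "cluster_radius",
                                  strict = TRUE)
  ), class = "kdiff_simconfig")
}

#' @export
print.kdiff_simconfig <- function(x, ...) {
  cat(sprintf(paste0(
    "Cox process config: side %.4f mi, kappa %.2g /mi^2, ",
    "lambda case/control %.4g/%.4g, cluster radius %.4g mi\n",
    "expected n = %.1f (%.1f%% cases)\n"),
    x$window$side_length, x$kappa, x$lambda_case, x$lambda_control,
    x$cluster_radius,
    x$kappa * x$window$area * (x$lambda_case + x$lambda_control),
    100 * x$lambda_case / max(x$lambda_case + x$lambda_control, .Machine$double.eps)))
  invisible(x)
}

#' Expected moments of the total sample size
#'
#' Closed-form compound-Poisson moments of the total number of points
#' generated by [generate_cox_pattern()] before window clipping:
#' with `mu = kappa * area` expected parents and `lambda = lambda_case +
#' lambda_control` children per parent, `E[n] = mu * lambda` and
#' `Var[n] = mu * (lambda + lambda^2)`.
#'
#' @param config A [sim_config()].
#' @return List with `mean_n`, `var_n`, `sd_n`, `mean_parents`.
#' @export
expected_pattern_moments <- function(config) {
  stopifnot(inherits(config, "kdiff_simconfig"))
  mu <- config$kappa * config$window$area
  lam <- config$lambda_case + config$lambda_control
  list(mean_n = mu * lam,
       var_n = mu * (lam + lam^2),
       sd_n = sqrt(mu * (lam + lam^2)),
       mean_parents = mu)
}

#' Study configuration
#'
#' Full configuration of the family-wise error simulation study: the
#' generator ([sim_config()]), the set of range counts to test, the number
#' of datasets per condition, the number of random labelings, the nominal
#' level, the test method and the master seed. Defaults reproduce the study
#' design: 2,000 datasets per condition at r = 1, 10, 50 and 100 ranges,
#' 199 relabelings, alpha = 0.05, pointwise envelopes.
#'
#' @param sim A [sim_config()].
#' @param range_counts Integer vector of numbers of ranges to test.
#' @param n_datasets Datasets per condition.
#' @param n_perm Number of random labelings per dataset.
#' @param alpha Nominal level of each test.
#' @param method One of `"pointwise"`, `"simultaneous"`, `"integrated"`.
#' @param master_seed Integer master seed; every random draw in the study is
#'   derived from it.
#' @return An object of class `kdiff_studyconfig`.
#' @export
study_config <- function(sim = sim_config(),
                         range_counts = c(1, 10, 50, 100),
                         n_datasets = 2000,
                         n_perm = 199,
                         alpha = 0.05,
                         method = c("pointwise", "simultaneous", "integrated"),
                         master_seed = 1L) {
  stopifnot(inherits(sim, "kdiff_simconfig"))
  method <- match.arg(method)
  if (!is.numeric(range_counts) || length(range_counts) < 1L ||
      any(range_counts < 1) || any(range_counts != round(range_counts))) {
    stop("invalid `range_counts`: must be positive integers", call. = FALSE)
  }
  if (!is.numeric(n_datasets) || length(n_datasets) != 1L || n_datasets < 1) {
    stop("invalid `n_datasets`: must be >= 1", call. = FALSE)
  }
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1) {
    stop("invalid `n_perm`: must be >= 1", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("invalid `alpha`: must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(master_seed) || length(master_seed) != 1L ||
      master_seed != round(master_seed)) {
    stop("invalid `master_seed`: must be an integer", call. = FALSE)
  }
  structure(list(
    sim = sim,
    range_counts = as.integer(sort(unique(range_counts))),
    n_datasets = as.integer(n_datasets),
    n_perm = as.integer(n_perm),
    alpha = as.numeric(alpha),
    method = method,
    master_seed = as.integer(master_seed)
  ), class = "kdiff_studyconfig")
}

#' @export
print.kdiff_studyconfig <- function(x, ...) {
  cat(sprintf(
    "FWE study config: r in {%s}, %d datasets/condition, %d relabelings,\n",
    paste(x$range_counts, collapse = ", "), x$n_datasets, x$n_perm))
  cat(sprintf("alpha %.3g, method %s, master seed %d\n",
              x$alpha, x$method, x$master_seed))
  print(x$sim)
  invisible(x)
}

config_keys <- c("side_length", "kappa", "lambda_case", "lambda_control",
                 "cluster_radius", "seed", "range_counts", "n_datasets",
                 "n_perm", "alpha", "method")

#' Load / save a study configuration (JSON or YAML)
#'
#' Configuration files hold a flat mapping with any subset of the keys
#' `side_length, kappa, lambda_case, lambda_control, cluster_radius, seed,
#' range_counts, n_datasets, n_perm, alpha, method`; omitted keys take the
#' study defaults. Unknown keys are a hard error (no silent typo
#' tolerance), and invalid values raise errors naming the offending key.
#' An empty file yields the full default configuration.
#'
#' @param path Config file path; format chosen by extension (`.json`,
#'   `.yaml`/`.yml`), falling back to trying JSON then YAML.
#' @return `load_config` returns a [study_config()];
#'   `save_config` invisibly returns `path`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) yaml::read_yaml(path))
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping of keys to values",
                          call. = FALSE)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  get_or <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  sim <- sim_config(
    side_length = get_or("side_length", sqrt(3e6)),
    kappa = get_or("kappa", 1e-4),
    lambda_case = get_or("lambda_case", 50),
    lambda_control = get_or("lambda_control", 50),
    cluster_radius = get_or("cluster_radius", 15)
  )
  study_config(
    sim = sim,
    range_counts = get_or("range_counts", c(1, 10, 50, 100)),
    n_datasets = get_or("n_datasets", 2000),
    n_perm = get_or("n_perm", 199),
    alpha = get_or("alpha", 0.05),
    method = get_or("method", "pointwise"),
    master_seed = get_or("seed", 1L)
  )
}

#' @rdname load_config
#' @param config A [study_config()] to serialize.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "kdiff_studyconfig"))
  flat <- list(
    side_length = config$sim$window$side_length,
    kappa = config$sim$kappa,
    lambda_case = config$sim$lambda_case,
    lambda_control = config$sim$lambda_control,
    cluster_radius = config$sim$cluster_radius,
    seed = config$master_seed,
    range_counts = config$range_counts,
    n_datasets = config$n_datasets,
    n_perm = config$n_perm,
    alpha = config$alpha,
    method = config$method
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(flat, path, precision = 17)
  } else {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  }
  invisible(path)
}
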