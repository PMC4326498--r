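#' Family-wise error rate estimate with binomial confidence interval
#'
#' `fwe = n_rejections / n_used`, with an approximately Gaussian (Wald)
#' interval `p +/- z * sqrt(p (1 - p) / n)` at the given confidence,
#' clipped to [0, 1]. The Wald form mirrors the study's reporting despite
#' its known boundary problems; a Wilson interval is available behind the
#' `interval` flag. A degenerate Wald interval (p = 0 or 1) is returned
#' with a warning.
#'
#' @param n_rejections Number of datasets with at least one rejection.
#' @param n_used Number of completed datasets (the denominator).
#' @param confidence Confidence level (default 0.95, z = 1.959964).
#' @param interval `"wald"` (default) or `"wilson"`.
#' @param r Optional number of ranges, recorded in the result.
#' @return Object of class `kdiff_fwe`: list with `r`, `n_used`,
#'   `n_rejections`, `fwe`, `ci_lower`, `ci_upper`, `confidence`,
#'   `interval`.
#' @examples
#' estimate_fwe(100, 2000)   # 0.05 (0.0404, 0.0596)
#' @export
estimate_fwe <- function(n_rejections, n_used, confidence = 0.95,
                         interval = c("wald", "wilson"), r = NA_integer_) {
  interval <- match.arg(interval)
  if (!is.numeric(n_used) || length(n_used) != 1L || n_used < 1) {
    stop("`n_used` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(n_rejections) || length(n_rejections) != 1L ||
      n_rejections < 0 || n_rejections > n_used) {
    stop("`n_rejections` must be between 0 and `n_used`", call. = FALSE)
  }
  p <- n_rejections / n_used
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  if (interval == "wald") {
    half <- z * sqrt(p * (1 - p) / n_used)
    if (half == 0) {
      warning("degenerate Wald interval (estimated rate is 0 or 1)",
              call. = FALSE)
    }
    lo <- p - half; hi <- p + half
  } else {
    den <- 1 + z^2 / n_used
    ctr <- (p + z^2 / (2 * n_used)) / den
    half <- z * sqrt(p * (1 - p) / n_used + z^2 / (4 * n_used^2)) / den
    lo <- ctr - half; hi <- ctr + half
  }
  structure(list(r = r, n_used = as.integer(n_used),
                 n_rejections = as.integer(n_rejections),
                 fwe = p,
                 ci_lower = max(0, lo), ci_upper = min(1, hi),
                 confidence = confidence, interval = interval),
            class = "kdiff_fwe")
}

#' @export
print.kdiff_fwe <- function(x, ...) {
  cat(sprintf("FWE %s= %.4f (%.0f%% CI %.4f - %.4f), %d/%d datasets\n",
              if (is.na(x$r)) "" else sprintf("at r = %d ", x$r),
              x$fwe, 100 * x$confidence, x$ci_lower, x$ci_upper,
              x$n_rejections, x$n_used))
  invisible(x)
}

# One simulated dataset -> test outcome, exclusion-aware.
# Returns list(ok, reject_any, reject_at, n_total, n_case, err)
run_one_dataset <- function(sim, grid, n_perm, method, alpha, stream) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set_rng_seed(stream)
  pattern <- generate_cox_pattern(sim)
  nt <- n_points(pattern); nc <- n_case(pattern)
  res <- tryCatch({
    out <- suppressWarnings(
      test_dataset(pattern, grid, n_perm = n_perm, method = method,
                   alpha = alpha))
    list(ok = TRUE, reject_any = out$reject_any,
         reject_at = out$reject_at_range,
         n_total = nt, n_case = nc, err = NA_character_)
  }, error = function(e) {
    list(ok = FALSE, reject_any = NA, reject_at = rep(NA, grid$r),
         n_total = nt, n_case = nc, err = conditionMessage(e))
  })
  res
}

#' Run one study condition: many datasets at a fixed number of ranges
#'
#' Generates `config$n_datasets` independent datasets from the configured
#' Cox process (one pre-assigned RNG stream per dataset, derived from the
#' master seed and `r`, so the run is fully reproducible and independent of
#' evaluation order), applies the multi-range test to each, and aggregates
#' the any-range rejections into an FWE estimate. Datasets that cannot be
#' tested (fewer than 2 points of a type, or undefined D values) are
#' excluded and counted, and the FWE denominator is the number of completed
#' datasets.
#'
#' With `out_dir` given, per-dataset results are appended to
#' `rejections_r<r>.csv` as they complete, and an interrupted run resumes
#' from that file.
#'
#' @param config A [study_config()].
#' @param r Number of ranges for this condition.
#' @param method Test method; defaults to `config$method`.
#' @param out_dir Optional directory for streaming/resume and reports.
#' @param progress Print per-dataset progress every 100 datasets.
#' @return List with `result` (a [estimate_fwe()] object), `rejections`
#'   (matrix, completed datasets x r, logical; for the integrated method a
#'   1-column matrix of overall rejections), `summary`
#'   (a [summarize_patterns()] of the generated sizes), `n_excluded`,
#'   `excluded_ids`, `r`, `method`.
#' @export
run_condition <- function(config, r, method = config$method, out_dir = NULL,
                          progress = FALSE) {
  stopifnot(inherits(config, "kdiff_studyconfig"))
  grid <- make_range_grid(config$sim$window$side_length, r)
  nd <- config$n_datasets
  streams <- rng_streams(derive_seed(config$master_seed, r), nd)
  r_eff <- if (method == "integrated") 1L else grid$r

  done <- NULL
  rej_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rej_path <- file.path(out_dir, sprintf("rejections_r%d.csv", r))
    if (file.exists(rej_path)) {
      done <- utils::read.csv(rej_path)
    }
  }
  flag_cols <- paste0("reject_", seq_len(r_eff))
  rows <- vector("list", nd)
  for (i in seq_len(nd)) {
    if (!is.null(done) && i %in% done$dataset_id) {
      rows[[i]] <- done[match(i, done$dataset_id), , drop = FALSE]
      next
    }
    res <- run_one_dataset(config$sim, grid, config$n_perm, method,
                           config$alpha, streams[[i]])
    flags <- if (method == "integrated") res$reject_any else res$reject_at
    row <- data.frame(dataset_id = i, n_total = res$n_total,
                      n_case = res$n_case,
                      reject_any = as.integer(res$reject_any))
    row[flag_cols] <- as.list(as.integer(flags))
    rows[[i]] <- row
    if (!is.null(rej_path)) {
      new_file <- !file.exists(rej_path)
      suppressWarnings(
        utils::write.table(row, rej_path, sep = ",", row.names = FALSE,
                           col.names = new_file, append = !new_file))
    }
    if (progress && i %% 100 == 0) {
      message(sprintf("r = %d: %d / %d datasets", r, i, nd))
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$reject_any)
  rejections <- as.matrix(tab[ok, flag_cols, drop = FALSE]) == 1
  dimnames(rejections) <- NULL
  result <- estimate_fwe(sum(tab$reject_any[ok]), sum(ok),
                         interval = "wald", r = as.integer(r))
  list(result = result,
       rejections = rejections,
       summary = summarize_patterns(tab[ok, c("n_total", "n_case")]),
       n_excluded = sum(!ok),
       excluded_ids = tab$dataset_id[!ok],
       r = as.integer(r),
       method = method)
}

#' Run the full FWE simulation study
#'
#' [run_condition()] for every entry of `config$range_counts`, each with
#' independently generated datasets (the study design), plus the summary
#' table. With `out_dir`, writes `fwe_summary.csv`, per-condition rejection
#' matrices, rejection-correlation matrices `corr_r<r>.csv` (conditions
#' with r >= 2), and a `manifest.json` recording the configuration, seed
#' derivations, package version and timings.
#'
#' @inheritParams run_condition
#' @return List with `conditions` (per-r results of [run_condition()]) and
#'   `report` (the [study_report()] table).
#' @export
run_study <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "kdiff_studyconfig"))
  t0 <- Sys.time()
  conditions <- list()
  timings <- numeric(0)
  for (r in config$range_counts) {
    t1 <- Sys.time()
    conditions[[as.character(r)]] <-
      run_condition(config, r, out_dir = out_dir, progress = progress)
    timings[as.character(r)] <-
      as.numeric(difftime(Sys.time(), t1, units = "secs"))
  }
  report <- study_report(lapply(conditions, `[[`, "result"),
                         summaries = lapply(conditions, `[[`, "summary"))
  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "fwe_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    for (cond in conditions) {
      if (cond$r >= 2 && cond$method != "integrated") {
        cm <- rejection_correlation(cond$rejections)
        utils::write.csv(cm,
                         file.path(out_dir, sprintf("corr_r%d.csv", cond$r)),
                         row.names = FALSE)
      }
    }
    manifest <- list(
      package = "kdiff",
      version = as.character(utils::packageVersion("kdiff")),
      created = format(Sys.time(), tz = "UTC", usetz = TRUE),
      master_seed = config$master_seed,
      condition_seeds = stats::setNames(
        lapply(config$range_counts,
               function(r) derive_seed(config$master_seed, r)),
        paste0("r", config$range_counts)),
      rng = "L'Ecuyer-CMRG, one nextRNGStream-derived stream per dataset",
      n_datasets = config$n_datasets,
      n_perm = config$n_perm,
      alpha = config$alpha,
      method = config$method,
      excluded = stats::setNames(
        lapply(conditions, `[[`, "n_excluded"),
        paste0("r", vapply(conditions, `[[`, 0L, "r"))),
      timings_sec = as.list(timings),
      total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = I(10))
    save_config(config, file.path(out_dir, "config.json"))
  }
  list(conditions = conditions, report = report)
}

#' Evaluate nested range grids on shared datasets
#'
#' Efficiency/diagnostic mode (the study itself used fresh datasets per
#' condition): each dataset is tested once at the finest grid, and the
#' coarser conditions are obtained by selecting the nested subset of
#' ranges from the same permutation null, so all conditions share datasets
#' *and* relabelings. Because the coarser grids are exact subsets, the
#' any-range rejection sets are nested per dataset, and the estimated FWE
#' is exactly (not just statistically) nondecreasing in r. Every
#' `range_counts` entry must divide the largest.
#'
#' @inheritParams run_condition
#' @param range_counts Nested range counts (default `config$range_counts`).
#' @return List as [run_study()]'s `conditions` (with `shared_datasets =
#'   TRUE` attached), plus `report`.
#' @export
run_nested <- function(config, range_counts = config$range_counts,
                       method = config$method, progress = FALSE) {
  stopifnot(inherits(config, "kdiff_studyconfig"))
  range_counts <- sort(unique(as.integer(range_counts)))
  r_max <- max(range_counts)
  if (any(r_max %% range_counts != 0)) {
    stop("all `range_counts` must divide the largest for nested evaluation",
         call. = FALSE)
  }
  side <- config$sim$window$side_length
  grid_max <- make_range_grid(side, r_max)
  nd <- config$n_datasets
  streams <- rng_streams(derive_seed(config$master_seed, r_max), nd)

  per_r <- lapply(range_counts, function(r) {
    list(flags = matrix(NA, nd, if (method == "integrated") 1L else r),
         any = rep(NA, nd))
  })
  names(per_r) <- as.character(range_counts)
  counts <- data.frame(n_total = rep(NA_integer_, nd),
                       n_case = rep(NA_integer_, nd))
  for (i in seq_len(nd)) {
    old <- save_rng_state()
    set_rng_seed(streams[[i]])
    pattern <- generate_cox_pattern(config$sim)
    counts$n_total[i] <- n_points(pattern)
    counts$n_case[i] <- n_case(pattern)
    null_max <- tryCatch(
      suppressWarnings(permutation_null(pattern, grid_max, config$n_perm)),
      error = function(e) NULL)
    restore_rng_state(old)
    if (is.null(null_max)) next
    # global exclusion keeps rows aligned across the nested conditions, so
    # the per-dataset monotonicity comparison is exact
    if (anyNA(null_max$observed) || anyNA(null_max$replicates)) next
    for (r in range_counts) {
      idx <- seq_len(r) * (r_max %/% r)
      sub <- structure(list(
        observed = null_max$observed[idx],
        replicates = null_max$replicates[, idx, drop = FALSE],
        grid = make_range_grid(side, r),
        n_perm = null_max$n_perm,
        n_case = null_max$n_case, n_control = null_max$n_control,
        seed = null_max$seed), class = "kdiff_null")
      out <- tryCatch(
        test_from_null(sub, method, config$alpha),
        error = function(e) NULL)
      if (is.null(out)) next
      key <- as.character(r)
      per_r[[key]]$any[i] <- out$reject_any
      per_r[[key]]$flags[i, ] <- if (method == "integrated") {
        out$reject_any
      } else {
        out$reject_at_range
      }
    }
    if (progress && i %% 50 == 0) {
      message(sprintf("nested: %d / %d datasets", i, nd))
    }
  }
  conditions <- lapply(names(per_r), function(key) {
    r <- as.integer(key)
    any_r <- per_r[[key]]$any
    ok <- !is.na(any_r)
    res <- list(
      result = estimate_fwe(sum(any_r[ok]), sum(ok), r = r),
      rejections = per_r[[key]]$flags[ok, , drop = FALSE],
      summary = summarize_patterns(counts[ok, , drop = FALSE]),
      n_excluded = sum(!ok),
      excluded_ids = which(!ok),
      r = r, method = method)
    attr(res, "shared_datasets") <- TRUE
    res
  })
  names(conditions) <- names(per_r)
  list(conditions = conditions,
       report = study_report(lapply(conditions, `[[`, "result"),
                             summaries = lapply(conditions, `[[`, "summary")),
       shared_datasets = TRUE)
}

#' Correlation of rejection outcomes across ranges
#'
#' Pairwise Pearson correlation (the phi coefficient, these being binary
#' indicators) of the per-range rejection flags across datasets. High
#' correlation between nearby ranges is why the familywise error, though
#' inflated, grows much more slowly than under independent tests. Columns
#' with zero variance (never or always rejected) have undefined
#' correlations, reported as `NA`, never as 0; defined diagonal entries
#' are 1.
#'
#' @param rejections Binary/logical matrix, datasets x ranges, at least 2
#'   rows.
#' @return r x r correlation matrix with `NA` rows/columns for undefined
#'   entries.
#' @export
rejection_correlation <- function(rejections) {
  rejections <- as.matrix(rejections) * 1
  if (nrow(rejections) < 2L) {
    stop("need at least 2 datasets to correlate rejections", call. = FALSE)
  }
  sds <- apply(rejections, 2L, stats::sd)
  C <- suppressWarnings(stats::cor(rejections))
  zv <- sds == 0
  C[zv, ] <- NA_real_
  C[, zv] <- NA_real_
  diag(C)[!zv] <- 1
  C
}

#' Study summary table
#'
#' One row per condition, ordered by the number of ranges tested: `r`,
#' `n_used`, `n_reject`, `fwe`, `ci_lower`, `ci_upper`, with the generator
#' summary (mean/sd of the sample size and case proportion) attached as
#' attribute `generator_summary` and shown by the print method.
#'
#' @param results Non-empty list of [estimate_fwe()] objects.
#' @param summaries Optional list of [summarize_patterns()] objects
#'   (one per condition) to aggregate into the generator summary.
#' @return A data frame of class `kdiff_report`.
#' @export
study_report <- function(results, summaries = NULL) {
  if (length(results) == 0L) stop("no results to report", call. = FALSE)
  stopifnot(all(vapply(results, inherits, TRUE, "kdiff_fwe")))
  df <- do.call(rbind, lapply(results, function(x) {
    data.frame(r = x$r, n_used = x$n_used, n_reject = x$n_rejections,
               fwe = x$fwe, ci_lower = x$ci_lower, ci_upper = x$ci_upper)
  }))
  df <- df[order(df$r), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(summaries)) {
    w <- vapply(summaries, `[[`, 0, "n_patterns")
    attr(df, "generator_summary") <- list(
      mean_n = sum(w * vapply(summaries, `[[`, 0, "mean_n")) / sum(w),
      mean_sd_n = mean(vapply(summaries, `[[`, 0, "sd_n")),
      mean_prop_case = sum(w * vapply(summaries, `[[`, 0,
                                      "mean_prop_case")) / sum(w),
      n_patterns = sum(w))
  }
  class(df) <- c("kdiff_report", "data.frame")
  df
}

#' @export
print.kdiff_report <- function(x, ...) {
  cat("Estimated FWE by number of ranges tested\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  gs <- attr(x, "generator_summary")
  if (!is.null(gs)) {
    cat(sprintf(
      "generator: mean n = %.1f (mean sd %.1f), mean prop case = %.4f over %d datasets\n",
      gs$mean_n, gs$mean_sd_n, gs$mean_prop_case, gs$n_patterns))
  }
  invisible(x)
}
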