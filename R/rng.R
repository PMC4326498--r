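#' Reproducible random-number streams
#'
#' All randomness in the package flows from a single master seed through
#' L'Ecuyer-CMRG stream splitting (`parallel::nextRNGStream`): each simulated
#' dataset gets its own pre-assigned stream, so results are independent of
#' evaluation order and of any parallel scheduling, and the whole study is a
#' pure function of its configuration.
#'
#' `rng_streams` derives `n` independent streams from `master_seed`;
#' `derive_seed` deterministically mixes a master seed with an index into a
#' new 32-bit seed (used, e.g., to give each study condition its own seed).
#'
#' @param master_seed Single integer master seed.
#' @param n Number of streams.
#' @return `rng_streams`: a list of `n` `.Random.seed` state vectors.
#'   `derive_seed`: a single integer in `[1, 2^31 - 19]`.
#' @export
rng_streams <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(n), length(n) == 1L, n >= 1)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set_rng_seed(master_seed)
  s <- get(".Random.seed", envir = globalenv())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

#' @rdname rng_streams
#' @param index Nonnegative integer distinguishing derived seeds.
#' @export
derive_seed <- function(master_seed, index) {
  # 64-bit-safe integer mixing in doubles (< 2^53), reduced mod a prime < 2^31
  m <- as.numeric(master_seed) %% 2147483647
  v <- (m * 48271 + as.numeric(index) * 2246822519 + 374761393) %% 2147483629
  as.integer(v + 1)
}

# Save/restore the global RNG state so package functions never leak RNG
# side effects into the caller's session.
save_rng_state <- function() {
  get0(".Random.seed", envir = globalenv(), inherits = FALSE)
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Install a seed: a single integer seeds a fresh L'Ecuyer-CMRG generator; a
# full state vector (as produced by rng_streams) is installed verbatim.
set_rng_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (length(seed) == 1L) {
    suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
    set.seed(as.integer(seed))
  } else {
    assign(".Random.seed", as.integer(seed), envir = globalenv())
  }
  invisible(NULL)
}
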