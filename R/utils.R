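#' stresstiming: single-cell stress-response timing and statistical kinetics
#'
#' Quantifies how precisely single bacterial cells time their gene-expression
#' responses to sudden stress. The package covers the full analysis chain:
#' simulation of microcolony lineage trees with stochastic promoter-activation
#' times ([generate_dataset()]), trace preprocessing ([compute_expression()]),
#' response-time extraction ([compute_response_times()]), lineage-aware
#' statistics ([subsample_trajectories()], [timing_summary()],
#' [paired_correlation()], [strict_order_test()]) and statistical-kinetics
#' inference of the number of rate-limiting molecular steps
#' ([randomness_and_steps()], [fit_erlang()], [ks_consistency()],
#' [precision_limit()]).
#'
#' @keywords internal
"_PACKAGE"

## Seed handling ------------------------------------------------------------
##
## Every stochastic operation takes an explicit `seed`. Internally we save and
## restore the caller's RNG state so that library code never perturbs the
## global stream, and we derive independent per-purpose substreams from a
## single master seed with `derive_seed()` (distinct large-prime strides keep
## substreams apart; results stay below 2^31 - 1 so they are valid R seeds).

local_seed <- function(seed, envir = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(seed)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically maps `(seed, stream)` to a new seed in `[1, 2^31 - 2]`,
#' used to give independent random streams to the simulation, subsampling,
#' bootstrap and permutation stages of a run.
#'
#' @param seed integer master seed.
#' @param stream non-negative integer identifying the substream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), stream >= 0)
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 48271 + 104729 * (as.numeric(stream) + 1)) %% (m - 1) + 1)
}

## Centered moving average; the half-width shrinks symmetrically near the
## edges so the window stays centered (a linear series is left unchanged).
moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1L || length(x) <= 1L) return(x)
  h <- (window - 1L) / 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    mean(x[(i - hi):(i + hi)])
  }, numeric(1))
}

## Consistent error helper: all validation errors carry the offending field.
fail <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
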