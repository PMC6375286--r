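## Statistical-kinetics inference.
##
## For a chain of n memory-less molecular steps, completion times are
## Erlang-distributed and satisfy sigma_t / mu_t >= 1 / sqrt(n). The inverse
## square of the observed ratio therefore lower-bounds the number of
## rate-limiting steps: R = (sigma_t / mu_t)^2, n_min = 1 / R, and the
## integer estimate is n = ceiling(n_min) ("rounding up"). Consistency of
## the data with the Erlang model is checked by a maximum-likelihood gamma
## fit followed by two-sample Kolmogorov-Smirnov comparisons against
## simulated datasets of the same size.

#' Randomness parameter and rate-limiting step count
#'
#' @param mu_t mean response time (> 0).
#' @param sigma_t standard deviation of response times. `sigma_t = 0` yields
#'   a flagged unbounded estimate (`unbounded = TRUE`, no finite step count).
#' @return a `"kinetics_estimate"` list: `ratio` (sigma_t/mu_t), `R`
#'   (ratio^2), `n_min_real` (1/R), `n_steps` (ceiling of 1/R), `unbounded`.
#' @examples
#' randomness_and_steps(1, 0.36)$n_steps   # 8
#' randomness_and_steps(1, 0.54)$n_steps   # 4
#' randomness_and_steps(1, 0.165)$n_steps  # 37
#' @export
randomness_and_steps <- function(mu_t, sigma_t) {
  if (!is_number(mu_t) || mu_t <= 0) fail("mu_t must be > 0")
  if (!is_number(sigma_t) || sigma_t < 0) fail("sigma_t must be >= 0")
  if (sigma_t == 0)
    return(structure(list(ratio = 0, R = 0, n_min_real = Inf,
                          n_steps = NA_integer_, unbounded = TRUE),
                     class = "kinetics_estimate"))
  ratio <- sigma_t / mu_t
  R <- ratio^2
  n_min <- 1 / R
  ## guard the exact integer case (ratio = 1/sqrt(k)) against fp noise
  n_steps <- max(1L, as.integer(ceiling(round(n_min, 9))))
  structure(list(ratio = ratio, R = R, n_min_real = n_min,
                 n_steps = n_steps, unbounded = FALSE),
            class = "kinetics_estimate")
}

#' @export
print.kinetics_estimate <- function(x, ...) {
  if (isTRUE(x$unbounded)) {
    cat("kinetics_estimate: sigma_t = 0; step count unbounded\n")
  } else {
    cat(sprintf(
      "kinetics_estimate: sigma_t/mu_t = %.3f, R = %.3f, n_min = %.2f -> n = %d step(s)\n",
      x$ratio, x$R, x$n_min_real, x$n_steps))
  }
  invisible(x)
}

#' Maximum-likelihood Erlang (gamma) fit to response times
#'
#' Fits a gamma distribution by maximum likelihood using the standard
#' digamma-based Newton iteration on the shape (initialized at the
#' Minka-style closed-form approximation), then rounds the shape half-up to
#' the nearest integer (the Erlang model allows only integer shapes) and
#' refits the scale at the rounded shape.
#'
#' @param times positive response times, at least 10 of them.
#' @return an `"erlang_fit"` list: `shape` (rounded, >= 1), `scale` (ML scale
#'   at the rounded shape, hours), `shape_ml` (unrounded ML shape),
#'   `scale_ml`, `n`.
#' @export
fit_erlang <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 10L) fail("need at least 10 response times")
  if (any(!is.finite(times) | times <= 0))
    fail("response times must all be positive and finite")
  s <- log(mean(times)) - mean(log(times))
  if (s <= 0)
    fail("degenerate sample (zero variance); gamma fit undefined")
  ## closed-form start, then Newton on the ML score for the shape k:
  ## log(k) - digamma(k) = s
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
    k <- k_new
  }
  shape <- max(1L, as.integer(floor(k + 0.5)))   # round half-up
  structure(list(shape = shape, scale = mean(times) / shape,
                 shape_ml = k, scale_ml = mean(times) / k,
                 n = length(times)),
            class = "erlang_fit")
}

#' @export
print.erlang_fit <- function(x, ...) {
  cat(sprintf(
    "erlang_fit: shape %d (ML %.2f), scale %.4g h, mean %.4g h, n = %d\n",
    x$shape, x$shape_ml, x$scale, x$shape * x$scale, x$n))
  invisible(x)
}

#' Simulated Kolmogorov-Smirnov consistency with the Erlang model
#'
#' Simulates `n_sim` datasets of the same size as the data from the fitted
#' gamma with integer (rounded) shape and the corresponding scale, runs a
#' two-sample KS test of each simulated set against the data, and returns
#' the fraction of simulations not rejected at level `alpha`. Values near 1
#' indicate the measured response times are consistent with an Erlang
#' distribution; note the fit is estimated from the same data, which makes
#' this check conservative (the fit absorbs part of any discrepancy).
#'
#' @param times positive response times.
#' @param fit an [fit_erlang()] result (default: fit `times`).
#' @param n_sim number of simulated datasets, default 1000.
#' @param alpha rejection level, default 0.05.
#' @param seed integer seed.
#' @return a `"ks_consistency"` list: `fraction` in \[0, 1\], `n_sim`,
#'   `alpha`, `shape`, `scale`.
#' @export
ks_consistency <- function(times, fit = fit_erlang(times), n_sim = 1000L,
                           alpha = 0.05, seed = 1L) {
  if (!is_count(n_sim)) fail("n_sim must be an integer >= 1")
  local_seed(seed)
  n <- length(times)
  ok <- vapply(seq_len(n_sim), function(i) {
    sim <- stats::rgamma(n, shape = fit$shape, scale = fit$scale)
    suppressWarnings(stats::ks.test(times, sim)$p.value) >= alpha
  }, logical(1))
  structure(list(fraction = mean(ok), n_sim = n_sim, alpha = alpha,
                 shape = fit$shape, scale = fit$scale),
            class = "ks_consistency")
}

#' @export
print.ks_consistency <- function(x, ...) {
  cat(sprintf(
    "ks_consistency: %.1f%% of %d simulated Erlang(%d) sets consistent at alpha = %.2f\n",
    100 * x$fraction, x$n_sim, x$shape, x$alpha))
  invisible(x)
}

#' Precision-limit line across promoters
#'
#' Given timing summaries for several promoters/conditions, the precision
#' limit is the line through the origin with slope equal to the smallest
#' observed `sigma_t / mu_t`: no promoter's timing variability falls below
#' it. The upper bound `sigma_t <= mu_t` (at most one rate-limiting step) is
#' validated for every point and violations are flagged.
#'
#' @param summaries a data.frame with columns `promoter`, `mu_t`, `sigma_t`,
#'   or a list of [timing_summary()] objects (names used as promoter ids).
#' @return a `"precision_limit"` list: `slope`, `anchor` (promoter with the
#'   smallest ratio), `points` (per-promoter mu_t, sigma_t, ratio),
#'   `violations` (promoters with sigma_t > mu_t).
#' @export
precision_limit <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    nm <- names(summaries)
    if (is.null(nm)) nm <- as.character(seq_along(summaries))
    summaries <- data.frame(
      promoter = nm,
      mu_t = vapply(summaries, `[[`, numeric(1), "mu_t"),
      sigma_t = vapply(summaries, `[[`, numeric(1), "sigma_t"))
  }
  if (nrow(summaries) < 1L) fail("no timing summaries given")
  pts <- data.frame(promoter = summaries$promoter, mu_t = summaries$mu_t,
                    sigma_t = summaries$sigma_t,
                    ratio = summaries$sigma_t / summaries$mu_t)
  i <- which.min(pts$ratio)
  structure(list(slope = pts$ratio[i], anchor = pts$promoter[i],
                 points = pts,
                 violations = pts$promoter[pts$sigma_t > pts$mu_t]),
            class = "precision_limit")
}

#' @export
print.precision_limit <- function(x, ...) {
  cat(sprintf(
    "precision_limit: slope %.3f (anchor %s, %d promoters); sigma_t grows by >= %d min per hour of mu_t\n",
    x$slope, x$anchor, nrow(x$points), slope_in_minutes(x$slope)))
  if (length(x$violations) > 0)
    cat(sprintf("  upper-bound violations (sigma_t > mu_t): %s\n",
                paste(x$violations, collapse = ", ")))
  invisible(x)
}

#' Precision-limit slope in minutes per hour
#'
#' Re-expresses the dimensionless slope sigma_t/mu_t as the number of
#' minutes the response-time standard deviation grows for every hour of mean
#' response time, rounded to the nearest minute.
#'
#' @param slope slope in `(0, 1]`.
#' @return integer minutes.
#' @examples
#' slope_in_minutes(0.165)  # 10
#' @export
slope_in_minutes <- function(slope) {
  if (!is_number(slope) || slope <= 0 || slope > 1)
    fail("slope must be in (0, 1]")
  as.integer(round(slope * 60))
}

#' Full kinetics report for one set of response times
#'
#' Convenience wrapper combining [randomness_and_steps()], [fit_erlang()]
#' and [ks_consistency()] for a response-time vector or a
#' [timing_summary()].
#'
#' @param times positive response times (one subsample or pooled set).
#' @param summary optional [timing_summary()]; when given, `mu_t`/`sigma_t`
#'   come from it instead of the plain mean/sd of `times`.
#' @param n_sim,alpha,seed passed to [ks_consistency()].
#' @return list with elements `estimate`, `fit`, `ks`.
#' @export
kinetics_report <- function(times, summary = NULL, n_sim = 1000L,
                            alpha = 0.05, seed = 1L) {
  mu <- if (is.null(summary)) mean(times) else summary$mu_t
  sg <- if (is.null(summary)) stats::sd(times) else summary$sigma_t
  est <- randomness_and_steps(mu, sg)
  fit <- fit_erlang(times)
  ks <- ks_consistency(times, fit, n_sim = n_sim, alpha = alpha, seed = seed)
  list(estimate = est, fit = fit, ks = ks)
}
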