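## Lineage-aware timing statistics.
##
## A microcolony's lineage tree pseudo-replicates every founder: all
## descendants of one founder share most of their history, so pooling leaves
## overstates the sample size. The remedy is subsampling: draw one random
## root-to-leaf trajectory per founder (uniform child choice at every
## division), compute the statistic on that sample, and repeat many times
## (1,000 by default). Summaries are averages over subsamples; errors come
## from founder-level bootstrap within the subsamples.

#' Configuration for lineage statistics
#'
#' @param n_subsamples number of random single-trajectory subsamples
#'   (default 1000).
#' @param n_bootstrap number of bootstrap replicates for standard errors
#'   (default 1000).
#' @param n_permutations number of Monte-Carlo permutations in the
#'   strict-order test (default 1000; exact enumeration replaces Monte Carlo
#'   for 7 or fewer founders).
#' @param seed integer seed; subsampling, bootstrap and permutation streams
#'   are derived independently from it.
#' @return an object of class `"stats_config"`.
#' @export
stats_config <- function(n_subsamples = 1000L, n_bootstrap = 1000L,
                         n_permutations = 1000L, seed = 1L) {
  for (v in list(n_subsamples, n_bootstrap, n_permutations))
    if (!is_count(v)) fail("all stats_config counts must be integers >= 1")
  structure(list(n_subsamples = as.integer(n_subsamples),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "stats_config")
}

#' Subsample single trajectories per founder
#'
#' For every subsample and every founder, walks from the founder to a leaf,
#' choosing uniformly among the daughters at each division, and records that
#' trajectory's response time in each channel. Non-responding trajectories
#' enter the sample as `NA` and are dropped per sample by downstream
#' statistics.
#'
#' @param table a trace table or expression table carrying the lineage
#'   (`cell_id`, `parent_id`, `time_h` columns).
#' @param rts a [compute_response_times()] result.
#' @param config a [stats_config()].
#' @return a `"trajectory_samples"` list: `times` — named list per channel of
#'   founders x n_subsamples matrices of response times; `leaves` — matrix of
#'   sampled leaf ids; `founders` — founder ids (rows).
#' @export
subsample_trajectories <- function(table, rts, config = stats_config()) {
  stopifnot(inherits(rts, "response_time_set") || is.data.frame(rts))
  if (any(is.na(rts$founder_id)))
    fail("response times include trajectories with no founder")
  local_seed(derive_seed(config$seed, 11L))
  first <- table[!duplicated(table$cell_id), ]
  children <- split(first$cell_id,
                    factor(first$parent_id, levels = first$cell_id))
  founders <- sort(unique(rts$founder_id))
  nf <- length(founders)
  S <- config$n_subsamples
  leaves <- matrix(NA, nrow = nf, ncol = S)
  for (s in seq_len(S)) {
    for (f in seq_len(nf)) {
      cur <- founders[f]
      repeat {
        kids <- children[[as.character(cur)]]
        if (is.null(kids) || length(kids) == 0) break
        cur <- if (length(kids) == 1L) kids else
          kids[sample.int(length(kids), 1L)]
      }
      leaves[f, s] <- cur
    }
  }
  channels <- unique(rts$channel)
  times <- lapply(channels, function(ch) {
    sub <- rts[rts$channel == ch, ]
    lut <- stats::setNames(sub$response_time, sub$trajectory_id)
    matrix(lut[as.character(leaves)], nrow = nf, ncol = S,
           dimnames = list(founders, NULL))
  })
  names(times) <- channels
  structure(list(times = times, leaves = leaves, founders = founders,
                 config = config),
            class = "trajectory_samples")
}

#' @export
print.trajectory_samples <- function(x, ...) {
  cat(sprintf("trajectory_samples: %d founders x %d subsamples, channels: %s\n",
              length(x$founders), ncol(x$leaves),
              paste(names(x$times), collapse = ", ")))
  invisible(x)
}

## column-wise sd of a matrix, NA-tolerant, vectorized
col_sds <- function(m) {
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  ss <- colSums(m^2, na.rm = TRUE)
  v <- (ss - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}

#' Subsample-averaged timing summary with bootstrap errors
#'
#' The mean response time `mu_t` is the average over subsamples of the
#' per-sample mean; the standard deviation `sigma_t` is the average over
#' subsamples of the per-sample standard deviation. Standard errors of both
#' come from resampling founders with replacement (`n_bootstrap` replicates),
#' re-averaging across the same subsamples each time.
#'
#' @param samples a [subsample_trajectories()] result, or a plain numeric
#'   matrix (founders x subsamples) of response times.
#' @param channel channel to summarize when `samples` holds several.
#' @param config a [stats_config()] (defaults to the one inside `samples`).
#' @return a `"timing_summary"` list: `mu_t`, `sigma_t`, `se_mu`, `se_sigma`,
#'   `n_founders`, `n_subsamples`, `responder_fraction`, `channel`.
#' @export
timing_summary <- function(samples, channel = NULL, config = NULL) {
  m <- if (is.matrix(samples)) samples else {
    if (is.null(channel)) channel <- names(samples$times)[1]
    samples$times[[channel]]
  }
  if (is.null(config))
    config <- if (is.matrix(samples)) stats_config() else samples$config
  nf <- nrow(m)
  if (nf < 2L) fail("need at least 2 founders for a timing summary")
  n_resp <- colSums(!is.na(m))
  if (all(n_resp < 2L))
    fail("fewer than 2 responders in every subsample; sigma_t undefined")
  mu_t <- mean(colMeans(m, na.rm = TRUE), na.rm = TRUE)
  sigma_t <- mean(col_sds(m), na.rm = TRUE)

  local_seed(derive_seed(config$seed, 13L))
  B <- config$n_bootstrap
  boot_mu <- boot_sigma <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(nf, nf, replace = TRUE)
    mb <- m[idx, , drop = FALSE]
    boot_mu[b] <- mean(colMeans(mb, na.rm = TRUE), na.rm = TRUE)
    boot_sigma[b] <- mean(col_sds(mb), na.rm = TRUE)
  }
  structure(list(mu_t = mu_t, sigma_t = sigma_t,
                 se_mu = stats::sd(boot_mu), se_sigma = stats::sd(boot_sigma),
                 n_founders = nf, n_subsamples = ncol(m),
                 responder_fraction = mean(!is.na(m)),
                 channel = if (is.null(channel)) NA_character_ else channel),
            class = "timing_summary")
}

#' @export
print.timing_summary <- function(x, ...) {
  cat(sprintf(
    "timing_summary (%s): mu_t = %.3f +/- %.3f h, sigma_t = %.3f +/- %.3f h\n",
    x$channel, x$mu_t, x$se_mu, x$sigma_t, x$se_sigma))
  cat(sprintf("  %d founders, %d subsamples, responder fraction %.2f\n",
              x$n_founders, x$n_subsamples, x$responder_fraction))
  invisible(x)
}

## complete pairs in subsample s
complete_pairs <- function(ma, mb, s) {
  ok <- !is.na(ma[, s]) & !is.na(mb[, s])
  list(a = ma[ok, s], b = mb[ok, s])
}

#' Subsample-averaged Pearson correlation for a dual-reporter pair
#'
#' Computes the Pearson correlation between the two channels' response times
#' within each subsample and reports the mean and sd of the coefficient over
#' subsamples plus the median of the per-sample two-sided P-values.
#' Subsamples with fewer than 3 complete pairs or a zero-variance channel
#' are skipped with a warning.
#'
#' @param samples a [subsample_trajectories()] result with two channels, or a
#'   list of two founders x subsamples matrices.
#' @param config a [stats_config()].
#' @return a `"pair_timing"` list: `r_mean`, `r_sd`, `p_median`,
#'   `n_samples_used`.
#' @export
paired_correlation <- function(samples, config = NULL) {
  mats <- if (inherits(samples, "trajectory_samples")) samples$times
          else samples
  if (length(mats) != 2L) fail("paired_correlation requires two channels")
  ma <- mats[[1]]; mb <- mats[[2]]
  S <- ncol(ma)
  r <- p <- rep(NA_real_, S)
  skipped <- 0L
  for (s in seq_len(S)) {
    cp <- complete_pairs(ma, mb, s)
    if (length(cp$a) < 3L || stats::sd(cp$a) == 0 || stats::sd(cp$b) == 0) {
      skipped <- skipped + 1L
      next
    }
    ct <- stats::cor.test(cp$a, cp$b, method = "pearson",
                          alternative = "two.sided")
    r[s] <- unname(ct$estimate)
    p[s] <- ct$p.value
  }
  if (skipped > 0L)
    warning(sprintf("%d of %d subsamples skipped (too few pairs or zero variance)",
                    skipped, S), call. = FALSE)
  if (all(is.na(r))) fail("no usable subsample for correlation")
  structure(list(r_mean = mean(r, na.rm = TRUE),
                 r_sd = stats::sd(r[!is.na(r)]),
                 p_median = stats::median(p, na.rm = TRUE),
                 n_samples_used = sum(!is.na(r))),
            class = "pair_timing")
}

#' @export
print.pair_timing <- function(x, ...) {
  cat(sprintf("pair_timing: r = %.3f +/- %.3f (median P = %.3g, %d samples)\n",
              x$r_mean, x$r_sd, x$p_median, x$n_samples_used))
  invisible(x)
}

## all permutations of 1..n (n <= 7 in practice: at most 5040 rows)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

## fraction of pairings whose order statistic is >= observed
order_null_fraction <- function(a, b, observed, n_permutations,
                                exact_limit = 7L) {
  n <- length(a)
  if (n <= exact_limit) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1, function(pr) sum(b[pr] > a))
  } else {
    stats <- vapply(seq_len(n_permutations), function(i)
      sum(b[sample.int(n)] > a), numeric(1))
  }
  mean(stats >= observed)
}

#' Strict-temporal-order permutation test for a dual-reporter pair
#'
#' The order statistic is the number of founders whose channel-B response
#' time strictly exceeds their channel-A time (ties count as non-ordered).
#' Within each subsample, the B times are randomly re-paired with the A
#' times (`n_permutations` times, or exhaustively for 7 or fewer founders)
#' and the fraction of pairings at least as strictly ordered as the observed
#' one is recorded; the reported P-value is the mean of these fractions over
#' all subsamples.
#'
#' @param samples a [subsample_trajectories()] result with two channels, or a
#'   list of two founders x subsamples matrices.
#' @param config a [stats_config()].
#' @param exact_limit largest number of pairs for which the null is
#'   enumerated exhaustively instead of Monte-Carlo sampled; default 7
#'   (5040 pairings). Set to 0 to force Monte Carlo.
#' @return a `"strict_order"` list: `order_statistic` (mean observed count
#'   over subsamples), `n_pairs` (mean complete pairs), `permutation_P`.
#' @export
strict_order_test <- function(samples, config = NULL, exact_limit = 7L) {
  mats <- if (inherits(samples, "trajectory_samples")) samples$times
          else samples
  if (length(mats) != 2L) fail("strict_order_test requires two channels")
  if (is.null(config))
    config <- if (inherits(samples, "trajectory_samples")) samples$config
              else stats_config()
  ma <- mats[[1]]; mb <- mats[[2]]
  S <- ncol(ma)
  local_seed(derive_seed(config$seed, 17L))
  obs <- frac <- npairs <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    cp <- complete_pairs(ma, mb, s)
    if (length(cp$a) < 2L) next
    observed <- sum(cp$b > cp$a)
    obs[s] <- observed
    npairs[s] <- length(cp$a)
    frac[s] <- order_null_fraction(cp$a, cp$b, observed,
                                   config$n_permutations, exact_limit)
  }
  if (all(is.na(frac))) fail("fewer than 2 complete pairs in every subsample")
  structure(list(order_statistic = mean(obs, na.rm = TRUE),
                 n_pairs = mean(npairs, na.rm = TRUE),
                 permutation_P = mean(frac, na.rm = TRUE)),
            class = "strict_order")
}

#' @export
print.strict_order <- function(x, ...) {
  cat(sprintf(
    "strict_order: %.2f of %.2f pairs ordered (B after A); permutation P = %.4f\n",
    x$order_statistic, x$n_pairs, x$permutation_P))
  invisible(x)
}
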