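## Chains of memory-less molecular steps.
##
## The central kinetic object: a response is modelled as the completion of a
## chain of n memory-less (exponential) steps, so completion times are
## Erlang-distributed with shape n and rate n / mean_time per step. The
## coefficient of variation of completion times is 1/sqrt(n), which is what
## lets timing variability bound the number of rate-limiting steps.

#' Specify a chain of memory-less molecular steps
#'
#' A chain of `n_steps` sequential, irreversible steps, each with an
#' exponential waiting time of rate `n_steps / mean_time`, so that the chain's
#' completion time has mean `mean_time` and is Erlang-distributed.
#'
#' @param n_steps number of memory-less steps (integer >= 1).
#' @param mean_time mean completion time of the whole chain, in hours.
#'   `mean_time = 0` is allowed and denotes a degenerate, instantaneous chain
#'   (used e.g. for reporters that add no delay); such a chain cannot be
#'   sampled with [sample_erlang()] but contributes zero time in composite
#'   architectures.
#' @return an object of class `"chain_spec"`.
#' @seealso [sample_erlang()], [dual_chain_spec()]
#' @export
chain_spec <- function(n_steps, mean_time) {
  if (!is_count(n_steps))
    fail("n_steps must be a single integer >= 1 (got %s)", format(n_steps))
  if (!is_number(mean_time) || mean_time < 0)
    fail("mean_time must be a single non-negative number (got %s)",
         format(mean_time))
  structure(list(n_steps = as.integer(n_steps), mean_time = mean_time),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("chain_spec: %d step(s), mean completion %.4g h (CV %.3f)\n",
              x$n_steps, x$mean_time,
              if (x$mean_time > 0) 1 / sqrt(x$n_steps) else 0))
  invisible(x)
}

#' Specify the chain architecture behind a dual-reporter pair
#'
#' Two reporters A and B can sit on the same causal chain of molecular events
#' (`"serial"`) or on independent chains running in parallel
#' (`"parallel"`). Serial: both responses share an upstream chain
#' (`shared`), reporter B additionally waits for a mid chain (`mid`), and each
#' reporter has its own detection chain, so the latent activation times are
#' `t_A = T_shared + T_repA` and `t_B = T_shared + T_mid + T_repB`.
#' Parallel: `t_A = T_indA + T_repA` and `t_B = T_indB + T_repB` with all
#' chains independent. Serial architectures produce a strict temporal order
#' and correlated times; parallel architectures produce neither.
#'
#' @param architecture `"serial"` or `"parallel"`.
#' @param shared,mid [chain_spec()]s, serial only.
#' @param independent_a,independent_b [chain_spec()]s, parallel only.
#' @param reporter_a,reporter_b [chain_spec()]s for the reporter-detection
#'   chains (use `chain_spec(1, 0)` for instantaneous reporters).
#' @return an object of class `"dual_chain_spec"`.
#' @seealso [sample_dual_times()]
#' @export
dual_chain_spec <- function(architecture = c("serial", "parallel"),
                            shared = NULL, mid = NULL,
                            independent_a = NULL, independent_b = NULL,
                            reporter_a = chain_spec(1, 0),
                            reporter_b = chain_spec(1, 0)) {
  architecture <- match.arg(architecture)
  chk <- function(x, name) {
    if (!inherits(x, "chain_spec"))
      fail("%s must be a chain_spec for the %s architecture", name,
           architecture)
    x
  }
  if (architecture == "serial") {
    chk(shared, "shared"); chk(mid, "mid")
  } else {
    chk(independent_a, "independent_a"); chk(independent_b, "independent_b")
  }
  chk(reporter_a, "reporter_a"); chk(reporter_b, "reporter_b")
  structure(list(architecture = architecture, shared = shared, mid = mid,
                 independent_a = independent_a, independent_b = independent_b,
                 reporter_a = reporter_a, reporter_b = reporter_b),
            class = "dual_chain_spec")
}

#' @export
print.dual_chain_spec <- function(x, ...) {
  cat(sprintf("dual_chain_spec: %s architecture\n", x$architecture))
  invisible(x)
}

#' Sample completion times of a chain of memory-less steps
#'
#' Draws completion times of a chain of `n_steps` exponential steps, i.e.
#' Erlang variates with shape `n_steps` and per-step rate
#' `n_steps / mean_time`. As `count` grows, the sample mean converges to
#' `mean_time` and the coefficient of variation to `1 / sqrt(n_steps)`.
#'
#' @param spec a [chain_spec()] with `mean_time > 0`.
#' @param count number of draws (integer >= 1).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return numeric vector of `count` completion times (hours).
#' @examples
#' x <- sample_erlang(chain_spec(37, 1.87), 1e4, seed = 1)
#' mean(x)            # ~ 1.87
#' sd(x) / mean(x)    # ~ 1 / sqrt(37) = 0.164
#' @export
sample_erlang <- function(spec, count, seed) {
  if (!inherits(spec, "chain_spec")) fail("spec must be a chain_spec")
  if (!is_count(count)) fail("count must be a single integer >= 1")
  if (spec$mean_time <= 0)
    fail("sample_erlang requires mean_time > 0 (got %s); a zero-duration chain has no waiting-time distribution",
         format(spec$mean_time))
  local_seed(seed)
  stats::rgamma(count, shape = spec$n_steps,
                rate = spec$n_steps / spec$mean_time)
}

## Internal: sample completion times allowing the degenerate zero-mean chain.
sample_chain_times <- function(spec, count) {
  if (spec$mean_time == 0) return(numeric(count) )
  stats::rgamma(count, shape = spec$n_steps,
                rate = spec$n_steps / spec$mean_time)
}

#' Sample latent activation-time pairs for a dual-reporter architecture
#'
#' Draws `count` pairs `(t_A, t_B)` of latent activation times under the
#' serial or parallel architecture of `spec` (see [dual_chain_spec()]).
#' Serial pairs share the upstream chain's completion time, so
#' `t_B - t_A = T_mid + T_repB - T_repA`; with zero-duration reporter chains
#' the order `t_B > t_A` holds for every pair and
#' `cor(t_A, t_B) = sd_shared / sqrt(sd_shared^2 + sd_mid^2)`. Parallel
#' pairs are independent.
#'
#' @param spec a [dual_chain_spec()].
#' @param count number of pairs.
#' @param seed integer seed.
#' @return a data.frame with columns `t_a`, `t_b`.
#' @export
sample_dual_times <- function(spec, count, seed) {
  if (!inherits(spec, "dual_chain_spec"))
    fail("spec must be a dual_chain_spec")
  if (!is_count(count)) fail("count must be a single integer >= 1")
  local_seed(seed)
  if (spec$architecture == "serial") {
    t_shared <- sample_chain_times(spec$shared, count)
    t_mid <- sample_chain_times(spec$mid, count)
    t_a <- t_shared + sample_chain_times(spec$reporter_a, count)
    t_b <- t_shared + t_mid + sample_chain_times(spec$reporter_b, count)
  } else {
    t_a <- sample_chain_times(spec$independent_a, count) +
      sample_chain_times(spec$reporter_a, count)
    t_b <- sample_chain_times(spec$independent_b, count) +
      sample_chain_times(spec$reporter_b, count)
  }
  data.frame(t_a = t_a, t_b = t_b)
}
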