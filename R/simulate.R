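## Microcolony lineage-tree simulation.
##
## Emulates the raw material of a time-lapse experiment: a few cells loaded
## into a chamber grow exponentially, divide into two daughters, and are
## imaged on a fixed frame grid. Time zero is stress addition throughout;
## "founders" are the cells alive at that moment, and they are the units of
## statistical independence for all downstream lineage statistics.

#' Specify a fluorescent reporter channel
#'
#' Describes how a latent promoter-activation event is observed: mature
#' fluorophore accumulates at `production_rate` starting `maturation_time`
#' after activation, is attenuated by `bleach_per_frame` at every imaging
#' frame, and is read out on top of cellular autofluorescence and a constant
#' per-pixel environment background, with additive Gaussian measurement noise
#' on the total.
#'
#' @param production_rate fluorescence units per hour once active (>= 0).
#' @param maturation_time fluorophore maturation delay, hours (>= 0). Around
#'   10 min for fast YFP/CFP variants, ~40 min for mCherry.
#' @param bleach_per_frame fraction of fluorescence lost per imaging frame,
#'   in `[0, 1)` (measured at up to 3% per frame for YFP, 0.5% for CFP).
#' @param autofluorescence baseline autofluorescence per unit area.
#' @param autofluorescence_trend linear drift of autofluorescence per hour
#'   (e.g. the upward drift of CFP-channel autofluorescence under some
#'   stressors).
#' @param background constant per-pixel environment background added to the
#'   emitted totals and reported in the `bg_` column.
#' @param noise_sd standard deviation of Gaussian measurement noise added to
#'   the total fluorescence of each cell at each frame (>= 0).
#' @return an object of class `"reporter_spec"`.
#' @export
reporter_spec <- function(production_rate = 100, maturation_time = 0,
                          bleach_per_frame = 0, autofluorescence = 0,
                          autofluorescence_trend = 0, background = 0,
                          noise_sd = 0) {
  if (!is_number(production_rate) || production_rate < 0)
    fail("production_rate must be >= 0")
  if (!is_number(maturation_time) || maturation_time < 0)
    fail("maturation_time must be >= 0")
  if (!is_number(bleach_per_frame) || bleach_per_frame < 0 ||
      bleach_per_frame >= 1)
    fail("bleach_per_frame must be in [0, 1)")
  if (!is_number(noise_sd) || noise_sd < 0) fail("noise_sd must be >= 0")
  if (!is_number(autofluorescence) || !is_number(autofluorescence_trend) ||
      !is_number(background))
    fail("autofluorescence, trend and background must be single numbers")
  structure(list(production_rate = production_rate,
                 maturation_time = maturation_time,
                 bleach_per_frame = bleach_per_frame,
                 autofluorescence = autofluorescence,
                 autofluorescence_trend = autofluorescence_trend,
                 background = background,
                 noise_sd = noise_sd),
            class = "reporter_spec")
}

#' Configure a microcolony simulation
#'
#' @param n_founders number of independent root cells seeded at the start of
#'   the pre-stress window. With a short pre-stress window (shorter than one
#'   doubling) these are exactly the founders present at stress addition;
#'   founders are always recomputed as the cells alive at time zero.
#' @param growth_rate_mean,growth_rate_sd per-cell exponential growth rate
#'   distribution, per hour; rates are drawn once per cell from a normal
#'   truncated at zero.
#' @param division_size_ratio relative size at division (nominally 2).
#' @param division_size_sd lognormal noise sd on the division size ratio.
#' @param frame_interval imaging interval, hours (10-20 min typical).
#' @param pre_stress_duration,post_stress_duration imaged time before/after
#'   stress addition, hours. `pre_stress_duration` should be a multiple of
#'   `frame_interval` so that a frame falls exactly at time zero.
#' @param chain a [chain_spec()] (single channel) or [dual_chain_spec()]
#'   (two channels) generating latent activation times per founder.
#' @param reporters named list of [reporter_spec()]s, one per channel; one
#'   entry for a single chain, two for a dual chain.
#' @param lineage_jitter_sd sd (hours) of zero-mean perturbation applied to a
#'   daughter's inherited activation time at each division; 0 means perfect
#'   inheritance within a founder's lineage.
#' @param seed integer seed fixing all randomness of the simulation.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 4,
                       growth_rate_mean = 0.3, growth_rate_sd = 0,
                       division_size_ratio = 2, division_size_sd = 0,
                       frame_interval = 0.25,
                       pre_stress_duration = 1, post_stress_duration = 8,
                       chain = chain_spec(8, 4),
                       reporters = list(yfp = reporter_spec()),
                       lineage_jitter_sd = 0,
                       seed = 1L) {
  if (!is_count(n_founders))
    fail("n_founders must be a single integer >= 1 (got %s)",
         format(n_founders))
  if (!is_number(growth_rate_mean) || growth_rate_mean <= 0)
    fail("growth_rate_mean must be > 0")
  if (!is_number(growth_rate_sd) || growth_rate_sd < 0)
    fail("growth_rate_sd must be >= 0")
  if (!is_number(division_size_ratio) || division_size_ratio <= 1)
    fail("division_size_ratio must be > 1")
  if (!is_number(division_size_sd) || division_size_sd < 0)
    fail("division_size_sd must be >= 0")
  if (!is_number(frame_interval) || frame_interval <= 0)
    fail("frame_interval must be > 0")
  if (!is_number(pre_stress_duration) || pre_stress_duration < 0)
    fail("pre_stress_duration must be >= 0")
  if (!is_number(post_stress_duration) || post_stress_duration <= 0)
    fail("post_stress_duration must be > 0")
  if (frame_interval > post_stress_duration)
    fail("frame_interval must not exceed post_stress_duration")
  if (!inherits(chain, "chain_spec") && !inherits(chain, "dual_chain_spec"))
    fail("chain must be a chain_spec or dual_chain_spec")
  n_ch <- if (inherits(chain, "dual_chain_spec")) 2L else 1L
  if (!is.list(reporters) || length(reporters) != n_ch ||
      is.null(names(reporters)) || any(names(reporters) == "") ||
      !all(vapply(reporters, inherits, logical(1), "reporter_spec")))
    fail("reporters must be a named list of %d reporter_spec(s)", n_ch)
  if (!is_number(lineage_jitter_sd) || lineage_jitter_sd < 0)
    fail("lineage_jitter_sd must be >= 0")
  structure(list(n_founders = as.integer(n_founders),
                 growth_rate_mean = growth_rate_mean,
                 growth_rate_sd = growth_rate_sd,
                 division_size_ratio = division_size_ratio,
                 division_size_sd = division_size_sd,
                 frame_interval = frame_interval,
                 pre_stress_duration = pre_stress_duration,
                 post_stress_duration = post_stress_duration,
                 chain = chain, reporters = reporters,
                 lineage_jitter_sd = lineage_jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a microcolony lineage tree
#'
#' Grows `n_founders` root cells from the start of the pre-stress window to
#' the end of the observation. Each cell grows exponentially at a per-cell
#' rate drawn from `N(growth_rate_mean, growth_rate_sd)` truncated at zero,
#' divides when its size reaches `division_size_ratio` times its birth size
#' (with lognormal noise on the ratio), and produces two daughters of half
#' its size. Per-frame sizes are emitted on the imaging frame grid; time zero
#' is stress addition and the founders slot lists the cells alive then.
#'
#' @param config a [sim_config()].
#' @return an object of class `"lineage_tree"`: a list with `cells`
#'   (cell_id, parent_id, birth_time, division_time, birth_size,
#'   growth_rate), `frames` (cell_id, frame, time_h, area), `founders`
#'   (cell ids alive at time zero) and `config`.
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(derive_seed(config$seed, 0L))
  t_start <- -config$pre_stress_duration
  t_end <- config$post_stress_duration
  grid <- seq(0L, floor((t_end - t_start) / config$frame_interval))
  frame_times <- t_start + grid * config$frame_interval

  draw_rate <- function() {
    repeat {
      g <- stats::rnorm(1, config$growth_rate_mean, config$growth_rate_sd)
      if (g > 0) return(g)
    }
  }
  draw_ratio <- function() {
    config$division_size_ratio *
      exp(stats::rnorm(1, 0, config$division_size_sd))
  }

  ## breadth-first over a FIFO queue: deterministic draw order under a seed
  cells <- list()
  queue <- lapply(seq_len(config$n_founders), function(i)
    list(parent = NA_integer_, birth_time = t_start, birth_size = 1))
  next_id <- 1L
  while (length(queue) > 0L) {
    cell <- queue[[1L]]; queue <- queue[-1L]
    id <- next_id; next_id <- next_id + 1L
    g <- draw_rate()
    ratio <- draw_ratio()
    t_div <- cell$birth_time + log(ratio) / g
    divides <- t_div <= t_end
    cells[[id]] <- list(cell_id = id, parent_id = cell$parent,
                        birth_time = cell$birth_time,
                        division_time = if (divides) t_div else NA_real_,
                        birth_size = cell$birth_size, growth_rate = g)
    if (divides) {
      size_at_div <- cell$birth_size * exp(g * (t_div - cell$birth_time))
      for (k in 1:2)
        queue[[length(queue) + 1L]] <- list(parent = id, birth_time = t_div,
                                            birth_size = size_at_div / 2)
    }
  }
  cells <- do.call(rbind, lapply(cells, as.data.frame))

  ## per-frame sizes: a cell owns frames in [birth, division)
  frames <- lapply(seq_len(nrow(cells)), function(i) {
    b <- cells$birth_time[i]
    d <- if (is.na(cells$division_time[i])) Inf else cells$division_time[i]
    k <- which(frame_times >= b & frame_times < d)
    if (length(k) == 0L) return(NULL)
    data.frame(cell_id = cells$cell_id[i], frame = k - 1L,
               time_h = frame_times[k],
               area = cells$birth_size[i] *
                 exp(cells$growth_rate[i] * (frame_times[k] - b)))
  })
  frames <- do.call(rbind, frames[!vapply(frames, is.null, logical(1))])
  frames <- frames[order(frames$cell_id, frames$frame), , drop = FALSE]
  rownames(frames) <- NULL

  founders <- cells$cell_id[cells$birth_time <= 0 &
                              (is.na(cells$division_time) |
                                 cells$division_time > 0)]
  structure(list(cells = cells, frames = frames,
                 founders = as.integer(founders), config = config),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf(
    "lineage_tree: %d cells, %d founders at stress addition, %d frame rows\n",
    nrow(x$cells), length(x$founders), nrow(x$frames)))
  invisible(x)
}

#' Assign latent promoter-activation times along a lineage tree
#'
#' Draws one latent activation time per channel per founder (from the Erlang
#' chain model) and propagates it to every descendant. At each division the
#' inherited time is optionally perturbed by zero-mean Gaussian jitter of sd
#' `lineage_jitter_sd` (and truncated at zero); with zero jitter every
#' descendant of a founder carries the founder's time exactly, which matches
#' treating the founder lineage as the unit of timing variability.
#' Cells that are ancestors of founders (alive only before stress addition)
#' receive `Inf`, i.e. they never activate.
#'
#' @param tree a [simulate_lineage()] result.
#' @param chain [chain_spec()] or [dual_chain_spec()]; defaults to the one in
#'   the tree's config.
#' @param lineage_jitter_sd jitter sd in hours (default from config).
#' @param seed integer seed (default derived from the config seed).
#' @return data.frame with columns `cell_id`, `founder_id`, and one
#'   activation-time column `t_act_<channel>` per channel, in hours after
#'   stress addition.
#' @export
assign_activation_times <- function(tree, chain = tree$config$chain,
                                    lineage_jitter_sd =
                                      tree$config$lineage_jitter_sd,
                                    seed = derive_seed(tree$config$seed, 1L)) {
  stopifnot(inherits(tree, "lineage_tree"))
  if (length(tree$founders) < 1L) fail("tree has no founders")
  local_seed(seed)
  nf <- length(tree$founders)
  channels <- names(tree$config$reporters)
  if (inherits(chain, "dual_chain_spec")) {
    if (length(channels) != 2L)
      fail("dual chain requires two reporter channels")
    pairs <- sample_dual_times(chain, nf, seed = derive_seed(seed, 7L))
    founder_times <- cbind(pairs$t_a, pairs$t_b)
  } else if (inherits(chain, "chain_spec")) {
    if (length(channels) != 1L)
      fail("single chain requires one reporter channel")
    founder_times <- matrix(sample_erlang(chain, nf,
                                          seed = derive_seed(seed, 7L)),
                            ncol = 1L)
  } else fail("chain must be a chain_spec or dual_chain_spec")

  cells <- tree$cells
  n <- nrow(cells)
  times <- matrix(Inf, nrow = n, ncol = length(channels))
  founder_of <- rep(NA_integer_, n)
  idx <- match(tree$founders, cells$cell_id)
  times[idx, ] <- founder_times
  founder_of[idx] <- tree$founders

  ## propagate down in birth order (parents always precede children by id)
  ord <- order(cells$birth_time, cells$cell_id)
  for (i in ord) {
    p <- cells$parent_id[i]
    if (is.na(p) || !is.na(founder_of[i])) next
    pi <- match(p, cells$cell_id)
    if (is.na(founder_of[pi])) next   # still pre-founder territory
    founder_of[i] <- founder_of[pi]
    jit <- if (lineage_jitter_sd > 0)
      stats::rnorm(length(channels), 0, lineage_jitter_sd) else 0
    times[i, ] <- pmax(times[pi, ] + jit, 0)
  }
  out <- data.frame(cell_id = cells$cell_id, founder_id = founder_of)
  for (j in seq_along(channels))
    out[[paste0("t_act_", channels[j])]] <- times[, j]
  out
}
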