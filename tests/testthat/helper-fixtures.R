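# Shared fixtures built in code.

# Brute-force Erlang oracle: completion time as an explicit sum of
# exponential step waiting times (independent of the packaged sampler path).
erlang_oracle <- function(n_steps, mean_time, count, seed) {
  set.seed(seed)
  rowSums(matrix(stats::rexp(count * n_steps,
                             rate = n_steps / mean_time),
                 nrow = count))
}

# A small noiseless single-channel colony for round-trip tests.
noiseless_config <- function(n_founders = 2, seed = 11,
                             chain = chain_spec(8, 4),
                             production_rate = 2000,
                             maturation_time = 0, post = 12) {
  sim_config(n_founders = n_founders, growth_rate_mean = 0.2,
             growth_rate_sd = 0, division_size_sd = 0,
             frame_interval = 0.25, pre_stress_duration = 1,
             post_stress_duration = post, chain = chain,
             reporters = list(yfp = reporter_spec(
               production_rate = production_rate,
               maturation_time = maturation_time)),
             lineage_jitter_sd = 0, seed = seed)
}

# Hand-built lineage table: one founder (1) dividing into (2, 3), each
# dividing into two leaves (4, 5) and (6, 7); frames at -0.5 .. 3.5 h.
toy_tree_table <- function(leaf_values = c(1, 2, 3, 4)) {
  mk <- function(cell, parent, frames, times) {
    data.frame(colony_id = 1, cell_id = cell,
               parent_id = if (is.na(parent)) NA else parent,
               frame = frames, time_h = times,
               area = 2^(times - times[1]), fluor_yfp = 1, bg_yfp = 0)
  }
  rbind(mk(1, NA, 0:1, c(-0.5, 0)),
        mk(2, 1, 2:3, c(0.5, 1)), mk(3, 1, 2:3, c(0.5, 1)),
        mk(4, 2, 4:5, c(1.5, 2)), mk(5, 2, 4:5, c(1.5, 2)),
        mk(6, 3, 4:5, c(1.5, 2)), mk(7, 3, 4:5, c(1.5, 2)))
}

toy_response_set <- function(leaf_values = c(1, 2, 3, 4),
                             channel = "yfp") {
  data.frame(colony_id = 1, founder_id = 1, trajectory_id = 4:7,
             channel = channel, measure = "threshold",
             response_time = leaf_values, responded = 1L,
             threshold_used = NA_real_)
}

# Direct founders x subsamples matrices for the pair statistics, bypassing
# tree subsampling: each subsample sees the same founder values.
constant_samples <- function(a, b, S = 50) {
  list(a = matrix(a, nrow = length(a), ncol = S),
       b = matrix(b, nrow = length(b), ncol = S))
}
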