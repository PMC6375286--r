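test_that("cells grow exponentially at the configured rate without noise", {
  cfg <- sim_config(n_founders = 1, growth_rate_mean = 0.5,
                    growth_rate_sd = 0, division_size_sd = 0,
                    frame_interval = 0.2, pre_stress_duration = 0.4,
                    post_stress_duration = 1, seed = 1)
  tree <- simulate_lineage(cfg)
  root <- tree$frames[tree$frames$cell_id == 1, ]
  expect_equal(root$area, exp(0.5 * (root$time_h + 0.4)), tolerance = 1e-12)
})

test_that("a noiseless colony doubles synchronously: 4 founders, 3 generations, 32 leaves", {
  g <- log(2) / 2  # 2 h generation time
  cfg <- sim_config(n_founders = 4, growth_rate_mean = g,
                    growth_rate_sd = 0, division_size_sd = 0,
                    frame_interval = 0.5, pre_stress_duration = 0.5,
                    post_stress_duration = 6, seed = 2)
  tree <- simulate_lineage(cfg)
  expect_length(tree$founders, 4)
  leaves <- setdiff(tree$cells$cell_id, tree$cells$parent_id)
  expect_length(leaves, 4 * 2^3)
  # each division yields exactly two daughters
  kids <- table(tree$cells$parent_id)
  expect_true(all(kids == 2))
})

test_that("lineage simulation is reproducible bit for bit", {
  cfg <- sim_config(n_founders = 3, growth_rate_sd = 0.05,
                    division_size_sd = 0.05, seed = 99)
  expect_identical(simulate_lineage(cfg), simulate_lineage(cfg))
})

test_that("activation times are inherited exactly when jitter is zero", {
  cfg <- noiseless_config(n_founders = 1, seed = 5)
  tree <- simulate_lineage(cfg)
  act <- assign_activation_times(tree)
  per_founder <- act[is.finite(act$t_act_yfp), ]
  expect_gt(nrow(per_founder), 1)
  expect_equal(length(unique(per_founder$t_act_yfp)), 1)
})

test_that("founder activation times reproduce the Erlang chain statistics", {
  cfg <- sim_config(n_founders = 200, growth_rate_mean = 0.1,
                    pre_stress_duration = 0.5, post_stress_duration = 2,
                    chain = chain_spec(8, 4), seed = 21)
  tree <- simulate_lineage(cfg)
  act <- assign_activation_times(tree)
  ft <- act$t_act_yfp[match(tree$founders, act$cell_id)]
  # founder draws are exactly the packaged Erlang sampler on the derived seed
  expected <- sample_erlang(chain_spec(8, 4), 200,
                            seed = derive_seed(derive_seed(21, 1L), 7L))
  expect_equal(ft, expected)
  expect_lt(abs(sd(ft) / mean(ft) - 1 / sqrt(8)), 3 / sqrt(200))
})

test_that("dual serial activation keeps the per-founder order contract", {
  dual <- dual_chain_spec("serial", shared = chain_spec(4, 2),
                          mid = chain_spec(2, 1))
  cfg <- sim_config(n_founders = 30, growth_rate_mean = 0.2,
                    chain = dual,
                    reporters = list(a = reporter_spec(),
                                     b = reporter_spec()),
                    seed = 31)
  tree <- simulate_lineage(cfg)
  act <- assign_activation_times(tree)
  f <- act[match(tree$founders, act$cell_id), ]
  expect_true(all(f$t_act_b > f$t_act_a))
})

test_that("per-division jitter perturbs daughters but not founders", {
  cfg <- sim_config(n_founders = 1, growth_rate_mean = log(2) / 2,
                    pre_stress_duration = 0.5, post_stress_duration = 6,
                    chain = chain_spec(8, 4), lineage_jitter_sd = 0.2,
                    seed = 8)
  tree <- simulate_lineage(cfg)
  act <- assign_activation_times(tree)
  times <- act$t_act_yfp[is.finite(act$t_act_yfp)]
  expect_gt(length(unique(times)), 1)
})

test_that("rendered expression is silent before activation and rises after", {
  cfg <- noiseless_config(n_founders = 1, seed = 12)
  ds <- generate_dataset(cfg)
  expr <- compute_expression(ds$traces)
  t_act <- ds$truth$activation_time[1]
  root <- expr[expr$cell_id == 1, ]
  expect_true(all(abs(root$expr_yfp[root$time_h < t_act]) < 1e-9))
  after <- expr$expr_yfp[expr$time_h >= t_act + cfg$frame_interval]
  expect_true(all(after > 0))
})

test_that("maturation delay shifts the detected response time by ~m", {
  m <- 0.5
  cfg0 <- noiseless_config(n_founders = 1, seed = 14)
  cfg1 <- noiseless_config(n_founders = 1, seed = 14, maturation_time = m)
  rt <- function(cfg) {
    ds <- generate_dataset(cfg)
    expr <- compute_expression(ds$traces)
    rts <- compute_response_times(expr)
    mean(rts$response_time)
  }
  expect_equal(rt(cfg1) - rt(cfg0), m, tolerance = cfg0$frame_interval)
})

test_that("photobleaching retains (1-b)^40 of an early bolus after 40 frames", {
  mk_traces <- function(t_act) {
    cfg <- sim_config(n_founders = 1, growth_rate_mean = 0.05,
                      growth_rate_sd = 0, division_size_sd = 0,
                      frame_interval = 0.1, pre_stress_duration = 0,
                      post_stress_duration = 4.6,
                      chain = chain_spec(1, 1),
                      reporters = list(yfp = reporter_spec(
                        production_rate = 100, bleach_per_frame = 0.03)),
                      seed = 3)
    tree <- simulate_lineage(cfg)
    act <- data.frame(cell_id = tree$cells$cell_id,
                      founder_id = tree$founders[1], t_act_yfp = t_act)
    render_traces(tree, act, cfg$reporters, seed = 1)
  }
  early <- mk_traces(0.1)   # activation exactly on a frame time
  late <- mk_traces(0.2)    # one frame later
  d <- early$fluor_yfp - late$fluor_yfp
  i0 <- which(d > 0)[1]
  expect_equal(d[i0 + 40] / d[i0], 0.97^40, tolerance = 1e-9)
  # to the printed precision, 30% of the initial signal is retained
  expect_equal(round(100 * 0.97^40), 30)
})

test_that("fluorescence is conserved at division (partitioned by size)", {
  cfg <- noiseless_config(n_founders = 1, seed = 16, post = 8)
  ds <- generate_dataset(cfg)
  tree <- ds$tree
  div <- tree$cells[!is.na(tree$cells$division_time) &
                      tree$cells$division_time > ds$truth$activation_time[1] +
                      1, ][1, ]
  expect_false(is.na(div$cell_id))
  kids <- tree$cells$cell_id[tree$cells$parent_id %in% div$cell_id]
  tr <- ds$traces
  parent_last <- max(tr$fluor_yfp[tr$cell_id == div$cell_id])
  kids_first <- sum(vapply(kids, function(k) {
    rows <- tr[tr$cell_id == k, ]
    rows$fluor_yfp[which.min(rows$frame)]
  }, numeric(1)))
  # daughters together carry the parent's signal forward (modulo the
  # production and bleaching accrued in the partial frame interval)
  expect_equal(kids_first, parent_last, tolerance = 0.1 * parent_last)
})

test_that("generate_dataset is reproducible and validates its config", {
  cfg <- noiseless_config(n_founders = 2, seed = 17)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$traces, d2$traces)
  expect_true(all(d1$truth$activation_time > 0))
  expect_error(sim_config(n_founders = 0), "n_founders")
})

test_that("written datasets round-trip through the trace reader", {
  cfg <- noiseless_config(n_founders = 2, seed = 18, post = 6)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_trace_table(file.path(dir, "traces.tsv"))
  expect_equal(back$fluor_yfp, ds$traces$fluor_yfp, tolerance = 1e-9)
  expect_equal(nrow(back), nrow(ds$traces))
})
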