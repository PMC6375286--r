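test_that("trace tables round-trip through write/read", {
  ds <- generate_dataset(noiseless_config(n_founders = 2, seed = 41,
                                          post = 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace_table(ds$traces, path)
  back <- read_trace_table(path)
  expect_equal(back$area, ds$traces$area, tolerance = 1e-9)
  expect_identical(back$cell_id, ds$traces$cell_id)
})

test_that("unknown extra columns are preserved with a warning", {
  tab <- toy_tree_table()
  tab$weird <- seq_len(nrow(tab))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace_table(tab, path)
  expect_warning(back <- read_trace_table(path), "weird")
  expect_identical(back$weird, tab$weird)
})

test_that("structural invariants are enforced with named offenders", {
  tab <- toy_tree_table()
  bad <- tab; bad$parent_id[bad$cell_id == 4] <- 99
  expect_error(validate_trace_table(bad), "absent parent 99")
  bad <- tab; bad$time_h[2] <- bad$time_h[1]
  expect_error(validate_trace_table(bad), "strictly increasing")
  bad <- tab; bad$area[3] <- -1
  expect_error(validate_trace_table(bad), "area")
  bad <- tab[, setdiff(names(tab), "time_h")]
  expect_error(validate_trace_table(bad), "time_h")
})

test_that("expression correction follows total/area - background - autofluorescence", {
  tab <- data.frame(colony_id = 1, cell_id = 1, parent_id = NA,
                    frame = 0:2, time_h = c(-1, 0, 1), area = 100,
                    fluor_yfp = 1000, bg_yfp = 2)
  expr <- compute_expression(tab, preprocess_config(),
                             autofluorescence = list(yfp = 3))
  expect_equal(expr$expr_yfp, rep(1000 / 100 - 2 - 3, 3))
})

test_that("per-timepoint autofluorescence subtracts the control series", {
  tab <- data.frame(colony_id = 1, cell_id = 1, parent_id = NA,
                    frame = 0:2, time_h = c(-1, 0, 1), area = 1,
                    fluor_yfp = 10, bg_yfp = 0)
  ctrl <- data.frame(frame = 0:2, value = c(3, 4, 5))
  expr <- compute_expression(
    tab, preprocess_config(autofluorescence_mode = "per_timepoint"),
    autofluorescence = list(yfp = ctrl))
  expect_equal(expr$expr_yfp, c(7, 6, 5))
  ctrl_short <- ctrl[1:2, ]
  expect_error(compute_expression(
    tab, preprocess_config(autofluorescence_mode = "per_timepoint"),
    autofluorescence = list(yfp = ctrl_short)), "cover frame")
})

test_that("negative corrected expression is retained, not clamped", {
  tab <- data.frame(colony_id = 1, cell_id = 1, parent_id = NA,
                    frame = 0:1, time_h = c(-1, 0), area = 10,
                    fluor_yfp = c(10, 6), bg_yfp = 1)
  expr <- compute_expression(tab, autofluorescence = list(yfp = 0.4))
  expect_equal(expr$expr_yfp[2], 6 / 10 - 1 - 0.4)
  expect_lt(expr$expr_yfp[2], 0)
})

test_that("expression correction is linear in the fluorescence scale", {
  ds <- generate_dataset(noiseless_config(n_founders = 1, seed = 43,
                                          post = 6))
  tab <- ds$traces
  scaled <- tab
  scaled$fluor_yfp <- 3 * scaled$fluor_yfp
  scaled$bg_yfp <- 3 * scaled$bg_yfp
  e1 <- compute_expression(tab)
  e2 <- compute_expression(scaled)
  expect_equal(e2$expr_yfp, 3 * e1$expr_yfp, tolerance = 1e-12)
})

test_that("normalization modes behave as documented", {
  tab <- data.frame(colony_id = 1, cell_id = rep(1:2, each = 3),
                    parent_id = NA, frame = rep(0:2, 2),
                    time_h = rep(c(-1, 0, 1), 2), area = 1,
                    fluor_yfp = c(0, 5, 10, 0, 10, 20), bg_yfp = 0)
  expr <- compute_expression(tab)
  own <- normalize_traces(expr, "own_max")
  expect_equal(own$expr_yfp[1:3], c(0, 0.5, 1))
  med <- normalize_traces(expr, "median_full_response")
  # cell-to-cell ratios preserved under the common colony scale
  expect_equal(med$expr_yfp[4:6] / med$expr_yfp[5],
               expr$expr_yfp[4:6] / expr$expr_yfp[5])
  flat <- expr; flat$expr_yfp <- 1
  expect_error(normalize_traces(flat, "median_full_response"), "zero")
})

test_that("growth-rate series recovers exponential growth exactly", {
  t <- seq(0, 5, by = 0.3)
  expect_equal(growth_rate_series(exp(0.5 * t), t),
               rep(0.5, length(t) - 1), tolerance = 1e-12)
  expect_equal(growth_rate_series(rep(2, 5), 1:5), rep(0, 4))
  raw <- growth_rate_series(c(1, 2, 8), c(0, 1, 2), window = 1)
  expect_equal(raw, c(log(2), log(4)))
  expect_error(growth_rate_series(c(1, -1), 1:2), "positive")
  expect_error(growth_rate_series(1, 1), "2 frames")
})

test_that("doubling series is continuous across divisions and anchored at zero", {
  # noiseless trajectory through two divisions, doubling time 2 h
  g <- log(2) / 2
  cfg <- sim_config(n_founders = 1, growth_rate_mean = g,
                    growth_rate_sd = 0, division_size_sd = 0,
                    frame_interval = 0.25, pre_stress_duration = 1,
                    post_stress_duration = 6, seed = 3)
  tree <- simulate_lineage(cfg)
  # follow first-born daughters to a leaf
  path <- 1L
  repeat {
    kids <- tree$cells$cell_id[tree$cells$parent_id %in% path[length(path)]]
    if (length(kids) == 0) break
    path <- c(path, kids[1])
  }
  rows <- tree$frames[tree$frames$cell_id %in% path, ]
  rows <- rows[order(rows$time_h), ]
  db <- doubling_series(rows$area, rows$time_h,
                        new_cell = c(TRUE, diff(rows$cell_id) != 0))
  expect_equal(db$doublings, db$time_h / 2, tolerance = 0.02)
  expect_equal(db$doublings[db$time_h == 0], 0, tolerance = 1e-9)
  # continuity: no jump larger than one frame's growth
  expect_lt(max(abs(diff(db$doublings))), 1.5 * 0.25 / 2)
  # integrates consistently with the growth-rate series
  gr <- growth_rate_series(rows$area, rows$time_h, window = 1)
  gr <- gr[abs(gr) < 1]  # drop the division discontinuities
  expect_equal(mean(gr) / log(2), 0.5, tolerance = 0.01)
})

test_that("population averaging bounds and degenerate cases", {
  x <- c(0, 2, 4, 8)
  out <- population_average(list(x, (x - min(x)) / (max(x) - min(x))))
  expect_equal(out$sd, rep(0, 4))
  expect_equal(out$mean, (x - min(x)) / 8)
  many <- population_average(replicate(7, cumsum(runif(10)),
                                       simplify = FALSE))
  expect_true(all(many$mean >= 0 & many$mean <= 1))
  expect_error(population_average(list(1:3, 1:4)), "common time grid")
  expect_error(population_average(list(rep(1, 3))), "constant")
})
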