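## Response-time extraction.
##
## A "trajectory" is a root-to-leaf path through the lineage tree: the
## expression history of one cell in the final frame, traced back through
## its ancestors. Response times are measured per trajectory, either against
## a colony-wide threshold (25% of the median full response among >3-fold
## responders) or against each trajectory's own half-maximum.

#' Response-time measurement configuration
#'
#' @param threshold_fraction fraction of the colony median trace's post-stress
#'   range defining the threshold; default 0.25.
#' @param responder_fold minimum fold change (max post-stress expression over
#'   pre-stress baseline) to count as a responder; default 3.
#' @param baseline_floor floor `eps` applied to the pre-stress baseline
#'   before computing fold change, preventing division by near-zero baselines
#'   after autofluorescence subtraction. Default 1.
#' @param interpolation `"linear"` (sub-frame crossing time by linear
#'   interpolation) or `"frame"` (time of the first frame at/above
#'   threshold).
#' @param time_axis `"hours"` or `"doublings"` (response times re-expressed
#'   as cumulative cell doublings via [doubling_series()]).
#' @return an object of class `"response_config"`.
#' @export
response_config <- function(threshold_fraction = 0.25, responder_fold = 3,
                            baseline_floor = 1,
                            interpolation = c("linear", "frame"),
                            time_axis = c("hours", "doublings")) {
  if (!is_number(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    fail("threshold_fraction must be in (0, 1)")
  if (!is_number(responder_fold) || responder_fold <= 1)
    fail("responder_fold must be > 1")
  if (!is_number(baseline_floor) || baseline_floor <= 0)
    fail("baseline_floor must be > 0")
  structure(list(threshold_fraction = threshold_fraction,
                 responder_fold = responder_fold,
                 baseline_floor = baseline_floor,
                 interpolation = match.arg(interpolation),
                 time_axis = match.arg(time_axis)),
            class = "response_config")
}

#' Extract root-to-leaf trajectories from a trace table
#'
#' @param table a trace table (or [compute_expression()] result) with lineage
#'   columns.
#' @return data.frame with one row per trajectory: `colony_id`,
#'   `trajectory_id` (the leaf cell), `founder_id` (the path cell alive at
#'   stress addition, NA if the path does not span time zero), and `path`
#'   (list column of cell ids from root to leaf).
#' @export
trajectories <- function(table) {
  first <- table[!duplicated(table$cell_id), ]
  parent_of <- stats::setNames(first$parent_id, first$cell_id)
  tmin <- tapply(table$time_h, table$cell_id, min)
  tmax <- tapply(table$time_h, table$cell_id, max)
  leaves <- setdiff(first$cell_id, first$parent_id[!is.na(first$parent_id)])
  paths <- lapply(leaves, function(leaf) {
    path <- leaf
    while (!is.na(parent_of[[as.character(path[1])]]))
      path <- c(parent_of[[as.character(path[1])]], path)
    path
  })
  ## founder: the path cell whose frames span stress addition; if time zero
  ## falls between two cells' frames, take the earlier post-stress cell
  founders <- vapply(paths, function(path) {
    ids <- as.character(path)
    span <- tmin[ids] <= 0 & tmax[ids] >= 0
    if (any(span)) return(path[which(span)[1]])
    post <- tmin[ids] > 0
    if (any(post) && !all(post)) path[which(post)[1]] else NA
  }, numeric(1))
  out <- data.frame(
    colony_id = first$colony_id[match(leaves, first$cell_id)],
    trajectory_id = leaves, founder_id = founders)
  out$path <- paths
  out
}

## Internal: expression time series of one trajectory (concatenated path).
trajectory_trace <- function(traces, path, channel) {
  rows <- traces[traces$cell_id %in% path, ]
  rows <- rows[order(rows$time_h), ]
  data.frame(time_h = rows$time_h, value = rows[[paste0("expr_", channel)]])
}

#' Classify responder trajectories
#'
#' A trajectory responds if its maximum post-stress expression exceeds
#' `responder_fold` times its pre-stress baseline (mean expression before
#' stress addition, floored at `baseline_floor`).
#'
#' @param traj_traces list of trajectory traces (data.frames with `time_h`,
#'   `value`), each with at least one pre-stress frame.
#' @param config a [response_config()].
#' @return list with `responder` (logical vector) and `fraction`.
#' @export
find_responders <- function(traj_traces, config = response_config()) {
  responder <- vapply(traj_traces, function(tr) {
    pre <- tr$value[tr$time_h < 0]
    if (length(pre) == 0) fail("trajectory has no pre-stress frames")
    baseline <- max(mean(pre), config$baseline_floor)
    post <- tr$value[tr$time_h >= 0]
    max(post) / baseline > config$responder_fold
  }, logical(1))
  list(responder = responder, fraction = mean(responder))
}

#' Colony-wide response threshold
#'
#' The threshold is defined on the pointwise median over all responder
#' trajectories, restricted to post-stress frames: threshold = median-trace
#' minimum + `threshold_fraction` x (median-trace maximum - minimum), i.e.
#' 25% of the median full response by default.
#'
#' @param traj_traces list of responder trajectory traces.
#' @param config a [response_config()].
#' @return the threshold (expression units).
#' @export
colony_threshold <- function(traj_traces, config = response_config()) {
  if (length(traj_traces) < 1) fail("no responder trajectories")
  post <- lapply(traj_traces, function(tr) tr[tr$time_h >= 0, ])
  med <- tapply(unlist(lapply(post, `[[`, "value")),
                unlist(lapply(post, `[[`, "time_h")),
                stats::median)
  rng <- max(med) - min(med)
  if (!is.finite(rng) || rng == 0)
    fail("median trace over responders has zero range")
  unname(min(med) + config$threshold_fraction * rng)
}

#' First upward threshold crossing of a trajectory
#'
#' Scans the post-stress part of the trace for the first frame at or above
#' the threshold. In `"linear"` mode the crossing time is interpolated
#' between the bracketing frames (a value exactly at threshold returns that
#' frame's time); `"frame"` mode returns the first frame's time directly.
#' Trajectories that never reach the threshold return `NA` and are flagged
#' as non-responders downstream.
#'
#' @param trace data.frame with `time_h`, `value`.
#' @param threshold threshold expression level.
#' @param config a [response_config()].
#' @return crossing time in hours after stress addition, or `NA`.
#' @export
detect_response_time <- function(trace, threshold,
                                 config = response_config()) {
  post <- trace[trace$time_h >= 0, ]
  if (nrow(post) == 0) fail("trajectory has no post-stress frames")
  hit <- which(post$value >= threshold)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (config$interpolation == "frame" || i == 1L ||
      post$value[i] == threshold)
    return(post$time_h[i])
  t0 <- post$time_h[i - 1]; t1 <- post$time_h[i]
  v0 <- post$value[i - 1]; v1 <- post$value[i]
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Per-trajectory half-maximum response time
#'
#' The alternative response-time measure: the first crossing of half of the
#' trajectory's own maximum expression, using the same interpolation
#' contract as [detect_response_time()].
#'
#' @param trace data.frame with `time_h`, `value`.
#' @param config a [response_config()].
#' @return crossing time in hours, or `NA` if the maximum is reached at the
#'   first post-stress frame.
#' @export
halfmax_response_time <- function(trace, config = response_config()) {
  post <- trace[trace$time_h >= 0, ]
  if (nrow(post) == 0) fail("trajectory has no post-stress frames")
  mx <- max(post$value)
  if (!is.finite(mx) || mx <= 0)
    fail("trajectory maximum is non-positive; half-max undefined")
  detect_response_time(trace, mx / 2, config)
}

#' Compute response times for every trajectory in a trace table
#'
#' Runs the full per-colony measurement: trajectory extraction, responder
#' classification (>`responder_fold` change), colony threshold (25% of the
#' median full response among responders) and first-crossing detection — or
#' the per-trajectory half-maximum measure. With `time_axis = "doublings"`
#' crossing times are converted to cumulative cell doublings on each
#' trajectory's own doubling curve.
#'
#' @param traces an [compute_expression()] result.
#' @param config a [response_config()].
#' @param measure `"threshold"` (colony threshold) or `"halfmax"`.
#' @return a `"response_time_set"` data.frame: one row per trajectory per
#'   channel with `colony_id`, `founder_id`, `trajectory_id`, `channel`,
#'   `measure`, `response_time`, `responded` (0/1), `threshold_used`;
#'   per-colony responder fractions in `attr(, "responder_fraction")`.
#' @export
compute_response_times <- function(traces, config = response_config(),
                                   measure = c("threshold", "halfmax")) {
  measure <- match.arg(measure)
  channels <- attr(traces, "channels")
  if (is.null(channels)) channels <- trace_channels_expr(traces)
  traj <- trajectories(traces)
  ## per-cell trace cache so trajectory assembly is a concatenation, not a
  ## table scan (microcolonies can hold thousands of trajectories)
  ord <- order(traces$cell_id, traces$time_h)
  cache_time <- split(traces$time_h[ord], traces$cell_id[ord])
  cache_val <- lapply(channels, function(ch)
    split(traces[[paste0("expr_", ch)]][ord], traces$cell_id[ord]))
  names(cache_val) <- channels
  assemble <- function(path, ch) {
    ids <- as.character(path)
    data.frame(time_h = unlist(cache_time[ids], use.names = FALSE),
               value = unlist(cache_val[[ch]][ids], use.names = FALSE))
  }
  res <- list(); frac <- list()
  for (col_id in unique(traj$colony_id)) {
    tsub <- traj[traj$colony_id == col_id, ]
    for (ch in channels) {
      trs <- lapply(tsub$path, assemble, ch = ch)
      resp <- find_responders(trs, config)
      thr <- NA_real_
      if (measure == "threshold") {
        if (!any(resp$responder))
          fail("colony %s channel %s has no responders", col_id, ch)
        thr <- colony_threshold(trs[resp$responder], config)
        rt <- vapply(seq_along(trs), function(i) {
          if (!resp$responder[i]) return(NA_real_)
          detect_response_time(trs[[i]], thr, config)
        }, numeric(1))
      } else {
        rt <- vapply(seq_along(trs), function(i) {
          if (!resp$responder[i]) return(NA_real_)
          halfmax_response_time(trs[[i]], config)
        }, numeric(1))
      }
      if (config$time_axis == "doublings")
        rt <- vapply(seq_along(rt), function(i) {
          if (is.na(rt[i])) return(NA_real_)
          to_doublings(traces, tsub$path[[i]], rt[i])
        }, numeric(1))
      res[[length(res) + 1L]] <- data.frame(
        colony_id = col_id, founder_id = tsub$founder_id,
        trajectory_id = tsub$trajectory_id, channel = ch, measure = measure,
        response_time = rt, responded = as.integer(!is.na(rt)),
        threshold_used = thr)
      frac[[length(frac) + 1L]] <- data.frame(
        colony_id = col_id, channel = ch,
        responder_fraction = mean(!is.na(rt)))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, responder_fraction = do.call(rbind, frac),
            config = config,
            class = c("response_time_set", "data.frame"))
}

## Channels of an expression table when the attribute got dropped.
trace_channels_expr <- function(traces) {
  sub("^expr_", "", grep("^expr_", names(traces), value = TRUE))
}

## Convert an hours response time to cumulative doublings on a trajectory.
to_doublings <- function(traces, path, t_hours) {
  rows <- traces[traces$cell_id %in% path, ]
  rows <- rows[order(rows$time_h), ]
  db <- doubling_series(rows$area, rows$time_h,
                        new_cell = c(TRUE, diff(match(rows$cell_id,
                                                      path)) != 0))
  stats::approx(db$time_h, db$doublings, xout = t_hours, rule = 2)$y
}

#' Write a response-time set as TSV
#'
#' @param rts a [compute_response_times()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_response_times <- function(rts, path) {
  utils::write.table(as.data.frame(rts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
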