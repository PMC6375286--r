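## Reading, validating and writing tracked single-cell trace tables.
##
## The on-disk format mirrors what segmentation/tracking tools (SchnitzCells
## and kin) export after tabulation: one row per cell per frame with lineage
## links, total fluorescence per channel and total area, tab-separated.

trace_core_cols <- c("colony_id", "cell_id", "parent_id", "frame", "time_h",
                     "area")

#' Channels present in a trace table
#'
#' @param table a trace table data.frame.
#' @return character vector of channel names (from `fluor_<ch>` columns).
#' @export
trace_channels <- function(table) {
  sub("^fluor_", "", grep("^fluor_", names(table), value = TRUE))
}

#' Validate a trace table
#'
#' Enforces the structural invariants of tracked microcolony data: required
#' columns present, areas positive, times strictly increasing within each
#' cell, every non-founder's parent present, and (where both have frames) the
#' parent's last frame immediately preceding the child's first.
#'
#' @param table a data.frame.
#' @return the table, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_trace_table <- function(table) {
  miss <- setdiff(trace_core_cols, names(table))
  if (length(miss) > 0)
    fail("trace table is missing required columns: %s",
         paste(miss, collapse = ", "))
  if (length(trace_channels(table)) == 0)
    fail("trace table has no fluor_<channel> columns")
  bad_area <- which(!is.finite(table$area) | table$area <= 0)
  if (length(bad_area) > 0)
    fail("non-positive or missing area at row %d (cell %s)",
         bad_area[1], table$cell_id[bad_area[1]])
  by_cell <- split(seq_len(nrow(table)), table$cell_id)
  for (rows in by_cell) {
    tt <- table$time_h[rows][order(table$frame[rows])]
    if (any(diff(tt) <= 0))
      fail("times not strictly increasing within cell %s (row %d)",
           table$cell_id[rows[1]], rows[which(diff(tt) <= 0)[1] + 1])
  }
  cell_ids <- unique(table$cell_id)
  pid <- table$parent_id[!duplicated(table$cell_id)]
  kid <- table$cell_id[!duplicated(table$cell_id)]
  orphan <- !is.na(pid) & !(pid %in% cell_ids)
  if (any(orphan))
    fail("cell %s references absent parent %s", kid[which(orphan)[1]],
         pid[which(orphan)[1]])
  ## frame continuity parent -> child
  first_frame <- tapply(table$frame, table$cell_id, min)
  last_frame <- tapply(table$frame, table$cell_id, max)
  for (i in which(!is.na(pid))) {
    p <- as.character(pid[i]); k <- as.character(kid[i])
    if (!is.na(last_frame[p]) && !is.na(first_frame[k]) &&
        first_frame[k] != last_frame[p] + 1L)
      fail("cell %s starts at frame %d but parent %s ends at frame %d",
           k, first_frame[k], p, last_frame[p])
  }
  invisible(table)
}

#' Read a trace table from a tab-separated file
#'
#' @param path path to a TSV file with the trace-table schema (`colony_id`,
#'   `cell_id`, `parent_id` (empty for founders), `frame`, `time_h`, `area`,
#'   `fluor_<channel>` totals, optional `bg_<channel>` per-pixel background).
#'   Unknown extra columns are preserved with a warning.
#' @param sep field separator, default tab.
#' @return a validated trace table data.frame.
#' @export
read_trace_table <- function(path, sep = "\t") {
  if (!file.exists(path)) fail("trace table not found: %s", path)
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  known <- c(trace_core_cols,
             grep("^(fluor|bg)_", names(tab), value = TRUE))
  extra <- setdiff(names(tab), known)
  if (length(extra) > 0)
    warning(sprintf("preserving unknown columns: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  if ("parent_id" %in% names(tab))
    tab$parent_id[tab$parent_id %in% c("", "NA")] <- NA
  validate_trace_table(tab)
  tab
}

#' Write a trace table to a tab-separated file
#'
#' @param table a trace table data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trace_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Preprocessing configuration
#'
#' @param background_mode `"per_frame"` (use the table's `bg_<ch>` column) or
#'   `"constant"` (subtract `background_value`).
#' @param background_value per-pixel background used in constant mode.
#' @param autofluorescence_mode `"constant"` or `"per_timepoint"`.
#' @param growth_window moving-average window (frames) for growth-rate
#'   smoothing; odd, default 3.
#' @param doubling_window moving-average window for the doubling series; odd,
#'   default 5.
#' @param extrapolation_points number of pre-division points used in the
#'   linear fit that bridges a division in the doubling series; default 3.
#' @return an object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(background_mode = c("per_frame", "constant"),
                              background_value = 0,
                              autofluorescence_mode = c("constant",
                                                        "per_timepoint"),
                              growth_window = 3L, doubling_window = 5L,
                              extrapolation_points = 3L) {
  background_mode <- match.arg(background_mode)
  autofluorescence_mode <- match.arg(autofluorescence_mode)
  for (w in c(growth_window, doubling_window))
    if (!is_count(w) || w %% 2 != 1)
      fail("smoothing windows must be odd integers >= 1")
  if (!is_count(extrapolation_points) || extrapolation_points < 2)
    fail("extrapolation_points must be an integer >= 2")
  structure(list(background_mode = background_mode,
                 background_value = background_value,
                 autofluorescence_mode = autofluorescence_mode,
                 growth_window = as.integer(growth_window),
                 doubling_window = as.integer(doubling_window),
                 extrapolation_points = as.integer(extrapolation_points)),
            class = "preprocess_config")
}

#' Compute corrected expression traces from raw totals
#'
#' Expression is the per-area fluorescence after background and
#' autofluorescence subtraction:
#' `expr = total / area - background_per_pixel - autofluorescence`.
#' Background comes from the table's per-frame `bg_<ch>` column or a
#' constant; autofluorescence is either a constant per channel or a
#' per-timepoint control series (the mean expression of cells devoid of that
#' fluorophore, imaged in the same experiment). Values may be negative after
#' subtraction and are deliberately not clamped, since clamping would bias
#' threshold crossings near zero.
#'
#' @param table a validated trace table.
#' @param config a [preprocess_config()].
#' @param autofluorescence named list per channel: a single number (constant
#'   mode) or a data.frame with columns `frame`, `value` covering every frame
#'   in the table (per-timepoint mode). Channels omitted default to 0.
#' @return an `"expression_traces"` data.frame: `colony_id`, `cell_id`,
#'   `parent_id`, `frame`, `time_h`, `area` plus one `expr_<ch>` column per
#'   channel; correction metadata in attributes.
#' @export
compute_expression <- function(table, config = preprocess_config(),
                               autofluorescence = list()) {
  validate_trace_table(table)
  channels <- trace_channels(table)
  out <- table[, trace_core_cols]
  for (ch in channels) {
    bg <- if (config$background_mode == "per_frame") {
      col <- paste0("bg_", ch)
      if (!col %in% names(table))
        fail("per_frame background requested but column %s is absent", col)
      table[[col]]
    } else config$background_value
    expr <- table[[paste0("fluor_", ch)]] / table$area - bg
    af <- autofluorescence[[ch]]
    if (is.null(af)) af <- 0
    if (config$autofluorescence_mode == "per_timepoint" &&
        is.data.frame(af)) {
      m <- match(table$frame, af$frame)
      if (anyNA(m))
        fail("autofluorescence control series for channel %s does not cover frame %s",
             ch, table$frame[which(is.na(m))[1]])
      af <- af$value[m]
    } else if (is.data.frame(af)) {
      fail("data.frame autofluorescence given for channel %s but mode is constant",
           ch)
    }
    out[[paste0("expr_", ch)]] <- expr - af
  }
  structure(out, channels = channels, correction = config,
            class = c("expression_traces", "data.frame"))
}

#' Normalize expression traces
#'
#' `"median_full_response"` rescales every cell in a colony by the range of
#' the colony's pointwise-median trace (the "median full response"), so
#' relative cell-to-cell differences are preserved; `"own_max"` divides each
#' cell's trace by its own maximum.
#'
#' @param traces an [compute_expression()] result.
#' @param mode `"median_full_response"` or `"own_max"`.
#' @return the traces with `expr_<ch>` columns rescaled.
#' @export
normalize_traces <- function(traces, mode = c("median_full_response",
                                              "own_max")) {
  mode <- match.arg(mode)
  channels <- attr(traces, "channels")
  for (ch in channels) {
    col <- paste0("expr_", ch)
    if (mode == "own_max") {
      for (cid in unique(traces$cell_id)) {
        rows <- traces$cell_id == cid
        mx <- max(traces[[col]][rows])
        if (!is.finite(mx) || mx == 0)
          fail("cell %s has zero or non-finite maximum in channel %s",
               cid, ch)
        traces[[col]][rows] <- traces[[col]][rows] / mx
      }
    } else {
      for (col_id in unique(traces$colony_id)) {
        rows <- traces$colony_id == col_id
        med <- tapply(traces[[col]][rows], traces$frame[rows],
                      stats::median)
        rng <- max(med) - min(med)
        if (!is.finite(rng) || rng == 0)
          fail("colony %s has zero median-trace range in channel %s",
               col_id, ch)
        traces[[col]][rows] <- traces[[col]][rows] / rng
      }
    }
  }
  traces
}

#' Instantaneous single-cell growth-rate series
#'
#' The growth rate between consecutive frames is the difference of the
#' logarithmic cell sizes divided by the time interval, smoothed with a
#' centered moving average (window 3 by default, shrinking at the edges).
#'
#' @param sizes positive cell sizes (lengths or areas).
#' @param times frame times, strictly increasing, same length.
#' @param window odd moving-average window; 1 returns raw differences.
#' @return numeric vector of length `length(sizes) - 1`, growth rate per
#'   hour attached to the interval midpoints.
#' @export
growth_rate_series <- function(sizes, times, window = 3L) {
  if (length(sizes) < 2L) fail("need at least 2 frames")
  if (any(sizes <= 0)) fail("sizes must be positive")
  if (length(times) != length(sizes)) fail("sizes and times differ in length")
  raw <- diff(log(sizes)) / diff(times)
  moving_average(raw, window)
}

#' Cumulative cell doublings along a trajectory
#'
#' Converts the log2 cell size along a single root-to-leaf trajectory into a
#' continuous doubling count: at each division (where log2 size drops by
#' about one) the post-division values are shifted up so that the value just
#' after division matches a linear extrapolation through the last
#' `extrapolation_points` pre-division points. The continuous curve is then
#' shifted so that it is 0 at stress addition (time zero, interpolated) and
#' smoothed (window 5 by default).
#'
#' @param sizes,times per-frame sizes and times along the trajectory.
#' @param new_cell logical, `TRUE` at the first frame of each new cell after
#'   a division.
#' @param window odd moving-average window, default 5.
#' @param extrapolation_points pre-division points in the bridging fit,
#'   default 3.
#' @return data.frame with columns `time_h` and `doublings`.
#' @export
doubling_series <- function(sizes, times, new_cell, window = 5L,
                            extrapolation_points = 3L) {
  stopifnot(length(sizes) == length(times),
            length(new_cell) == length(times))
  if (any(sizes <= 0)) fail("sizes must be positive")
  lg <- log2(sizes)
  div_at <- which(new_cell)
  div_at <- div_at[div_at > 1L]  # a new cell at frame 1 is just the root
  offset <- 0
  out <- lg
  for (d in div_at) {
    if (d <= 2L)
      fail("division at frame %d leaves nothing to fit the extrapolation", d)
    k <- max(1L, d - extrapolation_points):(d - 1L)
    fit <- stats::lm.fit(cbind(1, times[k]), out[k])
    predicted <- sum(fit$coefficients * c(1, times[d]))
    jump <- predicted - (lg[d] + offset)
    offset <- offset + jump
    out[d:length(out)] <- lg[d:length(out)] + offset
  }
  ## anchor at stress addition (t = 0), interpolating on the continuous curve
  anchor <- stats::approx(times, out, xout = 0, rule = 2)$y
  out <- out - anchor
  data.frame(time_h = times, doublings = moving_average(out, window))
}

#' Average several normalized population-level traces
#'
#' Each trace is min-max normalized to `[0, 1]` and the pointwise mean and
#' standard deviation across traces are returned — the standard way to
#' summarize a regulon from the responses of its member promoters.
#'
#' @param traces list of numeric vectors on a common time grid.
#' @param times optional common time grid (returned alongside).
#' @return data.frame with columns `time_h` (if given), `mean`, `sd`.
#' @export
population_average <- function(traces, times = NULL) {
  if (!is.list(traces) || length(traces) < 1L)
    fail("traces must be a non-empty list")
  n <- unique(lengths(traces))
  if (length(n) != 1L) fail("traces are not on a common time grid")
  norm <- lapply(traces, function(x) {
    r <- max(x) - min(x)
    if (!is.finite(r) || r == 0) fail("constant trace cannot be normalized")
    (x - min(x)) / r
  })
  m <- do.call(cbind, norm)
  sds <- if (ncol(m) > 1L) apply(m, 1, stats::sd) else rep(0, nrow(m))
  out <- data.frame(mean = rowMeans(m), sd = sds)
  if (!is.null(times)) {
    if (length(times) != n) fail("times length does not match traces")
    out <- cbind(data.frame(time_h = times), out)
  }
  out
}
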