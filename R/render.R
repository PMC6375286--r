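## Rendering fluorescence traces from a lineage tree and latent activation
## times. The renderer emits exactly what segmentation/tracking software
## would tabulate: per cell per frame, the total fluorescence and the total
## area, plus the per-pixel environment background, so that the standard
## preprocessing (total/area minus background minus autofluorescence)
## recovers the underlying expression signal.

#' Render fluorescence trace tables from a lineage tree
#'
#' For each channel, mature fluorophore accumulates in a cell at the
#' reporter's `production_rate` starting at `activation + maturation_time`,
#' is attenuated by `(1 - bleach_per_frame)` at every imaging frame, and is
#' split between daughters in proportion to their birth sizes (equal halves)
#' at division. The emitted total per frame is
#' `mature amount + (autofluorescence + trend * t) * area + background * area
#' + Gaussian noise`, alongside the per-pixel `background` in a `bg_` column.
#'
#' @param tree a [simulate_lineage()] result.
#' @param activation data.frame from [assign_activation_times()].
#' @param reporters named list of [reporter_spec()]s (default from config).
#' @param seed integer seed for the measurement noise.
#' @return a trace table data.frame with columns `colony_id`, `cell_id`,
#'   `parent_id`, `frame`, `time_h`, `area`, and per channel `fluor_<ch>`,
#'   `bg_<ch>`.
#' @export
render_traces <- function(tree, activation,
                          reporters = tree$config$reporters,
                          seed = derive_seed(tree$config$seed, 2L)) {
  stopifnot(inherits(tree, "lineage_tree"), is.data.frame(activation))
  channels <- names(reporters)
  need <- paste0("t_act_", channels)
  if (!all(need %in% names(activation)))
    fail("activation table lacks columns: %s",
         paste(setdiff(need, names(activation)), collapse = ", "))
  local_seed(seed)

  cells <- tree$cells
  frames <- tree$frames
  ## children lookup for division partitioning
  kids <- split(cells$cell_id, factor(cells$parent_id,
                                      levels = cells$cell_id))
  frames_by_cell <- split(seq_len(nrow(frames)), frames$cell_id)

  out <- frames[, c("cell_id", "frame", "time_h", "area")]
  out$colony_id <- 1L
  pid <- cells$parent_id[match(frames$cell_id, cells$cell_id)]
  out$parent_id <- pid
  out <- out[, c("colony_id", "cell_id", "parent_id", "frame", "time_h",
                 "area")]

  act_row <- match(cells$cell_id, activation$cell_id)

  for (ch in channels) {
    rs <- reporters[[ch]]
    t_act <- activation[[paste0("t_act_", ch)]][act_row]
    t_on <- t_act + rs$maturation_time     # production start per cell lineage
    amount_at_birth <- rep(0, nrow(cells))
    fl <- numeric(nrow(frames))

    ## process in birth order so parents are finished before daughters
    for (i in order(cells$birth_time, cells$cell_id)) {
      a <- amount_at_birth[i]
      t_prev <- cells$birth_time[i]
      on_i <- t_on[i]
      rows <- frames_by_cell[[as.character(cells$cell_id[i])]]
      if (!is.null(rows)) {
        for (r in rows) {
          tk <- frames$time_h[r]
          a <- a + rs$production_rate * max(0, tk - max(t_prev, on_i))
          a <- a * (1 - rs$bleach_per_frame)
          fl[r] <- a
          t_prev <- tk
        }
      }
      d <- cells$division_time[i]
      if (!is.na(d)) {
        a <- a + rs$production_rate * max(0, d - max(t_prev, on_i))
        ch_ids <- kids[[as.character(cells$cell_id[i])]]
        if (length(ch_ids) > 0) {
          ci <- match(ch_ids, cells$cell_id)
          w <- cells$birth_size[ci] / sum(cells$birth_size[ci])
          amount_at_birth[ci] <- a * w
        }
      }
    }
    autofl <- (rs$autofluorescence +
                 rs$autofluorescence_trend * frames$time_h) * frames$area
    noise <- if (rs$noise_sd > 0)
      stats::rnorm(nrow(frames), 0, rs$noise_sd) else 0
    out[[paste0("fluor_", ch)]] <- fl + autofl +
      rs$background * frames$area + noise
    out[[paste0("bg_", ch)]] <- rs$background
  }
  out <- out[order(out$cell_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic microcolony dataset
#'
#' Composes [simulate_lineage()], [assign_activation_times()] and
#' [render_traces()] into a single seed-reproducible call, returning both the
#' rendered trace table and a ground-truth table of latent activation times
#' for recovery tests.
#'
#' @param config a [sim_config()].
#' @return list with elements `traces` (trace table), `truth` (data.frame:
#'   `cell_id`, `founder_id`, `channel`, `activation_time`, `n_steps`,
#'   `mean_time`), `tree`, and `activation`.
#' @examples
#' ds <- generate_dataset(sim_config(n_founders = 2, seed = 7))
#' head(ds$traces)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_lineage(config)
  activation <- assign_activation_times(tree)
  traces <- render_traces(tree, activation)
  channels <- names(config$reporters)
  chain_of <- function(ch_idx) {
    if (inherits(config$chain, "chain_spec")) config$chain
    else if (ch_idx == 1L) {
      if (config$chain$architecture == "serial") config$chain$shared
      else config$chain$independent_a
    } else {
      if (config$chain$architecture == "serial") config$chain$mid
      else config$chain$independent_b
    }
  }
  truth <- do.call(rbind, lapply(seq_along(channels), function(j) {
    keep <- is.finite(activation[[paste0("t_act_", channels[j])]])
    cs <- chain_of(j)
    data.frame(cell_id = activation$cell_id[keep],
               founder_id = activation$founder_id[keep],
               channel = channels[j],
               activation_time = activation[[paste0("t_act_",
                                                    channels[j])]][keep],
               n_steps = cs$n_steps, mean_time = cs$mean_time)
  }))
  rownames(truth) <- NULL
  list(traces = traces, truth = truth, tree = tree, activation = activation)
}

#' Write a synthetic dataset to tab-separated files
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written (`traces.tsv`, `ground_truth.tsv`).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "traces.tsv")
  p2 <- file.path(dir, "ground_truth.tsv")
  write_trace_table(dataset$traces, p1)
  utils::write.table(dataset$truth, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(traces = p1, ground_truth = p2))
}
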