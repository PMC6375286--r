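## End-to-end pipeline: simulate -> preprocess -> respond -> stats ->
## kinetics, driven by a flat YAML configuration. Every stage writes its
## artifact as TSV or JSON into the output directory together with a stamp
## (config hash + seed), and any contiguous subset of stages can be rerun:
## a stage reads the artifact of its predecessor from disk, so cached
## upstream artifacts are reused when their stamp matches.

pipeline_stages <- c("simulate", "preprocess", "respond", "stats", "kinetics")

#' Read a pipeline run configuration
#'
#' The configuration is a flat YAML file with optional blocks `simulate`
#' (fields of [sim_config()]; `chain` given as `n_steps`/`mean_time` or a
#' dual-chain block with `architecture` and per-chain fields), `preprocess`
#' ([preprocess_config()] fields), `respond` ([response_config()] fields plus
#' `measure`), and `stats` ([stats_config()] fields), plus a global `seed`.
#'
#' @param path YAML file path.
#' @return a named list with resolved config objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) fail("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  build_run_config(cfg)
}

## Turn a plain list (e.g. parsed YAML) into resolved config objects.
build_run_config <- function(cfg) {
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    chain <- parse_chain(sc$chain)
    reporters <- lapply(sc$reporters %||% list(yfp = list()), function(r)
      do.call(reporter_spec, r))
    args <- sc[setdiff(names(sc), c("chain", "reporters", "seed"))]
    sim <- do.call(sim_config, c(args, list(chain = chain,
                                            reporters = reporters,
                                            seed = derive_seed(seed, 1L))))
  }
  pre <- do.call(preprocess_config, cfg$preprocess %||% list())
  respond_cfg <- cfg$respond %||% list()
  measure <- respond_cfg$measure %||% "threshold"
  respond <- do.call(response_config,
                     respond_cfg[setdiff(names(respond_cfg), "measure")])
  stats_cfg <- do.call(stats_config,
                       c(cfg$stats %||% list(),
                         list(seed = derive_seed(seed, 2L))))
  kin <- cfg$kinetics %||% list()
  list(seed = seed, simulate = sim, preprocess = pre, respond = respond,
       measure = measure, stats = stats_cfg,
       ks_sims = as.integer(kin$n_sim %||% 1000L),
       ks_alpha = kin$alpha %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_chain <- function(ch) {
  if (is.null(ch)) return(chain_spec(8, 4))
  if (!is.null(ch$architecture)) {
    mk <- function(x) if (is.null(x)) NULL else
      chain_spec(x$n_steps, x$mean_time)
    dual_chain_spec(architecture = ch$architecture,
                    shared = mk(ch$shared), mid = mk(ch$mid),
                    independent_a = mk(ch$independent_a),
                    independent_b = mk(ch$independent_b),
                    reporter_a = mk(ch$reporter_a) %||% chain_spec(1, 0),
                    reporter_b = mk(ch$reporter_b) %||% chain_spec(1, 0))
  } else {
    chain_spec(ch$n_steps, ch$mean_time)
  }
}

## stamp = reproducibility marker written next to every artifact
write_stamp <- function(out_dir, stage, seed, params) {
  stamp <- list(stage = stage, seed = seed,
                params_hash = sum(utf8ToInt(paste(
                  deparse(params, control = "all"), collapse = ""))))
  jsonlite::write_json(stamp, file.path(out_dir,
                                        paste0(stage, ".stamp.json")),
                       auto_unbox = TRUE)
}

#' Run the analysis pipeline
#'
#' Executes a contiguous subset of the stages simulate, preprocess, respond,
#' stats, kinetics. Each stage reads its input artifact from `out_dir`
#' (written by the preceding stage or a previous run) and writes its result
#' there: `traces.tsv` / `ground_truth.tsv`, `expression.tsv`,
#' `response_times.tsv`, `timing_summary.tsv` / `pair_report.json`,
#' `kinetics.json`. All randomness is derived from the config's global seed.
#'
#' @param config a configuration list from [read_run_config()], a YAML path,
#'   or a plain list with the same structure.
#' @param out_dir output directory.
#' @param stages character vector of stages to run (contiguous subset of
#'   `simulate`, `preprocess`, `respond`, `stats`, `kinetics`).
#' @param traces optional path to an existing trace table, used instead of
#'   `out_dir/traces.tsv` when the simulate stage is skipped.
#' @return invisibly, a list of the artifacts produced.
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stages,
                         traces = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  if (!all(stages %in% pipeline_stages))
    fail("unknown stage(s): %s; known stages are %s",
         paste(setdiff(stages, pipeline_stages), collapse = ", "),
         paste(pipeline_stages, collapse = ", "))
  idx <- sort(match(stages, pipeline_stages))
  if (length(idx) > 1 && any(diff(idx) != 1L))
    fail("stages must form a contiguous subset of the pipeline")
  stages <- pipeline_stages[idx]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  message(sprintf("pipeline: stages [%s], seed %d, out %s",
                  paste(stages, collapse = ", "), config$seed, out_dir))

  if ("simulate" %in% stages) {
    if (is.null(config$simulate))
      fail("simulate stage requested but no simulate block in config")
    ds <- generate_dataset(config$simulate)
    write_dataset(ds, out_dir)
    write_stamp(out_dir, "simulate", config$seed,
                config$simulate[setdiff(names(config$simulate), "chain")])
    artifacts$traces <- file.path(out_dir, "traces.tsv")
  }

  if ("preprocess" %in% stages) {
    tr_path <- artifacts$traces %||% traces %||%
      file.path(out_dir, "traces.tsv")
    if (!file.exists(tr_path))
      fail("preprocess stage needs a trace table; missing artifact: %s",
           tr_path)
    tab <- read_trace_table(tr_path)
    expr <- compute_expression(tab, config$preprocess)
    utils::write.table(as.data.frame(expr),
                       file.path(out_dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_stamp(out_dir, "preprocess", config$seed, config$preprocess)
    artifacts$expression <- file.path(out_dir, "expression.tsv")
  }

  if ("respond" %in% stages) {
    ep <- artifacts$expression %||% file.path(out_dir, "expression.tsv")
    if (!file.exists(ep))
      fail("respond stage needs expression traces; missing artifact: %s", ep)
    expr <- utils::read.delim(ep, stringsAsFactors = FALSE)
    expr$parent_id[expr$parent_id %in% c("", "NA")] <- NA
    class(expr) <- c("expression_traces", "data.frame")
    attr(expr, "channels") <- trace_channels_expr(expr)
    rts <- compute_response_times(expr, config$respond,
                                  measure = config$measure)
    write_response_times(rts, file.path(out_dir, "response_times.tsv"))
    write_stamp(out_dir, "respond", config$seed, config$respond)
    artifacts$response_times <- file.path(out_dir, "response_times.tsv")
  }

  if ("stats" %in% stages) {
    rp <- artifacts$response_times %||%
      file.path(out_dir, "response_times.tsv")
    ep <- artifacts$expression %||% file.path(out_dir, "expression.tsv")
    for (p in c(rp, ep)) if (!file.exists(p))
      fail("stats stage needs %s; missing artifact", p)
    rts <- utils::read.delim(rp, stringsAsFactors = FALSE)
    expr <- utils::read.delim(ep, stringsAsFactors = FALSE)
    samples <- subsample_trajectories(expr, rts, config$stats)
    sums <- lapply(names(samples$times), function(ch)
      timing_summary(samples, channel = ch))
    names(sums) <- names(samples$times)
    sum_df <- do.call(rbind, lapply(names(sums), function(ch) {
      s <- sums[[ch]]
      data.frame(channel = ch, mu_t = s$mu_t, sigma_t = s$sigma_t,
                 se_mu = s$se_mu, se_sigma = s$se_sigma,
                 n_founders = s$n_founders,
                 responder_fraction = s$responder_fraction)
    }))
    utils::write.table(sum_df, file.path(out_dir, "timing_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts$timing_summary <- file.path(out_dir, "timing_summary.tsv")
    if (length(samples$times) == 2L) {
      pc <- paired_correlation(samples, config$stats)
      so <- strict_order_test(samples, config$stats)
      jsonlite::write_json(list(r_mean = pc$r_mean, r_sd = pc$r_sd,
                                p_median = pc$p_median,
                                order_statistic = so$order_statistic,
                                n_pairs = so$n_pairs,
                                permutation_P = so$permutation_P),
                           file.path(out_dir, "pair_report.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts$pair_report <- file.path(out_dir, "pair_report.json")
    }
    write_stamp(out_dir, "stats", config$seed, config$stats)
  }

  if ("kinetics" %in% stages) {
    sp <- artifacts$timing_summary %||%
      file.path(out_dir, "timing_summary.tsv")
    rp <- artifacts$response_times %||%
      file.path(out_dir, "response_times.tsv")
    for (p in c(sp, rp)) if (!file.exists(p))
      fail("kinetics stage needs %s; missing artifact", p)
    sum_df <- utils::read.delim(sp, stringsAsFactors = FALSE)
    rts <- utils::read.delim(rp, stringsAsFactors = FALSE)
    reports <- lapply(seq_len(nrow(sum_df)), function(i) {
      ch <- sum_df$channel[i]
      times <- rts$response_time[rts$channel == ch & rts$responded == 1]
      est <- randomness_and_steps(sum_df$mu_t[i], sum_df$sigma_t[i])
      fit <- fit_erlang(times)
      ks <- ks_consistency(times, fit, n_sim = config$ks_sims,
                           alpha = config$ks_alpha,
                           seed = derive_seed(config$seed, 3L))
      list(channel = ch, mu_t = sum_df$mu_t[i], sigma_t = sum_df$sigma_t[i],
           ratio = est$ratio, R = est$R, n_steps = est$n_steps,
           erlang_shape = fit$shape, erlang_scale = fit$scale,
           ks_consistency = ks$fraction)
    })
    jsonlite::write_json(reports, file.path(out_dir, "kinetics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_stamp(out_dir, "kinetics", config$seed,
                list(config$ks_sims, config$ks_alpha))
    artifacts$kinetics <- file.path(out_dir, "kinetics.json")
  }
  invisible(artifacts)
}
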