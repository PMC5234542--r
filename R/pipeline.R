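#' Pipeline run configuration
#'
#' Collects every knob of the AFLP analysis (binning, calling, filtering,
#' network) plus input/output locations into one object. A YAML file with
#' the same nested keys can be loaded with [read_run_config()].
#'
#' @param peaks Path to a long-format peak CSV (ignored when `simulate` is
#'   given).
#' @param replicates Path to a replicate-map CSV (ignored when `simulate`
#'   is given).
#' @param simulate Optional [aflp_sim_config()]; when present the pipeline
#'   generates its input instead of reading files.
#' @param out_dir Output directory.
#' @param binning A [binning_config()].
#' @param thresholds A [call_thresholds()].
#' @param run_full Build the all-polymorphisms network variant.
#' @param run_reduced Build the reproducible-only (error-filtered) variant.
#' @param k_groups Number of genotype groups to delineate.
#' @param seed Integer seed recorded in the manifest.
#' @return A `run_config`.
#' @export
run_config <- function(peaks = NULL, replicates = NULL, simulate = NULL,
                       out_dir = "aflp-run", binning = binning_config(),
                       thresholds = call_thresholds(), run_full = TRUE,
                       run_reduced = TRUE, k_groups = 3L, seed = 1L) {
  stopifnot(is.null(simulate) || inherits(simulate, "aflp_sim_config"))
  structure(list(peaks = peaks, replicates = replicates, simulate = simulate,
                 out_dir = out_dir, binning = binning,
                 thresholds = thresholds, run_full = isTRUE(run_full),
                 run_reduced = isTRUE(run_reduced),
                 k_groups = as.integer(k_groups), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `binning`, `thresholds` and
#' `simulate` are nested maps passed to their constructors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (k in intersect(names(y), c("peaks", "replicates", "out_dir",
                                  "run_full", "run_reduced"))) {
    cfg[[k]] <- y[[k]]
  }
  if (!is.null(y$k_groups)) cfg$k_groups <- as.integer(y$k_groups)
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  if (!is.null(y$binning)) cfg$binning <- do.call(binning_config, y$binning)
  if (!is.null(y$thresholds)) {
    cfg$thresholds <- do.call(call_thresholds, y$thresholds)
  }
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$dropout_band)) sim$dropout_band <- unlist(sim$dropout_band)
    cfg$simulate <- do.call(aflp_sim_config, sim)
  }
  cfg
}

.stage <- function(log, name, expr) {
  cat(sprintf("[%s] stage %s: start\n", format(Sys.time(), "%H:%M:%S"), name),
      file = log, append = TRUE)
  res <- tryCatch(expr, error = function(e) {
    cat(sprintf("[%s] stage %s: FAILED (%s)\n",
                format(Sys.time(), "%H:%M:%S"), name, conditionMessage(e)),
        file = log, append = TRUE)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  cat(sprintf("[%s] stage %s: done\n", format(Sys.time(), "%H:%M:%S"), name),
      file = log, append = TRUE)
  res
}

#' Run the full AFLP delimitation pipeline
#'
#' Executes, in fixed order: input (read or simulate) -> raw-peak filter ->
#' per-channel binning -> normalisation and three-state calling ->
#' replicate error rates -> two-step error filter -> p-distances,
#' NeighborNet split network and group delineation for the full and/or
#' reduced matrices. All intermediate artifacts, a filter trace, a
#' machine-readable report (JSON) and a reproducibility manifest are
#' written under `cfg$out_dir`; partial outputs are retained on failure.
#'
#' @param cfg A [run_config()].
#' @return The run report, invisibly: a list with per-stage summaries
#'   (bin/fragment counts, error-rate range, filter trace sizes, group
#'   assignments, network fit).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(cfg$out_dir, "pipeline.log")
  cat("", file = log)
  report <- list(schema = "aflp-delimit-report/1", seed = cfg$seed)

  input <- .stage(log, "peak_io", {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_aflp(cfg$simulate)
      write_simulated(sim, file.path(cfg$out_dir, "simulated"))
      list(peaks = sim$peaks, reps = sim$replicates)
    } else {
      if (is.null(cfg$peaks) || !file.exists(cfg$peaks)) {
        stop("peaks file not found: ", if (is.null(cfg$peaks)) "<unset>"
             else cfg$peaks)
      }
      list(peaks = read_peak_table(cfg$peaks),
           reps = read_replicate_map(cfg$replicates))
    }
  })

  binned <- .stage(log, "binning", {
    kept <- filter_raw_peaks(input$peaks, cfg$binning)
    bn <- bin_channels(kept, cfg$binning, samples = input$reps$sample)
    for (ch in names(bn)) {
      write_binned_matrix(bn[[ch]],
                          file.path(cfg$out_dir,
                                    sprintf("binned_%s.csv", ch)))
    }
    report$peaks_in <- nrow(input$peaks)
    report$peaks_kept <- nrow(kept)
    report$bins_per_channel <- vapply(bn, ncol, integer(1))
    bn
  })

  calls <- .stage(log, "scoring", {
    cm <- score_channels(binned, cfg$thresholds)
    write_call_matrix(cm, file.path(cfg$out_dir, "calls_full.csv"))
    write_call_nexus(cm, file.path(cfg$out_dir, "calls_full.nex"))
    report$fragments_total <- ncol(cm)
    cm
  })

  qc <- .stage(log, "replicate_qc", {
    er <- replicate_difference_rates(calls, input$reps)
    utils::write.csv(as.data.frame(er),
                     file.path(cfg$out_dir, "replicate_error.csv"),
                     row.names = FALSE, quote = FALSE)
    filt <- error_filter(calls, input$reps)
    write_filter_trace(filt$trace, file.path(cfg$out_dir, "filter_trace.csv"))
    write_call_matrix(filt$calls,
                      file.path(cfg$out_dir, "calls_reduced.csv"))
    er_post <- replicate_difference_rates(filt$calls, input$reps)
    report$replicate_error_range <- as.numeric(attr(er, "range"))
    report$replicate_error_range_reduced <- as.numeric(attr(er_post, "range"))
    report$bins_step1_removed <- length(filt$trace$step1_removed)
    report$bins_step2_removed <- length(filt$trace$step2_removed)
    report$bins_retained <- length(filt$trace$retained)
    list(error = er, filtered = filt)
  })

  variants <- list()
  if (cfg$run_full) variants$full <- calls
  if (cfg$run_reduced) variants$reduced <- qc$filtered$calls
  report$networks <- list()
  for (v in names(variants)) {
    res <- .stage(log, paste0("network_", v), {
      pd <- p_distance_matrix(variants[[v]])
      write_phylip_dist(pd, file.path(cfg$out_dir,
                                      sprintf("pdist_%s.phy", v)))
      ss <- neighbor_net(pd)
      write_splits_nexus(ss, file.path(cfg$out_dir,
                                       sprintf("splits_%s.nex", v)))
      grp <- extract_groups(pd, k = cfg$k_groups)
      utils::write.csv(data.frame(sample = names(grp), group = as.integer(grp)),
                       file.path(cfg$out_dir, sprintf("groups_%s.csv", v)),
                       row.names = FALSE, quote = FALSE)
      list(fit = ss$fit, n_splits = length(ss$splits),
           groups = as.list(stats::setNames(as.integer(grp), names(grp))))
    })
    report$networks[[v]] <- res
  }

  manifest <- list(package = "aflpdelimit",
                   version = as.character(utils::packageVersion("aflpdelimit")),
                   seed = cfg$seed,
                   config = .config_as_list(cfg))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$binning <- unclass(out$binning)
  out$thresholds <- unclass(out$thresholds)
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  out
}
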