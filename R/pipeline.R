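#' Run the full quantitative flow-cytometry pipeline
#'
#' Orchestrates every stage from a single configuration: read events and
#' beads, fit the bead standard curve, hierarchically gate populations,
#' then, for each gated population and panel marker, calibrate intensities
#' to receptors/cell and compute the four reported metrics - composition,
#' ensemble receptor concentration, BIC-selected log-normal mixture
#' decomposition, and binned-distribution quadratic entropy - ending in
#' rule-based target scores. Deterministic given the configuration and its
#' seed.
#'
#' Populations with fewer than `min_cells` gated events are reported in the
#' composition only, with a warning in the run log. Per-marker fit failures
#' are logged and skipped; I/O and configuration errors halt the run.
#'
#' @param config A [pipeline_config()] (or path to a JSON config, which is
#'   passed through [load_config()]).
#' @param out_dir Optional directory; when given, writes `composition.csv`,
#'   `stats.csv`, `fits.json`, `targets.csv` and `run_log.txt`.
#' @return A `pipeline_result`: list with `composition`, `stats` (data
#'   frame), `fits` (named list of `mixture_fit`), `scores`, `targets`
#'   (ranked data frame), `curve`, `labels`, `log`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(level, msg) {
    log_lines <<- c(log_lines, paste0(level, ": ", msg))
  }

  if (is.null(config$events) || !file.exists(config$events)) {
    stop("event file not found: ", config$events %||% "<unset>", call. = FALSE)
  }
  note("INFO", paste("reading events from", config$events))
  events <- if (config$format == "fcs") read_fcs(config$events) else
    read_events_csv(config$events, panel = config$panel,
                    sample_id = config$sample_id)

  curve <- if (!is.null(config$beads)) {
    if (!file.exists(config$beads)) {
      stop("bead file not found: ", config$beads, call. = FALSE)
    }
    note("INFO", paste("fitting bead curve from", config$beads))
    fit_bead_curve(read_beads_csv(config$beads),
                   config$receptors_per_fluorophore)
  } else {
    stop("configuration supplies no bead calibration input", call. = FALSE)
  }
  note("INFO", sprintf("calibration: slope %.4f intercept %.4f R2 %.5f",
                       curve$slope, curve$intercept, curve$r_squared))

  note("INFO", "applying gate tree")
  labels <- apply_gates(events, config$gates)
  comp <- composition(labels)
  note("INFO", sprintf("%d live gated events, %d ungated",
                       attr(comp, "total_live"), attr(comp, "n_ungated")))

  markers <- intersect(config$markers, events$channels)
  missing_m <- setdiff(config$markers, events$channels)
  if (length(missing_m)) {
    note("WARNING", paste("marker channel(s) absent from events:",
                          paste(missing_m, collapse = ", ")))
  }
  stats_rows <- list()
  fits <- list()
  scores <- list()
  pop_i <- 0L
  for (pop in comp$population) {
    pop_i <- pop_i + 1L
    rows <- which(labels == pop)
    if (length(rows) < config$min_cells) {
      note("WARNING", sprintf(
        "population '%s' has %d cells (< %d): composition-only",
        pop, length(rows), config$min_cells))
      next
    }
    sub <- event_table(events$intensities[rows, , drop = FALSE],
                       events$channels, sample_id = events$sample_id,
                       panel = events$panel)
    mk_i <- 0L
    for (mk in markers) {
      mk_i <- mk_i + 1L
      seed_mk <- config$seed + 1000L * pop_i + mk_i
      res <- tryCatch({
        receptors <- calibrate(sub, mk, curve)
        dist <- receptor_distribution(receptors, pop, mk)
        ens <- ensemble_concentration(dist, n_boot = config$bootstrap,
                                      seed = seed_mk)
        qe <- receptor_qe(dist, bins = config$bins,
                          threshold = config$qe_threshold)
        fit <- select_bic(dist$values, k_range = config$k_range,
                          seed = seed_mk)
        if (length(attr(fit, "skipped_k"))) {
          note("WARNING", sprintf(
            "%s/%s: insufficient cells for k = %s", pop, mk,
            paste(attr(fit, "skipped_k"), collapse = ",")))
        }
        ref <- config$reference[[mk]]
        score <- score_target(dist, qe, fit, reference_gm = ref,
                              criteria = config$criteria)
        list(dist = dist, ens = ens, qe = qe, fit = fit, score = score)
      }, error = function(e) {
        note("WARNING", sprintf("%s/%s: analysis failed (%s)", pop, mk,
                                conditionMessage(e)))
        NULL
      })
      if (is.null(res)) next
      key <- paste(pop, mk, sep = "/")
      fits[[key]] <- res$fit
      scores[[key]] <- res$score
      stats_rows[[key]] <- data.frame(
        population = pop, marker = mk, n = res$dist$n_cells,
        n_excluded_nonpositive = res$dist$n_excluded_nonpositive,
        geometric_mean = res$ens$geometric_mean,
        arithmetic_mean = res$ens$arithmetic_mean,
        ci_lo = res$ens$ci[1], ci_hi = res$ens$ci[2],
        qe = res$qe$qe, qe_class = res$qe$heterogeneity_class,
        k = res$fit$k,
        k_class = heterogeneity_by_components(res$fit$k),
        bic = res$fit$bic)
    }
  }
  stats <- if (length(stats_rows)) {
    out <- do.call(rbind, stats_rows)
    rownames(out) <- NULL
    out
  } else data.frame()
  targets <- if (length(scores)) rank_targets(unname(scores)) else data.frame()

  provenance <- list(config_hash = config_hash(config),
                     seed = config$seed,
                     package = "qflowkit",
                     version = as.character(utils::packageVersion("qflowkit")))
  result <- structure(list(composition = comp, stats = stats, fits = fits,
                           scores = scores, targets = targets, curve = curve,
                           labels = labels, log = log_lines,
                           provenance = provenance),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$composition)
  if (nrow(x$stats)) {
    cat(sprintf("\n%d population x marker stats blocks; %d primary target(s), %d combination candidate(s)\n",
                nrow(x$stats), sum(x$targets$primary_target),
                sum(x$targets$combination_candidate)))
  }
  invisible(x)
}

#' Write pipeline reports to disk
#'
#' Emits `composition.csv`, `stats.csv`, `targets.csv`, `fits.json` (with
#' provenance and the per-fit BIC tables) and `run_log.txt`. Outputs carry
#' no timestamps, so identical runs produce byte-identical files.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(result$composition),
                   file.path(out_dir, "composition.csv"), row.names = FALSE)
  utils::write.csv(result$stats, file.path(out_dir, "stats.csv"),
                   row.names = FALSE)
  utils::write.csv(result$targets, file.path(out_dir, "targets.csv"),
                   row.names = FALSE)
  fits_out <- lapply(result$fits, function(f) {
    list(k = f$k, components = f$components, log_likelihood = f$log_likelihood,
         bic = f$bic, n = f$n,
         n_excluded_nonpositive = f$n_excluded_nonpositive,
         bic_table = attr(f, "bic_table"))
  })
  jsonlite::write_json(list(provenance = result$provenance,
                            calibration = unclass(result$curve),
                            fits = fits_out),
                       file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(list(unclass(config)$panel,
                                gate_node_to_list(config$gates),
                                config[setdiff(names(config),
                                               c("panel", "gates", "criteria"))],
                                unclass(config$criteria)),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(json))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a synthetic scenario to disk
#'
#' Generates a named scenario (currently `"paperlike"`, the glioblastoma
#' PDX-like panel) and writes the event table, bead calibration events, the
#' ground-truth JSON, and a ready-to-run pipeline configuration. Identical
#' seeds produce identical files.
#'
#' @param scenario Scenario name; `"paperlike"`.
#' @param n Number of cell events (>= 1).
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param bead_peaks Known fluorophores-per-bead for the calibration set.
#' @param n_per_peak Bead events per peak.
#' @return Named list of written file paths (`events`, `beads`, `truth`,
#'   `config`), invisibly.
#' @export
simulate_command <- function(scenario, n, seed = 0L, out_dir = ".",
                             bead_peaks = 10^(2:6), n_per_peak = 500L) {
  if (!identical(scenario, "paperlike")) {
    stop("unknown scenario '", scenario, "' (known: paperlike)", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  truth <- paperlike_scenario()
  sim <- generate_cells(truth, n, seed = seed)
  beads <- generate_beads(truth, bead_peaks, n_per_peak = n_per_peak,
                          seed = seed + 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(events = file.path(out_dir, "events.csv"),
                beads = file.path(out_dir, "beads.csv"),
                truth = file.path(out_dir, "truth.json"),
                config = file.path(out_dir, "config.json"))
  write_events_csv(sim$events, paths$events)
  write_beads_csv(beads, paths$beads)
  write_truth_json(truth, paths$truth)
  cfg <- pipeline_config(
    panel = as.list(setNames(RTK_PANEL, RTK_PANEL)),
    gates = default_gate_tree(truth),
    events = paths$events, format = "csv", beads = paths$beads,
    receptors_per_fluorophore = truth$receptors_per_fluorophore,
    markers = RTK_PANEL, sample_id = sprintf("%s-n%d-seed%d", scenario, n, seed),
    seed = seed)
  write_config(cfg, paths$config)
  invisible(paths)
}
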