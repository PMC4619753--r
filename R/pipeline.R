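#' Run the full analysis pipeline from a config
#'
#' Batch orchestration over a directory of recordings: preprocessing to
#' `.proc` files, per-subject quality control, seed or whole-brain FC with
#' group maps, and a graph-metric sparsity sweep. Stages are selected by the
#' config; each run writes a structured log with ISO timestamps. Per-subject
#' failures are logged and skipped; the returned status reflects partial
#' failure. Results are identical for any `n_jobs` because all seeds are
#' derived per subject before dispatch.
#'
#' The config is a named list (or a YAML file with the same structure):
#' \describe{
#'   \item{input_dir, output_dir}{directories; input holds .nirs/.csv files.}
#'   \item{stages}{character vector from "preprocess", "qc", "fc",
#'     "network" (default: all four).}
#'   \item{steps}{preprocessing step list, see [run_preprocessing()].}
#'   \item{qc}{list of [qc_report()] threshold overrides.}
#'   \item{fc}{list: `mode` ("whole"/"seed"), `seed_channel`, `method`,
#'     `signal`.}
#'   \item{network}{list: `sparsities`, `mode`, `n_random`.}
#'   \item{seed}{base RNG seed (default 1).}
#'   \item{n_jobs}{worker processes for the network sweep (default 1).}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with `preprocess` (status table), `qc` (reports),
#'   `fc` (per-subject results + `group` maps), `network` (sweep table),
#'   `log_path`, and `status` ("ok"/"partial").
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (f in c("input_dir", "output_dir"))
    if (is.null(config[[f]])) stop("config is missing required field: ", f)
  stages <- config$stages %||% c("preprocess", "qc", "fc", "network")
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  n_jobs <- config$n_jobs %||% 1L
  log_path <- file.path(out_dir, "pipeline_log.txt")
  logf <- function(...) cat(sprintf("[%s] %s\n",
                                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                    sprintf(...)),
                            file = log_path, append = TRUE)
  cat(character(0), file = log_path)
  logf("pipeline start: stages = %s, seed = %d, n_jobs = %d",
       paste(stages, collapse = ","), seed, n_jobs)
  result <- list(log_path = log_path, status = "ok")

  if ("preprocess" %in% stages) {
    logf("preprocess: input = %s", config$input_dir)
    pp <- run_preprocessing(config$input_dir, out_dir,
                            steps = config$steps %||% default_steps())
    result$preprocess <- pp
    if (any(pp$status == "failed")) {
      result$status <- "partial"
      for (i in which(pp$status == "failed"))
        logf("preprocess FAILED for %s: %s", pp$subject[i], pp$message[i])
    }
    logf("preprocess: %d ok, %d failed", sum(pp$status == "ok"),
         sum(pp$status == "failed"))
  }

  proc_files <- list.files(out_dir, pattern = "\\.proc$", full.names = TRUE)
  if (length(proc_files) == 0L) stop("no .proc files available in ", out_dir)
  recs <- lapply(proc_files, function(f) suppressMessages(read_proc(f)))
  names(recs) <- vapply(recs, function(r) r$raw$subject_id, "")

  if ("qc" %in% stages) {
    qc_args <- config$qc %||% list()
    reports <- lapply(recs, function(rec)
      do.call(qc_report, c(list(rec = rec$raw, conc = rec$conc), qc_args)))
    qc_path <- file.path(out_dir, "qc_report.tsv")
    write_qc_table(reports, qc_path)
    for (rep in reports)
      logf("qc %s: %s (%d flagged channel(s))", rep$subject_id,
           rep$subject_verdict, length(rep$flagged_channels))
    result$qc <- reports
  }

  if ("fc" %in% stages || "network" %in% stages) {
    fc_cfg <- config$fc %||% list()
    mode <- fc_cfg$mode %||% "whole"
    method <- fc_cfg$method %||% "pearson"
    sig <- fc_cfg$signal %||% "hbo"
    fc_res <- lapply(recs, function(rec) {
      if (mode == "seed")
        seed_fc(rec, fc_cfg$seed_channel %||% 1L, method = method, signal = sig)
      else whole_brain_fc(rec, method = method, signal = sig)
    })
    result$fc <- list(subjects = fc_res)
    if (length(fc_res) >= 2L) {
      gm <- group_maps(fc_res)
      result$fc$group <- gm
      utils::write.table(round(as.matrix(gm$z_to_r_map), 6),
                         file.path(out_dir, "group_z_to_r_map.tsv"),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      logf("fc: %s/%s group maps over %d subjects", method, mode, length(fc_res))
    } else logf("fc: %s/%s computed for %d subject (no group maps)",
                method, mode, length(fc_res))
  }

  if ("network" %in% stages) {
    if ((config$fc$mode %||% "whole") == "seed")
      stop("network analysis needs whole-brain FC matrices")
    net_cfg <- config$network %||% list()
    sweep <- sparsity_sweep(lapply(result$fc$subjects, `[[`, "values"),
                            s_values = net_cfg$sparsities %||% seq(0.1, 0.5, 0.1),
                            mode = net_cfg$mode %||% "binary",
                            n_random = net_cfg$n_random %||% 0L,
                            seed = seed, n_jobs = n_jobs)
    utils::write.table(sweep, file.path(out_dir, "network_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (any(sweep$status == "failed")) result$status <- "partial"
    logf("network: %d rows (%d failed)", nrow(sweep),
         sum(sweep$status == "failed"))
    result$network <- sweep
  }
  logf("pipeline end: status = %s", result$status)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
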