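#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the analysis defaults:
#' 30 Hz low-pass, 12 s epochs with 50% overlap, IAPF-anchored bands,
#' dwPLI connectivity, OMST thresholding, 50 null-model surrogates and
#' 20 Louvain restarts. All seeds are carried in the manifest so a run
#' can be reproduced bit-identically.
#'
#' @param cohort Optional [cohort_spec()] for a synthetic run.
#' @param epoch_length,overlap Epoching (seconds / fraction).
#' @param lowpass Low-pass cutoff in Hz.
#' @param search_window IAPF search window in Hz.
#' @param threshold `"omst"` or `"full"` (pass-through, no
#'   thresholding). Arbitrary proportional or absolute thresholds are
#'   deliberately not offered.
#' @param n_null Small-world surrogate count.
#' @param restarts Louvain restarts.
#' @param seed Master seed.
#' @param out_dir Optional output directory; when given, every stage's
#'   tables are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, epoch_length = 12, overlap = 0.5,
                            lowpass = 30, search_window = c(7, 13),
                            threshold = c("omst", "full"),
                            n_null = 50, restarts = 20, seed = 1,
                            out_dir = NULL) {
  threshold <- match.arg(threshold)
  structure(
    list(cohort = cohort, epoch_length = epoch_length, overlap = overlap,
         lowpass = lowpass, search_window = search_window,
         threshold = threshold, n_null = n_null, restarts = restarts,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(y$cohort)) {
    cohort <- do.call(cohort_spec, lapply(y$cohort, function(v) {
      if (is.list(v)) unlist(v) else v
    }))
  }
  pipeline_config(
    cohort = cohort,
    epoch_length = y$epoch_length %||% 12, overlap = y$overlap %||% 0.5,
    lowpass = y$lowpass %||% 30,
    search_window = unlist(y$search_window %||% c(7, 13)),
    threshold = y$threshold %||% "omst", n_null = y$n_null %||% 50,
    restarts = y$restarts %||% 20, seed = y$seed %||% 1,
    out_dir = y$out_dir
  )
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- unclass(config)
  if (!is.null(y$cohort)) {
    # named numeric vectors must become maps, not bare sequences
    y$cohort <- lapply(unclass(y$cohort), function(v) {
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
    })
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Process one subject's continuous EEG through the connectivity stages
#'
#' Low-pass filter, epoch, cross-spectra, IAPF and band derivation,
#' band-wise dwPLI, thresholding, graph metrics.
#'
#' @param eeg A [continuous_eeg()].
#' @param config A [pipeline_config()].
#' @param subject_id Identifier carried into the records.
#' @param seed Per-subject seed for modularity/small-world.
#' @return List: `iapf` (estimate), `bands` (tibble), `connectivity`
#'   (list per band), `selections` (OMST selections or `NULL` in full
#'   mode), `metrics` (tibble, one row per band).
#' @export
process_subject <- function(eeg, config = pipeline_config(),
                            subject_id = "sub-001", seed = 1) {
  eeg <- lowpass_filter(eeg, cutoff = config$lowpass)
  epochs <- segment_epochs(eeg, length = config$epoch_length,
                           overlap = config$overlap)
  csd <- compute_csd(epochs)
  iapf <- estimate_iapf(csd, search_window = config$search_window)
  bands <- derive_bands(iapf, fallback = TRUE)
  conn <- list(); selections <- list(); recs <- list()
  for (r in seq_len(nrow(bands))) {
    brow <- bands[r, ]
    bname <- as.character(brow$band)
    cm <- band_dwpli(csd, brow)
    conn[[bname]] <- cm
    g <- weighted_graph(cm)
    if (config$threshold == "omst") {
      sel <- select_omst(g)
      selections[[bname]] <- sel
      g_thr <- sel$thresholded
    } else {
      g_thr <- g
    }
    recs[[bname]] <- graph_metric_record(
      g_thr, connectivity = cm, subject_id = subject_id, band = bname,
      n_null = config$n_null, restarts = config$restarts, seed = seed
    )
  }
  list(iapf = iapf, bands = dplyr::mutate(bands, subject_id = subject_id,
                                          iapf = iapf$iapf, .before = 1L),
       connectivity = conn,
       selections = if (config$threshold == "omst") selections else NULL,
       metrics = dplyr::bind_rows(recs))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates each subject's signals from the cohort spec, runs
#' spectral -> connectivity -> thresholding -> graph metrics per
#' subject, plants behavioural scores on the computed metrics, fits the
#' regression grid and (optionally) writes every table plus a run
#' manifest. A failure in one subject is logged and skipped; the cohort
#' run continues. Identical config and seeds give identical outputs.
#'
#' @param config A [pipeline_config()] with a `cohort` spec.
#' @param planted_metric,planted_band Metric/band driving the planted
#'   behavioural scores.
#' @param progress Print per-subject progress to stderr.
#' @return List: `manifest`, `bands`, `metrics` (wide),
#'   `metrics_long`, `behavioural`, `models`, `model_table`.
#' @export
run_pipeline <- function(config, planted_metric = "dwpli_mean",
                         planted_band = "alpha", progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$cohort)) {
    stop("`config$cohort` must hold a cohort_spec for a synthetic run",
         call. = FALSE)
  }
  cohort <- generate_cohort(config$cohort)
  subs <- cohort$subjects
  bands_out <- list(); metrics_out <- list(); failures <- character(0)
  for (i in seq_len(nrow(subs))) {
    sid <- subs$subject_id[i]
    res <- tryCatch({
      eeg <- generate_subject_signals(subs$subject[[i]], seed = subs$seed[i])
      process_subject(eeg, config, subject_id = sid, seed = subs$seed[i])
    }, error = function(e) {
      warning("subject ", sid, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) { failures <- c(failures, sid); next }
    bands_out[[sid]] <- res$bands
    metrics_out[[sid]] <- res$metrics
    if (!is.null(config$out_dir)) {
      dir.create(file.path(config$out_dir, sid), recursive = TRUE,
                 showWarnings = FALSE)
      for (b in names(res$connectivity)) {
        write_connectivity(res$connectivity[[b]],
                           file.path(config$out_dir, sid,
                                     paste0("dwpli_", b, ".csv")))
        if (!is.null(res$selections)) {
          write_omst(res$selections[[b]],
                     file.path(config$out_dir, sid,
                               paste0("omst_", b, ".csv")))
        }
      }
    }
    if (progress) message(sid, " done")
  }
  if (length(metrics_out) == 0L) stop("no subject processed successfully",
                                      call. = FALSE)
  metrics <- dplyr::bind_rows(metrics_out)
  bands_tbl <- dplyr::bind_rows(bands_out)
  behavioural <- plant_fluency_scores(metrics, subs, config$cohort,
                                      metric = planted_metric,
                                      band = planted_band)
  models <- run_all_models(metrics, behavioural)
  model_tbl <- model_summary_table(models)
  manifest <- list(
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("eegconnectome")),
    n_subjects = nrow(subs), n_failed = length(failures),
    failed_subjects = failures,
    n_metric_rows = nrow(metrics), n_models = length(models),
    seed = config$seed,
    subject_seeds = stats::setNames(subs$seed, subs$subject_id)
  )
  out <- list(manifest = manifest, bands = bands_tbl, metrics = metrics,
              metrics_long = metrics_long(metrics),
              behavioural = behavioural, models = models,
              model_table = model_tbl)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(bands_tbl, file.path(config$out_dir, "bands.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(out$metrics_long,
                       file.path(config$out_dir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_behavioural(behavioural,
                      file.path(config$out_dir, "behavioural.tsv"))
    utils::write.table(model_tbl, file.path(config$out_dir, "models.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
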