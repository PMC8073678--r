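# Pipeline orchestration: validated configuration, per-subject
# processing, cohort assembly, statistics, and artifact writing.

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the ingest -> detect -> featureize
#' -> stats chain, each with the analysis defaults: confidence gate
#' C > 0.75, 4-frame boxcar smoothing, activation threshold 0.5 on the
#' 0--5 intensity scale, 1 s minimum event duration, 50% AU06 overlap
#' for the Social label, 0.5 s maximum bridged dropout, family-wise
#' alpha 0.05 over a 7-test follow-up family.
#'
#' @param confidence_threshold Confidence gate in \[0, 1\]; default 0.75.
#' @param smooth_width_frames Boxcar width; default 4.
#' @param activation_tau Activation threshold; default 0.5.
#' @param min_event_s Minimum event duration (s); default 1.0.
#' @param social_overlap_threshold AU06 co-activation fraction; default
#'   0.5.
#' @param max_gap_s Longest bridged dropout (s); default 0.5.
#' @param alpha Family-wise alpha; default 0.05.
#' @param m_tests Follow-up family size; default 7.
#' @param dv_set MANOVA DV labels; default [manova_dv_names()].
#' @param seed Integer seed recorded in the manifest; default 1.
#' @param input_dir Directory of per-subject OpenFace CSVs.
#' @param metadata_csv Cohort metadata CSV (`subject_id`, `group`,
#'   `sex`, `age_months`, `iq`).
#' @param output_dir Directory for pipeline artifacts.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(confidence_threshold = 0.75,
                            smooth_width_frames = 4L,
                            activation_tau = 0.5,
                            min_event_s = 1.0,
                            social_overlap_threshold = 0.5,
                            max_gap_s = 0.5,
                            alpha = 0.05,
                            m_tests = 7L,
                            dv_set = manova_dv_names(),
                            seed = 1L,
                            input_dir = NULL,
                            metadata_csv = NULL,
                            output_dir = NULL) {
  chk <- function(x, nm, lo, hi) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
      stop(sprintf("`%s` must be a single number in [%s, %s]", nm, lo, hi),
           call. = FALSE)
  }
  chk(confidence_threshold, "confidence_threshold", 0, 1)
  chk(smooth_width_frames, "smooth_width_frames", 1, Inf)
  chk(activation_tau, "activation_tau", 0, 5)
  chk(min_event_s, "min_event_s", 0, Inf)
  chk(social_overlap_threshold, "social_overlap_threshold",
      .Machine$double.eps, 1)
  chk(max_gap_s, "max_gap_s", 0, Inf)
  chk(alpha, "alpha", .Machine$double.eps, 1 - .Machine$double.eps)
  chk(m_tests, "m_tests", 1, Inf)
  structure(
    list(confidence_threshold = confidence_threshold,
         smooth_width_frames = as.integer(smooth_width_frames),
         activation_tau = activation_tau,
         min_event_s = min_event_s,
         social_overlap_threshold = social_overlap_threshold,
         max_gap_s = max_gap_s,
         alpha = alpha,
         m_tests = as.integer(m_tests),
         dv_set = dv_set,
         seed = as.integer(seed),
         input_dir = input_dir,
         metadata_csv = metadata_csv,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments; absent keys take the defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Process one gated recording into events and features
#'
#' Runs gate -> split -> detect -> featureize for a single subject's
#' series under a pipeline configuration.
#'
#' @param series An [au_frame_series()] (raw, gate not yet applied).
#' @param metadata One-row metadata for the subject.
#' @param config A [pipeline_config()].
#' @return A list with `features` (one-row tibble or `NULL` when the
#'   recording has no usable frames), `events`, and `recording` (the
#'   [recording_set()]).
#' @export
process_recording <- function(series, metadata, config = pipeline_config()) {
  gated <- apply_confidence_gate(series, config$confidence_threshold)
  rec <- split_at_dropouts(gated, config$max_gap_s)
  events <- smile_events(
    rec,
    smooth_width_frames = config$smooth_width_frames,
    tau = config$activation_tau,
    min_event_s = config$min_event_s,
    social_overlap_threshold = config$social_overlap_threshold)
  features <- if (rec$usable_seconds > 0) {
    fv <- subject_features(events, rec$usable_seconds, metadata)
    fv$confidence_mean <- rec$confidence_mean
    fv$confidence_pct <- rec$confidence_pct
    fv
  } else {
    NULL
  }
  list(features = features, events = events, recording = rec)
}

#' Analyze an in-memory cohort of traces
#'
#' Convenience wrapper used by simulation studies: applies
#' [process_recording()] to every trace, assembles the cohort table,
#' and (optionally) runs the statistical battery.
#'
#' @param traces Named list of [au_frame_series()], one per subject.
#' @param metadata Tibble with one row per subject (`subject_id` must
#'   match the trace names).
#' @param config A [pipeline_config()].
#' @param stats Logical; also run [run_group_stats()]? Default `FALSE`.
#' @return A list with `cohort` (a [assemble_cohort()] table), `events`,
#'   `features`, `dropped` (subjects with no usable frames), and
#'   `stats` (`NULL` unless requested).
#' @export
analyze_cohort <- function(traces, metadata, config = pipeline_config(),
                           stats = FALSE) {
  feats <- vector("list", length(traces))
  evs <- vector("list", length(traces))
  dropped <- character()
  for (i in seq_along(traces)) {
    id <- names(traces)[i]
    md <- metadata[metadata$subject_id == id, , drop = FALSE]
    if (nrow(md) != 1L) {
      stop("metadata must contain exactly one row for subject ", id,
           call. = FALSE)
    }
    out <- process_recording(traces[[i]], md, config)
    if (is.null(out$features)) {
      dropped <- c(dropped, id)
    } else {
      feats[[i]] <- out$features
      evs[[i]] <- out$events
    }
  }
  features <- do.call(rbind, feats[!vapply(feats, is.null, logical(1))])
  events <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
  cohort <- assemble_cohort(features, dv_names = config$dv_set)
  list(
    cohort = cohort,
    events = if (is.null(events)) empty_smile_events() else events,
    features = features,
    dropped = dropped,
    stats = if (stats) run_group_stats(cohort, alpha = config$alpha,
                                       m_tests = config$m_tests) else NULL
  )
}

#' Run the full analysis pipeline on a directory of recordings
#'
#' Ingests every per-subject OpenFace CSV in `config$input_dir`, applies
#' the confidence gate and dropout splitting, detects and classifies
#' smile events, extracts per-subject features, runs the group-level
#' statistical battery, and writes the artifacts to
#' `config$output_dir`: `events.csv`, `features.csv`,
#' `exclusions.csv`, `stats.json`, `report.txt`, and a
#' `manifest.yaml` recording the configuration and package version.
#' Identical inputs and configuration yield identical outputs.
#'
#' @param config A [pipeline_config()] with `input_dir`, `metadata_csv`,
#'   and `output_dir` set.
#' @return The [run_group_stats()] report, invisibly, with the cohort
#'   table attached as attribute `cohort`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  paths <- stage("ingest", {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir)) {
      stop("input directory not found: ", config$input_dir)
    }
    p <- list.files(config$input_dir, pattern = "\\.csv$", full.names = TRUE)
    p <- p[basename(p) != "metadata.csv"]
    if (length(p) == 0L) stop("no recording CSVs in ", config$input_dir)
    sort(p)
  })
  metadata <- stage("ingest", {
    if (is.null(config$metadata_csv)) {
      mp <- file.path(config$input_dir, "metadata.csv")
      if (!file.exists(mp)) stop("no metadata CSV given or found")
      mp
    } else config$metadata_csv
  })
  metadata <- stage("ingest", tibble::as_tibble(utils::read.csv(metadata)))

  traces <- stage("ingest", {
    tr <- lapply(paths, read_openface_csv)
    names(tr) <- vapply(tr, function(s) s$subject_id, character(1))
    tr
  })

  res <- stage("detect/featureize",
               analyze_cohort(traces, metadata, config, stats = FALSE))
  report <- stage("stats",
                  run_group_stats(res$cohort, alpha = config$alpha,
                                  m_tests = config$m_tests))

  stage("write", {
    out <- config$output_dir
    if (is.null(out)) stop("no output directory configured")
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$events, file.path(out, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(res$features, file.path(out, "features.csv"),
                     row.names = FALSE)
    excl <- attr(res$cohort, "exclusions")
    if (length(res$dropped) > 0L) {
      excl <- rbind(excl, tibble::tibble(subject_id = res$dropped,
                                         missing_dvs = "no usable frames"))
    }
    utils::write.csv(excl, file.path(out, "exclusions.csv"),
                     row.names = FALSE)
    write_stats_json(report, file.path(out, "stats.json"))
    writeLines(utils::capture.output(print(report)),
               file.path(out, "report.txt"))
    manifest <- unclass(config)
    manifest$package_version <- as.character(utils::packageVersion("smiletrace"))
    manifest$r_version <- paste(R.version$major, R.version$minor, sep = ".")
    manifest$n_recordings <- length(paths)
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    NULL
  })
  attr(report, "cohort") <- res$cohort
  invisible(report)
}

#' Boxplot panel of the cohort dependent variables
#'
#' Simple per-DV boxplots by group, for visual inspection of the
#' feature distributions (requires ggplot2).
#'
#' @param cohort A [assemble_cohort()] table.
#' @param dvs DV columns; default the univariate family.
#' @return A ggplot object.
#' @export
plot_dv_boxplots <- function(cohort, dvs = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  if (is.null(dvs)) dvs <- attr(cohort, "dv_family")
  d <- tibble::as_tibble(unclass_cohort(cohort))
  long <- do.call(rbind, lapply(dvs, function(nm) {
    vals <- as.numeric(d[[nm]])
    tibble::tibble(group = d$group, dv = nm, value = vals)
  }))
  ggplot2::ggplot(long[is.finite(long$value), ],
                  ggplot2::aes(x = group, y = value, fill = group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::facet_wrap(~dv, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}
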