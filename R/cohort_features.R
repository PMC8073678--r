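# Aggregation of smile events into the per-subject feature set and the
# cohort analysis table.

#' Per-subject smile feature vector
#'
#' Aggregates a subject's smile events into the seven-measure feature
#' set: mean event duration, mean event intensity, and frequency per
#' 120 s of usable interaction, separately for Simple (`SI`) and Social
#' (`SO`) Smiles (intensity for `SO` covers both AU12 and AU06). When a
#' subject produced no event of a type, that type's duration and
#' intensity are missing (`NA`, a mean over zero events is undefined)
#' while its frequency is genuinely 0.
#'
#' @param events Tibble of smile events for one subject
#'   (see [smile_events()]).
#' @param usable_seconds Seconds of gate-passing recording for the
#'   subject; must be > 0.
#' @param metadata One-row data.frame or named list with `subject_id`,
#'   `group` (`"ASD"`/`"TD"`), `sex` (`"M"`/`"F"`), `age_months`, and
#'   optionally `iq`.
#' @return A one-row tibble with identifiers, covariates, event counts,
#'   `dur_SI`, `dur_SO`, `int_SI_au12`, `int_SO_au12`, `int_SO_au06`,
#'   `freq_SI`, `freq_SO`, and `usable_seconds`.
#' @export
subject_features <- function(events, usable_seconds, metadata) {
  if (!is.numeric(usable_seconds) || length(usable_seconds) != 1L ||
      !is.finite(usable_seconds) || usable_seconds <= 0) {
    stop("`usable_seconds` must be a single positive number", call. = FALSE)
  }
  md <- as.list(metadata)
  if (is.null(md$subject_id)) stop("metadata must include subject_id",
                                   call. = FALSE)
  if (nrow(events) > 0L &&
      !all(events$subject_id %in% c(md$subject_id, NA))) {
    stop("events contain subject ids other than ", md$subject_id,
         call. = FALSE)
  }
  si <- events[events$smile_type == "SI", , drop = FALSE]
  so <- events[events$smile_type == "SO", , drop = FALSE]
  mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  tibble::new_tibble(list(
    subject_id = as.character(md$subject_id),
    group = if (is.null(md$group)) NA_character_ else as.character(md$group),
    sex = if (is.null(md$sex)) NA_character_ else as.character(md$sex),
    age_months = if (is.null(md$age_months)) NA_real_ else as.numeric(md$age_months),
    iq = if (is.null(md$iq)) NA_real_ else as.numeric(md$iq),
    n_events_SI = nrow(si),
    n_events_SO = nrow(so),
    dur_SI = mean_or_na(si$duration_s),
    dur_SO = mean_or_na(so$duration_s),
    int_SI_au12 = mean_or_na(si$mean_au12),
    int_SO_au12 = mean_or_na(so$mean_au12),
    int_SO_au06 = mean_or_na(so$mean_au06),
    freq_SI = 120 * nrow(si) / usable_seconds,
    freq_SO = 120 * nrow(so) / usable_seconds,
    usable_seconds = usable_seconds
  ), nrow = 1L)
}

#' Default dependent-variable sets
#'
#' The multivariate analysis uses six dependent variables: duration and
#' frequency per smile type, Simple-Smile AU12 intensity, and a
#' Social-Smile intensity composite (mean of the event-level AU12 and
#' AU06 intensities). The univariate follow-up family splits the Social
#' intensity composite back into its AU12 and AU06 components, giving
#' seven tests.
#'
#' @return Character vector of column names.
#' @export
manova_dv_names <- function() {
  c("dur_SI", "dur_SO", "freq_SI", "freq_SO", "int_SI_au12",
    "int_SO_composite")
}

#' @rdname manova_dv_names
#' @export
followup_dv_names <- function() {
  c("dur_SI", "dur_SO", "freq_SI", "freq_SO", "int_SI_au12",
    "int_SO_au12", "int_SO_au06")
}

#' Assemble the cohort analysis table
#'
#' Binds per-subject feature vectors into a cohort table, derives the
#' Social-intensity composite DV, and applies the missing-data policy.
#' Under the default listwise (complete-case) policy, subjects missing
#' any multivariate DV are excluded from the analysis table and logged;
#' under `"pairwise"` all subjects are retained and each univariate
#' analysis uses whatever cases are complete for its own DV.
#'
#' @param features A tibble of [subject_features()] rows (or a list of
#'   such one-row tibbles).
#' @param dv_policy `"listwise"` (default) or `"pairwise"`.
#' @param dv_names DVs for the multivariate analysis; default
#'   [manova_dv_names()].
#' @return A `cohort_table`: the analysis tibble with attributes
#'   `dv_names`, `dv_family` (the univariate follow-up set),
#'   `exclusions` (tibble of excluded subjects and reasons), `all_data`
#'   (every input row), and `dv_policy`.
#' @export
assemble_cohort <- function(features, dv_policy = c("listwise", "pairwise"),
                            dv_names = manova_dv_names()) {
  dv_policy <- match.arg(dv_policy)
  if (is.list(features) && !is.data.frame(features)) {
    features <- do.call(rbind, features)
  }
  if (anyDuplicated(features$subject_id)) {
    stop("duplicate subject_id in cohort features", call. = FALSE)
  }
  features$int_SO_composite <-
    (features$int_SO_au12 + features$int_SO_au06) / 2

  present <- intersect(dv_names, names(features))
  if (length(present) < length(dv_names)) {
    stop("feature table lacks DV column(s): ",
         paste(setdiff(dv_names, present), collapse = ", "), call. = FALSE)
  }
  dvm <- as.matrix(features[, dv_names])
  incomplete <- apply(dvm, 1L, function(z) any(!is.finite(z)))
  exclusions <- tibble::tibble(
    subject_id = features$subject_id[incomplete],
    missing_dvs = vapply(which(incomplete), function(i) {
      paste(dv_names[!is.finite(dvm[i, ])], collapse = ";")
    }, character(1))
  )
  data <- if (dv_policy == "listwise") {
    features[!incomplete, , drop = FALSE]
  } else {
    features
  }
  structure(
    data,
    dv_names = dv_names,
    dv_family = followup_dv_names(),
    exclusions = exclusions,
    all_data = features,
    dv_policy = dv_policy,
    class = c("cohort_table", class(data))
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subject(s) in analysis (%s policy), %d excluded\n",
              nrow(x), attr(x, "dv_policy"), nrow(attr(x, "exclusions"))))
  print(tibble::as_tibble(unclass_cohort(x)), ...)
  invisible(x)
}

unclass_cohort <- function(x) {
  class(x) <- setdiff(class(x), "cohort_table")
  attr(x, "dv_names") <- NULL; attr(x, "dv_family") <- NULL
  attr(x, "exclusions") <- NULL; attr(x, "all_data") <- NULL
  attr(x, "dv_policy") <- NULL
  x
}

# Complete cases of the cohort for a set of columns, with group as factor.
cohort_complete <- function(cohort, cols) {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- tibble::as_tibble(unclass_cohort(cohort))
  keep <- rep(TRUE, nrow(d))
  for (cl in cols) keep <- keep & is.finite(as.numeric(d[[cl]]))
  keep <- keep & !is.na(d$group)
  d[keep, , drop = FALSE]
}
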