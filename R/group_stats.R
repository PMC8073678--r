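# Group-level statistical battery: one-way MANOVA (Pillai's trace),
# Bonferroni-corrected univariate follow-up ANOVAs with partial eta
# squared, assumption checks, partial Spearman correlations, and
# demographic comparisons.

#' Per-test Bonferroni threshold
#'
#' Family-wise error control by dividing the family-wise alpha by the
#' number of tests: a follow-up family of 7 tests at alpha = 0.05 gives
#' a per-test threshold of 0.05/7 = 0.00714 (reported rounded to five
#' decimals).
#'
#' @param alpha Family-wise significance level in (0, 1); default 0.05.
#' @param m Number of tests in the family, >= 1.
#' @return The per-test threshold `alpha / m` (unrounded).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("`m` must be a single integer >= 1", call. = FALSE)
  }
  alpha / m
}

#' One-way MANOVA on the cohort dependent variables
#'
#' Tests for a multivariate group difference (ASD vs TD) over the
#' dependent variables with Pillai's trace and its standard F
#' approximation (computed via [stats::manova()]). With two groups all
#' four classical MANOVA statistics yield the same exact F, with
#' degrees of freedom `(p, N - p - 1)` for `p` DVs and `N` complete
#' cases.
#'
#' @param cohort A [assemble_cohort()] table.
#' @param dvs Dependent-variable columns; default the cohort's
#'   `dv_names` attribute.
#' @return A `manova_result` list: `statistic_name`, `statistic_value`
#'   (Pillai's trace), `F_approx`, `df_between`, `df_error`, `p_value`,
#'   `n`, `dvs`.
#' @export
run_manova <- function(cohort, dvs = NULL) {
  if (is.null(dvs)) dvs <- attr(cohort, "dv_names")
  d <- cohort_complete(cohort, dvs)
  g <- factor(d$group)
  if (nlevels(g) < 2L) {
    stop("MANOVA needs both group labels present", call. = FALSE)
  }
  n <- nrow(d)
  p <- length(dvs)
  if (n < p + nlevels(g)) {
    stop("too few complete cases (", n, ") for ", p, " dependent variables",
         call. = FALSE)
  }
  y <- as.matrix(d[, dvs])
  if (p == 1L) {
    # one response: Pillai reduces to SSB/(SSB+SSW) and F to the ANOVA F
    a <- run_anova(cohort, dvs, m_tests = 1L)
    return(structure(
      list(statistic_name = "Pillai", statistic_value = a$partial_eta2,
           F_approx = a$F, df_between = 1, df_error = a$df2,
           p_value = a$p_raw, n = a$n, dvs = dvs),
      class = "manova_result"))
  }
  fit <- stats::manova(y ~ g)
  sm <- tryCatch(
    summary(fit, test = "Pillai")$stats,
    error = function(e) {
      stop("MANOVA failed (", conditionMessage(e),
           "); the pooled covariance may be singular - consider dropping ",
           "or combining collinear dependent variables", call. = FALSE)
    }
  )
  structure(
    list(
      statistic_name = "Pillai",
      statistic_value = unname(sm[1L, "Pillai"]),
      F_approx = unname(sm[1L, "approx F"]),
      df_between = unname(sm[1L, "num Df"]),
      df_error = unname(sm[1L, "den Df"]),
      p_value = unname(sm[1L, "Pr(>F)"]),
      n = n,
      dvs = dvs
    ),
    class = "manova_result"
  )
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("One-way MANOVA (%s): V = %.4f, F(%g, %g) = %.3f, p = %.4g (n = %d)\n",
              x$statistic_name, x$statistic_value, x$df_between, x$df_error,
              x$F_approx, x$p_value, x$n))
  invisible(x)
}

#' One-way two-group ANOVA with partial eta squared
#'
#' Univariate follow-up to the MANOVA for a single dependent variable:
#' a one-way, two-group analysis of variance with effect size
#' partial eta squared = SSB / (SSB + SSW), compared against the
#' Bonferroni per-test threshold for a family of `m_tests` tests.
#' Degenerate inputs are handled explicitly: zero within-group variance
#' gives F = 0 (equal group means) or infinite F (unequal means).
#'
#' @param cohort A [assemble_cohort()] table.
#' @param dv Name of the dependent-variable column.
#' @param m_tests Size of the follow-up family for the Bonferroni
#'   threshold; default 7.
#' @param alpha Family-wise alpha; default 0.05.
#' @return An `anova_result` list: `dv_name`, `F`, `df1`, `df2`,
#'   `p_raw`, `p_threshold_bonferroni`, `significant`, `partial_eta2`,
#'   `group_means`, `group_sds`, `group_ns`, `n`.
#' @export
run_anova <- function(cohort, dv, m_tests = 7L, alpha = 0.05) {
  d <- cohort_complete(cohort, dv)
  g <- factor(d$group)
  y <- as.numeric(d[[dv]])
  tab <- table(g)
  if (nlevels(g) != 2L || any(tab < 2L)) {
    stop("ANOVA on `", dv, "` needs >= 2 observations in each of 2 groups",
         call. = FALSE)
  }
  n <- length(y)
  means <- tapply(y, g, mean)
  sds <- tapply(y, g, stats::sd)
  grand <- mean(y)
  ssb <- sum(tab * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- 1L
  df2 <- n - 2L
  if (ssw <= 0) {
    if (ssb <= 0) {
      f <- 0; p <- 1; eta <- 0
    } else {
      f <- Inf; p <- 0; eta <- 1
    }
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    eta <- ssb / (ssb + ssw)
  }
  thr <- bonferroni_threshold(alpha, m_tests)
  structure(
    list(
      dv_name = dv, F = f, df1 = df1, df2 = df2, p_raw = p,
      p_threshold_bonferroni = thr, significant = is.finite(p) && p < thr,
      partial_eta2 = eta,
      group_means = as.numeric(means), group_sds = as.numeric(sds),
      group_ns = as.integer(tab), groups = names(tab), n = n
    ),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "ANOVA %s: F(%d, %d) = %.3f, p = %.4g (Bonferroni threshold %.5f%s), partial eta2 = %.3f\n",
    x$dv_name, x$df1, x$df2, x$F, x$p_raw, x$p_threshold_bonferroni,
    if (x$significant) ", significant" else "", x$partial_eta2))
  invisible(x)
}

#' MANOVA assumption checks
#'
#' Runs the conventional pre-MANOVA screen: Shapiro-Wilk normality of
#' each DV within each group, Levene's homogeneity-of-variance test per
#' DV (mean-centred by default), Mahalanobis distance of every complete
#' case to the pooled DV centroid against a chi-squared cutoff
#' (`p < 0.001` on `p_dv` degrees of freedom), and the maximum absolute
#' pairwise Pearson correlation among DVs as a multicollinearity screen
#' (flagged above 0.9).
#'
#' @param cohort A [assemble_cohort()] table.
#' @param dvs DV columns; default the cohort's `dv_names`.
#' @param levene_center `"mean"` (default) or `"median"`.
#' @return An `assumption_report` list with components `shapiro`
#'   (tibble), `levene` (tibble), `mahalanobis` (distances, cutoff,
#'   outlier flags), `pairwise_pearson_max_r`, `multicollinearity_flag`,
#'   and `notes`.
#' @export
check_assumptions <- function(cohort, dvs = NULL,
                              levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  if (is.null(dvs)) dvs <- attr(cohort, "dv_names")
  d <- cohort_complete(cohort, dvs)
  g <- factor(d$group)
  notes <- character()

  sh <- list()
  for (dv in dvs) {
    for (lev in levels(g)) {
      y <- as.numeric(d[[dv]][g == lev])
      if (length(y) < 3L || stats::sd(y) == 0) {
        notes <- c(notes, sprintf(
          "Shapiro-Wilk skipped for %s in group %s (n = %d%s)",
          dv, lev, length(y),
          if (length(y) >= 3L) ", constant" else ""))
        sh[[length(sh) + 1L]] <- tibble::tibble(
          dv = dv, group = lev, W = NA_real_, p = NA_real_, n = length(y))
      } else {
        s <- stats::shapiro.test(y)
        sh[[length(sh) + 1L]] <- tibble::tibble(
          dv = dv, group = lev, W = unname(s$statistic),
          p = s$p.value, n = length(y))
      }
    }
  }
  shapiro <- do.call(rbind, sh)

  lv <- lapply(dvs, function(dv) {
    lt <- car::leveneTest(as.numeric(d[[dv]]) ~ g, center = levene_center)
    tibble::tibble(dv = dv, F = lt[1L, "F value"], df1 = lt[1L, "Df"],
                   df2 = lt[2L, "Df"], p = lt[1L, "Pr(>F)"])
  })
  levene <- do.call(rbind, lv)

  y <- as.matrix(d[, dvs])
  ctr <- colMeans(y)
  cv <- stats::cov(y)
  md2 <- tryCatch(stats::mahalanobis(y, ctr, cv), error = function(e) {
    notes <<- c(notes, paste("Mahalanobis screen skipped:",
                             conditionMessage(e)))
    rep(NA_real_, nrow(y))
  })
  cutoff <- stats::qchisq(0.999, df = length(dvs))
  outliers <- is.finite(md2) & md2 > cutoff

  cm <- stats::cor(y)
  off <- abs(cm[upper.tri(cm)])
  max_r <- if (length(off)) max(off) else NA_real_

  structure(
    list(
      shapiro = shapiro,
      levene = levene,
      mahalanobis = list(
        distance2 = as.numeric(md2), subject_id = d$subject_id,
        cutoff_chi2 = cutoff, df = length(dvs),
        max_distance2 = if (any(is.finite(md2))) max(md2, na.rm = TRUE) else NA_real_,
        outliers = d$subject_id[outliers]
      ),
      pairwise_pearson_max_r = max_r,
      multicollinearity_flag = is.finite(max_r) && max_r > 0.9,
      notes = notes
    ),
    class = "assumption_report"
  )
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("MANOVA assumption checks\n")
  nviol <- sum(x$shapiro$p < 0.01, na.rm = TRUE)
  cat(sprintf("  Shapiro-Wilk: %d of %d group-by-DV cells non-normal at p < 0.01\n",
              nviol, nrow(x$shapiro)))
  cat(sprintf("  Levene: min p = %.3f across %d DVs\n",
              min(x$levene$p), nrow(x$levene)))
  cat(sprintf("  Mahalanobis: max D2 = %.2f (chi2 cutoff %.2f); %d outlier(s)\n",
              x$mahalanobis$max_distance2, x$mahalanobis$cutoff_chi2,
              length(x$mahalanobis$outliers)))
  cat(sprintf("  Max |pairwise Pearson r| among DVs = %.3f%s\n",
              x$pairwise_pearson_max_r,
              if (x$multicollinearity_flag) " (multicollinearity flag)" else ""))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Partial Spearman rank correlation
#'
#' Spearman correlation between `x` and `y` controlling for covariates:
#' all variables are rank-transformed, `x` and `y` residualized on the
#' covariate ranks by least squares, and the product-moment correlation
#' of the residuals returned with a t-based p-value on
#' `n - 2 - n_covariates` degrees of freedom. Invariant under strictly
#' monotone transforms of `x` and `y`.
#'
#' @param data Data.frame with the relevant rows (e.g. one group of the
#'   cohort).
#' @param x,y Column names of the two variables to correlate.
#' @param covariates Character vector of covariate column names; default
#'   `c("iq", "sex")`. A character/factor covariate with two levels is
#'   coded 0/1.
#' @return A `partial_correlation` list: `x`, `y`, `covariates`, `rho`,
#'   `n`, `p_value`, `note` (`NA` rho with a note for degenerate input).
#' @export
partial_spearman <- function(data, x, y, covariates = c("iq", "sex")) {
  cols <- c(x, y, covariates)
  d <- data[, cols, drop = FALSE]
  num <- lapply(cols, function(cl) {
    v <- d[[cl]]
    if (is.character(v) || is.factor(v)) {
      v <- as.factor(v)
      if (nlevels(v) > 2L) {
        stop("covariate `", cl, "` has more than two levels", call. = FALSE)
      }
      as.numeric(v) - 1
    } else {
      as.numeric(v)
    }
  })
  keep <- Reduce(`&`, lapply(num, is.finite))
  n <- sum(keep)
  res <- function(note) {
    structure(list(x = x, y = y, covariates = covariates, rho = NA_real_,
                   n = n, p_value = NA_real_, note = note),
              class = "partial_correlation")
  }
  if (n < 4L) return(res("fewer than 4 complete rows"))
  m <- vapply(num, function(v) v[keep], numeric(n))
  if (stats::sd(m[, 1L]) == 0 || stats::sd(m[, 2L]) == 0) {
    return(res("constant variable"))
  }
  rk <- apply(m, 2L, rank)
  z <- rk[, -(1:2), drop = FALSE]
  rx <- stats::lsfit(z, rk[, 1L])$residuals
  ry <- stats::lsfit(z, rk[, 2L])$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(res("variable fully explained by covariates"))
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - ncol(z)
  if (df < 1L) return(res("not enough degrees of freedom"))
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(x = x, y = y, covariates = covariates, rho = rho, n = n,
                 p_value = p, note = NA_character_),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  if (is.na(x$rho)) {
    cat(sprintf("Partial Spearman %s ~ %s | %s: undefined (%s)\n",
                x$x, x$y, paste(x$covariates, collapse = ", "), x$note))
  } else {
    cat(sprintf("Partial Spearman %s ~ %s | %s: rho = %.3f, p = %.4g (n = %d)\n",
                x$x, x$y, paste(x$covariates, collapse = ", "),
                x$rho, x$p_value, x$n))
  }
  invisible(x)
}

#' Partial Spearman screens within one group
#'
#' Runs the two series of covariate-controlled Spearman correlations
#' used to check that group findings are not driven by cognitive level
#' or sex: each dependent variable against IQ (controlling sex) and
#' against sex (controlling IQ), within the requested group.
#'
#' @param cohort A [assemble_cohort()] table.
#' @param group Group label to subset; default `"ASD"`.
#' @param dvs DV columns; default the univariate follow-up family.
#' @return A tibble with one row per (DV, target) pair.
#' @export
run_partial_correlations <- function(cohort, group = "ASD", dvs = NULL) {
  if (is.null(dvs)) dvs <- attr(cohort, "dv_family")
  d <- tibble::as_tibble(unclass_cohort(cohort))
  d <- d[!is.na(d$group) & d$group == group, , drop = FALSE]
  rows <- list()
  for (dv in dvs) {
    for (target in c("iq", "sex")) {
      ctrl <- setdiff(c("iq", "sex"), target)
      pc <- partial_spearman(d, dv, target, covariates = ctrl)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = group, dv = dv, target = target,
        controlling = paste(ctrl, collapse = ","),
        rho = pc$rho, n = pc$n, p = pc$p_value, note = pc$note)
    }
  }
  do.call(rbind, rows)
}

#' Demographic group comparisons
#'
#' Descriptive comparisons of the two groups in the style of a cohort
#' characteristics table: equal-variance two-sample t-tests for
#' continuous descriptors and a Pearson chi-squared test (without
#' continuity correction) for the sex distribution.
#'
#' @param cohort A [assemble_cohort()] table (the full input rows are
#'   used, not only analysis-complete cases).
#' @param continuous Continuous descriptor columns; defaults to those of
#'   `age_months`, `iq`, `usable_seconds` present in the table.
#' @param categorical Categorical descriptor columns; default `"sex"`.
#' @return A tibble with `variable`, `test` (`"t"` or `"chi2"`),
#'   `statistic`, `df`, `p`, per-group summaries, and `note`.
#' @export
compare_demographics <- function(cohort,
                                 continuous = NULL,
                                 categorical = "sex") {
  d <- attr(cohort, "all_data")
  if (is.null(d)) d <- tibble::as_tibble(unclass_cohort(cohort))
  g <- factor(d$group)
  if (nlevels(g) != 2L) stop("both groups must be non-empty", call. = FALSE)
  if (is.null(continuous)) {
    continuous <- intersect(c("age_months", "iq", "usable_seconds"), names(d))
  }
  lv <- levels(g)
  rows <- list()
  for (v in continuous) {
    y <- as.numeric(d[[v]])
    ok <- is.finite(y)
    y1 <- y[ok & g == lv[1L]]; y2 <- y[ok & g == lv[2L]]
    if (length(y1) < 2L || length(y2) < 2L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, test = "t", statistic = NA_real_, df = NA_real_,
        p = NA_real_, summary1 = NA_character_, summary2 = NA_character_,
        note = "too few complete observations")
      next
    }
    tt <- tryCatch(stats::t.test(y1, y2, var.equal = TRUE),
                   error = function(e) NULL)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, test = "t",
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
      p = if (is.null(tt)) NA_real_ else tt$p.value,
      summary1 = sprintf("%.1f (%.1f)", mean(y1), stats::sd(y1)),
      summary2 = sprintf("%.1f (%.1f)", mean(y2), stats::sd(y2)),
      note = if (is.null(tt)) "t-test degenerate (constant data)"
             else NA_character_)
  }
  for (v in categorical) {
    tab <- table(g, d[[v]])
    if (ncol(tab) < 2L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, test = "chi2", statistic = NA_real_, df = NA_real_,
        p = NA_real_, summary1 = NA_character_, summary2 = NA_character_,
        note = "category absent; chi-squared skipped")
      next
    }
    cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, test = "chi2", statistic = unname(cs$statistic),
      df = unname(cs$parameter), p = cs$p.value,
      summary1 = paste(sprintf("%s:%d", colnames(tab), tab[1L, ]),
                       collapse = " "),
      summary2 = paste(sprintf("%s:%d", colnames(tab), tab[2L, ]),
                       collapse = " "),
      note = NA_character_)
  }
  do.call(rbind, rows)
}

#' Run the full group-level statistical battery
#'
#' Orchestrates the cohort analysis: assumption checks, the one-way
#' MANOVA on the six-DV set, the seven Bonferroni-corrected univariate
#' follow-up ANOVAs, covariate-controlled Spearman screens within the
#' clinical group, and demographic comparisons.
#'
#' @param cohort A [assemble_cohort()] table.
#' @param alpha Family-wise alpha for the follow-ups; default 0.05.
#' @param m_tests Follow-up family size; default the length of the
#'   cohort's `dv_family`.
#' @param correlation_group Group for the covariate screens; default
#'   `"ASD"`. Set to `NULL` to skip (e.g. when IQ is unavailable).
#' @return A `group_stats_report` list with components `manova`,
#'   `anovas` (named list of `anova_result`), `assumptions`,
#'   `partial_correlations`, `demographics`, `exclusions`, and
#'   `settings`.
#' @export
run_group_stats <- function(cohort, alpha = 0.05, m_tests = NULL,
                            correlation_group = "ASD") {
  family <- attr(cohort, "dv_family")
  if (is.null(m_tests)) m_tests <- length(family)
  anovas <- lapply(family, function(dv)
    run_anova(cohort, dv, m_tests = m_tests, alpha = alpha))
  names(anovas) <- family
  pcorr <- if (is.null(correlation_group)) NULL else
    run_partial_correlations(cohort, group = correlation_group)
  structure(
    list(
      manova = run_manova(cohort),
      anovas = anovas,
      assumptions = check_assumptions(cohort),
      partial_correlations = pcorr,
      demographics = compare_demographics(cohort),
      exclusions = attr(cohort, "exclusions"),
      settings = list(alpha = alpha, m_tests = m_tests,
                      bonferroni_threshold = bonferroni_threshold(alpha, m_tests),
                      dv_names = attr(cohort, "dv_names"),
                      dv_family = family)
    ),
    class = "group_stats_report"
  )
}

#' @export
print.group_stats_report <- function(x, ...) {
  cat("== Group statistics report ==\n")
  print(x$manova)
  cat(sprintf("Follow-up ANOVAs (Bonferroni threshold %.5f over %d tests):\n",
              x$settings$bonferroni_threshold, x$settings$m_tests))
  for (a in x$anovas) { cat("  "); print(a) }
  print(x$assumptions)
  if (!is.null(x$partial_correlations)) {
    sig <- sum(x$partial_correlations$p < 0.05, na.rm = TRUE)
    cat(sprintf("Partial Spearman screens: %d of %d at p < 0.05\n",
                sig, nrow(x$partial_correlations)))
  }
  if (nrow(x$exclusions) > 0L) {
    cat(sprintf("Excluded subjects (missing DVs): %s\n",
                paste(x$exclusions$subject_id, collapse = ", ")))
  }
  invisible(x)
}

#' Write a stats report to JSON
#'
#' Serializes a [run_group_stats()] report to machine-readable JSON.
#'
#' @param report A `group_stats_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(report, path) {
  x <- report
  x$manova <- unclass(x$manova)
  x$anovas <- lapply(x$anovas, unclass)
  x$assumptions <- unclass(x$assumptions)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
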