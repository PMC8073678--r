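cohort_from <- function(d) assemble_cohort(d)

test_that("Bonferroni threshold is alpha/m and exact under multiplication", {
  expect_equal(round(bonferroni_threshold(0.05, 7), 5), 0.00714)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  for (m in 1:20) expect_identical(bonferroni_threshold(0.04, m) * m, 0.04)
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})

test_that("two-group ANOVA reproduces hand-computed sums of squares", {
  d <- make_feature_cohort(3, 3, seed = 1)
  d$int_SI_au12 <- c(1, 2, 3, 4, 5, 6)
  a <- run_anova(cohort_from(d), "int_SI_au12", m_tests = 7)
  expect_equal(a$F, 13.5)         # SSB = 13.5, SSW = 4, F = 13.5/(4/4)
  expect_equal(a$df1, 1)
  expect_equal(a$df2, 4)
  expect_equal(a$partial_eta2, 13.5 / 17.5)
  expect_equal(sort(a$group_means), c(2, 5))

  d$int_SI_au12 <- rep(c(1, 2, 3), 2)
  a0 <- run_anova(cohort_from(d), "int_SI_au12")
  expect_equal(a0$F, 0)
  expect_equal(a0$partial_eta2, 0)
})

test_that("ANOVA agrees with the built-in linear-model fit on random data", {
  for (seed in 1:10) {
    d <- make_feature_cohort(sample(5:20, 1), sample(5:20, 1), seed = seed)
    a <- run_anova(cohort_from(d), "freq_SO")
    ref <- stats::anova(stats::lm(freq_SO ~ group, data = d))
    expect_equal(a$F, ref$`F value`[1])
    expect_equal(a$p_raw, ref$`Pr(>F)`[1])
    expect_equal(a$df2, ref$Df[2])
    expect_equal(a$partial_eta2,
                 ref$`Sum Sq`[1] / sum(ref$`Sum Sq`))
  }
})

test_that("degenerate zero-variance inputs follow the documented rules", {
  d <- make_feature_cohort(3, 3, seed = 2)
  d$dur_SI <- rep(2, 6)
  a <- run_anova(cohort_from(d), "dur_SI")
  expect_equal(a$F, 0)

  d$dur_SI <- rep(c(1, 2), c(3, 3))
  a2 <- run_anova(cohort_from(d), "dur_SI")
  expect_true(is.infinite(a2$F))
  expect_equal(a2$partial_eta2, 1)
})

test_that("partial eta squared is invariant under affine DV rescaling", {
  d <- make_feature_cohort(8, 8, seed = 3, shift = c(freq_SO = -1))
  a <- run_anova(cohort_from(d), "freq_SO")
  d2 <- d
  d2$freq_SO <- 7.3 * d2$freq_SO - 2.1
  a2 <- run_anova(cohort_from(d2), "freq_SO")
  expect_equal(a$partial_eta2, a2$partial_eta2)
  expect_equal(a$F, a2$F)
})

test_that("MANOVA on copied group means gives Pillai and F of zero", {
  d <- make_feature_cohort(10, 10, seed = 4)
  dvs <- followup_dv_names()
  d[d$group == "TD", dvs] <- d[d$group == "ASD", dvs]  # exact copies
  m <- run_manova(cohort_from(d))
  expect_equal(m$statistic_value, 0, tolerance = 1e-10)
  expect_equal(m$F_approx, 0, tolerance = 1e-10)
})

test_that("single-DV MANOVA F equals the univariate ANOVA F and t^2", {
  for (seed in 1:10) {
    d <- make_feature_cohort(sample(6:15, 1), sample(6:15, 1), seed = seed)
    m <- run_manova(cohort_from(d), dvs = "int_SI_au12")
    a <- run_anova(cohort_from(d), "int_SI_au12")
    expect_equal(m$F_approx, a$F, tolerance = 1e-10)
    tt <- stats::t.test(int_SI_au12 ~ group, data = d, var.equal = TRUE)
    expect_equal(m$F_approx, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("two-group Pillai F equals the Hotelling T^2 transform", {
  set.seed(40)
  for (rep in 1:10) {
    p <- sample(2:6, 1)
    n1 <- sample((p + 3):15, 1); n2 <- sample((p + 3):15, 1)
    d <- make_feature_cohort(n1, n2, seed = 40 + rep)
    dvs <- followup_dv_names()[seq_len(p)]
    m <- run_manova(cohort_from(d), dvs = dvs)
    ref <- hotelling_F(as.matrix(d[, dvs]), d$group)
    expect_equal(m$F_approx, ref$F, tolerance = 1e-8)
    expect_equal(m$df_between, ref$df1)
    expect_equal(m$df_error, ref$df2)
  }
})

test_that("MANOVA dfs follow (p, N - p - 1) and too-few cases error", {
  d <- make_feature_cohort(10, 8, seed = 5)
  m <- run_manova(cohort_from(d))
  expect_equal(m$df_between, 6)
  expect_equal(m$df_error, 18 - 6 - 1)
  tiny <- make_feature_cohort(3, 3, seed = 6)
  expect_error(run_manova(cohort_from(tiny)), "complete cases")
})

test_that("feature-level type-I error stays at the nominal level", {
  # both groups drawn from the same distribution; exact binomial 99%
  # band around alpha = 0.05 over 1000 replicates
  set.seed(777)
  rej <- 0L
  for (i in 1:1000) {
    d <- make_feature_cohort(15, 15)
    a <- run_anova(cohort_from(d), "int_SI_au12", m_tests = 1)
    rej <- rej + (a$p_raw < 0.05)
  }
  lo <- stats::qbinom(0.005, 1000, 0.05)
  hi <- stats::qbinom(0.995, 1000, 0.05)
  expect_gte(rej, lo)
  expect_lte(rej, hi)
})

test_that("assumption screen flags what it should on crafted cohorts", {
  d <- make_feature_cohort(10, 10, seed = 7)
  # plant a subject exactly at the complete-case DV centroid
  ct0 <- cohort_from(d)
  dvs <- attr(ct0, "dv_names")
  ctr_target <- colMeans(as.matrix(ct0[, dvs])[-1, , drop = FALSE])
  d[1, names(ctr_target)] <- as.list(ctr_target)
  d$int_SO_au12[1] <- ctr_target[["int_SO_composite"]]
  d$int_SO_au06[1] <- ctr_target[["int_SO_composite"]]
  ct <- cohort_from(d)
  rep_ <- check_assumptions(ct)
  i1 <- which(rep_$mahalanobis$subject_id == d$subject_id[1])
  ctr_dist <- rep_$mahalanobis$distance2[i1]
  expect_lt(ctr_dist, min(rep_$mahalanobis$distance2[-i1]))
  expect_equal(nrow(rep_$levene), length(dvs))
  expect_equal(nrow(rep_$shapiro), 2 * length(dvs))
  expect_false(rep_$multicollinearity_flag)

  # duplicated DV content -> perfect pairwise correlation, flag set,
  # and the MANOVA errors informatively
  d2 <- make_feature_cohort(10, 10, seed = 8)
  d2$dur_SO <- d2$dur_SI
  ct2 <- cohort_from(d2)
  rep2 <- check_assumptions(ct2)
  expect_equal(rep2$pairwise_pearson_max_r, 1.0)
  expect_true(rep2$multicollinearity_flag)
  expect_error(run_manova(ct2), "singular|rank|collinear")
})

test_that("Shapiro cells with too few observations are skipped with a note", {
  d <- make_feature_cohort(2, 10, seed = 9)
  rep_ <- check_assumptions(cohort_from(d))
  expect_true(any(grepl("skipped", rep_$notes)))
  expect_true(any(is.na(rep_$shapiro$W)))
})

test_that("partial Spearman matches the closed-form partial rank correlation", {
  set.seed(50)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    d <- tibble::tibble(x = stats::rnorm(n),
                        y = stats::rnorm(n),
                        z = stats::rnorm(n))
    pc <- partial_spearman(d, "x", "y", covariates = "z")
    rx <- rank(d$x); ry <- rank(d$y); rz <- rank(d$z)
    rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz)
    ryz <- stats::cor(ry, rz)
    ref <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(pc$rho, ref, tolerance = 1e-10)
    expect_equal(pc$n, n)
  }
})

test_that("partial Spearman is invariant under monotone transforms", {
  set.seed(51)
  d <- tibble::tibble(x = stats::rnorm(20), y = stats::rnorm(20),
                      iq = stats::rnorm(20), sex = rep(c("M", "F"), 10))
  a <- partial_spearman(d, "x", "y")
  d2 <- d
  d2$x <- exp(d2$x)
  d2$y <- d2$y^3
  b <- partial_spearman(d2, "x", "y")
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_value, b$p_value)
})

test_that("partial Spearman handles identical and degenerate inputs", {
  d <- tibble::tibble(x = c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5),
                      iq = c(80, 95, 70, 88, 101, 77, 90, 85),
                      sex = rep(c("M", "F"), 4))
  d$y <- d$x
  expect_equal(partial_spearman(d, "x", "y")$rho, 1, tolerance = 1e-12)

  d$y <- rep(2, 8)
  expect_true(is.na(partial_spearman(d, "x", "y")$rho))
  expect_match(partial_spearman(d, "x", "y")$note, "constant")

  few <- d[1:3, ]
  few$y <- few$x
  expect_match(partial_spearman(few, "x", "y")$note, "fewer than 4")
})

test_that("demographic comparisons use pooled t and Pearson chi-squared", {
  d <- make_feature_cohort(18, 15, seed = 10)
  d$sex <- rep("F", 33)
  d$sex[d$group == "ASD"][1:17] <- "M"
  d$sex[d$group == "TD"][1:13] <- "M"
  out <- compare_demographics(cohort_from(d))
  chi <- out[out$variable == "sex", ]
  # hand-computed Pearson chi-squared on the 2x2 table [[17,1],[13,2]]
  obs <- matrix(c(17, 13, 1, 2), 2)
  exp_ <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(chi$statistic, sum((obs - exp_)^2 / exp_))

  d$age_months <- rep(seq_len(33) %% 5, length.out = 33)
  d$age_months[d$group == "TD"] <- d$age_months[d$group == "ASD"][1:15]
  out2 <- compare_demographics(cohort_from(d), continuous = "age_months")
  expect_equal(out2$statistic[out2$variable == "age_months"], 0,
               tolerance = 1e-12)
})

test_that("the full battery assembles and serializes", {
  d <- make_feature_cohort(12, 12, seed = 11,
                           shift = c(int_SI_au12 = -1, freq_SO = -2))
  rep_ <- run_group_stats(cohort_from(d))
  expect_s3_class(rep_, "group_stats_report")
  expect_length(rep_$anovas, 7)
  expect_equal(rep_$settings$bonferroni_threshold, 0.05 / 7)
  expect_true(rep_$anovas$int_SI_au12$significant)
  expect_s3_class(rep_$partial_correlations, "tbl_df")
  expect_output(print(rep_), "MANOVA")

  p <- withr::local_tempfile(fileext = ".json")
  write_stats_json(rep_, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$manova$statistic_name, "Pillai")
  expect_equal(back$settings$m_tests, 7)
})
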