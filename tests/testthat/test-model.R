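ref <- frt_reference_model()

test_that("the published adjustment formulas evaluate verbatim", {
  # semantic FM raw 4, age 80: 4 + 3.553 * (log10(20) - 1.69)
  expect_equal(adjust_score(4, age = 80, subscale = "semantic_fm"),
               4 + 3.553 * (log10(20) - 1.69))
  expect_equal(round(adjust_score(4, age = 80, subscale = "semantic_fm"), 3),
               4 - 1.382)
  # failed recognition raw 2, age 90, female
  expect_equal(
    adjust_score(2, age = 90, sex = "F", subscale = "failed_recognition"),
    2 + 3.099 * (1 - 1.69) - 0.601 * (-0.42)
  )
  # free recall subtracts both demographic terms
  expect_equal(
    adjust_score(20, age = 70, education = 8, subscale = "free_recall"),
    20 - 10.23 * (log10(30) - 1.69) - 2.317 * (sqrt(8) - 3.54)
  )
})

test_that("adjustment is the identity at the centering covariates (all six subscales)", {
  dem <- centering_demographics()
  raws <- c(17, 29, 2, 4, 1, 5)
  for (i in seq_along(frt_subscales)) {
    s <- frt_subscales[i]
    if (s == "failed_recognition") {
      # the sex code never equals 0 for a single subject; the identity at
      # sex-centered 0 follows by linearity from the population-weighted
      # mean of the male and female adjustments (weights 0.42 M / 0.58 F)
      adj_m <- adjust_score(raws[i], age = dem$age, sex = "M", subscale = s)
      adj_f <- adjust_score(raws[i], age = dem$age, sex = "F", subscale = s)
      expect_equal(0.42 * adj_m + 0.58 * adj_f, raws[i], tolerance = 1e-12)
    } else {
      expect_equal(
        adjust_score(raws[i], age = dem$age, sex = dem$sex,
                     education = dem$education, subscale = s),
        raws[i], tolerance = 1e-12
      )
    }
  }
})

test_that("adjustment corrections have the orientation-correct signs", {
  # higher_better: older subjects gain, educated subjects lose
  ages <- c(30, 50, 70, 88)
  fr <- correction_at(age = ages, education = 12, subscale = "free_recall")
  expect_true(all(diff(fr) > 0))
  fr_edu <- correction_at(age = 50, education = c(5, 8, 13, 18),
                          subscale = "free_recall")
  expect_true(all(diff(fr_edu) < 0))
  # higher_worse: reversed
  tf <- correction_at(age = ages, education = 12, subscale = "total_fm")
  expect_true(all(diff(tf) < 0))
  tf_edu <- correction_at(age = 50, education = c(5, 8, 13, 18),
                          subscale = "total_fm")
  expect_true(all(diff(tf_edu) > 0))
})

test_that("adjust/correction enforce domains and required covariates", {
  expect_error(adjust_score(5, age = 17, subscale = "semantic_fm"),
               class = "frt_domain_error")
  expect_error(adjust_score(5, age = 101, subscale = "semantic_fm"),
               class = "frt_domain_error")
  expect_error(adjust_score(2, age = 50, subscale = "failed_recognition"),
               "requires sex", class = "frt_domain_error")
  expect_error(adjust_score(20, age = 50, subscale = "free_recall"),
               "requires education", class = "frt_domain_error")
  expect_error(adjust_score(5, age = 50, subscale = "lure_only"),
               class = "frt_domain_error")
})

test_that("OLS fitting matches the explicit normal-equations oracle", {
  set.seed(99)
  n <- 200
  cohort <- data.frame(
    subject_id = seq_len(n),
    age = sample(18:91, n, TRUE),
    sex = sample(c("M", "F"), n, TRUE),
    education = sample(2:20, n, TRUE)
  )
  t_age <- age_transform(cohort$age)
  t_edu <- education_transform(cohort$education)
  cohort$free_recall <- 18 + 5.0 * t_age + 1.0 * t_edu + rnorm(n, sd = 2)
  m <- fit_normative_model(cohort, "free_recall",
                           candidates = c("age", "education"),
                           select = FALSE)
  comp <- m$subscales$free_recall
  want <- oracle_ols(cbind(t_age, t_edu), cohort$free_recall)
  expect_equal(unname(comp$coef), unname(want[2:3]), tolerance = 1e-8)
  expect_equal(unname(comp$centering),
               c(mean(t_age), mean(t_edu)), tolerance = 1e-12)
})

test_that("selection controls false retention on pure-noise cohorts", {
  retained <- 0L
  none <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    set.seed(1000 + seed)
    n <- 500
    cohort <- data.frame(
      subject_id = seq_len(n),
      age = sample(18:91, n, TRUE),
      sex = sample(c("M", "F"), n, TRUE),
      education = sample(2:20, n, TRUE),
      semantic_fm = rnorm(n, 4, 2)
    )
    m <- fit_normative_model(cohort, "semantic_fm")
    k <- length(m$subscales$semantic_fm$coef)
    retained <- retained + k
    if (k == 0L) none <- none + 1L
  }
  # expected false-retention rate alpha = 0.05 per predictor
  expect_lte(retained / (3 * n_seeds), 0.10)
  expect_gte(none / n_seeds, 0.80)
})

test_that("degenerate covariates are rejected by name", {
  set.seed(4)
  cohort <- data.frame(
    subject_id = 1:60, age = sample(20:80, 60, TRUE), sex = "F",
    education = sample(2:20, 60, TRUE), free_recall = rnorm(60, 18, 4)
  )
  expect_error(fit_normative_model(cohort, "free_recall"),
               "sex", class = "frt_domain_error")
  expect_error(fit_normative_model(cohort[1:20, ], "free_recall",
                                   candidates = c("age", "education")),
               "too small", class = "frt_domain_error")
})

test_that("fit/adjust round-trip leaves adjusted scores uncorrelated with covariates", {
  cohort <- generate_cohort(cohort_config(n = 5000, seed = 31,
                                          discretize = FALSE))
  m <- fit_all_normative_models(cohort)
  adj <- adjust_cohort(cohort, m)
  tv <- transform_covariates(cohort$age, cohort$sex, cohort$education)
  for (s in frt_subscales) {
    for (p in names(m$subscales[[s]]$coef)) {
      expect_lt(abs(cor(adj[[s]], tv[[p]])), 0.02)
    }
  }
})

test_that("generating coefficients are recovered across replicate cohorts", {
  # structural scales (recognition, total_fm) inherit their coefficients
  # from the generated components; estimates are averaged over replicate
  # cohorts to push Monte-Carlo error well below the 5% radius
  implied <- list(
    free_recall = c(age = 10.23, education = 2.317),
    failed_recognition = c(age = -3.099, sex = 0.601),
    semantic_fm = c(age = -3.553),
    non_semantic_fm = c(age = -1.19, education = -0.261),
    total_fm = c(age = -(3.553 + 1.19), education = -0.261),
    recognition = c(age = 3.099 + 3.553 + 1.19, sex = -0.601,
                    education = 0.261)
  )
  seeds <- c(201, 202, 203, 204)
  est <- lapply(frt_subscales, function(s) matrix(
    NA_real_, length(seeds), length(implied[[s]]),
    dimnames = list(NULL, names(implied[[s]]))
  ))
  names(est) <- frt_subscales
  for (k in seq_along(seeds)) {
    cohort <- generate_cohort(cohort_config(n = 5000, seed = seeds[k],
                                            discretize = FALSE))
    for (s in frt_subscales) {
      m <- fit_normative_model(cohort, s,
                               candidates = names(implied[[s]]),
                               select = FALSE)
      est[[s]][k, ] <- m$subscales[[s]]$coef[colnames(est[[s]])]
    }
  }
  for (s in frt_subscales) {
    avg <- colMeans(est[[s]])
    se <- apply(est[[s]], 2, sd) / sqrt(length(seeds))
    for (p in names(implied[[s]])) {
      # 5% of the generating value, except where that is below the
      # Monte-Carlo noise floor of the averaged estimate (small education
      # and sex coefficients), where a 3-se bound applies
      tol <- max(0.05 * abs(implied[[s]][[p]]), 3 * se[[p]])
      expect_lt(abs(avg[[p]] - implied[[s]][[p]]), tol,
                label = sprintf("|bias| for %s:%s", s, p))
    }
  }
})

test_that("internal correlations handle duplicates, degeneracy and the structural limit", {
  set.seed(12)
  n <- 50
  cohort <- data.frame(
    free_recall = rnorm(n), recognition = rnorm(n),
    failed_recognition = rnorm(n), semantic_fm = rnorm(n),
    non_semantic_fm = 0, total_fm = 0
  )
  cohort$recognition <- cohort$free_recall           # duplicated column
  cohort$total_fm <- cohort$semantic_fm + cohort$non_semantic_fm
  res <- internal_correlations(cohort)
  expect_equal(res$r["free_recall", "recognition"], 1)
  expect_identical(res$degenerate, "non_semantic_fm")
  expect_true(is.na(res$r["non_semantic_fm", "semantic_fm"]))
  # var(non_semantic) -> 0 makes r(semantic, total) -> 1
  expect_equal(res$r["semantic_fm", "total_fm"], 1)
  expect_error(internal_correlations(cohort[1:2, ]),
               class = "frt_domain_error")
})

test_that("model JSON serialization round-trips", {
  cohort <- generate_cohort(cohort_config(n = 300, seed = 5))
  m <- fit_all_normative_models(cohort)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_s3_class(back, "frt_model")
  expect_equal(back$subscales, m$subscales, tolerance = 1e-12)
  expect_identical(back$source, m$source)
  # published model too
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(ref, path2)
  expect_equal(read_model_json(path2)$subscales, ref$subscales,
               tolerance = 1e-12)
})
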