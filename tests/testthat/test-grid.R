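ref <- frt_reference_model()

test_that("corrections evaluate the formulas exactly", {
  dem <- centering_demographics()
  expect_equal(correction_at(age = dem$age, education = dem$education,
                             subscale = "free_recall"), 0, tolerance = 1e-12)
  expect_equal(correction_at(age = 80, subscale = "semantic_fm"),
               3.553 * (log10(20) - 1.69))
  expect_equal(
    correction_at(age = 44, sex = "M", subscale = "failed_recognition"),
    3.099 * (log10(56) - 1.69) - 0.601 * 0.58
  )
})

test_that("every grid cell equals the formula at its representative demographics", {
  bands <- frt_demographic_bands()
  for (s in c("free_recall", "recognition", "total_fm")) {
    g <- build_grid(ref, s)
    want <- correction_at(age = g$cells$rep_age,
                          education = g$cells$rep_education,
                          model = ref, subscale = s)
    expect_lt(max(abs(g$cells$correction - want)), 1e-9)
    expect_equal(g$cells$correction_2dp, round(want, 2))
    expect_identical(nrow(g$cells), 28L)  # 7 age x 4 education
  }
  gf <- build_grid(ref, "failed_recognition")
  expect_identical(nrow(gf$cells), 14L)   # 7 age x 2 sex, no education
  want <- correction_at(age = gf$cells$rep_age, sex = gf$cells$sex,
                        model = ref, subscale = "failed_recognition")
  expect_lt(max(abs(gf$cells$correction - want)), 1e-9)
})

test_that("grid corrections follow the published sign pattern", {
  g <- build_grid(ref, "free_recall")
  m <- matrix(g$cells$correction, nrow = 7)  # age bands x education bands
  # increase with age within every education column
  expect_true(all(apply(m, 2, function(col) all(diff(col) > 0))))
  # decrease with education within every age row
  expect_true(all(apply(m, 1, function(row) all(diff(row) < 0))))
  # oldest/least-educated cell positive; youngest/most-educated negative
  expect_gt(m[7, 1], 0)
  expect_lt(m[1, 4], 0)
  # higher_worse scale reverses both monotonicities
  gt <- build_grid(ref, "total_fm")
  mt <- matrix(gt$cells$correction, nrow = 7)
  expect_true(all(apply(mt, 2, function(col) all(diff(col) < 0))))
  expect_true(all(apply(mt, 1, function(row) all(diff(row) > 0))))
})

test_that("extrapolated flags mirror empty normative cells", {
  g <- build_grid(ref, "free_recall")
  flag <- function(age_band, edu_band) {
    g$cells$extrapolated[g$cells$age_band == age_band &
                           g$cells$education_band == edu_band]
  }
  expect_true(flag("18-30", "1-5"))   # no 18-30 primary-educated subjects
  expect_true(flag("30-39", "1-5"))
  expect_true(flag("50-59", "1-5"))
  expect_true(flag("30-39", "6-8"))
  expect_true(flag("80+", ">13"))
  expect_false(flag("18-30", "9-13"))
  expect_false(flag("40-49", "1-5"))  # n = 1 cell is sampled, not extrapolated
  expect_false(any(build_grid(ref, "failed_recognition")$cells$extrapolated))
})

test_that("semantic and non-semantic FM get no grid", {
  expect_error(build_grid(ref, "semantic_fm"), "cut-offs",
               class = "frt_domain_error")
  expect_error(build_grid(ref, "non_semantic_fm"), class = "frt_domain_error")
  expect_error(build_grid(ref, "bogus"), class = "frt_domain_error")
})

test_that("adjust_via_grid agrees with the formula within the cell spread", {
  g <- build_grid(ref, "free_recall")
  bands <- frt_demographic_bands()
  # exact agreement at representative demographics
  for (i in sample(nrow(g$cells), 8)) {
    cell <- g$cells[i, ]
    res <- adjust_via_grid(20, age = cell$rep_age,
                           education = cell$rep_education, grid = g)
    expect_equal(res$adjusted,
                 20 + correction_at(age = cell$rep_age,
                                    education = cell$rep_education,
                                    subscale = "free_recall"),
                 tolerance = 1e-9)
    expect_identical(res$method, "grid")
  }
  # random subjects: deviation bounded by the within-cell formula range
  set.seed(21)
  for (k in 1:200) {
    age <- sample(18:91, 1)
    edu <- sample(2:20, 1)
    raw <- sample(0:36, 1)
    res <- adjust_via_grid(raw, age = age, education = edu, grid = g)
    exact <- raw + correction_at(age = age, education = edu,
                                 subscale = "free_recall")
    ai <- which(bands$age$lo <= age & age <= bands$age$hi)
    ei <- which(bands$education$lo <= edu & edu <= bands$education$hi)
    corners <- expand.grid(a = unlist(bands$age[ai, c("lo", "hi")]),
                           e = unlist(bands$education[ei, c("lo", "hi")]))
    spread <- diff(range(correction_at(age = corners$a, education = corners$e,
                                       subscale = "free_recall")))
    expect_lte(abs(res$adjusted - exact), spread + 1e-9)
  }
})

test_that("demographics outside the covariate domain error; outside bands fall back to formula", {
  g <- build_grid(ref, "free_recall")
  expect_error(adjust_via_grid(18, age = 17, education = 10, grid = g),
               class = "frt_domain_error")
  # education below every band (0 years) -> formula fallback, flagged
  res <- adjust_via_grid(18, age = 50, education = 0.5, grid = g)
  expect_identical(res$method, "formula")
  expect_true(res$extrapolated)
  expect_equal(res$adjusted,
               18 + correction_at(age = 50, education = 0.5,
                                  subscale = "free_recall"))
})

test_that("ES is invariant to grid vs formula adjustment at representative demographics", {
  cohort <- generate_cohort(cohort_config(n = 232, seed = 77))
  nm <- suppressMessages(run_norms(cohort, model = "published"))
  g <- nm$grids$free_recall
  tab <- nm$es_tables$free_recall
  set.seed(3)
  for (i in sample(nrow(g$cells), 6)) {
    cell <- g$cells[i, ]
    raw <- sample(5:30, 1)
    via_grid <- adjust_via_grid(raw, age = cell$rep_age,
                                education = cell$rep_education,
                                grid = g)$adjusted
    via_formula <- adjust_score(raw, age = cell$rep_age,
                                education = cell$rep_education,
                                model = nm$model, subscale = "free_recall")
    expect_identical(assign_es(via_grid, tab), assign_es(via_formula, tab))
  }
})

test_that("grid CSV export round-trips the cells", {
  g <- build_grid(ref, "total_fm")
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  back <- utils::read.csv(path)
  expect_equal(back$correction, g$cells$correction)
  expect_equal(back$extrapolated, g$cells$extrapolated)
})
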