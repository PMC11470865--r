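#' Normative-sample demographic structure
#'
#' Cell counts of the published normative sample (n = 232) by education
#' band x age band x sex, decoded from the demographic table. Row/column
#' totals: 23/26/92/91 by education, 97/16/17/38/24/24/16 by age band,
#' 134 F / 98 M. (The study text reports "99 male"; the table's cells sum
#' to 98 - the one-subject discrepancy is in the source and is left as
#' the table states.)
#'
#' @return List of two 4 x 7 integer matrices `F` and `M`
#'   (education bands x age bands).
#' @export
frt_table1_counts <- function() {
  age_bands <- c("18-30", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")
  edu_bands <- c("1-5", "6-8", "9-13", ">13")
  Fm <- matrix(c(
    0, 0, 1, 0, 2, 8, 8,
    1, 0, 1, 4, 4, 3, 0,
    17, 1, 8, 12, 3, 6, 2,
    31, 7, 1, 10, 3, 1, 0
  ), nrow = 4L, byrow = TRUE, dimnames = list(edu_bands, age_bands))
  Mm <- matrix(c(
    0, 0, 0, 0, 0, 1, 3,
    3, 0, 1, 2, 2, 2, 3,
    22, 5, 1, 4, 8, 3, 0,
    23, 3, 4, 6, 2, 0, 0
  ), nrow = 4L, byrow = TRUE, dimnames = list(edu_bands, age_bands))
  list(F = Fm, M = Mm)
}

# integer age support per age band (upper band capped at the sample's
# oldest participant, 91)
frt_age_support <- list(
  "18-30" = 18:29, "30-39" = 30:39, "40-49" = 40:49, "50-59" = 50:59,
  "60-69" = 60:69, "70-79" = 70:79, "80+" = 80:91
)

# within-band education (years) support and weights, concentrated on the
# Italian terminal attainments (5, 8, 13, 18); chosen once so the sampled
# cohort reproduces the normative means of education (~12.97) and of
# sqrt(education) (~3.54)
frt_edu_support <- list(
  "1-5" = list(values = 2:5, weights = c(1, 1, 2, 4)),
  "6-8" = list(values = 6:8, weights = c(1, 1, 3)),
  "9-13" = list(values = 9:13, weights = c(1, 1, 1, 1, 10)),
  ">13" = list(values = 14:20, weights = c(1, 1, 2, 1, 8, 1, 1))
)

#' Published marginal descriptives of the six subscores
#'
#' Mean, SD, median and observed range of each raw subscore in the
#' normative sample; the generator's default intercepts and its
#' calibration targets.
#'
#' @return data.frame keyed by subscale.
#' @export
frt_reference_descriptives <- function() {
  data.frame(
    subscale = frt_subscales,
    mean = c(17.49, 29.35, 2.15, 4.24, 0.26, 4.50),
    sd = c(4.88, 2.97, 1.89, 2.02, 0.68, 2.35),
    median = c(18, 29, 2, 4, 0, 4),
    min_obs = c(0, 0, 0, 0, 0, 0),
    max_obs = c(29, 36, 11, 9, 4, 11),
    row.names = frt_subscales
  )
}

# scales drawn directly; recognition and total_fm are structural identities
frt_generated_scales <- c("free_recall", "failed_recognition",
                          "semantic_fm", "non_semantic_fm")

# one-time calibration (scratch/calibrate.R): latent loadings, residual
# sds and the non-semantic latent offset chosen so the discretized n=5000
# cohort matches the published marginal SDs and the within-test
# correlation block; frozen here, not tuned per run
frt_gen_defaults <- list(
  ability = c(free_recall = 2.7639, failed_recognition = -0.8492,
              semantic_fm = -0.1375, non_semantic_fm = -1.3698),
  bias = c(free_recall = 0, failed_recognition = -0.6927,
           semantic_fm = 1.5219, non_semantic_fm = 1.0849),
  noise_sd = c(free_recall = 2.2612, failed_recognition = 1.6463,
               semantic_fm = 1.3099, non_semantic_fm = 0.1005),
  nonsem_offset = -1.4608
)

#' Configuration for the synthetic cohort generator
#'
#' The defaults ARE the published normative conditions: n = 232 subjects
#' drawn from the demographic cell frequencies of the normative sample,
#' raw scores generated from the published regression coefficients around
#' the published subscore means, with residual structure (two latent
#' factors - general memory ability and liberal response bias - plus
#' Gaussian noise) calibrated once so the discretized cohort reproduces
#' the published marginal SDs and within-test correlations.
#'
#' @param n Cohort size (default 232).
#' @param seed RNG seed (`NULL` = leave RNG state alone).
#' @param demographic_source `"table1"` (normative cell frequencies) or
#'   `"uniform"` (age uniform on 18-91, education uniform on 2-20, sex
#'   Bernoulli(99/232) male).
#' @param coefficients Per-subscale named coefficient vectors on the
#'   transformed-covariate scale for the four directly generated scales
#'   (free recall, failed recognition, semantic FM, non-semantic FM);
#'   default: the published model.
#' @param intercepts Expected raw score at the centering demographics;
#'   default: published means. Must lie within the score ranges.
#' @param noise_sd Per-scale residual sd (calibrated defaults).
#' @param ability,bias Latent-factor loadings (calibrated defaults).
#' @param nonsem_offset Latent shift applied to non-semantic FM before
#'   rounding/clamping in discretized mode only: the observed scale is
#'   zero-inflated (median 0), which a Gaussian centered on the mean
#'   cannot reproduce. See the methods vignette.
#' @param discretize Round to integers, clamp to score ranges and
#'   re-derive the identity scores (default `TRUE`).
#' @return An object of class `frt_cohort_config`.
#' @export
cohort_config <- function(n = 232L, seed = NULL,
                          demographic_source = c("table1", "uniform"),
                          coefficients = NULL, intercepts = NULL,
                          noise_sd = frt_gen_defaults$noise_sd,
                          ability = frt_gen_defaults$ability,
                          bias = frt_gen_defaults$bias,
                          nonsem_offset = frt_gen_defaults$nonsem_offset,
                          discretize = TRUE) {
  demographic_source <- match.arg(demographic_source)
  stopifnot_scalar_number(n, "n", lo = 1)
  if (is.null(coefficients)) {
    ref <- frt_reference_model()
    coefficients <- lapply(ref$subscales[frt_generated_scales], `[[`, "coef")
  }
  if (is.null(intercepts)) {
    desc <- frt_reference_descriptives()
    intercepts <- stats::setNames(desc[frt_generated_scales, "mean"],
                                  frt_generated_scales)
  }
  for (s in frt_generated_scales) {
    rng <- frt_score_ranges[[s]]
    if (is.na(intercepts[[s]]) || intercepts[[s]] < rng[1L] ||
        intercepts[[s]] > rng[2L]) {
      frt_domain_error(sprintf(
        "intercept for '%s' (%g) outside its score range [%d, %d]",
        s, intercepts[[s]], rng[1L], rng[2L]
      ))
    }
  }
  if (any(noise_sd < 0)) frt_domain_error("noise_sd must be >= 0")
  structure(
    list(n = as.integer(n), seed = seed,
         demographic_source = demographic_source,
         coefficients = coefficients, intercepts = intercepts,
         noise_sd = noise_sd, ability = ability, bias = bias,
         nonsem_offset = nonsem_offset, discretize = isTRUE(discretize)),
    class = "frt_cohort_config"
  )
}

#' Sample demographics for a synthetic cohort
#'
#' With `demographic_source = "table1"`, draws (age band x education band
#' x sex) cells with probabilities proportional to the normative cell
#' counts, then an integer age uniform within the band and an integer
#' education from the within-band attainment weights. With `"uniform"`,
#' age ~ Uniform{18..91}, education ~ Uniform{2..20}, sex ~
#' Bernoulli(99/232) male. Deterministic under a fixed `config$seed`.
#'
#' @param config An [cohort_config()].
#' @return data.frame with `subject_id`, `age`, `sex`, `education`.
#' @export
sample_demographics <- function(config = cohort_config()) {
  if (!inherits(config, "frt_cohort_config")) {
    frt_domain_error("'config' must be an frt_cohort_config")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  if (config$demographic_source == "uniform") {
    out <- data.frame(
      subject_id = sprintf("sim%05d", seq_len(n)),
      age = sample(18:91, n, replace = TRUE),
      sex = ifelse(stats::runif(n) < 99 / 232, "M", "F"),
      education = sample(2:20, n, replace = TRUE)
    )
    return(out)
  }
  counts <- frt_table1_counts()
  cells <- rbind(
    data.frame(expand.grid(edu_band = rownames(counts$F),
                           age_band = colnames(counts$F),
                           stringsAsFactors = FALSE),
               sex = "F", count = as.vector(counts$F)),
    data.frame(expand.grid(edu_band = rownames(counts$M),
                           age_band = colnames(counts$M),
                           stringsAsFactors = FALSE),
               sex = "M", count = as.vector(counts$M))
  )
  cells <- cells[cells$count > 0L, ]
  idx <- sample(nrow(cells), n, replace = TRUE, prob = cells$count)
  age <- vapply(cells$age_band[idx], function(b) {
    sup <- frt_age_support[[b]]
    sup[sample.int(length(sup), 1L)]
  }, integer(1L))
  education <- vapply(cells$edu_band[idx], function(b) {
    sup <- frt_edu_support[[b]]
    sup$values[sample.int(length(sup$values), 1L, prob = sup$weights)]
  }, integer(1L))
  data.frame(
    subject_id = sprintf("sim%05d", seq_len(n)),
    age = as.integer(age),
    sex = cells$sex[idx],
    education = as.integer(education)
  )
}

#' Generate FRT raw scores for given demographics
#'
#' For each subject, the four directly generated scales are drawn as
#' `intercept + sum B_j (x_j - c_j) + lambda_a * ability + lambda_b * bias
#' + noise` on the transformed-covariate scale (centering 1.69 / 3.54 /
#' centered sex code), so older age worsens and education improves each
#' scale per its orientation. The identity scales follow structurally:
#' `total_fm = semantic_fm + non_semantic_fm` and
#' `recognition = 36 - failed_recognition - total_fm`. With
#' `discretize = TRUE`, scores are rounded, clamped to their printed
#' ranges (non-semantic FM receives its calibrated zero-inflation offset
#' first) and the identity scales re-derived so the structural invariants
#' hold exactly.
#'
#' Seeding: uses `config$seed + 1` so that demographics (seeded at
#' `config$seed`) and scores use distinct deterministic streams.
#'
#' @param demographics data.frame from [sample_demographics()] (or any
#'   frame with `age`, `sex`, `education`).
#' @param config An [cohort_config()].
#' @return data.frame: demographics plus the six score columns. If the
#'   noiseless linear predictor falls outside the score range for more
#'   than half the subjects on any scale, a warning is attached.
#' @export
generate_scores <- function(demographics, config = cohort_config()) {
  if (!inherits(config, "frt_cohort_config")) {
    frt_domain_error("'config' must be an frt_cohort_config")
  }
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- nrow(demographics)
  z_age <- age_transform(demographics$age) - 1.69
  z_edu <- education_transform(demographics$education) - 3.54
  z_sex <- sex_code(demographics$sex)

  g_ability <- stats::rnorm(n)
  g_bias <- stats::rnorm(n)

  lp <- function(scale) {
    cf <- config$coefficients[[scale]]
    v <- rep(config$intercepts[[scale]], n)
    if ("age" %in% names(cf)) v <- v + cf[["age"]] * z_age
    if ("education" %in% names(cf)) v <- v + cf[["education"]] * z_edu
    if ("sex" %in% names(cf)) v <- v + cf[["sex"]] * z_sex
    v
  }

  cont <- list()
  for (s in frt_generated_scales) {
    mu <- lp(s)
    rng <- frt_score_ranges[[s]]
    frac_out <- mean(mu < rng[1L] | mu > rng[2L])
    if (frac_out > 0.5) {
      warning(sprintf(
        "coefficients imply out-of-range mean %s for %.0f%% of subjects",
        s, 100 * frac_out
      ), call. = FALSE)
    }
    cont[[s]] <- mu +
      (config$ability[[s]] %||% 0) * g_ability +
      (config$bias[[s]] %||% 0) * g_bias +
      stats::rnorm(n, sd = config$noise_sd[[s]])
  }

  if (config$discretize) {
    cont$non_semantic_fm <- cont$non_semantic_fm + config$nonsem_offset
    for (s in frt_generated_scales) {
      rng <- frt_score_ranges[[s]]
      cont[[s]] <- pmin(pmax(round(cont[[s]]), rng[1L]), rng[2L])
    }
  }
  total_fm <- cont$semantic_fm + cont$non_semantic_fm
  recognition <- 36 - cont$failed_recognition - total_fm

  out <- demographics
  out$free_recall <- cont$free_recall
  out$recognition <- recognition
  out$failed_recognition <- cont$failed_recognition
  out$semantic_fm <- cont$semantic_fm
  out$non_semantic_fm <- cont$non_semantic_fm
  out$total_fm <- total_fm
  out
}

#' Generate a complete synthetic normative cohort
#'
#' [sample_demographics()] followed by [generate_scores()].
#'
#' @param config An [cohort_config()].
#' @return Cohort data.frame (demographics + six scores).
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 232, seed = 1))
#' colMeans(cohort[frt_subscales])
#' @export
generate_cohort <- function(config = cohort_config()) {
  generate_scores(sample_demographics(config), config)
}

#' Read / write cohort CSV files
#'
#' Fixed-header dialect: `subject_id, age, sex, education` plus the six
#' raw-score columns named as in [frt_subscales]. Extra columns (e.g.
#' external instruments) are carried through untouched but never
#' modelled.
#'
#' @param path CSV path.
#' @param cohort Cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) frt_stop("frt_io_error", sprintf("cannot read '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cohort_schema(df)
  df
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  check_cohort_schema(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
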