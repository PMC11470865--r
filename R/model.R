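#' The published normative model
#'
#' Retained predictors and unstandardized coefficients of the multiple
#' regressions of each raw FRT subscore on transformed demographics, stored
#' exactly as printed, together with the centering constants (1.69 for
#' `log10(100 - age)`, 3.54 for `sqrt(education)`; the sex code -0.42/0.58
#' is already centered) and each scale's orientation. The adjustment rule
#' is uniform across subscales:
#'
#' `adjusted = raw - sum_j B_j * (x_j - c_j)`
#'
#' with the signed `B_j` below, which reproduces the six printed formulas
#' verbatim (higher-better scales have positive `B`, so demographic terms
#' are subtracted; higher-worse scales have negative `B`, so they are
#' added):
#'
#' | subscale | age B | sex B | education B |
#' |---|---|---|---|
#' | free_recall | 10.23 | - | 2.317 |
#' | recognition | 6.771 | - | 0.693 |
#' | failed_recognition | -3.099 | 0.601 | - |
#' | semantic_fm | -3.553 | - | - |
#' | non_semantic_fm | -1.19 | - | -0.261 |
#' | total_fm | -3.837 | - | -0.698 |
#'
#' Fit statistics (R, R^2, F, p) are carried as printed reference metadata
#' and never used in computation. Adjusted scores are real-valued; no
#' clamping to the raw range is applied (Equivalent-Score bands, not
#' ranges, interpret them).
#'
#' @return An object of class `frt_model`.
#' @export
frt_reference_model <- function() {
  cent <- c(age = 1.69, education = 3.54, sex = 0)
  mk <- function(coef, fit) {
    list(coef = coef,
         centering = cent[names(coef)],
         edu_transform = "sqrt",
         fit = fit)
  }
  subscales <- list(
    free_recall = mk(c(age = 10.23, education = 2.317),
                     list(R = 0.705, R2 = 0.497, F = 113.113, p = "<0.001")),
    recognition = mk(c(age = 6.771, education = 0.693),
                     list(R = 0.609, R2 = 0.376, F = 7.385, p = "<0.001")),
    failed_recognition = mk(c(age = -3.099, sex = 0.601),
                            list(R = 0.368, R2 = 0.135, F = 17.897,
                                 p = "<0.001")),
    semantic_fm = mk(c(age = -3.553),
                     list(R = 0.381, R2 = 0.145, F = 39.125, p = "<0.001")),
    non_semantic_fm = mk(c(age = -1.19, education = -0.261),
                         list(R = 0.583, R2 = 0.339, F = 58.805,
                              p = "<0.001")),
    total_fm = mk(c(age = -3.837, education = -0.698),
                  list(R = 0.507, R2 = 0.257, F = 39.553, p = "<0.001"))
  )
  for (s in names(subscales)) {
    subscales[[s]]$orientation <- unname(frt_orientations[s])
  }
  structure(
    list(subscales = subscales, source = "published",
         schema_version = frt_schema_version),
    class = "frt_model"
  )
}

model_component <- function(model, subscale) {
  if (!inherits(model, "frt_model")) {
    frt_domain_error("'model' must be an frt_model")
  }
  match_subscale(subscale)
  comp <- model$subscales[[subscale]]
  if (is.null(comp)) {
    frt_domain_error(sprintf("model has no component for subscale '%s'",
                             subscale))
  }
  comp
}

# demographic terms sum_j B_j (x_j - c_j) for one subscale; the normative
# covariate domain is age 18-99, education 0-20+ (>= 0)
demographic_terms <- function(age, sex, education, comp, subscale) {
  if (any(age < 18 | age >= 100)) {
    frt_domain_error("age outside the normative domain [18, 99]")
  }
  terms <- 0
  cf <- comp$coef
  if ("age" %in% names(cf)) {
    terms <- terms + cf[["age"]] * (age_transform(age) - comp$centering[["age"]])
  }
  if ("education" %in% names(cf)) {
    if (is.null(education)) {
      frt_domain_error(sprintf("subscale '%s' requires education", subscale))
    }
    t_edu <- education_transform(education, comp$edu_transform %||% "sqrt")
    terms <- terms + cf[["education"]] * (t_edu - comp$centering[["education"]])
  }
  if ("sex" %in% names(cf)) {
    if (is.null(sex)) {
      frt_domain_error(sprintf("subscale '%s' requires sex", subscale))
    }
    terms <- terms + cf[["sex"]] * (sex_code(sex) - comp$centering[["sex"]])
  }
  terms
}

#' Demographically adjust a raw score
#'
#' Implements `adjusted = raw - sum_j B_j (x_j - c_j)` for the requested
#' subscale. At the centering covariates the adjustment is the identity.
#' The result is real-valued (not rounded); round only for presentation.
#'
#' @param raw Raw score(s).
#' @param age,sex,education Demographics (vectors recycled against `raw`).
#'   Covariates not used by the subscale's model may be `NULL`.
#' @param model An [frt_model] (default: the published model).
#' @param subscale One of [frt_subscales].
#' @return Numeric adjusted score(s).
#' @examples
#' # an 80-year-old's semantic false memory of 4 is corrected downward:
#' adjust_score(4, age = 80, subscale = "semantic_fm")
#' @export
adjust_score <- function(raw, age, sex = NULL, education = NULL,
                         model = frt_reference_model(), subscale) {
  comp <- model_component(model, subscale)
  as.numeric(raw) - demographic_terms(age, sex, education, comp, subscale)
}

#' Additive demographic correction
#'
#' The signed correction such that `adjusted = raw + correction`, i.e.
#' `adjust_score(0, ...)`: exact formula evaluation, no grid involved.
#'
#' @inheritParams adjust_score
#' @export
correction_at <- function(age, sex = NULL, education = NULL,
                          model = frt_reference_model(), subscale) {
  adjust_score(0, age = age, sex = sex, education = education,
               model = model, subscale = subscale)
}

#' Adjust all six subscores of a cohort
#'
#' @param cohort data.frame with `age`, `sex`, `education` and the six raw
#'   score columns (see [frt_subscales]).
#' @param model An [frt_model].
#' @return data.frame of adjusted scores (same six columns).
#' @export
adjust_cohort <- function(cohort, model = frt_reference_model()) {
  check_cohort_schema(cohort)
  out <- cohort[intersect("subject_id", names(cohort))]
  for (s in names(model$subscales)) {
    out[[s]] <- adjust_score(cohort[[s]], age = cohort$age, sex = cohort$sex,
                             education = cohort$education,
                             model = model, subscale = s)
  }
  out
}

check_cohort_schema <- function(cohort, scores = frt_subscales) {
  need <- c("age", "sex", "education", scores)
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    frt_schema_error(sprintf("cohort is missing column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  invisible(cohort)
}

#' Fit a normative regression model for one subscale
#'
#' Ordinary least squares of the raw score on transformed covariates,
#' mirroring the published procedure: candidate predictors are transformed
#' age `log10(100 - age)`, education (square root, or raw years for
#' screening failed recognition) and the centered male indicator; the
#' multiple model is fitted and, when `select = TRUE`, predictors with
#' `p >= alpha` are dropped and the model refitted on the survivors.
#' Centering constants are the cohort means of the transformed covariates
#' (the sex code is re-centered at the cohort male share), so the fitted
#' adjustment is the identity at the cohort's demographic centroid.
#'
#' @param cohort data.frame with `age`, `sex`, `education` and the raw
#'   score column for `subscale`. Needs `n >= 30`.
#' @param subscale One of [frt_subscales].
#' @param candidates Candidate predictors, subset of
#'   `c("age", "sex", "education")`.
#' @param alpha Retention threshold on the multiple-model p-values
#'   (default 0.05).
#' @param edu_transform `"sqrt"` (default) or `"identity"`.
#' @param select Drop non-significant predictors (default `TRUE`); with
#'   `FALSE` all candidates are retained regardless of p-value.
#' @return A single-component [frt_model] (access via
#'   `$subscales[[subscale]]`) with coefficients, centering constants and
#'   fit statistics (R, R2, F, p, per-predictor p-values, residual sd).
#' @export
fit_normative_model <- function(cohort, subscale,
                                candidates = c("age", "sex", "education"),
                                alpha = 0.05,
                                edu_transform = c("sqrt", "identity"),
                                select = TRUE) {
  match_subscale(subscale)
  edu_transform <- match.arg(edu_transform)
  candidates <- match.arg(candidates, several.ok = TRUE)
  check_cohort_schema(cohort, scores = subscale)
  n <- nrow(cohort)
  if (n < 30L) {
    frt_domain_error(sprintf("cohort size %d < 30; too small to fit norms", n))
  }
  y <- as.numeric(cohort[[subscale]])

  X <- data.frame(row.names = seq_len(n))
  if ("age" %in% candidates) X$age <- age_transform(cohort$age)
  if ("education" %in% candidates) {
    X$education <- education_transform(cohort$education, edu_transform)
  }
  if ("sex" %in% candidates) {
    male <- sex_code(cohort$sex) + frt_male_share  # back to 0/1 indicator
    X$sex <- male - mean(male)
  }
  degenerate <- vapply(X, function(v) stats::var(v) == 0, logical(1L))
  if (any(degenerate)) {
    frt_domain_error(sprintf(
      "degenerate covariate(s) with zero variance: %s",
      paste(names(X)[degenerate], collapse = ", ")
    ))
  }

  fit_once <- function(Xk) {
    if (ncol(Xk) == 0L) return(NULL)
    stats::lm(y ~ ., data = cbind(y = y, Xk))
  }
  fit <- fit_once(X)
  retained <- names(X)
  if (select && !is.null(fit)) {
    pvals <- summary(fit)$coefficients[-1L, 4L]
    retained <- names(X)[pvals < alpha]
    fit <- fit_once(X[, retained, drop = FALSE])
  }

  cent <- c(age = 1.69, education = 3.54, sex = 0)  # placeholder shape
  cent["age"] <- if ("age" %in% names(X)) mean(X$age) else NA_real_
  cent["education"] <- if ("education" %in% names(X)) mean(X$education)
                       else NA_real_
  cent["sex"] <- 0  # sex predictor is mean-centered by construction

  if (is.null(fit)) {
    coef_out <- stats::setNames(numeric(0), character(0))
    fitstats <- list(R = 0, R2 = 0, F = NA_real_, p = NA_real_,
                     p_values = stats::setNames(numeric(0), character(0)),
                     sigma = stats::sd(y), n = n)
  } else {
    sm <- summary(fit)
    coef_out <- stats::coef(fit)[-1L]
    names(coef_out) <- retained
    fstat <- sm$fstatistic
    fitstats <- list(
      R = sqrt(sm$r.squared), R2 = sm$r.squared,
      F = unname(fstat[1L]),
      p = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                           lower.tail = FALSE)),
      p_values = stats::setNames(sm$coefficients[-1L, 4L], retained),
      sigma = sm$sigma, n = n
    )
  }

  comp <- list(
    coef = coef_out,
    centering = cent[names(coef_out)],
    edu_transform = edu_transform,
    orientation = unname(frt_orientations[subscale]),
    fit = fitstats
  )
  out <- list(subscales = stats::setNames(list(comp), subscale),
              source = "fitted", schema_version = frt_schema_version)
  class(out) <- "frt_model"
  out
}

#' Fit normative models for all six subscales
#'
#' Runs [fit_normative_model()] per subscale (failed recognition screens
#' education untransformed, matching the published procedure) and merges
#' the components into one [frt_model].
#'
#' @inheritParams fit_normative_model
#' @export
fit_all_normative_models <- function(cohort,
                                     candidates = c("age", "sex", "education"),
                                     alpha = 0.05, select = TRUE) {
  comps <- lapply(frt_subscales, function(s) {
    m <- fit_normative_model(
      cohort, s, candidates = candidates, alpha = alpha,
      edu_transform = if (s == "failed_recognition") "identity" else "sqrt",
      select = select
    )
    m$subscales[[s]]
  })
  structure(
    list(subscales = stats::setNames(comps, frt_subscales),
         source = "fitted", schema_version = frt_schema_version),
    class = "frt_model"
  )
}

#' @export
print.frt_model <- function(x, ...) {
  cat(sprintf("FRT normative model (%s)\n", x$source))
  for (s in names(x$subscales)) {
    comp <- x$subscales[[s]]
    if (!length(comp$coef)) {
      cat(sprintf("  %-18s : no retained predictors\n", s))
    } else {
      cat(sprintf("  %-18s : %s\n", s,
                  paste(sprintf("%s = %.4g", names(comp$coef), comp$coef),
                        collapse = ", ")))
    }
  }
  invisible(x)
}

#' Pearson correlations among the six FRT subscores
#'
#' Used to validate synthetic cohorts against the published within-test
#' correlation block. Pairs involving a zero-variance column are flagged
#' and reported as `NA`.
#'
#' @param cohort data.frame containing the six score columns.
#' @return List with matrices `r` and `p` (6 x 6) and a character vector
#'   `degenerate` naming zero-variance columns.
#' @export
internal_correlations <- function(cohort) {
  missing <- setdiff(frt_subscales, names(cohort))
  if (length(missing)) {
    frt_schema_error(sprintf("cohort is missing score column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  if (nrow(cohort) < 3L) frt_domain_error("need n >= 3 for correlations")
  sc <- as.matrix(cohort[frt_subscales])
  degenerate <- frt_subscales[apply(sc, 2L, stats::var) == 0]
  k <- length(frt_subscales)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(frt_subscales,
                                                   frt_subscales))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (frt_subscales[i] %in% degenerate ||
          frt_subscales[j] %in% degenerate) next
      ct <- stats::cor.test(sc[, i], sc[, j])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p, degenerate = degenerate)
}

#' Serialize / deserialize a normative model as JSON
#'
#' Versioned, full-precision JSON so that write-then-read reproduces the
#' model exactly.
#'
#' @param model An [frt_model].
#' @param path Output / input path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(serialize_model(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

# named atomic vectors must become lists to keep their names in JSON
named_as_list <- function(x) if (is.null(x)) NULL else as.list(x)

serialize_model <- function(model) {
  if (!inherits(model, "frt_model")) {
    frt_domain_error("'model' must be an frt_model")
  }
  raw <- unclass(model)
  raw$subscales <- lapply(raw$subscales, function(comp) {
    comp$coef <- named_as_list(comp$coef)
    comp$centering <- named_as_list(comp$centering)
    if (!is.null(comp$fit$p_values)) {
      comp$fit$p_values <- named_as_list(comp$fit$p_values)
    }
    comp
  })
  raw
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rehydrate_model(raw)
}

# rebuild an frt_model from parsed JSON (shared by model and norms readers)
rehydrate_model <- function(raw) {
  if (!identical(as.integer(raw$schema_version), frt_schema_version)) {
    frt_schema_error(sprintf("unsupported model schema_version: %s",
                             raw$schema_version %||% "<missing>"))
  }
  empty_named <- stats::setNames(numeric(0), character(0))
  for (s in names(raw$subscales)) {
    comp <- raw$subscales[[s]]
    cf <- unlist(comp$coef)
    comp$coef <- if (is.null(cf)) empty_named else cf
    cv <- unlist(comp$centering)
    comp$centering <- if (is.null(cv)) empty_named else cv
    # JSON nulls drop NA fit fields of predictor-free models; restore the
    # canonical shape and field order
    fit <- comp$fit
    if (!is.null(fit)) {
      pv <- unlist(fit$p_values)
      comp$fit <- list(
        R = fit$R %||% NA_real_, R2 = fit$R2 %||% NA_real_,
        F = fit$F %||% NA_real_, p = fit$p %||% NA_real_,
        p_values = if (is.null(pv)) empty_named else pv,
        sigma = fit$sigma %||% NA_real_, n = fit$n %||% NA_integer_
      )
      # published models carry only the printed R/R2/F/p
      if (is.null(fit$sigma) && is.null(fit$p_values)) {
        comp$fit <- fit
      }
    }
    raw$subscales[[s]] <- comp
  }
  structure(list(subscales = raw$subscales, source = raw$source,
                 schema_version = as.integer(raw$schema_version)),
            class = "frt_model")
}
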