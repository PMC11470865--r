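#' Demographic covariate transforms
#'
#' The normative models regress raw FRT scores not on age, education and sex
#' directly but on transformed covariates: age enters as `log10(100 - age)`
#' (strictly decreasing on the normative age range, linearising the
#' accelerating decline near the upper ages), education as `sqrt(years)`
#' (or untransformed years, used only during screening for failed
#' recognition), and sex as a centered male indicator taking the value
#' 0.58 for males and -0.42 for females (male share of the normative
#' sample ~ 0.42, so the code is mean-centered by construction).
#'
#' @param age Age in years; must be below 100 (transform domain) and
#'   non-negative.
#' @param education Years of schooling, non-negative.
#' @param sex Character/factor with values in `"M"`/`"F"` (also accepts
#'   `"male"`/`"female"`, case-insensitive) or a 0/1 male indicator.
#' @param transform `"sqrt"` (default) or `"identity"` for education.
#' @return Transformed numeric vector of the same length as the input.
#' @examples
#' age_transform(90)      # log10(10) = 1
#' education_transform(16) # 4
#' sex_code(c("M", "F"))  # 0.58 -0.42
#' @name covariate-transforms
NULL

# male share of the normative demographic table; centers the sex indicator
frt_male_share <- 0.42

#' @rdname covariate-transforms
#' @export
age_transform <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age))) {
    frt_domain_error("'age' must be finite numeric")
  }
  if (any(age >= 100)) {
    frt_domain_error("age transform log10(100 - age) undefined for age >= 100")
  }
  if (any(age < 0)) {
    frt_domain_error("negative age")
  }
  log10(100 - age)
}

#' @rdname covariate-transforms
#' @export
education_transform <- function(education, transform = c("sqrt", "identity")) {
  transform <- match.arg(transform)
  if (!is.numeric(education) || any(!is.finite(education))) {
    frt_domain_error("'education' must be finite numeric")
  }
  if (any(education < 0)) {
    frt_domain_error("negative education (years of schooling)")
  }
  if (transform == "sqrt") sqrt(education) else education
}

#' @rdname covariate-transforms
#' @export
sex_code <- function(sex) {
  if (is.factor(sex)) sex <- as.character(sex)
  if (is.numeric(sex)) {
    if (any(!sex %in% c(0, 1))) {
      frt_domain_error("numeric 'sex' must be a 0/1 male indicator")
    }
    male <- sex == 1
  } else if (is.character(sex)) {
    s <- toupper(substr(trimws(sex), 1L, 1L))
    if (any(!s %in% c("M", "F"))) {
      frt_domain_error("'sex' must be 'M'/'F' (or 'male'/'female')")
    }
    male <- s == "M"
  } else {
    frt_domain_error("'sex' must be character, factor, or 0/1 numeric")
  }
  ifelse(male, 1 - frt_male_share, -frt_male_share)
}

#' Transform a subject's covariates for the normative models
#'
#' @param age,sex,education Vectors of equal length (or length 1);
#'   see [age_transform()] for domains. `sex` may be `NULL` when no
#'   subscale under consideration uses it.
#' @param edu_transform Education transform, `"sqrt"` or `"identity"`.
#' @return A data.frame with columns `age` (transformed), `education`
#'   (transformed, absent if `education` is `NULL`) and `sex` (centered
#'   code, absent if `sex` is `NULL`).
#' @export
transform_covariates <- function(age, sex = NULL, education = NULL,
                                 edu_transform = c("sqrt", "identity")) {
  edu_transform <- match.arg(edu_transform)
  out <- data.frame(age = age_transform(age))
  if (!is.null(sex)) out$sex <- sex_code(sex)
  if (!is.null(education)) {
    out$education <- education_transform(education, edu_transform)
  }
  out
}
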