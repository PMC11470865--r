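#' Demographic bands for the correction grids
#'
#' Age bands follow 10-year steps (18-30, 30-39, ..., 80+); education
#' bands follow the Italian schooling system (1-5 primary, 6-8 middle,
#' 9-13 high school, >13 tertiary). Representative demographics per band
#' are the band midpoints (ages 24, 34.5, 44.5, 54.5, 64.5, 74.5, 85;
#' education 3, 7, 11, 16.5) - a documented package choice, since the
#' values behind the originally printed grid are unstated; grid cells are
#' therefore validated against this package's own formulas, with the
#' printed grid used only for sign/ordering patterns.
#'
#' @return List with data.frames `age` and `education`, each with
#'   `label`, `lo`, `hi`, `rep`.
#' @export
frt_demographic_bands <- function() {
  list(
    age = data.frame(
      label = c("18-30", "30-39", "40-49", "50-59", "60-69", "70-79", "80+"),
      lo = c(18, 30, 40, 50, 60, 70, 80),
      hi = c(29, 39, 49, 59, 69, 79, 99),
      rep = c(24, 34.5, 44.5, 54.5, 64.5, 74.5, 85)
    ),
    education = data.frame(
      label = c("1-5", "6-8", "9-13", ">13"),
      lo = c(1, 6, 9, 14),
      hi = c(5, 8, 13, 20),
      rep = c(3, 7, 11, 16.5)
    )
  )
}

# subscales for which a correction grid is produced; semantic and
# non-semantic FM get stratified raw cut-offs only
frt_grid_subscales <- c("free_recall", "recognition", "failed_recognition",
                        "total_fm")

band_index <- function(x, bands) {
  idx <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(bands))) {
    idx[x >= bands$lo[i] & x <= bands$hi[i]] <- i
  }
  idx
}

# normative-sample occupancy of age x education cells (sexes pooled);
# zero cells are the grid's extrapolated entries
grid_cell_occupancy <- function() {
  counts <- frt_table1_counts()
  apply(counts$F + counts$M, c(1L, 2L), sum)
}

#' Build a correction grid for one subscale
#'
#' One signed correction per demographic cell, computed by exact formula
#' evaluation ([correction_at()]) at the cell's representative
#' demographics. Free recall, recognition and total false memory grids are
#' age band x education band; the failed recognition grid is age band x
#' sex (its model has no education term). Cells whose age x education
#' combination is absent from the normative sample are flagged
#' `extrapolated`, mirroring the published grid's asterisks: the formula is
#' global in age and education, so those cells are formula extrapolations
#' beyond sampled demographics.
#'
#' @param model An [frt_model] containing the subscale.
#' @param subscale One of `free_recall`, `recognition`,
#'   `failed_recognition`, `total_fm`.
#' @param bands Band definitions, see [frt_demographic_bands()].
#' @return An object of class `frt_correction_grid`: data.frame `cells`
#'   with band labels, representative demographics, full-precision
#'   `correction`, 2-decimal `correction_2dp` and `extrapolated` flag.
#' @export
build_grid <- function(model = frt_reference_model(), subscale,
                       bands = frt_demographic_bands()) {
  match_subscale(subscale)
  if (!subscale %in% frt_grid_subscales) {
    frt_domain_error(sprintf(
      "no correction grid for '%s': it needs no formula correction, only stratified cut-offs (see stratified_cutoffs)",
      subscale
    ))
  }
  comp <- model_component(model, subscale)
  ab <- bands$age
  if (subscale == "failed_recognition") {
    cells <- expand.grid(age_band = ab$label, sex = c("F", "M"),
                         stringsAsFactors = FALSE)
    cells$rep_age <- ab$rep[match(cells$age_band, ab$label)]
    cells$correction <- correction_at(age = cells$rep_age, sex = cells$sex,
                                      model = model, subscale = subscale)
    cells$extrapolated <- FALSE  # every age band contains both sexes
  } else {
    eb <- bands$education
    cells <- expand.grid(age_band = ab$label, education_band = eb$label,
                         stringsAsFactors = FALSE)
    cells$rep_age <- ab$rep[match(cells$age_band, ab$label)]
    cells$rep_education <- eb$rep[match(cells$education_band, eb$label)]
    # age x education grids show the sex-averaged correction: a fitted
    # model may retain a sex term (the published ones here do not), which
    # vanishes at the centered sex code
    grid_model <- model
    if ("sex" %in% names(comp$coef)) {
      grid_model$subscales[[subscale]]$coef <-
        comp$coef[setdiff(names(comp$coef), "sex")]
      grid_model$subscales[[subscale]]$centering <-
        comp$centering[setdiff(names(comp$coef), "sex")]
    }
    cells$correction <- correction_at(age = cells$rep_age,
                                      education = cells$rep_education,
                                      model = grid_model, subscale = subscale)
    occ <- grid_cell_occupancy()
    cells$extrapolated <- occ[cbind(
      match(cells$education_band, rownames(occ)),
      match(cells$age_band, colnames(occ))
    )] == 0L
  }
  cells$correction_2dp <- round(cells$correction, 2L)
  structure(
    list(subscale = subscale, cells = cells, bands = bands,
         schema_version = frt_schema_version),
    class = "frt_correction_grid"
  )
}

#' Adjust a raw score via the correction grid
#'
#' Looks up the subject's demographic cell and adds its correction. When
#' the demographics fall outside every band combination handled by the
#' grid the exact formula is used instead ("extrapolation formula"); the
#' result reports which route was taken.
#'
#' @param raw Raw score(s).
#' @param age,sex,education Demographics (vectorized).
#' @param grid An [build_grid()] result.
#' @param model Model used for the formula fallback (default: published).
#' @return data.frame with `adjusted`, `correction`, `method`
#'   (`"grid"`/`"formula"`) and `extrapolated`.
#' @export
adjust_via_grid <- function(raw, age, sex = NULL, education = NULL, grid,
                            model = frt_reference_model()) {
  if (!inherits(grid, "frt_correction_grid")) {
    frt_domain_error("'grid' must be an frt_correction_grid")
  }
  subscale <- grid$subscale
  n <- max(length(raw), length(age), length(sex %||% 1),
           length(education %||% 1))
  raw <- rep_len(as.numeric(raw), n)
  age <- rep_len(age, n)
  ai <- band_index(age, grid$bands$age)
  cells <- grid$cells
  if (subscale == "failed_recognition") {
    if (is.null(sex)) frt_domain_error("failed_recognition grid requires sex")
    sx <- rep_len(toupper(substr(as.character(sex), 1L, 1L)), n)
    key <- match(paste(grid$bands$age$label[ai], sx),
                 paste(cells$age_band, cells$sex))
  } else {
    if (is.null(education)) {
      frt_domain_error(sprintf("'%s' grid requires education", subscale))
    }
    education <- rep_len(education, n)
    ei <- band_index(education, grid$bands$education)
    key <- match(paste(grid$bands$age$label[ai],
                       grid$bands$education$label[ei]),
                 paste(cells$age_band, cells$education_band))
  }
  corr <- cells$correction[key]
  method <- ifelse(is.na(key), "formula", "grid")
  extrap <- cells$extrapolated[key]
  if (any(is.na(key))) {
    # formula fallback: exact evaluation (errors propagate on true domain
    # violations such as age below 18)
    i <- which(is.na(key))
    corr[i] <- correction_at(
      age = age[i],
      sex = if (!is.null(sex)) rep_len(sex, n)[i],
      education = if (!is.null(education)) rep_len(education, n)[i],
      model = model, subscale = subscale
    )
    extrap[i] <- TRUE
  }
  data.frame(adjusted = raw + corr, correction = corr, method = method,
             extrapolated = extrap)
}

#' @export
print.frt_correction_grid <- function(x, ...) {
  cat(sprintf("Correction grid [%s]\n", x$subscale))
  print(grid_matrix(x))
  if (any(x$cells$extrapolated)) {
    cat("(* extrapolated: demographic combination absent from the normative sample)\n")
  }
  invisible(x)
}

grid_matrix <- function(grid) {
  cells <- grid$cells
  if (grid$subscale == "failed_recognition") {
    rows <- c("F", "M")
    m <- matrix("", length(rows), nrow(grid$bands$age),
                dimnames = list(rows, grid$bands$age$label))
    for (i in seq_len(nrow(cells))) {
      m[cells$sex[i], cells$age_band[i]] <-
        sprintf("%.2f", cells$correction_2dp[i])
    }
  } else {
    rows <- grid$bands$education$label
    m <- matrix("", length(rows), nrow(grid$bands$age),
                dimnames = list(rows, grid$bands$age$label))
    for (i in seq_len(nrow(cells))) {
      m[cells$education_band[i], cells$age_band[i]] <-
        paste0(sprintf("%.2f", cells$correction_2dp[i]),
               if (cells$extrapolated[i]) "*" else "")
    }
  }
  m
}

#' Export a correction grid as CSV
#'
#' Band rows x age-band columns of 2-decimal corrections plus a flags
#' column marking extrapolated cells.
#'
#' @param grid An [build_grid()] result.
#' @param path Output path.
#' @export
write_grid_csv <- function(grid, path) {
  cells <- grid$cells
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}
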