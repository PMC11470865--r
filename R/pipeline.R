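#' Batch-score response sheets
#'
#' Reads a sheet CSV (possibly many subjects), validates and scores each
#' sheet, and collects per-subject validation failures without aborting
#' the batch. Rejections are logged to stderr; data goes to files only.
#'
#' @param input Path to a sheet CSV (see [read_sheet_csv()]).
#' @param output Optional path for the score CSV (one row per subject).
#' @return List with `scores` (data.frame: subject_id + six subscores) and
#'   `rejected` (data.frame: subject_id, reason), invisibly if `output`
#'   is given.
#' @export
run_score <- function(input, output = NULL) {
  sheets <- read_sheet_csv(input, validate = FALSE)
  if (length(sheets) == 0L) {
    frt_stop("frt_io_error", sprintf("'%s' contains 0 subject rows", input))
  }
  scores <- list()
  rejected <- list()
  for (id in names(sheets)) {
    res <- tryCatch(score_sheet(sheets[[id]]), frtnorms_error = identity)
    if (inherits(res, "condition")) {
      rejected[[id]] <- data.frame(subject_id = id,
                                   reason = conditionMessage(res))
      frt_log("rejected sheet '%s': %s", id, conditionMessage(res))
    } else {
      scores[[id]] <- data.frame(subject_id = id, t(as.integer(res)))
      names(scores[[id]])[-1L] <- frt_subscales
    }
  }
  out <- list(
    scores = if (length(scores)) do.call(rbind, c(scores, make.row.names = FALSE))
             else data.frame(subject_id = character(0)),
    rejected = if (length(rejected))
      do.call(rbind, c(rejected, make.row.names = FALSE))
    else data.frame(subject_id = character(0), reason = character(0))
  )
  frt_log("scored %d sheet(s), rejected %d", nrow(out$scores),
          nrow(out$rejected))
  if (!is.null(output)) {
    utils::write.csv(out$scores, output, row.names = FALSE)
    return(invisible(out))
  }
  out
}

# demographic strata used for the raw-score cut-offs of the two false
# memory scales that need no formula correction
semantic_stratum <- function(age) {
  ifelse(age < 60, "age<60", "age>=60")
}

non_semantic_stratum <- function(age, education) {
  ifelse(age < 60, "age<60",
    ifelse(age < 80,
      ifelse(education <= 5, "age60-79 edu<=5", "age60-79 edu>5"),
      "age>=80"))
}

#' Fit the full set of norms from a cohort
#'
#' Runs the complete norming procedure on a normative cohort: fits the six
#' subscale regressions (or takes the published model), adjusts the cohort,
#' builds Equivalent-Score tables from the adjusted scores of the four
#' scales that receive a formula correction (free recall, recognition,
#' failed recognition, total false memory), builds their correction grids,
#' and computes stratified raw-score cut-offs for semantic and
#' non-semantic false memory.
#'
#' @param cohort Cohort data.frame or path to a cohort CSV.
#' @param model `"fit"` (default: fit on the cohort) or `"published"`, or
#'   an [frt_model] to use directly.
#' @param coverage,confidence Tolerance-limit levels.
#' @param out Optional path: write the versioned norms artifact as JSON.
#' @return An object of class `frt_norms`.
#' @export
run_norms <- function(cohort, model = c("fit", "published"),
                      coverage = 0.95, confidence = 0.95, out = NULL) {
  if (is.character(cohort) && length(cohort) == 1L) {
    cohort <- read_cohort_csv(cohort)
  }
  check_cohort_schema(cohort)
  n <- nrow(cohort)
  mn <- min_norm_n(coverage, confidence)
  if (n < mn) {
    frt_stop("frt_insufficient_n",
             sprintf("cohort n = %d below the tolerance-limit minimum; need n >= %d at %g/%g",
                     n, mn, coverage, confidence),
             n = n, min_n = mn)
  }
  if (inherits(model, "frt_model")) {
    mdl <- model
  } else {
    model <- match.arg(model)
    mdl <- if (model == "published") frt_reference_model()
           else fit_all_normative_models(cohort)
  }
  adjusted <- adjust_cohort(cohort, mdl)
  es_tables <- stats::setNames(lapply(frt_grid_subscales, function(s) {
    build_es_table(adjusted[[s]], orientation = frt_orientations[[s]],
                   coverage = coverage, confidence = confidence,
                   subscale = s)
  }), frt_grid_subscales)
  grids <- stats::setNames(lapply(frt_grid_subscales, function(s) {
    build_grid(mdl, s)
  }), frt_grid_subscales)
  cutoffs <- list(
    semantic_fm = stratified_cutoffs(
      cohort$semantic_fm, semantic_stratum(cohort$age),
      orientation = "higher_worse", coverage = coverage,
      confidence = confidence
    ),
    non_semantic_fm = stratified_cutoffs(
      cohort$non_semantic_fm,
      non_semantic_stratum(cohort$age, cohort$education),
      orientation = "higher_worse", coverage = coverage,
      confidence = confidence
    )
  )
  norms <- structure(
    list(model = mdl, es_tables = es_tables, grids = grids,
         cutoffs = cutoffs, n = n, coverage = coverage,
         confidence = confidence, schema_version = frt_schema_version),
    class = "frt_norms"
  )
  frt_log("norms fitted on n = %d (outer/inner ranks %d/%d)", n,
          es_tables[[1L]]$outer_rank, es_tables[[1L]]$inner_rank)
  if (!is.null(out)) {
    write_norms_json(norms, out)
    return(invisible(norms))
  }
  norms
}

#' Evaluate newly tested subjects against fitted norms
#'
#' Per subject and subscale: the exact-formula adjusted score, the
#' Equivalent Score, and an abnormality flag (ES 0, i.e. at or beyond the
#' outer tolerance limit). Semantic and non-semantic false memory are
#' flagged against their stratified raw cut-offs and carry no ES (`NA`);
#' a stratum without a valid cut-off yields `NA` flags.
#'
#' @param subjects data.frame or CSV path with demographics and the six
#'   raw score columns.
#' @param norms An [run_norms()] result (or path to its JSON artifact).
#' @param out Optional report CSV path.
#' @return data.frame report: for each subscale `<s>_raw`, `<s>_adj`,
#'   `<s>_es`, `<s>_abnormal`. An empty subjects table yields an empty
#'   report (no error).
#' @export
run_evaluate <- function(subjects, norms, out = NULL) {
  if (is.character(subjects) && length(subjects) == 1L) {
    subjects <- utils::read.csv(subjects, stringsAsFactors = FALSE)
  }
  if (is.character(norms) && length(norms) == 1L) {
    norms <- read_norms_json(norms)
  }
  if (!inherits(norms, "frt_norms")) {
    frt_domain_error("'norms' must be an frt_norms object or artifact path")
  }
  if (nrow(subjects) > 0L) check_cohort_schema(subjects)
  report <- data.frame(
    subject_id = if (nrow(subjects)) subjects$subject_id %||%
      sprintf("subj%04d", seq_len(nrow(subjects))) else character(0)
  )
  for (s in frt_subscales) {
    raw <- if (nrow(subjects)) as.numeric(subjects[[s]]) else numeric(0)
    report[[paste0(s, "_raw")]] <- raw
    if (s %in% frt_grid_subscales) {
      adj <- if (nrow(subjects)) {
        adjust_score(raw, age = subjects$age, sex = subjects$sex,
                     education = subjects$education, model = norms$model,
                     subscale = s)
      } else numeric(0)
      es <- assign_es(adj, norms$es_tables[[s]])
      report[[paste0(s, "_adj")]] <- round(adj, 2L)
      report[[paste0(s, "_es")]] <- es
      report[[paste0(s, "_abnormal")]] <- es == 0L
    } else {
      strat <- if (s == "semantic_fm") semantic_stratum(subjects$age)
               else non_semantic_stratum(subjects$age, subjects$education)
      co <- norms$cutoffs[[s]]
      row <- match(strat, co$stratum)
      cut <- co$cutoff[row]
      report[[paste0(s, "_adj")]] <- raw  # no correction needed
      report[[paste0(s, "_es")]] <- rep(NA_integer_, nrow(subjects))
      report[[paste0(s, "_abnormal")]] <- raw >= cut
    }
  }
  frt_log("evaluated %d subject(s)", nrow(report))
  if (!is.null(out)) {
    utils::write.csv(report, out, row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Simulate a cohort and write it as CSV
#'
#' @param n Cohort size.
#' @param seed RNG seed.
#' @param out Output CSV path.
#' @param config Optional full [cohort_config()] (overrides `n`, `seed`).
#' @return The cohort, invisibly.
#' @export
run_simulate <- function(n = 232L, seed = 1L, out, config = NULL) {
  if (is.null(config)) config <- cohort_config(n = n, seed = seed)
  cohort <- generate_cohort(config)
  write_cohort_csv(cohort, out)
  frt_log("simulated cohort n = %d (seed %s) -> %s", nrow(cohort),
          format(config$seed), out)
  invisible(cohort)
}

#' Serialize / deserialize a norms artifact as JSON
#'
#' Single versioned JSON document holding the model, Equivalent-Score
#' tables, correction grids and stratified cut-offs. Deliberately carries
#' no timestamp so identical inputs produce byte-identical artifacts.
#'
#' @param norms An [run_norms()] result.
#' @param path File path.
#' @export
write_norms_json <- function(norms, path) {
  if (!inherits(norms, "frt_norms")) {
    frt_domain_error("'norms' must be an frt_norms object")
  }
  payload <- list(
    schema_version = norms$schema_version,
    n = norms$n, coverage = norms$coverage, confidence = norms$confidence,
    model = serialize_model(norms$model),
    es_tables = lapply(norms$es_tables, function(t) {
      t <- unclass(t)
      t$boundaries <- named_as_list(t$boundaries)
      t$boundaries_original <- named_as_list(t$boundaries_original)
      t
    }),
    grids = lapply(norms$grids, function(g) {
      list(subscale = g$subscale, cells = g$cells, bands = g$bands,
           schema_version = g$schema_version)
    }),
    cutoffs = norms$cutoffs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_norms_json
#' @export
read_norms_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(raw$schema_version), frt_schema_version)) {
    frt_schema_error(sprintf("unsupported norms schema_version: %s",
                             raw$schema_version %||% "<missing>"))
  }
  es_tables <- lapply(raw$es_tables, function(t) {
    t$n <- as.integer(t$n)
    t$outer_rank <- as.integer(t$outer_rank)
    t$inner_rank <- as.integer(t$inner_rank)
    t$boundaries <- vapply(t$boundaries, as.numeric, numeric(1L))
    t$boundaries_original <- vapply(t$boundaries_original, as.numeric,
                                    numeric(1L))
    t$cutoff <- as.numeric(t$cutoff)
    t$schema_version <- as.integer(t$schema_version)
    class(t) <- "frt_es_table"
    t
  })
  grids <- lapply(raw$grids, function(g) {
    g$cells <- as.data.frame(g$cells)
    g$cells$correction <- as.numeric(g$cells$correction)
    g$cells$correction_2dp <- as.numeric(g$cells$correction_2dp)
    g$bands <- lapply(g$bands, as.data.frame)
    g$schema_version <- as.integer(g$schema_version)
    class(g) <- "frt_correction_grid"
    g
  })
  cutoffs <- lapply(raw$cutoffs, function(co) {
    co <- as.data.frame(co)
    co$cutoff <- as.numeric(co$cutoff)
    co$n <- as.integer(co$n)
    co$min_n <- as.integer(co$min_n)
    co
  })
  structure(
    list(model = rehydrate_model(raw$model), es_tables = es_tables,
         grids = grids, cutoffs = cutoffs, n = as.integer(raw$n),
         coverage = as.numeric(raw$coverage),
         confidence = as.numeric(raw$confidence),
         schema_version = as.integer(raw$schema_version)),
    class = "frt_norms"
  )
}

#' @export
print.frt_norms <- function(x, ...) {
  cat(sprintf("FRT norms (n = %d, %g%%/%g%% tolerance limits, model: %s)\n",
              x$n, 100 * x$coverage, 100 * x$confidence, x$model$source))
  for (s in names(x$es_tables)) {
    t <- x$es_tables[[s]]
    cat(sprintf("  %-18s cut-off: %s %.2f (adjusted scale)\n", s,
                t$cutoff_direction, t$cutoff))
  }
  for (s in names(x$cutoffs)) {
    co <- x$cutoffs[[s]]
    ok <- co$valid
    cat(sprintf("  %-18s raw cut-offs: %s\n", s,
                paste(sprintf("%s %s %s", co$stratum, co$direction,
                              ifelse(ok, format(co$cutoff), "n/a (small stratum)")),
                      collapse = "; ")))
  }
  invisible(x)
}
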