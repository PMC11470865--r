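#' Item-level FRT scoring
#'
#' A response sheet records, for each of the three valenced lists, the number
#' of encoding words correctly produced at free recall (0-12) and the 12
#' yes/no recognition endorsements, each tagged with its item class:
#' `OLD` (6 studied words), `LURE` (1 critical lure), `SEMANTIC_ASSOCIATE`
#' (2 strong associates) and `UNRELATED` (3 unrelated words). Words
#' themselves are not modelled; items are abstract slots tagged by class,
#' so scoring is list-content-agnostic.
#'
#' Scoring rules (summing across the three lists):
#' * `free_recall` = total correct free-recall productions (0-36; each
#'   encoding list holds 12 words). Free-recall intrusions, if recorded,
#'   enter no subscore.
#' * `recognition` = hits (OLD endorsed) + correct rejections (new items
#'   not endorsed), 0-36. This is forced by the arithmetic identity
#'   `recognition + failed_recognition + total_fm = 36`.
#' * `failed_recognition` = OLD items not endorsed (misses), 0-18.
#' * `semantic_fm` = LURE + SEMANTIC_ASSOCIATE items endorsed, 0-9.
#' * `non_semantic_fm` = UNRELATED items endorsed, 0-9.
#' * `total_fm` = `semantic_fm + non_semantic_fm`, 0-18.
#'
#' @name frt-scoring
NULL

frt_item_classes <- c("OLD", "LURE", "SEMANTIC_ASSOCIATE", "UNRELATED")
frt_list_composition <- c(
  OLD = 6L, LURE = 1L, SEMANTIC_ASSOCIATE = 2L, UNRELATED = 3L
)
frt_n_lists <- 3L
frt_words_per_list <- 12L

#' Construct a response sheet
#'
#' @param subject_id Opaque subject identifier (scalar).
#' @param free_recall_hits Integer vector of length 3: correct free-recall
#'   productions per list, each in 0-12.
#' @param recognition A data.frame with columns `list_index` (1-3),
#'   `item_class` (see [frt_item_classes]) and `endorsed` (logical or 0/1),
#'   one row per recognition item (36 rows). An optional `item_index`
#'   column (1-12 within list) is preserved.
#' @param validate Validate structural invariants (default `TRUE`).
#' @return An object of class `frt_response_sheet`.
#' @export
response_sheet <- function(subject_id, free_recall_hits, recognition,
                           validate = TRUE) {
  recognition <- as.data.frame(recognition)
  if (!is.null(recognition$endorsed)) {
    recognition$endorsed <- as.logical(recognition$endorsed)
  }
  sheet <- structure(
    list(
      subject_id = as.character(subject_id)[1L],
      free_recall_hits = as.integer(free_recall_hits),
      recognition = recognition
    ),
    class = "frt_response_sheet"
  )
  if (validate) validate_response_sheet(sheet)
  sheet
}

#' Validate a response sheet's structural invariants
#'
#' Checks list count, per-list free-recall range, and the 6/1/2/3
#' recognition composition of every list. The error message names the
#' violated invariant.
#'
#' @param sheet An [response_sheet()] object.
#' @return `sheet`, invisibly, if valid; otherwise a classed
#'   `frt_validation_error` condition is signalled.
#' @export
validate_response_sheet <- function(sheet) {
  if (!inherits(sheet, "frt_response_sheet")) {
    frt_validation_error("not an frt_response_sheet object")
  }
  fr <- sheet$free_recall_hits
  if (length(fr) != frt_n_lists) {
    frt_validation_error(sprintf(
      "invariant 'exactly 3 lists': got %d free_recall_hits entries",
      length(fr)
    ))
  }
  if (anyNA(fr) || any(fr < 0L | fr > frt_words_per_list)) {
    frt_validation_error(
      "invariant 'free_recall_hits per list in [0, 12]' violated"
    )
  }
  rec <- sheet$recognition
  need <- c("list_index", "item_class", "endorsed")
  if (!all(need %in% names(rec))) {
    frt_validation_error(sprintf(
      "recognition table missing column(s): %s",
      paste(setdiff(need, names(rec)), collapse = ", ")
    ))
  }
  if (anyNA(rec$endorsed)) {
    frt_validation_error("recognition endorsements contain missing values")
  }
  if (!setequal(unique(rec$list_index), seq_len(frt_n_lists))) {
    frt_validation_error(
      "invariant 'exactly 3 lists': recognition list_index must cover 1..3"
    )
  }
  if (any(!rec$item_class %in% frt_item_classes)) {
    frt_validation_error(sprintf(
      "unknown item_class value(s): %s",
      paste(unique(setdiff(rec$item_class, frt_item_classes)), collapse = ", ")
    ))
  }
  for (l in seq_len(frt_n_lists)) {
    cls <- rec$item_class[rec$list_index == l]
    counts <- table(factor(cls, levels = frt_item_classes))
    if (!all(counts == frt_list_composition[names(counts)])) {
      frt_validation_error(sprintf(
        paste0("invariant 'recognition composition 6 OLD / 1 LURE / ",
               "2 SEMANTIC_ASSOCIATE / 3 UNRELATED' violated in list %d ",
               "(got %s)"),
        l, paste(sprintf("%d %s", counts, names(counts)), collapse = ", ")
      ))
    }
  }
  invisible(sheet)
}

#' Score a response sheet into the six FRT subscores
#'
#' @param sheet A valid [response_sheet()].
#' @return Named integer vector of class `frt_score_set` with elements
#'   `free_recall`, `recognition`, `failed_recognition`, `semantic_fm`,
#'   `non_semantic_fm`, `total_fm`.
#' @examples
#' sh <- simulate_response_sheet("s1", p_old = 1, p_lure = 0,
#'                               p_assoc = 0, p_unrel = 0, recall_rate = 1)
#' score_sheet(sh)  # perfect performance: 36 36 0 0 0 0
#' @export
score_sheet <- function(sheet) {
  validate_response_sheet(sheet)
  rec <- sheet$recognition
  old <- rec$item_class == "OLD"
  sem_new <- rec$item_class %in% c("LURE", "SEMANTIC_ASSOCIATE")
  unrel <- rec$item_class == "UNRELATED"
  endorsed <- as.logical(rec$endorsed)

  semantic_fm <- sum(sem_new & endorsed)
  non_semantic_fm <- sum(unrel & endorsed)
  total_fm <- semantic_fm + non_semantic_fm
  failed <- sum(old & !endorsed)
  hits <- sum(old & endorsed)
  correct_rejections <- sum((sem_new | unrel) & !endorsed)

  out <- c(
    free_recall = sum(sheet$free_recall_hits),
    recognition = hits + correct_rejections,
    failed_recognition = failed,
    semantic_fm = semantic_fm,
    non_semantic_fm = non_semantic_fm,
    total_fm = total_fm
  )
  structure(as.integer(out), names = names(out), class = "frt_score_set",
            subject_id = sheet$subject_id)
}

#' @export
print.frt_score_set <- function(x, ...) {
  cat("FRT score set", if (!is.null(attr(x, "subject_id")))
    sprintf("(subject %s)", attr(x, "subject_id")), "\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Simulate one response sheet
#'
#' Draws recognition endorsements independently per item class and
#' free-recall hit counts binomially. Intended for tests, demos and batch
#' fixtures; it makes no claim of psychometric realism at the item level.
#'
#' @param subject_id Identifier.
#' @param p_old,p_lure,p_assoc,p_unrel Endorsement probabilities for OLD,
#'   LURE, SEMANTIC_ASSOCIATE and UNRELATED items.
#' @param recall_rate Per-word free-recall probability (12 words/list).
#' @return An `frt_response_sheet`.
#' @export
simulate_response_sheet <- function(subject_id = "sim",
                                    p_old = 0.85, p_lure = 0.55,
                                    p_assoc = 0.35, p_unrel = 0.05,
                                    recall_rate = 0.5) {
  cls <- rep(rep(frt_item_classes, times = frt_list_composition),
             times = frt_n_lists)
  p <- c(OLD = p_old, LURE = p_lure, SEMANTIC_ASSOCIATE = p_assoc,
         UNRELATED = p_unrel)[cls]
  rec <- data.frame(
    list_index = rep(seq_len(frt_n_lists), each = frt_words_per_list),
    item_index = rep(seq_len(frt_words_per_list), times = frt_n_lists),
    item_class = cls,
    endorsed = stats::runif(length(cls)) < p
  )
  response_sheet(
    subject_id,
    free_recall_hits = stats::rbinom(frt_n_lists, frt_words_per_list,
                                     recall_rate),
    recognition = rec
  )
}

#' Read / write response-sheet CSV files
#'
#' The sheet CSV dialect is long-format, UTF-8, comma-separated, with
#' header `subject_id,list_index,item_index,item_class,endorsed,
#' free_recall_hits`: one row per recognition item (`item_index` 1-12,
#' `endorsed` 0/1, `free_recall_hits` empty) plus one row per list carrying
#' `free_recall_hits` (item columns empty). Multiple subjects may share a
#' file.
#'
#' @param path CSV path.
#' @param validate Validate each sheet on read (default `TRUE`); invalid
#'   sheets raise on read unless `validate = FALSE`.
#' @return `read_sheet_csv()`: named list of `frt_response_sheet` objects.
#' @export
read_sheet_csv <- function(path, validate = TRUE) {
  if (!file.exists(path)) frt_stop("frt_io_error", sprintf("cannot read '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "list_index", "item_index", "item_class",
            "endorsed", "free_recall_hits")
  if (!all(need %in% names(df))) {
    frt_schema_error(sprintf(
      "sheet CSV missing column(s): %s",
      paste(setdiff(need, names(df)), collapse = ", ")
    ))
  }
  sheets <- lapply(split(df, df$subject_id), function(d) {
    fr_rows <- d[is.na(d$item_index) | d$item_class %in% c("", NA), ]
    it_rows <- d[!(is.na(d$item_index) | d$item_class %in% c("", NA)), ]
    fr <- fr_rows$free_recall_hits[order(fr_rows$list_index)]
    response_sheet(
      d$subject_id[1L],
      free_recall_hits = fr,
      recognition = it_rows[, c("list_index", "item_index", "item_class",
                                "endorsed")],
      validate = validate
    )
  })
  sheets[unique(df$subject_id)]
}

#' @rdname read_sheet_csv
#' @param sheets A single sheet or list of sheets to serialize.
#' @export
write_sheet_csv <- function(sheets, path) {
  if (inherits(sheets, "frt_response_sheet")) sheets <- list(sheets)
  rows <- lapply(sheets, function(s) {
    it <- s$recognition
    if (is.null(it$item_index)) {
      it$item_index <- stats::ave(seq_len(nrow(it)), it$list_index,
                                  FUN = seq_along)
    }
    rbind(
      data.frame(subject_id = s$subject_id, list_index = it$list_index,
                 item_index = it$item_index, item_class = it$item_class,
                 endorsed = as.integer(it$endorsed),
                 free_recall_hits = NA_integer_),
      data.frame(subject_id = s$subject_id,
                 list_index = seq_len(frt_n_lists),
                 item_index = NA_integer_, item_class = "",
                 endorsed = NA_integer_,
                 free_recall_hits = s$free_recall_hits)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
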