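#' Nonparametric one-sided tolerance-limit ranks
#'
#' For a normative sample of size `n`, the outer tolerance limit is the
#' order statistic (counted from the worst score, rank 1) that bounds the
#' lowest `1 - coverage` fraction of the population with the requested
#' confidence; scores at or beyond it are defensibly abnormal. The inner
#' limit bounds the uncertain region from above. With
#' `X ~ Binomial(n, 1 - coverage)`:
#' * outer rank = the largest `r >= 1` with `P(X <= r - 1) <= 1 - confidence`;
#' * inner rank = the smallest `r` with `P(X >= r) <= 1 - confidence`.
#'
#' At the defaults (95% coverage, 95% confidence) and `n = 232` this gives
#' ranks 6 and 18. For small `n` no valid outer rank exists (even the
#' sample minimum fails the confidence requirement); `NA_integer_` is
#' returned rather than an error so callers can report the minimum
#' required `n` (see [min_norm_n()]).
#'
#' @param n Sample size (>= 1).
#' @param coverage Population fraction to bound (default 0.95).
#' @param confidence Confidence level (default 0.95).
#' @param side `"outer"` or `"inner"`.
#' @return Integer rank, or `NA_integer_` when no valid rank exists.
#' @examples
#' tolerance_rank(232, side = "outer")  # 6
#' tolerance_rank(232, side = "inner")  # 18
#' tolerance_rank(10, side = "outer")   # NA: sample too small
#' @export
tolerance_rank <- function(n, coverage = 0.95, confidence = 0.95,
                           side = c("outer", "inner")) {
  side <- match.arg(side)
  stopifnot_scalar_number(n, "n", lo = 1)
  stopifnot_scalar_number(coverage, "coverage")
  stopifnot_scalar_number(confidence, "confidence")
  if (coverage <= 0 || coverage >= 1 || confidence <= 0 || confidence >= 1) {
    frt_domain_error("'coverage' and 'confidence' must lie strictly in (0, 1)")
  }
  n <- as.integer(n)
  p <- 1 - coverage
  alpha <- 1 - confidence
  if (side == "outer") {
    # pbinom(r - 1, n, p) is increasing in r; largest r with tail <= alpha
    r <- 0L
    while (r < n && stats::pbinom(r, n, p) <= alpha) r <- r + 1L
    if (r == 0L) NA_integer_ else r
  } else {
    # smallest r with P(X >= r) <= alpha
    r <- stats::qbinom(1 - alpha, n, p)  # P(X <= r) >= 1 - alpha
    while (r <= n && 1 - stats::pbinom(r - 1L, n, p) > alpha) r <- r + 1L
    if (r > n) NA_integer_ else as.integer(r)
  }
}

#' Minimum normative sample size admitting an outer tolerance limit
#'
#' Smallest `n` such that `coverage^n <= 1 - confidence`, i.e. the sample
#' minimum qualifies as an outer limit. 59 at the 95/95 defaults.
#'
#' @inheritParams tolerance_rank
#' @export
min_norm_n <- function(coverage = 0.95, confidence = 0.95) {
  as.integer(ceiling(log(1 - confidence) / log(coverage)))
}

#' Build an Equivalent-Score table from adjusted scores
#'
#' Scores are oriented so that larger = better (negated for `higher_worse`
#' subscales), ranked worst to best, and banded into the five-level
#' Equivalent Score (ES) scale:
#' * ES 0: at or below the outer tolerance limit (`b0`) - abnormal;
#' * ES 1: above `b0`, at or below the inner limit (`b1`);
#' * ES 2 / ES 3: the observations strictly between the inner limit and
#'   the median split into two equal-count halves (boundary `b2`; an odd
#'   observation goes to the lower band);
#' * ES 4: above the sample median (`b3`).
#'
#' Boundary ties always fall in the lower (worse) band. For `higher_worse`
#' subscales banding happens on the negated axis and boundaries are
#' reported on the original scale.
#'
#' @param adjusted Numeric vector of adjusted (or raw, for subscales
#'   needing no correction) scores from the normative sample.
#' @param orientation `"higher_better"` or `"higher_worse"`.
#' @param coverage,confidence Tolerance-limit levels (defaults 0.95/0.95).
#' @param subscale Optional subscale label carried in the table.
#' @return An object of class `frt_es_table` with fields `n`, `outer_rank`,
#'   `inner_rank`, oriented boundaries `b0 <= b1 <= b2 <= b3`, the
#'   boundaries on the original scale, the cut-off and its direction.
#' @examples
#' tab <- build_es_table(1:232, "higher_better")
#' tab$outer_rank; tab$inner_rank      # 6, 18
#' assign_es(c(6, 7, 118), tab)        # 0, 1, 4
#' @export
build_es_table <- function(adjusted, orientation = c("higher_better",
                                                     "higher_worse"),
                           coverage = 0.95, confidence = 0.95,
                           subscale = NULL) {
  orientation <- match.arg(orientation)
  adjusted <- as.numeric(adjusted)
  if (anyNA(adjusted)) frt_domain_error("adjusted scores contain NA")
  n <- length(adjusted)
  outer <- tolerance_rank(n, coverage, confidence, "outer")
  inner <- tolerance_rank(n, coverage, confidence, "inner")
  if (is.na(outer) || is.na(inner)) {
    frt_stop("frt_insufficient_n",
             sprintf("n = %d too small for tolerance limits at %g/%g; minimum n = %d",
                     n, coverage, confidence, min_norm_n(coverage, confidence)),
             n = n, min_n = min_norm_n(coverage, confidence))
  }
  oriented <- if (orientation == "higher_worse") -adjusted else adjusted
  s <- sort(oriented)
  if (s[1L] == s[n]) {
    frt_stop("frt_degenerate_sample",
             "all adjusted scores identical; ES bands undefined")
  }
  med <- stats::median(s)
  # ranks of observations strictly between the inner limit and the median:
  # below the median means rank <= floor(n/2) (even n) or < (n+1)/2 (odd n)
  last_below_median <- if (n %% 2L == 0L) n %/% 2L else (n - 1L) %/% 2L
  k <- max(0L, last_below_median - inner)
  b2_rank <- inner + ceiling(k / 2)
  b0 <- s[outer]
  b1 <- s[inner]
  b2 <- s[b2_rank]
  b3 <- med
  structure(
    list(
      subscale = subscale, orientation = orientation, n = n,
      coverage = coverage, confidence = confidence,
      outer_rank = outer, inner_rank = inner,
      boundaries = c(b0 = b0, b1 = b1, b2 = b2, b3 = b3),
      boundaries_original = if (orientation == "higher_worse")
        c(b0 = -b0, b1 = -b1, b2 = -b2, b3 = -b3)
      else c(b0 = b0, b1 = b1, b2 = b2, b3 = b3),
      cutoff = if (orientation == "higher_worse") -b0 else b0,
      cutoff_direction = if (orientation == "higher_worse") ">=" else "<=",
      schema_version = frt_schema_version
    ),
    class = "frt_es_table"
  )
}

#' Assign Equivalent Scores
#'
#' Deterministic band lookup: on the oriented (larger = better) axis,
#' ES 0 iff `score <= b0`, ES 1 iff `b0 < score <= b1`, ES 2 iff
#' `b1 < score <= b2`, ES 3 iff `b2 < score <= b3`, ES 4 otherwise. Every
#' real input maps to exactly one band.
#'
#' @param score Numeric vector of adjusted scores (original scale).
#' @param table An [build_es_table()] result.
#' @return Integer vector of ES values 0-4.
#' @export
assign_es <- function(score, table) {
  if (!inherits(table, "frt_es_table")) {
    frt_domain_error("'table' must be an frt_es_table")
  }
  x <- if (table$orientation == "higher_worse") -as.numeric(score)
       else as.numeric(score)
  b <- table$boundaries
  out <- integer(length(x))
  out[x > b[["b0"]]] <- 1L
  out[x > b[["b1"]]] <- 2L
  out[x > b[["b2"]]] <- 3L
  out[x > b[["b3"]]] <- 4L
  out
}

#' Abnormality cut-off of an Equivalent-Score table
#'
#' The outer tolerance limit on the original scale, with the direction of
#' abnormality: a score at or below it (`"<="`, higher-better subscales)
#' or at or above it (`">="`, higher-worse subscales) has probability
#' below `1 - coverage` of belonging to the normal population, at the
#' table's confidence level.
#'
#' @param table An [build_es_table()] result.
#' @return List with `value` and `direction`.
#' @export
cutoff_value <- function(table) {
  if (!inherits(table, "frt_es_table")) {
    frt_domain_error("'table' must be an frt_es_table")
  }
  list(value = table$cutoff, direction = table$cutoff_direction)
}

#' @export
print.frt_es_table <- function(x, ...) {
  cat(sprintf(
    "Equivalent-Score table%s (n = %d, %s)\n",
    if (!is.null(x$subscale)) paste0(" [", x$subscale, "]") else "",
    x$n, x$orientation
  ))
  cat(sprintf("  outer/inner tolerance ranks: %d / %d (%g%% coverage, %g%% confidence)\n",
              x$outer_rank, x$inner_rank, 100 * x$coverage, 100 * x$confidence))
  b <- x$boundaries_original
  dir <- x$cutoff_direction
  lab <- if (dir == "<=") {
    c(sprintf("ES 0: score <= %.2f", b[["b0"]]),
      sprintf("ES 1: (%.2f, %.2f]", b[["b0"]], b[["b1"]]),
      sprintf("ES 2: (%.2f, %.2f]", b[["b1"]], b[["b2"]]),
      sprintf("ES 3: (%.2f, %.2f]", b[["b2"]], b[["b3"]]),
      sprintf("ES 4: score > %.2f", b[["b3"]]))
  } else {
    c(sprintf("ES 0: score >= %.2f", b[["b0"]]),
      sprintf("ES 1: [%.2f, %.2f)", b[["b1"]], b[["b0"]]),
      sprintf("ES 2: [%.2f, %.2f)", b[["b2"]], b[["b1"]]),
      sprintf("ES 3: [%.2f, %.2f)", b[["b3"]], b[["b2"]]),
      sprintf("ES 4: score < %.2f", b[["b3"]]))
  }
  cat(paste0("  ", lab, collapse = "\n"), "\n")
  cat(sprintf("  cut-off: abnormal if score %s %.2f\n", dir, x$cutoff))
  invisible(x)
}

#' Stratified raw-score cut-offs
#'
#' For subscales that require no demographic correction by formula
#' (semantic and non-semantic false memory), cut-offs are computed on raw
#' scores within demographic strata. Each stratum's cut-off is its outer
#' tolerance limit; strata smaller than [min_norm_n()] get `NA` with the
#' minimum `n` reported.
#'
#' @param scores Raw scores.
#' @param stratum Factor/character vector (same length) naming each
#'   subject's stratum.
#' @param orientation Score orientation (both FM subscales are
#'   `"higher_worse"`).
#' @inheritParams tolerance_rank
#' @return data.frame with columns `stratum`, `n`, `cutoff`, `direction`,
#'   `valid`, `min_n`.
#' @export
stratified_cutoffs <- function(scores, stratum,
                               orientation = "higher_worse",
                               coverage = 0.95, confidence = 0.95) {
  stopifnot(length(scores) == length(stratum))
  mn <- min_norm_n(coverage, confidence)
  res <- lapply(split(as.numeric(scores), stratum), function(x) {
    n <- length(x)
    r <- tolerance_rank(max(n, 1L), coverage, confidence, "outer")
    if (n < 1L || is.na(r)) {
      data.frame(n = n, cutoff = NA_real_, valid = FALSE)
    } else {
      oriented <- sort(if (orientation == "higher_worse") -x else x)
      v <- oriented[r]
      data.frame(n = n,
                 cutoff = if (orientation == "higher_worse") -v else v,
                 valid = TRUE)
    }
  })
  out <- do.call(rbind, res)
  out <- data.frame(stratum = names(res), out, row.names = NULL)
  out$direction <- if (orientation == "higher_worse") ">=" else "<="
  out$min_n <- mn
  out
}
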