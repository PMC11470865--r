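# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit per-item recounts, direct binomial
# summation via lchoose, explicit normal-equations solves.

# brute-force recount of the six subscores, item by item
oracle_recount <- function(sheet) {
  rec <- sheet$recognition
  hits <- miss <- sem <- non <- cr <- 0L
  for (i in seq_len(nrow(rec))) {
    cl <- rec$item_class[i]
    e <- isTRUE(as.logical(rec$endorsed[i]))
    if (cl == "OLD") {
      if (e) hits <- hits + 1L else miss <- miss + 1L
    } else if (cl %in% c("LURE", "SEMANTIC_ASSOCIATE")) {
      if (e) sem <- sem + 1L else cr <- cr + 1L
    } else if (cl == "UNRELATED") {
      if (e) non <- non + 1L else cr <- cr + 1L
    }
  }
  c(free_recall = sum(sheet$free_recall_hits),
    recognition = hits + cr,
    failed_recognition = miss,
    semantic_fm = sem,
    non_semantic_fm = non,
    total_fm = sem + non)
}

# direct term-by-term binomial summation, no pbinom/qbinom
oracle_binom_cdf <- function(q, n, p) {
  if (q < 0) return(0)
  k <- 0:min(q, n)
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

oracle_outer_rank <- function(n, coverage = 0.95, confidence = 0.95) {
  p <- 1 - coverage
  alpha <- 1 - confidence
  r <- 0L
  while (r < n && oracle_binom_cdf(r, n, p) <= alpha) r <- r + 1L
  if (r == 0L) NA_integer_ else r
}

oracle_inner_rank <- function(n, coverage = 0.95, confidence = 0.95) {
  p <- 1 - coverage
  alpha <- 1 - confidence
  for (r in 1:n) {
    upper <- 1 - oracle_binom_cdf(r - 1L, n, p)
    if (upper <= alpha) return(as.integer(r))
  }
  NA_integer_
}

# linear-scan ES assignment: re-derives the band edges from the raw
# normative sample (sorting, rank lookups, equal-count split) and walks
# them one by one for each score
oracle_es_scan <- function(score, sample, orientation,
                           coverage = 0.95, confidence = 0.95) {
  s <- sort(if (orientation == "higher_worse") -as.numeric(sample)
            else as.numeric(sample))
  n <- length(s)
  outer <- oracle_outer_rank(n, coverage, confidence)
  inner <- oracle_inner_rank(n, coverage, confidence)
  med <- if (n %% 2L == 0L) (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
         else s[(n + 1L) %/% 2L]
  below <- if (n %% 2L == 0L) n %/% 2L else (n - 1L) %/% 2L
  k <- max(0L, below - inner)
  edges <- c(s[outer], s[inner], s[inner + ceiling(k / 2)], med)
  x <- if (orientation == "higher_worse") -score else score
  band <- 0L
  for (e in edges) {
    if (x <= e) return(band)
    band <- band + 1L
  }
  band
}

# explicit normal-equations OLS
oracle_ols <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1L]
}

# random sheet with arbitrary flat endorsement probability
random_sheet <- function(id, p = 0.5) {
  cls <- rep(rep(c("OLD", "LURE", "SEMANTIC_ASSOCIATE", "UNRELATED"),
                 times = c(6L, 1L, 2L, 3L)), times = 3L)
  response_sheet(
    id,
    free_recall_hits = sample(0:12, 3L, replace = TRUE),
    recognition = data.frame(
      list_index = rep(1:3, each = 12L),
      item_index = rep(1:12, times = 3L),
      item_class = cls,
      endorsed = stats::runif(36L) < p
    )
  )
}

# demographics pinned exactly at the published centering constants
centering_demographics <- function(n = 1L, sex = "F") {
  data.frame(
    subject_id = sprintf("c%02d", seq_len(n)),
    age = 100 - 10^1.69,       # t_age = 1.69 exactly
    sex = rep_len(sex, n),
    education = 3.54^2         # sqrt(education) = 3.54 exactly
  )
}
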