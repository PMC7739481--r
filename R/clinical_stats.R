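#' Score the Social Avoidance and Distress Scale (SADS)
#'
#' 28 yes/no items: the first 14 measure social avoidance, the last 14 social
#' distress.  Item scores are summed; a total above 9 flags the respondent as
#' suffering social avoidance and distress.
#'
#' @param items length-28 vector of 0/1 (or logical) responses, avoidance
#'   items first.
#' @return list with `avoidance`, `distress`, `total`, `flagged`.
#' @export
score_sads <- function(items) {
  items <- as.integer(items)
  if (length(items) != 28 || any(is.na(items)) || !all(items %in% c(0L, 1L)))
    stop("SADS requires exactly 28 binary items")
  avoidance <- sum(items[1:14])
  distress <- sum(items[15:28])
  total <- avoidance + distress
  list(avoidance = avoidance, distress = distress, total = total,
       flagged = total > 9)
}

#' Score and classify the Rosenberg Self-Esteem Scale (SES)
#'
#' 10 items on a 1-4 scale, summed to a total in 10-40 and classified as
#' low (< 26), moderate (26-32) or high (>= 33).  The published cut points
#' leave a total of exactly 25 unassigned ("lower than 25" versus "26-32");
#' it is assigned to `low` so that the categories partition the range.  No
#' reverse scoring is applied by default; `reverse_standard = TRUE` applies
#' the instrument's conventional reverse coding of items 3, 5, 8, 9, 10.
#'
#' @param items length-10 integer vector with values in 1..4.
#' @param reverse_standard apply standard reverse coding (default FALSE).
#' @return list with `total` and `category` (factor low/moderate/high).
#' @export
classify_ses <- function(items, reverse_standard = FALSE) {
  items <- as.integer(items)
  if (length(items) != 10 || any(is.na(items)) || !all(items %in% 1:4))
    stop("SES requires exactly 10 items with values in 1..4")
  if (reverse_standard) {
    rev_items <- c(3L, 5L, 8L, 9L, 10L)
    items[rev_items] <- 5L - items[rev_items]
  }
  total <- sum(items)
  category <- if (total <= 25) "low" else if (total <= 32) "moderate" else "high"
  list(total = total,
       category = factor(category, levels = c("low", "moderate", "high")))
}

#' One-sample t statistic from printed summary statistics
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with `df = n - 1`, for comparing a
#' reported sample mean against a population norm when only the rounded
#' summaries are available.
#'
#' @param mean sample mean.
#' @param sd sample standard deviation (> 0).
#' @param n sample size (>= 2).
#' @param mu0 reference (norm) mean.
#' @return list with `t` and `df`.
#' @export
one_sample_t_from_summary <- function(mean, sd, n, mu0) {
  if (sd <= 0) stop("sd must be positive")
  if (n < 2) stop("n must be at least 2")
  list(t = (mean - mu0) / (sd / sqrt(n)), df = n - 1L)
}

#' Pearson chi-square test of a contingency table
#'
#' `sum((O - E)^2 / E)` with expectations from the margins,
#' `df = (r - 1)(c - 1)`, no continuity correction.
#'
#' @param counts r x c matrix of non-negative integer counts, r, c >= 2,
#'   with no zero row or column margin.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
chi_square_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("every row and column margin must be positive")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Score a table of questionnaire records
#'
#' Applies [score_sads()] and [classify_ses()] row-wise to a respondent
#' table whose first 28 columns are SADS items and next 10 are SES items.
#'
#' @param records data.frame or matrix with 38 columns.
#' @param reverse_standard forwarded to [classify_ses()].
#' @return data.frame with one row per respondent: `sads_avoidance`,
#'   `sads_distress`, `sads_total`, `sads_flagged`, `ses_total`,
#'   `ses_category`.
#' @export
score_questionnaires <- function(records, reverse_standard = FALSE) {
  records <- as.matrix(records)
  if (ncol(records) != 38)
    stop("expected 38 columns: 28 SADS items then 10 SES items")
  out <- lapply(seq_len(nrow(records)), function(i) {
    s <- score_sads(records[i, 1:28])
    e <- classify_ses(records[i, 29:38], reverse_standard)
    data.frame(sads_avoidance = s$avoidance, sads_distress = s$distress,
               sads_total = s$total, sads_flagged = s$flagged,
               ses_total = e$total, ses_category = as.character(e$category),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
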