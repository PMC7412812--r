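#' Percent-positivity category
#'
#' Maps the percentage of positively stained tumor cells to the 0-3
#' category scale: 0 for no staining, 1 below 25%, 2 for 25-75%
#' (boundaries included), 3 above 75%.
#'
#' @param pct Percent positive cells in `[0, 100]` (vectorized).
#' @return Integer category 0-3.
#' @export
percent_category <- function(pct) {
  if (any(pct < 0 | pct > 100)) stop("percent out of [0, 100]")
  ifelse(pct == 0, 0L,
         ifelse(pct < 25, 1L,
                ifelse(pct <= 75, 2L, 3L)))
}

#' Composite expression score
#'
#' Combines staining intensity (0-3) and percent category (0-3) into the
#' total expression score.  The operative scoring rule multiplies the two
#' (default); the additive reading described alongside it is selectable
#' with `mode = "sum"`.
#'
#' @param intensity Staining intensity 0-3 (vectorized).
#' @param pcat Percent category 0-3 from [percent_category()].
#' @param mode `"product"` (default) or `"sum"`.
#' @return Integer total score.
#' @export
total_score <- function(intensity, pcat, mode = c("product", "sum")) {
  mode <- match.arg(mode)
  if (any(!intensity %in% 0:3) || any(!pcat %in% 0:3))
    stop("intensity and percent category must be integers 0-3")
  if (mode == "product") as.integer(intensity * pcat)
  else as.integer(intensity + pcat)
}

#' Classify a total expression score
#'
#' Printed cut points: strong (+++) for total >= 6, moderate (++) for
#' 4-5, weak (+) for 1-3, null (-) for 0.  The binary summary is low for
#' {null, weak} and high for {moderate, strong}.
#'
#' @param total Total score(s) from [total_score()], non-negative.
#' @return data.frame (`total`, `category`, `binary`).
#' @export
classify_score <- function(total) {
  if (any(total < 0)) stop("negative total score")
  category <- ifelse(total >= 6, "strong",
                     ifelse(total >= 4, "moderate",
                            ifelse(total >= 1, "weak", "null")))
  binary <- ifelse(category %in% c("moderate", "strong"), "high", "low")
  data.frame(total = as.integer(total),
             category = factor(category, levels = c("null", "weak",
                                                    "moderate", "strong")),
             binary = factor(binary, levels = c("low", "high")),
             stringsAsFactors = FALSE)
}

#' Score an IHC sample table
#'
#' Convenience wrapper: percent category, total score and classification
#' for each sample row.
#'
#' @param samples data.frame with `sample_id`, `intensity` (0-3),
#'   `percent_positive` (0-100) and optionally `grade` (WHO grade 1-4 or
#'   "I".."IV").
#' @param mode Scoring mode, see [total_score()].
#' @return The input with `percent_category`, `total`, `category`,
#'   `binary` columns appended.
#' @export
score_ihc <- function(samples, mode = c("product", "sum")) {
  mode <- match.arg(mode)
  pcat <- percent_category(samples$percent_positive)
  tot <- total_score(samples$intensity, pcat, mode)
  cls <- classify_score(tot)
  cbind(samples, percent_category = pcat, total = tot,
        category = cls$category, binary = cls$binary)
}

#' Association between expression and glioma grade
#'
#' Pearson chi-square test (no continuity correction) on the contingency
#' of binary expression (low/high) against grade group (low grade = WHO
#' I-II, high grade = III-IV).
#'
#' @param scored Output of [score_ihc()] including a `grade` column
#'   (numeric 1-4 or Roman "I".."IV").
#' @return `list(statistic, df, p_value, table)`.
#' @export
grade_association <- function(scored) {
  g <- scored$grade
  if (is.character(g) || is.factor(g))
    g <- match(toupper(as.character(g)), c("I", "II", "III", "IV"))
  if (any(is.na(g)) || !all(g %in% 1:4)) stop("grades must be WHO I-IV")
  group <- factor(ifelse(g <= 2, "low_grade", "high_grade"),
                  levels = c("low_grade", "high_grade"))
  tab <- table(group, expression = scored$binary)
  if (any(dim(tab) < 2L) || any(rowSums(tab) == 0L))
    stop("degenerate contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}
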