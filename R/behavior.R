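# Freezing-score computation and the discrimination-exclusion filter.

#' Baseline-corrected freezing scores for one mouse
#'
#' Per condition, the mean over presentations of (presentation freezing % -
#' baseline freezing %), floored at 0 (freezing below the 2-min habituation
#' baseline is treated as noise).
#'
#' @param record data.frame for one mouse with columns `baseline`,
#'   `condition` (`CS_PLUS`/`CS_MINUS`) and `freezing` (%), as produced by
#'   [simulate_freezing()].
#' @return named numeric vector `c(cs_plus = , cs_minus = )` in percent.
#' @export
freezing_score <- function(record) {
  stopifnot(all(c("baseline", "condition", "freezing") %in% names(record)))
  if (any(record$freezing < 0 | record$freezing > 100) ||
      any(record$baseline < 0 | record$baseline > 100))
    stop("freezing percentages must lie in [0, 100]")
  sc <- function(cond) {
    r <- record[record$condition == cond, ]
    mean(pmax(0, r$freezing - r$baseline))
  }
  c(cs_plus = sc("CS_PLUS"), cs_minus = sc("CS_MINUS"))
}

#' Discrimination-exclusion filter
#'
#' A mouse is retained only if it discriminates between the conditioned
#' stimuli: it is excluded when the CS+ minus CS- freezing difference is
#' strictly below 30 percentage points (a difference of exactly 30 is
#' included).
#'
#' @param cs_plus,cs_minus baseline-corrected freezing scores, %.
#' @return logical: `TRUE` to include the mouse.
#' @export
discrimination_filter <- function(cs_plus, cs_minus) {
  stopifnot(cs_plus >= 0, cs_plus <= 100, cs_minus >= 0, cs_minus <= 100)
  (cs_plus - cs_minus) >= 30
}

#' Group freezing analysis
#'
#' Computes per-mouse freezing scores, applies the discrimination filter,
#' and returns scores with group means and SEMs.
#'
#' @param records data.frame of per-mouse records ([simulate_freezing()]).
#' @return list with `scores` (data.frame: mouse_id, cs_plus, cs_minus,
#'   included) and `group` (means and SEMs over included mice).
#' @export
analyze_freezing <- function(records) {
  ids <- unique(records$mouse_id)
  rows <- lapply(ids, function(id) {
    s <- freezing_score(records[records$mouse_id == id, ])
    data.frame(mouse_id = id, cs_plus = s[["cs_plus"]],
               cs_minus = s[["cs_minus"]],
               included = discrimination_filter(s[["cs_plus"]],
                                                s[["cs_minus"]]),
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  inc <- scores[scores$included, ]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(scores = scores,
       group = list(n = nrow(inc),
                    cs_plus_mean = mean(inc$cs_plus),
                    cs_plus_sem = sem(inc$cs_plus),
                    cs_minus_mean = mean(inc$cs_minus),
                    cs_minus_sem = sem(inc$cs_minus)))
}
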