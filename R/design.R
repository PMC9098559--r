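#' Sample-exclusion bookkeeping
#'
#' Applies a sequence of exclusion counts to an initial enrolment count
#' and returns the remaining sample after each step. Used to document
#' and check cohort-construction arithmetic (enrolment, medical/quality
#' exclusions, functional-data exclusions) from stated counts.
#'
#' @param initial initial number of participants.
#' @param exclusions integer vector of successive exclusion counts.
#' @return integer vector of remaining counts after each step; the last
#'   element is the final analyzed sample.
#' @examples
#' exclusionFlow(1601, c(340, 54, 514))  # 1261 1207 693
#' @export
exclusionFlow <- function(initial, exclusions) {
  stopifnot(initial >= 0, all(exclusions >= 0))
  out <- initial - cumsum(as.integer(exclusions))
  if (any(out < 0)) stop("exclusions exceed the available sample")
  as.integer(out)
}

#' Concatenated group-matrix dimensions and scan duration
#'
#' Arithmetic of the pooled group decomposition input: subjects'
#' timeseries are temporally concatenated, so the pooled matrix has
#' `n_subjects * timepoints` rows and `n_vertices` columns, and a single
#' subject's acquisition lasts `timepoints * tr_seconds` seconds.
#'
#' @param n_subjects subjects concatenated.
#' @param timepoints volumes per subject.
#' @param n_vertices surface vertices (columns).
#' @param tr_seconds repetition time in seconds.
#' @return list with `rows`, `cols`, `duration_seconds`,
#'   `duration_minutes`.
#' @examples
#' concatenationFacts(100, 555, 17734, 3)  # 55500 rows, 27.75 min
#' @export
concatenationFacts <- function(n_subjects, timepoints, n_vertices,
                               tr_seconds) {
  list(rows = n_subjects * timepoints,
       cols = n_vertices,
       duration_seconds = timepoints * tr_seconds,
       duration_minutes = timepoints * tr_seconds / 60)
}

#' Number of scales in a K range
#'
#' @param k_min,k_max inclusive bounds of the swept network counts.
#' @return integer count of scales.
#' @examples
#' scaleCount(2, 30)  # 29
#' @export
scaleCount <- function(k_min, k_max) {
  stopifnot(k_min >= 2, k_max >= k_min)
  as.integer(k_max - k_min + 1L)
}
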