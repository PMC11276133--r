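#' Potter grade from an ePVS count
#'
#' Maps a per-image ePVS count onto the ordinal 0--4 Potter scale used for
#' visual rating of perivascular-space burden: grade 0 for no ePVS, 1 for
#' 1--10 (mild), 2 for 11--20 (moderate), 3 for 21--40 (frequent) and 4 for
#' more than 40 (severe). Real-valued predictions (e.g. network outputs mapped
#' back to counts) are rounded half-up to the nearest integer before the
#' bracket lookup, because the brackets are defined on integer counts.
#'
#' @param count Numeric vector of nonnegative counts; may be fractional.
#' @return Integer vector of grades in `0:4`.
#' @examples
#' grade_from_count(c(0, 5, 11, 40, 41))
#' grade_from_count(10.5) # rounds half-up to 11 -> grade 2
#' @export
grade_from_count <- function(count) {
  if (!is.numeric(count) || length(count) == 0) {
    stopf("`count` must be a nonempty numeric vector")
  }
  if (anyNA(count)) stopf("`count` contains missing values")
  if (any(count < 0)) stopf("`count` must be nonnegative")
  n <- round_half_up(count)
  ifelse(n == 0, 0L,
    ifelse(n <= 10, 1L,
      ifelse(n <= 20, 2L,
        ifelse(n <= 40, 3L, 4L))))
}

#' Subject-level grade by the max rule
#'
#' A subject is rated on six part images (three contiguous axial slices x two
#' hemispheres); the subject-level grade is the highest of the six part-level
#' grades.
#'
#' @param part_grades Integer vector of exactly six grades in `0:4`.
#' @return A single integer grade.
#' @examples
#' subject_grade(c(1, 2, 2, 3, 1, 0))
#' @export
subject_grade <- function(part_grades) {
  if (length(part_grades) != 6) {
    stopf("`part_grades` must contain exactly 6 grades (got %d)",
          length(part_grades))
  }
  if (anyNA(part_grades) || !all(part_grades %in% 0:4)) {
    stopf("part grades must be integers in 0..4")
  }
  as.integer(max(part_grades))
}

#' The Potter grade scale as a table
#'
#' @return A tibble with one row per grade: grade, lower and upper count
#'   bounds (upper bound `Inf` for grade 4), and the conventional label.
#' @export
grade_scale <- function() {
  tibble(
    grade = 0:4,
    count_min = c(0L, 1L, 11L, 21L, 41L),
    count_max = c(0, 10, 20, 40, Inf),
    label = c("none", "mild", "moderate", "frequent", "severe")
  )
}
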