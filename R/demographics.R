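#' Packaged demographics and clinical outcomes of the hop-test cohort
#'
#' A transcription of the demographics and clinical outcome measures of the
#' 23-subject cohort the package's statistics target: 11 ACLR subjects
#' (10-15 years post-reconstruction) and 12 healthy controls, with age, index
#' limb, BMI, follow-up years, Tegner activity score, KT-1000 side-to-side
#' laxity difference (mm; positive = more lax than contralateral) and hop
#' distance ratio (%; >100 = farther than contralateral). One control
#' subject's follow-up interval is unavailable (`NA`).
#'
#' @return A tibble with one row per subject.
#' @examples
#' demo <- hop_demographics()
#' summarize_cohort(demo) |>
#'   dplyr::filter(group == "ACLR", variable == "age_years")
#' @export
hop_demographics <- function() {
  path <- system.file("extdata", "cohort_demographics.csv", package = "hopwave",
                      mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
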