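# Summary statistics of the public contrast-CT kidney cohort the phantom
# generator emulates (3847 patients, 12,446 slices; Kaggle CT kidney
# dataset).  The tables ship as plain CSV under inst/extdata; the derived
# quantities below are recomputed from the raw counts.

cohort_csv <- function(name)
  read.csv(system.file("extdata", name, package = "nephrodx"),
           stringsAsFactors = FALSE)

#' Volume-reconstruction summary of the reference cohort
#'
#' Patient counts and slice statistics for complete versus
#' slice-interpolated volumes, with the interpolated fraction recomputed
#' from the raw counts.
#'
#' @return A list with the `table` and derived `interpolated_pct`,
#'   `total_patients`.
#' @export
cohortVolumeStats <- function() {
  tab <- cohort_csv("ct_kidney_cohort_volumes.csv")
  total <- sum(tab$patients)
  interp <- tab$patients[tab$volume_type == "interpolated"]
  list(table = tab, total_patients = total,
       interpolated_pct = 100 * interp / total)
}

#' Split summary of the reference cohort
#'
#' Patient and slice counts per split with slices-per-patient recomputed
#' from the raw counts, plus the pathology-prevalence fraction.
#'
#' @return A list with the `table` (including derived
#'   `slices_per_patient`), `total_patients`, `total_slices` and the
#'   overall `slices_per_patient`.
#' @export
cohortSplitStats <- function() {
  tab <- cohort_csv("ct_kidney_cohort_splits.csv")
  tab$slices_per_patient <- tab$ct_slices / tab$patients
  tab$pathology_frac <- tab$patients_with_pathology / tab$patients
  list(table = tab, total_patients = sum(tab$patients),
       total_slices = sum(tab$ct_slices),
       slices_per_patient = sum(tab$ct_slices) / sum(tab$patients))
}

#' Pathology class distribution of the reference cohort
#' @return The class-count table with per-class totals and fractions.
#' @export
cohortClassStats <- function() {
  tab <- cohort_csv("ct_kidney_cohort_classes.csv")
  tab$total <- tab$training + tab$validation + tab$test
  tab$fraction <- tab$total / sum(tab$total)
  tab
}
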