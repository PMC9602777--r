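# Bundled study tables: individual-level data for the 12-patient MS cohort
# and the pooled control normative summaries, shipped as plain-text CSV
# under inst/extdata and loaded fresh on each call.

extdata <- function(file) {
  system.file("extdata", file, package = "hygrosense", mustWork = TRUE)
}

#' Characteristics of the 12-patient MS cohort
#'
#' Individual characteristics (sex, age, height, mass, ethnicity, EDSS,
#' MS type, medications) of the 12 participants with multiple sclerosis
#' assessed by the hygrosensory QST protocol.
#'
#' @return Participants tibble in the [hygro_dataset()] schema.
#' @export
#' @examples
#' summarize_cohort(ms_participants_table(), groups = "MS")
ms_participants_table <- function() {
  p <- read_table_file(extdata("ms_participants.csv"), "participants")
  p$id <- as.character(p$id)
  p$ms_type <- as.character(p$ms_type)
  p$medications <- as.character(p$medications)
  p
}

#' Individual MS wetness perceptions and z-scores (dynamic, thermoneutral)
#'
#' Per-participant absolute wetness perception (mm VAS) and published
#' z-scores for the dynamic stimulation of forehead and finger pad during
#' the thermoneutral session: 12 participants x 2 sites x 3 stimulus
#' qualities = 72 observations.
#'
#' @return Tibble with columns `participant_id`, `site`, `quality`,
#'   `wetness_mm`, `z`.
#' @export
ms_wetness_table <- function() {
  x <- read_table_file(extdata("ms_wetness_profiles.csv"), "ms wetness")
  x$participant_id <- as.character(x$participant_id)
  x
}

#' Control normative summary statistics for wetness perception
#'
#' Group mean and SD (mm VAS) of the pooled healthy-control normative data
#' sets for dynamic wetness perception: n = 51 for the forehead and n = 31
#' for the finger pad, per stimulus quality. Raw normative observations are
#' not bundled; these summaries parameterize the synthetic-cohort generator
#' defaults.
#'
#' @return Tibble with columns `site`, `quality`, `n`, `mean_mm`, `sd_mm`.
#' @export
ctr_normative_summary <- function() {
  read_table_file(extdata("ctr_normative_summary.csv"), "normative summary")
}
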