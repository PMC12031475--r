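# Aggregate tables from the reference feasibility study of the wearable
# system this package models: 21 participants (12 relatively healthy [RH],
# 9 self-reporting a neurodegenerative disorder [ND]) each playing three
# 5-minute games. Only published aggregates are bundled; raw recordings were
# never released.

#' Reference feasibility-study demographics
#'
#' Participant ages and group labels for the reference cohort: 12 relatively
#' healthy (RH) participants and 9 participants self-reporting a
#' neurodegenerative disorder (Parkinson's disease, multiple sclerosis, ALS,
#' spinal muscular atrophy, Charcot-Marie-Tooth disease, essential tremor).
#'
#' @return data frame with columns `participant_id`, `age`, `diagnosis`,
#'   `group` ("RH" or "ND").
#' @export
ref_demographics <- function() {
  data.frame(
    participant_id = c(paste0("P", 1:12), paste0("ND", 1:9)),
    age = c(19, 19, 23, 26, 49, 56, 63, 69, 72, 75, 82, 89,
            61, 78, 79, 81, 61, 66, 57, 71, 84),
    diagnosis = c(rep("RH", 12),
                  "PD", "PD", "PD", "PD", "MS", "ALS", "SMA", "CMT", "ET"),
    group = c(rep("RH", 12), rep("ND", 9)),
    stringsAsFactors = FALSE
  )
}

#' Reference grip-detection confusion counts
#'
#' Aggregated true-positive / false-positive / false-negative counts of
#' video-verified grip detections per group. Note the published per-group F1
#' for the ND group (0.8401) is a mean of per-participant F1 scores, which
#' is not recoverable from these pooled counts; the RH pooled-count F1
#' coincides with its printed mean (0.8343).
#'
#' @return data frame with columns `group`, `tp`, `fp`, `fn`.
#' @export
ref_detection_counts <- function() {
  data.frame(group = c("RH", "ND"),
             tp = c(3450, 2184),
             fp = c(1323, 777),
             fn = c(47, 46),
             stringsAsFactors = FALSE)
}

#' Reference questionnaire per-question means
#'
#' Published per-question mean (and SD) satisfaction scores on the 1-5
#' Likert scale for the six questionnaire items; the grand satisfaction
#' score is the mean of the six question means.
#'
#' @return data frame with columns `question`, `mean`, `sd`.
#' @export
ref_useq_means <- function() {
  data.frame(question = paste0("Q", 1:6),
             mean = c(4.76, 4.81, 4.05, 4.95, 4.38, 4.95),
             sd = c(0.44, 0.40, 0.97, 0.22, 0.80, 0.21),
             stringsAsFactors = FALSE)
}
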