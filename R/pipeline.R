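#' Run the full screening / geo-validation / dedup pipeline
#'
#' Convenience driver: screens the cohort, classifies the geography of
#' the retained records, clusters them by shared IP and variant email,
#' labels multiplicity, profiles burst intervals, charges each record to
#' its exclusion stage, and assembles the participant flow.
#'
#' @param records Submission tibble (see [read_submissions()]).
#' @param config A [pipeline_config()].
#' @return A list with elements `screen`, `verdicts`, `clusters`,
#'   `labels`, `intervals`, `charges`, `flow`, and `unique_eligible`
#'   (the retained, region-validated, non-duplicate records).
#' @export
run_pipeline <- function(records, config = pipeline_config()) {
  scr <- screen_cohort(records)
  retained <- scr$retained
  verdicts <- classify_geography(retained, config)
  clusters <- cluster_submissions(retained, config$email_threshold)
  labels <- label_multiplicity(clusters, retained, config$email_threshold)
  intervals <- interval_profile(clusters, config$interval_windows)
  charges <- charge_exclusions(retained, verdicts, config$email_threshold)
  flow <- build_flow(scr$counts, charges)
  unique_ids <- charges$submission_id[charges$charge == "unique_eligible"]
  list(
    screen = scr,
    verdicts = verdicts,
    clusters = clusters,
    labels = labels,
    intervals = intervals,
    charges = charges,
    flow = flow,
    unique_eligible = retained[retained$submission_id %in% unique_ids, ,
                               drop = FALSE]
  )
}
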