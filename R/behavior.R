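#' @include io.R
NULL

#' Score task performance per load
#'
#' Pools trials across the two runs (20 per load for complete data).
#' Accuracy is the proportion of correct trials out of all trials;
#' no-response trials (missing correctness) count as incorrect. Mean
#' response time is taken over correct trials only and is `NA` when no
#' trial was correct.
#'
#' @param eventsList list of two validated event tables.
#' @param subject subject id for the summary rows.
#' @return data.frame: subject, load, n_trials, n_correct, accuracy,
#'   mean_rt_correct.
#' @export
scoreBehavior <- function(eventsList, subject = "unknown") {
  probes <- do.call(rbind, lapply(eventsList, function(ev)
    ev[ev$event_type == "probe", c("load", "trial_id", "correct",
                                   "response_time")]))
  out <- lapply(c(1L, 3L, 5L), function(l) {
    rows <- probes[probes$load == l, , drop = FALSE]
    correct <- !is.na(rows$correct) & rows$correct
    rts <- rows$response_time[correct & !is.na(rows$response_time)]
    data.frame(subject = subject, load = l, n_trials = nrow(rows),
               n_correct = sum(correct),
               accuracy = if (nrow(rows)) sum(correct) / nrow(rows) else NA_real_,
               mean_rt_correct = if (length(rts)) mean(rts) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
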