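#' Published per-participant synergy-map divergence statistics
#'
#' Reference tables from a 20-participant keypress-learning cohort (10 of
#' whom returned for a second day): for each participant, the observed
#' Jensen-Shannon measure between two epochs' synergy distributions, the
#' permutation p-value, and its z-score. Three comparisons are shipped:
#' first trial vs the early-learning cutoff trial (trial 12), cutoff trial
#' vs final trial (trial 36), and Day-1 final trial vs Day-2 trial 3.
#'
#' These tables serve as in-package inputs for group-level (Stouffer)
#' meta-analysis and for validating the p-to-z convention -- the pipeline
#' produces the same three columns for any dataset it is run on.
#'
#' @param comparison One of `"trial1_vs_trial12"`, `"trial12_vs_trial36"`,
#'   `"day1_vs_day2"`.
#' @return Data frame with columns `participant`, `observed_jsd`, `p_perm`,
#'   `z`.
#' @examples
#' tab <- cohort_jsd_table("trial1_vs_trial12")
#' stouffer_combine(tab$z)
#' @export
cohort_jsd_table <- function(comparison = c("trial1_vs_trial12",
                                            "trial12_vs_trial36",
                                            "day1_vs_day2")) {
  comparison <- match.arg(comparison)
  path <- system.file("extdata",
                      paste0("cohort_jsd_", comparison, ".csv"),
                      package = "synkin", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(participant = "character"))
}
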