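## Baseline cohort characteristics of the multi-center study design the
## demo emulates, and their marginal totals.

#' Baseline cohort characteristics table
#'
#' Per-study subject counts of the seven-center, three-ancestry-group
#' North American study design the synthetic generator emulates: total
#' subjects, female subjects, subjects per ancestry group, allergic
#' rhinitis cases, and asthma cases.
#'
#' @return data.frame, one row per study center.
#' @export
cohortTable <- function() {
    .readTsv(system.file("extdata", "cohort_baseline.tsv",
                         package = "ariNet", mustWork = TRUE))
}

#' Marginal totals of the cohort table
#'
#' Sums the per-study counts into the study-level totals: overall
#' subjects, females, ancestry-group totals, allergic rhinitis cases
#' and the case prevalence.
#'
#' @param tbl data.frame from [cohortTable()].
#' @return named list of totals; \code{ar_prevalence} is the case
#'   fraction.
#' @export
cohortSummary <- function(tbl = cohortTable()) {
    list(n_subjects = sum(tbl$n),
         n_female = sum(tbl$n_female),
         n_european_american = sum(tbl$n_european_american),
         n_latino = sum(tbl$n_latino),
         n_african_american = sum(tbl$n_african_american),
         n_ar_cases = sum(tbl$n_ar),
         n_asthma = sum(tbl$n_asthma),
         ar_prevalence = sum(tbl$n_ar) / sum(tbl$n))
}
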