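#' Reference group summaries of microstate metrics in chronic insomnia
#'
#' Bundled group-level summary statistics (mean and SD per microstate class
#' and metric) reported for a chronic-insomnia electroacupuncture cohort:
#' healthy controls (`HC`, n = 19) and patients before (`Pre-EA`) and after
#' (`Post-EA`) treatment (n = 41). These printed values serve as
#' documentation-test inputs for the package's metric conventions (coverages
#' summing to ~100, the coverage = occurrence x duration identity) and as
#' realistic targets for the simulator defaults; they are not recomputed by
#' the package.
#'
#' @return tidy tibble with columns `metric`, `class`, `group`, `mean`, `sd`.
#' @export
ci_reference_metrics <- function() {
  tibble::tribble(
    ~metric,      ~class, ~group,    ~mean,  ~sd,
    "coverage",   "A",    "HC",      17.66,  8.82,
    "coverage",   "B",    "HC",      21.37,  6.87,
    "coverage",   "C",    "HC",      23.42, 16.16,
    "coverage",   "D",    "HC",      33.00, 12.88,
    "coverage",   "A",    "Pre-EA",  23.09,  6.87,
    "coverage",   "B",    "Pre-EA",  21.12,  6.87,
    "coverage",   "C",    "Pre-EA",  26.83, 11.48,
    "coverage",   "D",    "Pre-EA",  28.95,  8.52,
    "coverage",   "A",    "Post-EA", 20.86, 14.19,
    "coverage",   "B",    "Post-EA", 27.83, 16.99,
    "coverage",   "C",    "Post-EA", 34.73, 18.41,
    "coverage",   "D",    "Post-EA", 16.59, 12.32,
    "duration",   "A",    "HC",      58.38,  8.64,
    "duration",   "B",    "HC",      66.85, 16.53,
    "duration",   "C",    "HC",      66.52, 26.49,
    "duration",   "D",    "HC",      75.97, 22.73,
    "duration",   "A",    "Pre-EA",  62.01,  7.25,
    "duration",   "B",    "Pre-EA",  59.75,  6.82,
    "duration",   "C",    "Pre-EA",  69.04, 26.39,
    "duration",   "D",    "Pre-EA",  67.19, 12.99,
    "duration",   "A",    "Post-EA", 57.67, 14.96,
    "duration",   "B",    "Post-EA", 66.08, 29.04,
    "duration",   "C",    "Post-EA", 76.36, 34.97,
    "duration",   "D",    "Post-EA", 51.14, 18.45,
    "occurrence", "A",    "HC",       2.89,  1.21,
    "occurrence", "B",    "HC",       3.71,  1.12,
    "occurrence", "C",    "HC",       3.25,  1.34,
    "occurrence", "D",    "HC",       4.24,  1.05,
    "occurrence", "A",    "Pre-EA",   3.69,  0.97,
    "occurrence", "B",    "Pre-EA",   3.51,  0.80,
    "occurrence", "C",    "Pre-EA",   3.84,  0.74,
    "occurrence", "D",    "Pre-EA",   4.28,  0.88,
    "occurrence", "A",    "Post-EA",  3.28,  1.61,
    "occurrence", "B",    "Post-EA",  3.93,  1.33,
    "occurrence", "C",    "Post-EA",  4.38,  1.37,
    "occurrence", "D",    "Post-EA",  2.89,  1.50
  )
}

#' Reference transition-probability summaries (organizational transition
#' matrix)
#'
#' Companion to [ci_reference_metrics()]: the printed group means and SDs of
#' the 12 ordered between-class transition percentages for the same cohort.
#'
#' @return tidy tibble with columns `from`, `to`, `group`, `mean`, `sd`.
#' @export
ci_reference_transitions <- function() {
  tibble::tribble(
    ~from, ~to, ~group,    ~mean,  ~sd,
    "A", "B", "HC",       6.13, 3.19,
    "A", "C", "HC",       5.57, 3.20,
    "A", "D", "HC",       8.19, 4.30,
    "B", "A", "HC",       6.06, 3.08,
    "B", "C", "HC",       7.88, 5.77,
    "B", "D", "HC",      12.65, 7.95,
    "C", "A", "HC",       5.71, 3.23,
    "C", "B", "HC",       7.82, 5.62,
    "C", "D", "HC",       9.58, 5.45,
    "D", "A", "HC",       8.08, 4.28,
    "D", "B", "HC",      12.59, 7.79,
    "D", "C", "HC",       9.74, 5.39,
    "A", "B", "Pre-EA",   6.52, 2.45,
    "A", "C", "Pre-EA",   8.01, 2.66,
    "A", "D", "Pre-EA",   9.29, 3.63,
    "B", "A", "Pre-EA",   6.65, 2.40,
    "B", "C", "Pre-EA",   7.56, 2.81,
    "B", "D", "Pre-EA",   8.60, 2.38,
    "C", "A", "Pre-EA",   7.98, 2.72,
    "C", "B", "Pre-EA",   7.58, 2.87,
    "C", "D", "Pre-EA",  10.02, 3.47,
    "D", "A", "Pre-EA",   9.16, 3.48,
    "D", "B", "Pre-EA",   8.67, 2.66,
    "D", "C", "Pre-EA",   9.97, 3.35,
    "A", "B", "Post-EA",  6.79, 2.45,
    "A", "C", "Post-EA",  9.69, 1.04,
    "A", "D", "Post-EA",  5.56, 5.81,
    "B", "A", "Post-EA",  6.94, 4.27,
    "B", "C", "Post-EA", 13.82, 1.43,
    "B", "D", "Post-EA",  6.76, 5.92,
    "C", "A", "Post-EA",  9.56, 6.73,
    "C", "B", "Post-EA", 13.93, 9.30,
    "C", "D", "Post-EA",  7.33, 5.06,
    "D", "A", "Post-EA",  5.52, 5.85,
    "D", "B", "Post-EA",  6.80, 6.12,
    "D", "C", "Post-EA",  7.31, 5.26
  )
}

#' Reference responder counts for the prediction stage
#'
#' The printed class structure of the treated cohort: 41 patients, 14
#' responders and 27 non-responders under the 50% PSQI-reduction rule; the
#' quantities the responder-arithmetic worked example reproduces.
#'
#' @return one-row tibble: `n`, `responders`, `non_responders`.
#' @export
ci_reference_cohort <- function() {
  tibble::tibble(n = 41L, responders = 14L, non_responders = 27L)
}
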