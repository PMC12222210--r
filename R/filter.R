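#' Select candidate SV-tagging loci from two cohorts' NMI tables
#'
#' Applies the three filters that define the high-confidence candidate set:
#' NMI frequency at least `f_disc_min` in the discovery cohort, at least
#' `f_both_min` in *both* cohorts, and absence from a blacklist of loci
#' already known as common structural variants in reference populations.
#' Per-step in/out counts are recorded so the filtering is auditable.
#'
#' @param disc,valid NMI tables from [nmi_frequencies()] for the discovery
#'   and validation cohorts; they must share manifest loci.
#' @param blacklist Character vector of `locus_id`s to exclude (matched by id
#'   only).
#' @param f_disc_min Minimum NMI frequency in the discovery cohort
#'   (default 0.02, the assumed population frequency of the phenotype and
#'   40x the array's technical error rate).
#' @param f_both_min Minimum NMI frequency required in both cohorts
#'   (default 0.15).
#' @return A tibble of retained loci (columns `locus_id`, `chrom`, `pos`,
#'   `nmi_freq_disc`, `nmi_freq_valid`) of class `nmisv_candidates`, with a
#'   `steps` attribute logging counts in/out per filter step and a
#'   `thresholds` attribute.
#' @export
select_candidates <- function(disc, valid, blacklist = character(),
                              f_disc_min = 0.02, f_both_min = 0.15) {
  j <- inner_join(
    select(disc, "locus_id", "chrom", "pos", nmi_freq_disc = "nmi_freq"),
    select(valid, "locus_id", nmi_freq_valid = "nmi_freq"),
    by = "locus_id"
  )
  if (nrow(j) == 0) abort("discovery and validation tables share no manifest loci")
  steps <- list()
  log_step <- function(name, n_in, n_out) {
    steps[[length(steps) + 1]] <<- tibble(step = name, n_in = n_in, n_out = n_out)
  }
  n0 <- nrow(j)
  j1 <- filter(j, !is.na(.data$nmi_freq_disc), .data$nmi_freq_disc >= f_disc_min)
  log_step(sprintf("discovery_freq>=%.4g", f_disc_min), n0, nrow(j1))
  j2 <- filter(j1, !is.na(.data$nmi_freq_valid),
               .data$nmi_freq_disc >= f_both_min,
               .data$nmi_freq_valid >= f_both_min)
  log_step(sprintf("both_freq>=%.4g", f_both_min), nrow(j1), nrow(j2))
  j3 <- filter(j2, !(.data$locus_id %in% blacklist))
  log_step("blacklist", nrow(j2), nrow(j3))
  structure(
    j3,
    steps = bind_rows(steps),
    thresholds = c(f_disc_min = f_disc_min, f_both_min = f_both_min),
    n_blacklist = length(blacklist),
    class = c("nmisv_candidates", class(j3))
  )
}

#' Binomial probability of recurrent assay failure at one locus
#'
#' The probability that a SNP assay with per-assay failure probability
#' `error_rate` fails `k` times in `n` independent tests, used to argue that
#' loci violating Mendelian expectations in many families cannot be
#' explained by the platform's technical error rate (about 0.05% per assay
#' for the arrays modelled here). Computed in log space.
#'
#' @param error_rate Per-trial failure probability in `[0, 1]`.
#' @param n Number of trials.
#' @param k Number of failures, `0 <= k <= n`.
#' @param tail `"pmf"` for the point probability `P(X = k)`; `"upper"` for
#'   `P(X >= k)`.
#' @return A probability.
#' @export
#' @examples
#' binomial_error_probability(0.0005, 380, 7) # ~1.4e-9
binomial_error_probability <- function(error_rate, n, k,
                                       tail = c("pmf", "upper")) {
  tail <- match.arg(tail)
  stopifnot(error_rate >= 0, error_rate <= 1, n >= 0)
  if (k > n || k < 0) abort("k must satisfy 0 <= k <= n")
  if (tail == "pmf") {
    exp(dbinom(k, n, error_rate, log = TRUE))
  } else {
    if (k == 0) 1 else pbinom(k - 1, n, error_rate, lower.tail = FALSE)
  }
}

#' Number of families corresponding to an NMI frequency
#'
#' Converts a frequency threshold to a count of families, using floor
#' rounding (so a 2% rate in 380 families corresponds to 7 individuals,
#' 0.02 * 380 = 7.6 -> 7). Floor is a reporting convention, not a
#' mathematically canonical choice; the rounding rule is recorded in the
#' result's name.
#'
#' @param f Frequency in `[0, 1]`.
#' @param n_families Number of families tested.
#' @return Named integer (`floor`).
#' @export
min_count_at_frequency <- function(f, n_families) {
  stopifnot(f >= 0, f <= 1, n_families >= 0)
  c(floor = as.integer(floor(f * n_families)))
}
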