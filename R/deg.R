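#' Filter an expression summary to testable genes
#'
#' Keeps genes whose maximum group mean exceeds `min_mean` (strict
#' inequality) and drops genes on the X and Y chromosomes, matching the
#' autosomal scope of the upstream NMI analysis. Differential-expression
#' calling itself (mapping, normalisation, FDR) is upstream of this package:
#' `is_de` arrives as an input column.
#'
#' @param summary Tibble with columns `gene_id`, `chrom`, `max_group_mean`,
#'   `is_de` (logical).
#' @param min_mean Expression floor (default 1).
#' @return The filtered tibble.
#' @export
filter_expressed <- function(summary, min_mean = 1) {
  summary <- as_tibble(summary)
  stopifnot(all(c("gene_id", "chrom", "max_group_mean") %in% names(summary)))
  filter(summary,
         .data$max_group_mean > min_mean,
         !(norm_chrom(.data$chrom) %in% c("X", "Y")))
}

#' Are target genes differentially expressed more often than expected?
#'
#' Compares the differential-expression rate among a designated target gene
#' set (e.g. genes regulated by transcription factors whose binding sites
#' are disrupted) to the genome-wide rate. The expected number of
#' differentially expressed target genes is `(D / G) * T`, where `G` is the
#' number of expressed genes, `D` the number differentially expressed, and
#' `T` the number of expressed target genes; the primary statistic is a
#' 1-df two-cell goodness of fit of the observed DE-target count against
#' that expectation. Because the exact chi-square construction for this
#' design is a modelling choice, the 2x2 contingency chi-square (with and
#' without Yates continuity correction) is also reported.
#'
#' @param expressed Expression summary already filtered by
#'   [filter_expressed()]; must contain `gene_id` and `is_de`.
#' @param target_genes Character vector of target gene ids (intersected with
#'   the expressed genes).
#' @return One-row tibble of class `nmisv_deg`: `G`, `D`, `T_genes`,
#'   `t_obs`, `overall_rate`, `target_rate`, `expected`, `fold`, `chi2`,
#'   `p`, `chi2_2x2`, `p_2x2`, `p_2x2_yates`, `flagged`.
#' @export
target_deg_test <- function(expressed, target_genes) {
  expressed <- as_tibble(expressed)
  stopifnot(all(c("gene_id", "is_de") %in% names(expressed)))
  g_all <- expressed$gene_id
  de <- as.logical(expressed$is_de)
  G <- length(g_all)
  D <- sum(de)
  in_target <- g_all %in% unique(target_genes)
  T_genes <- sum(in_target)
  if (T_genes == 0) abort("no target genes among the expressed genes")
  t_obs <- sum(de & in_target)
  overall_rate <- D / G
  target_rate <- t_obs / T_genes
  expected <- overall_rate * T_genes
  fold <- if (overall_rate > 0) target_rate / overall_rate else NA_real_
  flagged <- expected == 0 || expected == T_genes
  if (!flagged) {
    chi2 <- (t_obs - expected)^2 / expected +
      (t_obs - expected)^2 / (T_genes - expected)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p <- NA_real_
  }
  tab <- matrix(c(t_obs, T_genes - t_obs,
                  D - t_obs, (G - T_genes) - (D - t_obs)), nrow = 2)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  cs_y <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  res <- tibble(
    G = G, D = D, T_genes = T_genes, t_obs = t_obs,
    overall_rate = overall_rate, target_rate = target_rate,
    expected = expected, fold = fold, chi2 = chi2, p = p,
    chi2_2x2 = unname(cs$statistic), p_2x2 = cs$p.value,
    p_2x2_yates = cs_y$p.value, flagged = flagged
  )
  structure(res, class = c("nmisv_deg", class(res)))
}
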