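#' Build a trio cohort object
#'
#' A `trio_cohort` bundles a SNP manifest, a pedigree of father/mother/child
#' trios, and the genotype call matrix. The calls are kept as a compact
#' integer matrix (loci in rows, individuals in columns; see
#' [genotype_codes()]); everything derived from the cohort is returned as a
#' tibble. The target scale (up to ~10^6 loci by ~10^4 individuals) is held
#' in memory; there is no streaming mode.
#'
#' @param manifest Tibble with columns `locus_id`, `chrom`, `pos` (1-based).
#' @param trios Tibble with columns `father`, `mother`, `child` (individual
#'   ids), optionally `family`.
#' @param calls Integer matrix, `nrow(manifest)` rows by individuals, with
#'   dimnames `list(locus_id, individual_id)`; values 0/1/2/NA.
#' @param pedigree Optional tibble describing all individuals (columns
#'   `individual`, `family`, `father`, `mother`); reconstructed from `trios`
#'   when absent.
#' @return An object of class `trio_cohort`.
#' @export
trio_cohort <- function(manifest, trios, calls, pedigree = NULL) {
  manifest <- as_tibble(manifest)
  trios <- as_tibble(trios)
  stopifnot(all(c("locus_id", "chrom", "pos") %in% names(manifest)),
            all(c("father", "mother", "child") %in% names(trios)))
  if (anyDuplicated(manifest$locus_id)) {
    abort("duplicate locus_id in manifest")
  }
  if (any(manifest$pos < 1)) abort("manifest positions must be 1-based (>= 1)")
  if (!is.matrix(calls) || nrow(calls) != nrow(manifest)) {
    abort("calls must be a matrix with one row per manifest locus")
  }
  if (is.null(rownames(calls))) rownames(calls) <- manifest$locus_id
  members <- unique(c(trios$father, trios$mother, trios$child))
  missing_ind <- setdiff(members, colnames(calls))
  if (length(missing_ind)) {
    abort(paste0("trio members absent from call matrix: ",
                 paste(head(missing_ind, 5), collapse = ", ")))
  }
  bad <- with(trios, father == mother | father == child | mother == child)
  if (any(bad)) abort("trio member ids must be distinct within a trio")
  if (is.null(pedigree)) {
    pedigree <- dplyr::bind_rows(
      tibble(individual = trios$child, father = trios$father,
             mother = trios$mother),
      tibble(individual = unique(c(trios$father, trios$mother)),
             father = "0", mother = "0")
    )
  }
  structure(
    list(manifest = manifest, trios = trios, calls = calls,
         pedigree = as_tibble(pedigree)),
    class = "trio_cohort"
  )
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("<trio_cohort> %d loci x %d individuals, %d trios\n",
              nrow(x$manifest), ncol(x$calls), nrow(x$trios)))
  invisible(x)
}

#' Classify a trio genotype combination at a biallelic autosomal locus
#'
#' A (father, mother, child) call triple is a `"violation"` when no pair of
#' transmitted alleles, one from each parent, can produce the child genotype;
#' `"incomplete"` when any of the three calls is missing; `"consistent"`
#' otherwise. Vectorised over the three arguments.
#'
#' @param father,mother,child Integer genotype calls (0/1/2/NA, see
#'   [genotype_codes()]).
#' @return Character vector in `c("consistent", "violation", "incomplete")`.
#' @export
#' @examples
#' classify_trio(0L, 0L, 1L) # child carries an allele absent in both parents
#' classify_trio(1L, 1L, 2L) # both parents can transmit the alternate allele
classify_trio <- function(father, mother, child) {
  n <- max(length(father), length(mother), length(child))
  f <- rep_len(as.integer(father), n)
  m <- rep_len(as.integer(mother), n)
  c_ <- rep_len(as.integer(child), n)
  ok <- function(x) is.na(x) | (x >= 0L & x <= 2L)
  if (!all(ok(f) & ok(m) & ok(c_))) abort("genotype calls must be 0, 1, 2 or NA")
  inc <- is.na(f) | is.na(m) | is.na(c_)
  viol <- !inc & (
    (c_ == 0L & (f == 2L | m == 2L)) |
    (c_ == 2L & (f == 0L | m == 0L)) |
    (c_ == 1L & ((f == 0L & m == 0L) | (f == 2L & m == 2L)))
  )
  out <- rep("consistent", n)
  out[viol] <- "violation"
  out[inc] <- "incomplete"
  out
}

#' Per-locus non-Mendelian inheritance frequencies for a cohort
#'
#' Classifies every (locus, trio) pair and aggregates to per-locus counts of
#' informative trios (all three calls present) and Mendelian violations. The
#' NMI frequency is violations / informative trios; loci with no informative
#' trio get `nmi_freq = NA` and are flagged. Loci on X, Y or MT are dropped
#' before classification: only autosomal transmission rules are implemented.
#'
#' @param cohort A [trio_cohort()].
#' @return A tibble (one row per autosomal manifest locus) with columns
#'   `locus_id`, `chrom`, `pos`, `n_informative`, `n_violations`, `nmi_freq`,
#'   `undefined`.
#' @export
nmi_frequencies <- function(cohort) {
  stopifnot(inherits(cohort, "trio_cohort"))
  if (nrow(cohort$trios) < 1) abort("cohort has no trios")
  keep <- !is_sex_or_mito(cohort$manifest$chrom)
  if (!all(keep)) {
    inform(sprintf("dropping %d non-autosomal loci before NMI classification",
                   sum(!keep)))
  }
  man <- cohort$manifest[keep, , drop = FALSE]
  fa <- cohort$calls[keep, cohort$trios$father, drop = FALSE]
  mo <- cohort$calls[keep, cohort$trios$mother, drop = FALSE]
  ch <- cohort$calls[keep, cohort$trios$child, drop = FALSE]
  inc <- is.na(fa) | is.na(mo) | is.na(ch)
  viol <- !inc & (
    (ch == 0L & (fa == 2L | mo == 2L)) |
    (ch == 2L & (fa == 0L | mo == 0L)) |
    (ch == 1L & ((fa == 0L & mo == 0L) | (fa == 2L & mo == 2L)))
  )
  n_inf <- as.integer(rowSums(!inc))
  n_vio <- as.integer(rowSums(viol))
  tibble(
    locus_id = man$locus_id, chrom = man$chrom, pos = man$pos,
    n_informative = n_inf, n_violations = n_vio,
    nmi_freq = ifelse(n_inf > 0L, n_vio / n_inf, NA_real_),
    undefined = n_inf == 0L
  )
}

#' Concordance of NMI frequency spectra between two cohorts
#'
#' Given per-locus NMI tables from a discovery and a validation cohort,
#' computes (i) the fraction of loci at or above `min_freq` in the first
#' cohort that are also at or above it in the second, and (ii) the Pearson
#' correlation of the NMI frequencies over loci at or above the threshold in
#' both.
#'
#' @param a,b NMI tables from [nmi_frequencies()] sharing a manifest.
#' @param min_freq Frequency threshold in `[0, 1]`.
#' @return One-row tibble with `overlap_fraction`, `pearson_r`, `n_a`,
#'   `n_b`, `n_both`. `pearson_r` is `NA` (with a warning) when fewer than
#'   two loci qualify in both cohorts.
#' @export
cohort_concordance <- function(a, b, min_freq) {
  stopifnot(min_freq >= 0, min_freq <= 1)
  j <- inner_join(
    select(a, "locus_id", fa = "nmi_freq"),
    select(b, "locus_id", fb = "nmi_freq"),
    by = "locus_id"
  )
  if (nrow(j) == 0) abort("NMI tables share no loci")
  in_a <- !is.na(j$fa) & j$fa >= min_freq
  in_b <- !is.na(j$fb) & j$fb >= min_freq
  both <- in_a & in_b
  overlap <- if (sum(in_a) > 0) sum(both) / sum(in_a) else NA_real_
  if (sum(both) >= 2) {
    r <- cor(j$fa[both], j$fb[both])
  } else {
    warn("fewer than 2 loci pass min_freq in both cohorts; pearson_r is NA")
    r <- NA_real_
  }
  tibble(overlap_fraction = overlap, pearson_r = r,
         n_a = sum(in_a), n_b = sum(in_b), n_both = sum(both))
}
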