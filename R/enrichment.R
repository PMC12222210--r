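#' Flanking windows around SNP loci
#'
#' Converts 1-based SNP positions to 0-based half-open windows of
#' `2 * flank_bp + 1` bp centred on the SNP (left-clipped at 0). This is the
#' single place where the 1-based manifest coordinate system is converted to
#' the 0-based half-open interval system used by every interval consumer.
#'
#' @param loci Tibble with columns `locus_id`, `chrom`, `pos` (1-based).
#' @param flank_bp Flank size in bp on each side of the SNP (default 1000,
#'   chosen to capture variation linked to a tagged structural variant and
#'   comparable to typical transcription-factor binding site sizes).
#' @return Tibble `chrom`, `start`, `end`, `locus_id`, one window per locus
#'   in input order.
#' @export
#' @examples
#' make_windows(tibble::tibble(locus_id = "rs1", chrom = "1", pos = 1001))
make_windows <- function(loci, flank_bp = 1000) {
  stopifnot(flank_bp >= 0)
  loci <- as_tibble(loci)
  tibble(
    chrom = norm_chrom(loci$chrom),
    start = pmax(0L, as.integer(loci$pos) - 1L - as.integer(flank_bp)),
    end = as.integer(loci$pos) + as.integer(flank_bp),
    locus_id = loci$locus_id
  )
}

# 0-based half-open tibble -> GRanges (IRanges is 1-based closed).
as_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(intervals$chrom),
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end)
  )
}

#' Which windows overlap a feature track?
#'
#' Returns, for each window, whether it overlaps at least one track interval
#' by at least 1 bp. Track intervals are merged per chromosome first, so a
#' window counts at most once per feature class no matter how many raw
#' intervals it touches.
#'
#' @param windows,track Tibbles of 0-based half-open intervals (`chrom`,
#'   `start`, `end`).
#' @return Logical vector along `windows`, named by `locus_id` when present.
#' @export
overlap_flags <- function(windows, track) {
  if (nrow(track) == 0) {
    return(setNames(rep(FALSE, nrow(windows)), windows$locus_id))
  }
  hits <- GenomicRanges::countOverlaps(
    as_granges(windows), GenomicRanges::reduce(as_granges(track))) > 0
  if ("locus_id" %in% names(windows)) names(hits) <- windows$locus_id
  hits
}

#' Count windows overlapping a feature track
#'
#' @inheritParams overlap_flags
#' @return Integer count of windows overlapping at least one interval.
#' @export
count_overlaps <- function(windows, track) {
  sum(overlap_flags(windows, track))
}

#' Draw the null ensemble of random SNP sets from the array background
#'
#' Samples `n_sets` sets of `set_size` loci uniformly without replacement
#' from the background manifest, excluding the candidate loci (sampling is
#' with replacement *across* sets). The ensemble supplies the expected
#' feature-overlap counts against which candidate overlap is tested.
#'
#' @param background Character vector of background locus ids, or a tibble
#'   with a `locus_id` column (the array manifest).
#' @param candidates Character vector (or tibble) of candidate locus ids to
#'   exclude from the pool.
#' @param set_size Number of loci per null set (normally the candidate-set
#'   size).
#' @param n_sets Number of null sets (default 100).
#' @param seed Integer seed; the ensemble is reproducible given the seed.
#' @return An object of class `nmisv_null_sets`: list with `sets` (a
#'   `set_size` x `n_sets` character matrix of locus ids), `set_size`,
#'   `n_sets`, `n_background`, `seed`.
#' @export
sample_null_sets <- function(background, candidates, set_size,
                             n_sets = 100, seed = NULL) {
  bg <- if (is.data.frame(background)) background$locus_id else background
  cand <- if (is.data.frame(candidates)) candidates$locus_id else candidates
  pool <- setdiff(bg, cand)
  if (length(pool) < set_size) {
    abort(sprintf("background minus candidates has %d loci; need %d",
                  length(pool), set_size))
  }
  sets <- with_seed_if(seed, {
    vapply(seq_len(n_sets), function(i) sample(pool, set_size),
           character(set_size))
  })
  structure(list(sets = sets, set_size = as.integer(set_size),
                 n_sets = as.integer(n_sets),
                 n_background = length(pool), seed = seed),
            class = "nmisv_null_sets")
}

#' @export
print.nmisv_null_sets <- function(x, ...) {
  cat(sprintf("<nmisv_null_sets> %d sets of %d loci from %d background loci\n",
              x$n_sets, x$set_size, x$n_background))
  invisible(x)
}

#' Per-set overlap counts for a null ensemble
#'
#' @param null_sets An [sample_null_sets()] ensemble.
#' @param flags Logical vector named by `locus_id` (e.g. from
#'   [overlap_flags()] on the full manifest's windows), `TRUE` where the
#'   locus' window overlaps the feature class.
#' @return Integer vector of length `n_sets`.
#' @export
ensemble_counts <- function(null_sets, flags) {
  stopifnot(inherits(null_sets, "nmisv_null_sets"), !is.null(names(flags)))
  m <- matrix(flags[null_sets$sets], nrow = null_sets$set_size)
  if (anyNA(m)) abort("null-set loci missing from flags vector")
  as.integer(colSums(m))
}

#' Test one feature class for enrichment against the null ensemble
#'
#' The expected overlap count `E` is the null-ensemble mean; the statistic
#' is a 1-df two-cell goodness of fit over (overlap, non-overlap):
#' `X^2 = (O - E)^2 / E + (O - E)^2 / (N - E)` with `N = set_size`, with the
#' p-value from the upper tail of chi-square(1). An empirical permutation
#' p-value (two-sided rank of `O` among the null counts) is also reported.
#' Classes where the observed or expected count is at or below `min_count`
#' are flagged and their p-values suppressed (the chi-square approximation
#' is unreliable there).
#'
#' @param observed Observed overlap count for the candidate set.
#' @param null_counts Integer vector of per-set null overlap counts (or an
#'   `nmisv_null_sets`-derived vector from [ensemble_counts()]).
#' @param set_size Number of loci per set.
#' @param class_label Feature class name.
#' @param correction `"bonferroni"` (default) multiplies the raw p by
#'   `n_tests`, capped at 1. For Benjamini-Hochberg control across a family
#'   of classes use [enrich_features()], which adjusts jointly.
#' @param n_tests Size of the test family for the Bonferroni correction.
#' @param min_count Low-count suppression threshold (default 5).
#' @return One-row tibble: `class_label`, `observed`, `null_mean`,
#'   `null_sd`, `ratio`, `chi2`, `p_raw`, `p_perm`, `p_adj`, `direction`
#'   (`enriched` / `depleted` / `ns`), `low_count_flag`.
#' @export
enrichment_test <- function(observed, null_counts, set_size,
                            class_label = "feature",
                            correction = c("bonferroni", "bh"),
                            n_tests = 1, min_count = 5) {
  correction <- match.arg(correction)
  stopifnot(observed >= 0, observed <= set_size, n_tests >= 1)
  nc <- as.numeric(null_counts)
  e <- mean(nc)
  n <- as.numeric(set_size)
  o <- as.numeric(observed)
  low <- o <= min_count || e <= min_count
  degenerate <- (e <= 0 || e >= n) && o != e
  if (e > 0 && e < n) {
    chi2 <- (o - e)^2 / e + (o - e)^2 / (n - e)
    p_raw <- pchisq(chi2, df = 1, lower.tail = FALSE)
  } else if (o == e) {
    chi2 <- 0
    p_raw <- 1
  } else {
    chi2 <- NA_real_
    p_raw <- NA_real_
  }
  if (low || degenerate) p_raw <- NA_real_  # chi-square unreliable here
  p_perm <- (1 + sum(abs(nc - e) >= abs(o - e))) / (length(nc) + 1)
  p_adj <- if (correction == "bonferroni") pmin(1, p_raw * n_tests) else p_raw
  direction <- if (o == e) "ns" else if (o > e) "enriched" else "depleted"
  tibble(
    class_label = class_label, observed = as.integer(observed),
    null_mean = e, null_sd = sd(nc), ratio = if (e > 0) o / e else NA_real_,
    chi2 = chi2, p_raw = p_raw, p_perm = p_perm, p_adj = p_adj,
    direction = direction, low_count_flag = low || degenerate
  )
}

#' Feature-class enrichment of candidate loci against the array background
#'
#' The full windowed-enrichment analysis: builds `+/- flank_bp` windows for
#' every manifest locus, draws one null ensemble of `n_sets` random same-size
#' SNP sets from the background excluding candidates, counts window/track
#' overlaps per feature class, and tests each class with
#' [enrichment_test()]. Multiplicity is corrected across the supplied family
#' of classes: Bonferroni (`p_adj = p_raw * n_tests`) or Benjamini-Hochberg
#' (joint step-up across the family).
#'
#' @param candidates Candidate loci: tibble with `locus_id` (e.g. from
#'   [select_candidates()]) or a character vector of ids.
#' @param manifest Array manifest tibble (`locus_id`, `chrom`, `pos`).
#' @param tracks Named list of feature tracks (tibbles `chrom`, `start`,
#'   `end`), one per class; names are the class labels.
#' @param flank_bp Window flank (default 1000).
#' @param n_sets,seed Null-ensemble size and seed (see
#'   [sample_null_sets()]).
#' @param correction `"bonferroni"` or `"bh"`; applied across the classes in
#'   `tracks` (`n_tests = length(tracks)` unless overridden).
#' @param n_tests Family size for Bonferroni (defaults to the number of
#'   classes tested).
#' @param min_count Low-count suppression threshold (default 5).
#' @return Tibble of class `nmisv_enrichment`, one row per feature class
#'   (see [enrichment_test()]), with attributes `set_size`, `n_sets`,
#'   `seed`, `correction`, `flank_bp`.
#' @export
enrich_features <- function(candidates, manifest, tracks, flank_bp = 1000,
                            n_sets = 100, seed = NULL,
                            correction = c("bonferroni", "bh"),
                            n_tests = NULL, min_count = 5) {
  correction <- match.arg(correction)
  cand <- if (is.data.frame(candidates)) candidates$locus_id else candidates
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    abort("tracks must be a named list (names are the class labels)")
  }
  n_tests <- n_tests %||% length(tracks)
  windows <- make_windows(manifest, flank_bp = flank_bp)
  if (!all(cand %in% manifest$locus_id)) {
    abort("candidate loci missing from manifest")
  }
  ens <- sample_null_sets(manifest$locus_id, cand, set_size = length(cand),
                          n_sets = n_sets, seed = seed)
  rows <- purrr::imap(tracks, function(track, label) {
    flags <- overlap_flags(windows, track)
    enrichment_test(
      observed = sum(flags[cand]),
      null_counts = ensemble_counts(ens, flags),
      set_size = length(cand), class_label = label,
      correction = "bonferroni", n_tests = n_tests, min_count = min_count
    )
  })
  res <- bind_rows(rows)
  if (correction == "bh") res$p_adj <- p.adjust(res$p_raw, method = "BH")
  structure(res,
            set_size = length(cand), n_sets = n_sets, seed = seed,
            correction = correction, flank_bp = flank_bp,
            class = c("nmisv_enrichment", class(res)))
}

#' Exact-locus overlap with a site list
#'
#' For site lists keyed by locus (eQTL catalogues), candidates are matched
#' exactly rather than by windowed overlap: by `locus_id` when both sides
#' carry ids, otherwise by `(chrom, pos)`.
#'
#' @param loci Tibble of query loci (`locus_id` and/or `chrom` + `pos`).
#' @param sites Tibble of sites with the same keying options.
#' @return Integer: number of query loci present in the site list.
#'   Duplicate sites are deduplicated with a warning.
#' @export
exact_match_overlap <- function(loci, sites) {
  sum(exact_match_flags(loci, sites))
}

#' @rdname exact_match_overlap
#' @return `exact_match_flags()` returns a logical vector along `loci`,
#'   named by `locus_id` when available.
#' @export
exact_match_flags <- function(loci, sites) {
  loci <- as_tibble(loci)
  sites <- as_tibble(sites)
  has_ids <- function(x) "locus_id" %in% names(x) && !anyNA(x$locus_id)
  if (has_ids(loci) && has_ids(sites)) {
    key <- sites$locus_id
  } else {
    if (!all(c("chrom", "pos") %in% names(loci)) ||
        !all(c("chrom", "pos") %in% names(sites))) {
      abort("need locus_id on both sides, or chrom+pos on both sides")
    }
    key <- paste(norm_chrom(sites$chrom), sites$pos, sep = ":")
  }
  if (anyDuplicated(key)) {
    warn("duplicate sites deduplicated before exact matching")
    key <- unique(key)
  }
  if (has_ids(loci) && "locus_id" %in% names(sites) && !anyNA(sites$locus_id)) {
    flags <- loci$locus_id %in% key
  } else {
    flags <- paste(norm_chrom(loci$chrom), loci$pos, sep = ":") %in% key
  }
  if ("locus_id" %in% names(loci)) names(flags) <- loci$locus_id
  flags
}

#' Exact-match enrichment of candidate loci in a site list
#'
#' The eQTL-style analysis: observed and null overlap use exact locus
#' matching against `sites` instead of windowed interval overlap. When
#' `group_col` names a column of `sites` (e.g. a tissue/organ bin), one test
#' per group plus an `"overall"` test is run, with multiplicity corrected
#' across those tests.
#'
#' @inheritParams enrich_features
#' @param sites Site list tibble (`locus_id` and/or `chrom` + `pos`,
#'   optionally a grouping column).
#' @param group_col Optional name of a grouping column in `sites`.
#' @return An `nmisv_enrichment` tibble (one row per group plus overall).
#' @export
enrich_exact <- function(candidates, manifest, sites, group_col = NULL,
                         n_sets = 100, seed = NULL,
                         correction = c("bonferroni", "bh"), min_count = 5) {
  correction <- match.arg(correction)
  cand <- if (is.data.frame(candidates)) candidates$locus_id else candidates
  sites <- as_tibble(sites)
  groups <- list(overall = sites)
  if (!is.null(group_col)) {
    stopifnot(group_col %in% names(sites))
    split_sites <- split(sites, sites[[group_col]])
    groups <- c(groups, split_sites)
  }
  ens <- sample_null_sets(manifest$locus_id, cand, set_size = length(cand),
                          n_sets = n_sets, seed = seed)
  rows <- purrr::imap(groups, function(s, label) {
    flags <- exact_match_flags(manifest, s)
    enrichment_test(
      observed = sum(flags[cand]),
      null_counts = ensemble_counts(ens, flags),
      set_size = length(cand), class_label = label,
      correction = "bonferroni", n_tests = length(groups),
      min_count = min_count
    )
  })
  res <- bind_rows(rows)
  if (correction == "bh") res$p_adj <- p.adjust(res$p_raw, method = "BH")
  structure(res,
            set_size = length(cand), n_sets = n_sets, seed = seed,
            correction = correction, flank_bp = NA_integer_,
            class = c("nmisv_enrichment", class(res)))
}
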