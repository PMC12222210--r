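#' Hypergeometric term enrichment for a gene set
#'
#' One-sided hypergeometric (equivalently Fisher exact) over-representation
#' test per annotation term, with Benjamini-Hochberg control across all
#' tested terms. This is the generic in-package equivalent of portal-based
#' gene-ontology enrichment: annotations are supplied as a plain
#' term-to-gene table, so no ontology download is involved, and no ontology
#' graph propagation is performed.
#'
#' @param gene_set Character vector of genes of interest. Genes outside the
#'   universe are dropped with a warning.
#' @param annotations Tibble with columns `term_id`, `gene_id`.
#' @param universe Character vector of all genes eligible for annotation
#'   (default: all genes in `annotations`).
#' @param fdr_threshold FDR significance threshold recorded in the result
#'   (default 0.05).
#' @return Tibble of class `nmisv_terms`, one row per term with `term_id`,
#'   `k` (set genes with term), `K` (universe genes with term), `n` (set
#'   size), `N` (universe size), `fold` = `(k/n)/(K/N)`, `p_raw`
#'   (hypergeometric upper tail `P(X >= k)`), `q_bh`, `significant`; sorted
#'   by `q_bh` then decreasing `fold`.
#' @export
hypergeom_enrichment <- function(gene_set, annotations, universe = NULL,
                                 fdr_threshold = 0.05) {
  annotations <- as_tibble(annotations)
  stopifnot(all(c("term_id", "gene_id") %in% names(annotations)))
  universe <- universe %||% unique(annotations$gene_id)
  if (length(universe) == 0) abort("empty gene universe")
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) abort("empty gene set")
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    warn(sprintf("%d gene(s) outside the universe dropped from the set",
                 length(outside)))
    gene_set <- setdiff(gene_set, outside)
    if (length(gene_set) == 0) abort("no gene-set members remain in the universe")
  }
  ann <- distinct(filter(annotations, .data$gene_id %in% universe))
  if (nrow(ann) == 0) abort("no annotations fall inside the universe")
  n <- length(gene_set)
  N <- length(universe)
  res <- ann |>
    group_by(.data$term_id) |>
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = sum(unique(.data$gene_id) %in% gene_set),
              .groups = "drop") |>
    mutate(
      n = n, N = N,
      fold = (.data$k / n) / (.data$K / N),
      p_raw = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE)
    ) |>
    mutate(q_bh = p.adjust(.data$p_raw, method = "BH"),
           significant = .data$q_bh < fdr_threshold) |>
    arrange(.data$q_bh, desc(.data$fold))
  structure(res, fdr_threshold = fdr_threshold,
            class = c("nmisv_terms", class(res)))
}

#' Random gene-set baselines
#'
#' Draws `n_sets` gene sets of `set_size` from `universe` excluding
#' `excluded`, either as disjoint sets partitioning a single
#' without-replacement sample (`mode = "partition"`, mirroring the design of
#' comparing a region-defined gene set against several disjoint random sets
#' from the complement) or as independent without-replacement samples
#' (`mode = "resample"`).
#'
#' @param universe Character vector of genes to sample from.
#' @param excluded Genes removed from the pool before sampling (e.g. the
#'   focal set).
#' @param set_size Genes per baseline set.
#' @param n_sets Number of baseline sets.
#' @param seed Integer seed.
#' @param mode `"partition"` (disjoint) or `"resample"` (independent).
#' @return List of `n_sets` character vectors.
#' @export
random_geneset_baseline <- function(universe, excluded = character(),
                                    set_size, n_sets, seed = NULL,
                                    mode = c("partition", "resample")) {
  mode <- match.arg(mode)
  pool <- setdiff(unique(universe), excluded)
  if (mode == "partition") {
    if (length(pool) < set_size * n_sets) {
      abort(sprintf("pool of %d genes cannot be partitioned into %d disjoint sets of %d",
                    length(pool), n_sets, set_size))
    }
    with_seed_if(seed, {
      picked <- sample(pool, set_size * n_sets)
      unname(split(picked, rep(seq_len(n_sets), each = set_size)))
    })
  } else {
    if (length(pool) < set_size) {
      abort("pool smaller than set_size")
    }
    with_seed_if(seed, {
      lapply(seq_len(n_sets), function(i) sample(pool, set_size))
    })
  }
}

#' Genes lying within genomic regions
#'
#' A gene is "within" a region class if any portion of the gene body
#' overlaps a region interval by at least 1 bp. Used, e.g., to build the
#' set of genes residing in the densest heterochromatin bands for
#' comparison against euchromatin baselines.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open gene bodies).
#' @param regions Tibble of region intervals (`chrom`, `start`, `end`).
#' @return Character vector of `gene_id`s overlapping at least one region.
#' @export
genes_in_regions <- function(genes, regions) {
  genes <- as_tibble(genes)
  flags <- overlap_flags(genes, regions)
  unique(genes$gene_id[flags])
}
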