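#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> NMI -> candidate filter -> feature enrichment ->
#' term enrichment -> DEG enrichment with one configuration and one master
#' seed, writing every inter-stage artefact as a documented text file
#' (PED/MAP, BED, TSV) plus a JSON run manifest with the configuration
#' hash, per-stage seeds, row counts and timestamps. Stages communicate only
#' through those files: the NMI stage re-reads the PED/MAP the simulate
#' stage wrote. Stages whose inputs are supplied in `inputs` are skipped.
#'
#' @param config A [sim_config()], or a path to a YAML file with its fields.
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of `config$seed`. Per-stage seeds are
#'   derived deterministically from the master seed and the stage name.
#' @param stages Character vector of stages to run, in dependency order;
#'   default all of `"simulate"`, `"nmi"`, `"filter"`, `"enrich"`,
#'   `"terms"`, `"degtest"`.
#' @param inputs Optional named list of pre-supplied inputs replacing the
#'   simulate stage: `cohorts` (list with `discovery`/`validation`
#'   [trio_cohort()]s), `tracks` (named list of interval tibbles),
#'   `blacklist` (character).
#' @param f_disc_min,f_both_min Candidate-filter thresholds (defaults 0.02
#'   and 0.15).
#' @return Invisibly, a list with the main in-memory results (`nmi_disc`,
#'   `nmi_valid`, `candidates`, `enrichment`, `terms`, `deg`, `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), outdir, seed = NULL,
                         stages = c("simulate", "nmi", "filter", "enrich",
                                    "terms", "degtest"),
                         inputs = list(),
                         f_disc_min = 0.02, f_both_min = 0.15) {
  if (is.character(config)) {
    cfg_list <- yaml::read_yaml(config)
    cfg_list$genome <- if (!is.null(cfg_list$genome)) as_tibble(cfg_list$genome)
    cfg_list$tracks <- if (!is.null(cfg_list$tracks)) as_tibble(cfg_list$tracks)
    cfg_list <- cfg_list[!vapply(cfg_list, is.null, logical(1))]
    config <- do.call(sim_config, cfg_list)
  }
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest_log <- list(
    config_hash = rlang::hash(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("nmisv")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"), stages = list()
  )
  log_stage <- function(name, counts) {
    manifest_log$stages[[name]] <<- list(
      seed = derive_seed(config$seed, name), counts = as.list(counts),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  }
  res <- list()
  p <- function(...) file.path(outdir, ...)

  if ("simulate" %in% stages && is.null(inputs$cohorts)) {
    sim <- simulate_trio_cohorts(config)
    write_ped_map(sim$discovery, p("cohort_a.ped"), p("cohort_a.map"))
    write_ped_map(sim$validation, p("cohort_b.ped"), p("cohort_b.map"))
    write_results_tsv(sim$truth, p("truth_loci.tsv"))
    cand_truth <- sim$truth$locus_id[sim$truth$is_sv]
    trk <- simulate_tracks(sim$discovery$manifest, cand_truth,
                           config$genome, config$tracks,
                           seed = derive_seed(config$seed, "tracks"))
    for (cl in names(trk$tracks)) {
      write_bed(trk$tracks[[cl]], p(paste0("track_", cl, ".bed")))
    }
    write_results_tsv(trk$truth, p("truth_tracks.tsv"))
    degsim <- simulate_deg_table(config$deg,
                                 seed = derive_seed(config$seed, "deg"))
    write_results_tsv(degsim$expression, p("expression.tsv"))
    writeLines(degsim$targets, p("target_genes.txt"))
    universe <- degsim$expression$gene_id
    lg <- simulate_locus_genes(sim$discovery$manifest, universe,
                               seed = derive_seed(config$seed, "locus_genes"))
    write_results_tsv(lg, p("locus_genes.tsv"))
    ann <- simulate_annotations(universe, gene_set = degsim$targets,
                                seed = derive_seed(config$seed, "annotations"))
    write_results_tsv(ann, p("annotations.tsv"))
    inputs$cohorts <- list(discovery = sim$discovery,
                           validation = sim$validation)
    inputs$tracks <- trk$tracks
    res$truth <- sim$truth
    log_stage("simulate", c(loci = nrow(sim$discovery$manifest),
                            families = nrow(sim$discovery$trios),
                            sv = length(cand_truth)))
  }

  if ("nmi" %in% stages) {
    # round-trip through the on-disk PED/MAP: stages talk via files
    disc <- if (file.exists(p("cohort_a.ped"))) {
      read_ped_map(p("cohort_a.ped"), p("cohort_a.map"))
    } else inputs$cohorts$discovery
    valid <- if (file.exists(p("cohort_b.ped"))) {
      read_ped_map(p("cohort_b.ped"), p("cohort_b.map"))
    } else inputs$cohorts$validation
    res$nmi_disc <- nmi_frequencies(disc)
    res$nmi_valid <- nmi_frequencies(valid)
    write_results_tsv(res$nmi_disc, p("nmi_discovery.tsv"))
    write_results_tsv(res$nmi_valid, p("nmi_validation.tsv"))
    conc <- cohort_concordance(res$nmi_disc, res$nmi_valid, f_both_min)
    write_results_tsv(conc, p("concordance.tsv"))
    log_stage("nmi", c(loci_disc = nrow(res$nmi_disc),
                       loci_valid = nrow(res$nmi_valid)))
  }

  if ("filter" %in% stages) {
    if (is.null(res$nmi_disc)) {
      res$nmi_disc <- read_results_tsv(p("nmi_discovery.tsv"))
      res$nmi_valid <- read_results_tsv(p("nmi_validation.tsv"))
    }
    blacklist <- inputs$blacklist %||% character()
    res$candidates <- select_candidates(res$nmi_disc, res$nmi_valid,
                                        blacklist = blacklist,
                                        f_disc_min = f_disc_min,
                                        f_both_min = f_both_min)
    write_results_tsv(res$candidates, p("candidates.tsv"))
    write_results_tsv(attr(res$candidates, "steps"), p("filter_steps.tsv"))
    log_stage("filter", c(candidates = nrow(res$candidates)))
  }

  if ("enrich" %in% stages && nrow(res$candidates %||% tibble()) > 1) {
    man <- inputs$cohorts$discovery$manifest
    res$enrichment <- enrich_features(
      res$candidates, man, inputs$tracks,
      seed = derive_seed(config$seed, "enrich"))
    er <- res$enrichment
    attr(er, "seed") <- derive_seed(config$seed, "enrich")
    write_results_tsv(er, p("enrichment.tsv"))
    # ratio bar-plot data (observed/null ratio per class, reference 1)
    write_results_tsv(
      select(as_tibble(res$enrichment), "class_label", "ratio", "p_adj",
             "direction"),
      p("enrichment_ratios.tsv"))
    log_stage("enrich", c(classes = nrow(res$enrichment)))
  }

  if ("terms" %in% stages && file.exists(p("locus_genes.tsv")) &&
      nrow(res$candidates %||% tibble()) > 0) {
    lg <- read_results_tsv(p("locus_genes.tsv"))
    ann <- read_results_tsv(p("annotations.tsv"))
    genes <- unique(lg$gene_id[lg$locus_id %in% res$candidates$locus_id])
    res$terms <- hypergeom_enrichment(genes, ann,
                                      universe = unique(lg$gene_id))
    write_results_tsv(res$terms, p("term_enrichment.tsv"))
    log_stage("terms", c(terms = nrow(res$terms),
                         genes = length(genes)))
  }

  if ("degtest" %in% stages && file.exists(p("expression.tsv"))) {
    expr <- read_results_tsv(p("expression.tsv"))
    targets <- readLines(p("target_genes.txt"))
    expressed <- filter_expressed(expr)
    res$deg <- target_deg_test(expressed, targets)
    write_results_tsv(res$deg, p("deg_enrichment.tsv"))
    log_stage("degtest", c(G = res$deg$G, D = res$deg$D,
                           T_genes = res$deg$T_genes))
  }

  manifest_log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest_log, p("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest_log
  invisible(res)
}
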