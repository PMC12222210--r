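#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with the defaults that
#' define the package's reference study conditions: two independent trio
#' cohorts of 400 families genotyped on a shared 10,000-SNP manifest, 50
#' loci carrying a planted deletion ("null") allele under the array probe at
#' deletion-allele frequency `q ~ U(0.3, 0.5)`, per-assay background miscall
#' probability 5e-4 (the 0.05% technical error rate of the modelled
#' platform), feature tracks with configurable planted enrichment folds, and
#' a differential-expression table with a planted excess of DE among target
#' genes. At planted-SV loci the surviving (real) allele frequency is drawn
#' from `U(0.4, 0.6)`: a hemizygote miscall only violates Mendelian
#' expectations when the other parent is informative, and array SNPs are
#' ascertained to be common, so intermediate frequencies at assayed loci are
#' the realistic regime.
#'
#' @param n_families Families (= trios) per cohort.
#' @param n_snps Manifest size.
#' @param genome Tibble `chrom`, `length` (bp) defining the synthetic
#'   genome.
#' @param n_sv Number of planted deletion loci (shared by both cohorts).
#' @param q_range Range of the deletion-allele frequency at planted loci.
#' @param sv_ref_freq_range Range of the reference-allele fraction among the
#'   two real alleles at planted loci.
#' @param ref_freq_range Same, at background loci.
#' @param background_error Per-assay probability that a call is replaced by
#'   a uniformly chosen different call state (including missing).
#' @param tracks Tibble `class_label`, `n_intervals`, `mean_length`,
#'   `planted_fold` describing the synthetic feature tracks.
#' @param deg List with `n_genes`, `overall_de_rate`, `target_set_size`,
#'   `target_de_rate`, `frac_low_expr`, `frac_sex`.
#' @param seed Integer master seed; a single seed determines the entire
#'   dataset.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 400,
                       n_snps = 10000,
                       genome = tibble(chrom = as.character(1:4),
                                       length = rep(5e7, 4)),
                       n_sv = 50,
                       q_range = c(0.3, 0.5),
                       sv_ref_freq_range = c(0.4, 0.6),
                       ref_freq_range = c(0.05, 0.95),
                       background_error = 5e-4,
                       tracks = tibble(
                         class_label = c("gpos100", "H3K9me3", "H3K27me3"),
                         n_intervals = c(4000, 5000, 5000),
                         mean_length = c(2000, 1000, 1000),
                         planted_fold = c(2, 2, 1)
                       ),
                       deg = list(n_genes = 15000, overall_de_rate = 0.048,
                                  target_set_size = 500,
                                  target_de_rate = 0.082,
                                  frac_low_expr = 0.05, frac_sex = 0.02),
                       seed = 1) {
  cfg <- list(n_families = n_families, n_snps = n_snps,
              genome = as_tibble(genome), n_sv = n_sv, q_range = q_range,
              sv_ref_freq_range = sv_ref_freq_range,
              ref_freq_range = ref_freq_range,
              background_error = background_error, tracks = as_tibble(tracks),
              deg = deg, seed = as.integer(seed))
  stopifnot(n_families > 0, n_snps > 0, n_sv >= 0, n_sv <= n_snps,
            all(cfg$q_range >= 0), all(cfg$q_range <= 1),
            background_error >= 0, background_error <= 1,
            all(cfg$tracks$planted_fold >= 0))
  structure(cfg, class = "sim_config")
}

# Random manifest over the synthetic genome, sorted by (chrom, pos), with
# per-locus allele letters (ref = lexicographically smaller, so a PED/MAP
# round trip preserves genotype codes).
simulate_manifest <- function(n_snps, genome, seed = NULL) {
  with_seed_if(seed, {
    counts <- as.vector(stats::rmultinom(1, n_snps,
                                         genome$length / sum(genome$length)))
    parts <- purrr::map2(genome$chrom, seq_along(counts), function(ch, i) {
      n <- counts[i]
      tibble(chrom = ch,
             pos = sort(sample.int(genome$length[i] - 2000L, n)) + 1000L)
    })
    man <- bind_rows(parts)
    pairs <- t(vapply(seq_len(n_snps),
                      function(i) sort(sample(c("A", "C", "G", "T"), 2)),
                      character(2)))
    man |>
      mutate(locus_id = sprintf("rs%07d", row_number()),
             ref_allele = pairs[, 1], alt_allele = pairs[, 2]) |>
      select("locus_id", "chrom", "pos", "ref_allele", "alt_allele")
  })
}

# One cohort under the null-allele model. f_ref = frequency of the ref
# allele among real alleles; q = deletion-allele frequency. Alleles are
# coded 0 = ref, 1 = alt, 2 = deletion; parents are drawn in Hardy-Weinberg
# proportions and children by Mendelian transmission. A carrier of exactly
# one deletion allele is CALLED homozygous for its remaining real allele;
# deletion homozygotes are CALLED missing. Background miscalls then replace
# each call independently with probability `error` by a uniformly random
# different state among {HOM_REF, HET, HOM_ALT, MISSING}.
simulate_cohort <- function(manifest, f_ref, q, n_families, error,
                            prefix, seed = NULL) {
  L <- nrow(manifest)
  F_ <- n_families
  p_ref <- f_ref * (1 - q)
  p_alt <- (1 - f_ref) * (1 - q)
  with_seed_if(seed, {
    draw <- function() {
      u <- matrix(runif(L * F_), L, F_)
      (u > p_ref) + (u > p_ref + p_alt)
    }
    f1 <- draw(); f2 <- draw(); m1 <- draw(); m2 <- draw()
    pick_f <- matrix(runif(L * F_) < 0.5, L, F_)
    pick_m <- matrix(runif(L * F_) < 0.5, L, F_)
    cf <- f1; cf[!pick_f] <- f2[!pick_f]
    cm <- m1; cm[!pick_m] <- m2[!pick_m]

    call_geno <- function(x, y) {
      g <- matrix(NA_integer_, nrow(x), ncol(x))
      both_real <- x < 2 & y < 2
      g[both_real] <- as.integer(x[both_real] + y[both_real])
      one_del <- xor(x == 2, y == 2)
      other <- x; other[x == 2] <- y[x == 2]
      g[one_del] <- as.integer(2L * other[one_del])
      g  # both deletion alleles -> NA (no-call)
    }
    miscall <- function(g) {
      n <- length(g)
      k <- rbinom(1, n, error)
      if (k == 0) return(g)
      idx <- sample.int(n, k)
      s <- g[idx]
      s[is.na(s)] <- 3L
      s_new <- (s + sample(1:3, k, replace = TRUE)) %% 4L
      s_new[s_new == 3L] <- NA_integer_
      g[idx] <- s_new
      g
    }
    fa <- miscall(call_geno(f1, f2))
    mo <- miscall(call_geno(m1, m2))
    ch <- miscall(call_geno(cf, cm))

    fam <- sprintf("%sF%04d", prefix, seq_len(F_))
    fa_id <- paste0(fam, "_fa"); mo_id <- paste0(fam, "_mo")
    ch_id <- paste0(fam, "_ch")
    calls <- cbind(fa, mo, ch)
    dimnames(calls) <- list(manifest$locus_id, c(fa_id, mo_id, ch_id))
    trios <- tibble(family = fam, father = fa_id, mother = mo_id,
                    child = ch_id)
    pedigree <- bind_rows(
      tibble(individual = fa_id, family = fam, father = "0", mother = "0",
             sex = "1", phenotype = "1"),
      tibble(individual = mo_id, family = fam, father = "0", mother = "0",
             sex = "2", phenotype = "1"),
      tibble(individual = ch_id, family = fam, father = fa_id,
             mother = mo_id, sex = "0", phenotype = "2")
    )
    trio_cohort(select(manifest, "locus_id", "chrom", "pos",
                       "ref_allele", "alt_allele"),
                trios, calls, pedigree)
  })
}

#' Simulate two trio cohorts with planted null-allele structural variants
#'
#' Generates a shared SNP manifest, plants `n_sv` deletion loci (shared
#' truth: same loci and deletion-allele frequencies in both cohorts), and
#' draws two cohorts of independent individuals under Hardy-Weinberg
#' parental genotypes and Mendelian transmission, with the null-allele call
#' model (hemizygote miscalled homozygous, deletion homozygote missing) and
#' independent background miscalls.
#'
#' @param config A [sim_config()].
#' @return List with elements `discovery` and `validation` (each a
#'   [trio_cohort()]) and `truth`, a tibble `locus_id`, `is_sv`, `q`,
#'   `ref_freq`.
#' @export
simulate_trio_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- simulate_manifest(config$n_snps, config$genome,
                                seed = derive_seed(config$seed, "manifest"))
  truth <- with_seed_if(derive_seed(config$seed, "sv_truth"), {
    is_sv <- rep(FALSE, config$n_snps)
    is_sv[sample.int(config$n_snps, config$n_sv)] <- TRUE
    q <- rep(0, config$n_snps)
    q[is_sv] <- runif(config$n_sv, config$q_range[1], config$q_range[2])
    f_ref <- runif(config$n_snps, config$ref_freq_range[1],
                   config$ref_freq_range[2])
    f_ref[is_sv] <- runif(config$n_sv, config$sv_ref_freq_range[1],
                          config$sv_ref_freq_range[2])
    tibble(locus_id = manifest$locus_id, is_sv = is_sv, q = q,
           ref_freq = f_ref)
  })
  disc <- simulate_cohort(manifest, truth$ref_freq, truth$q,
                          config$n_families, config$background_error,
                          prefix = "A", seed = derive_seed(config$seed, "cohort_a"))
  valid <- simulate_cohort(manifest, truth$ref_freq, truth$q,
                           config$n_families, config$background_error,
                           prefix = "B", seed = derive_seed(config$seed, "cohort_b"))
  list(discovery = disc, validation = valid, truth = truth)
}

#' Simulate feature tracks with planted enrichment at candidate loci
#'
#' Background intervals are placed uniformly over the synthetic genome; the
#' empirical background window-overlap rate `pi0` is then estimated from the
#' non-candidate windows, and each candidate window independently receives
#' an additional interval (centred on its SNP) with the probability that
#' makes the expected candidate overlap rate equal `planted_fold * pi0`.
#' For `planted_fold < 1` the background intervals are first resampled away
#' from candidate windows and candidate windows receive an interval with
#' probability `planted_fold * pi0` (so `planted_fold = 0` avoids candidate
#' windows entirely).
#'
#' @param manifest Manifest tibble (`locus_id`, `chrom`, `pos`).
#' @param candidates Character vector of candidate locus ids.
#' @param genome Tibble `chrom`, `length`.
#' @param classes Tibble `class_label`, `n_intervals`, `mean_length`,
#'   `planted_fold`.
#' @param flank_bp Window flank used to define "overlap" (default 1000).
#' @param seed Integer seed.
#' @return List with `tracks` (named list of interval tibbles) and `truth`
#'   (the `classes` tibble augmented with the realised `pi0` and planting
#'   probability `p_add`).
#' @export
simulate_tracks <- function(manifest, candidates, genome, classes,
                            flank_bp = 1000, seed = NULL) {
  classes <- select(as_tibble(classes), "class_label", "n_intervals",
                    "mean_length", "planted_fold")
  windows <- make_windows(manifest, flank_bp = flank_bp)
  is_cand <- manifest$locus_id %in% candidates
  cand_windows <- windows[is_cand, , drop = FALSE]
  out <- with_seed_if(seed, {
    purrr::pmap(classes, function(class_label, n_intervals, mean_length,
                                  planted_fold) {
      draw_bg <- function(n) {
        ci <- sample.int(nrow(genome), n, replace = TRUE,
                         prob = genome$length)
        len <- pmax(50L, as.integer(round(
          rgamma(n, shape = 4, scale = mean_length / 4))))
        start <- as.integer(floor(runif(n) * (genome$length[ci] - len)))
        tibble(chrom = genome$chrom[ci], start = start, end = start + len,
               name = class_label)
      }
      bg <- draw_bg(n_intervals)
      if (planted_fold < 1) {
        # keep background clear of candidate windows, then thin planting
        for (i in 1:20) {
          hit <- overlap_flags(bg, cand_windows)
          if (!any(hit)) break
          bg[hit, ] <- draw_bg(sum(hit))
        }
        pi0 <- mean(overlap_flags(windows[!is_cand, , drop = FALSE], bg))
        p_add <- planted_fold * pi0
      } else {
        pi0 <- mean(overlap_flags(windows[!is_cand, , drop = FALSE], bg))
        if (pi0 >= 1) abort("background overlap rate is 1; cannot plant enrichment")
        p_add <- pi0 * (planted_fold - 1) / (1 - pi0)
        if (p_add > 1) {
          abort(sprintf(
            "planted_fold %.3g infeasible for class %s (background rate %.3g)",
            planted_fold, class_label, pi0))
        }
      }
      plant_at <- which(is_cand)[runif(sum(is_cand)) < p_add]
      planted <- if (length(plant_at)) {
        len <- pmax(50L, as.integer(round(
          rgamma(length(plant_at), shape = 4, scale = mean_length / 4))))
        centre <- manifest$pos[plant_at] - 1L
        start <- pmax(0L, centre - len %/% 2L)
        tibble(chrom = norm_chrom(manifest$chrom[plant_at]), start = start,
               end = start + len, name = class_label)
      } else {
        tibble(chrom = character(), start = integer(), end = integer(),
               name = character())
      }
      track <- arrange(bind_rows(mutate(bg, chrom = norm_chrom(.data$chrom)),
                                 planted),
                       .data$chrom, .data$start, .data$end)
      list(track = track,
           truth = tibble(class_label = class_label, pi0 = pi0,
                          p_add = p_add, planted_fold = planted_fold))
    })
  })
  tracks <- purrr::map(out, "track")
  names(tracks) <- classes$class_label
  list(tracks = tracks, truth = bind_rows(purrr::map(out, "truth")))
}

#' Simulate a differential-expression summary with a planted target excess
#'
#' Genes get a log-normal expression level (with a configurable fraction
#' forced below the expression floor) and a chromosome (with a configurable
#' fraction on X/Y); differential-expression flags are Bernoulli with rate
#' `overall_de_rate` for non-targets and `target_de_rate` for the target
#' set.
#'
#' @param deg List of parameters as in [sim_config()]'s `deg` element.
#' @param seed Integer seed.
#' @return List with `expression` (tibble `gene_id`, `chrom`,
#'   `max_group_mean`, `is_de`), `targets` (character vector) and `truth`.
#' @export
simulate_deg_table <- function(deg, seed = NULL) {
  with_seed_if(seed, {
    n <- deg$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    chrom <- sample(as.character(1:22), n, replace = TRUE)
    sex <- runif(n) < deg$frac_sex
    chrom[sex] <- sample(c("X", "Y"), sum(sex), replace = TRUE)
    expr <- rlnorm(n, meanlog = 1.5, sdlog = 1)
    low <- runif(n) < deg$frac_low_expr
    expr[low] <- runif(sum(low))
    targets <- sample(gene_id, deg$target_set_size)
    is_target <- gene_id %in% targets
    rate <- ifelse(is_target, deg$target_de_rate, deg$overall_de_rate)
    is_de <- runif(n) < rate
    list(
      expression = tibble(gene_id = gene_id, chrom = chrom,
                          max_group_mean = expr, is_de = is_de),
      targets = targets,
      truth = tibble(gene_id = gene_id, is_target = is_target,
                     de_rate_generative = rate)
    )
  })
}

#' Simulate a term-annotation table over a gene universe
#'
#' Random term memberships (sizes log-uniform within `size_range`); when a
#' `gene_set` is given, the first `n_enriched` terms preferentially sample
#' from it so planted enrichment exists.
#'
#' @param universe Character vector of gene ids.
#' @param n_terms Number of terms.
#' @param size_range Term size range.
#' @param gene_set Optional focal gene set for planted enrichment.
#' @param n_enriched Number of planted enriched terms (default 2 when
#'   `gene_set` is given).
#' @param seed Integer seed.
#' @return Tibble `term_id`, `gene_id`.
#' @export
simulate_annotations <- function(universe, n_terms = 40,
                                 size_range = c(10, 200), gene_set = NULL,
                                 n_enriched = if (is.null(gene_set)) 0 else 2,
                                 seed = NULL) {
  with_seed_if(seed, {
    sizes <- as.integer(round(exp(runif(n_terms, log(size_range[1]),
                                        log(size_range[2])))))
    rows <- purrr::map(seq_len(n_terms), function(i) {
      if (i <= n_enriched && length(gene_set)) {
        n_in <- min(length(gene_set), ceiling(sizes[i] / 2))
        genes <- c(sample(gene_set, n_in),
                   sample(setdiff(universe, gene_set), sizes[i] - n_in))
      } else {
        genes <- sample(universe, min(sizes[i], length(universe)))
      }
      tibble(term_id = sprintf("T%04d", i), gene_id = genes)
    })
    bind_rows(rows)
  })
}

#' Assign manifest loci to genes
#'
#' A generic locus-to-gene join table (each locus assigned one gene from the
#' universe, uniformly at random), standing in for portal-based gene
#' assignment of array loci.
#'
#' @param manifest Manifest tibble.
#' @param universe Character vector of gene ids.
#' @param seed Integer seed.
#' @return Tibble `locus_id`, `gene_id`.
#' @export
simulate_locus_genes <- function(manifest, universe, seed = NULL) {
  with_seed_if(seed, {
    tibble(locus_id = manifest$locus_id,
           gene_id = sample(universe, nrow(manifest), replace = TRUE))
  })
}
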