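test_that("a clean simulation (q = 0, no error) yields zero violations", {
  cfg <- sim_config(n_families = 80, n_snps = 100, n_sv = 0,
                    background_error = 0, seed = 5)
  sim <- simulate_trio_cohorts(cfg)
  nmi <- nmi_frequencies(sim$discovery)
  expect_equal(sum(nmi$n_violations), 0L)
  expect_equal(sum(nmi$n_informative), 80L * 100L)  # nothing missing either
})

test_that("the hemizygote miscall turns a consistent trio into a called violation", {
  # truth: father alt/del, mother ref/ref, child ref/del. Called genotypes:
  # father HOM_ALT (deletion masks the alt hemizygote), mother HOM_REF,
  # child HOM_REF -- a HOM_REF x HOM_ALT pair cannot have a HOM_REF child.
  call_geno <- function(a1, a2) {
    if (a1 == 2 && a2 == 2) return(NA_integer_)
    if (a1 == 2) return(if (a2 == 1) 2L else 0L)
    if (a2 == 2) return(if (a1 == 1) 2L else 0L)
    as.integer(a1 + a2)
  }
  fg <- call_geno(1, 2); mg <- call_geno(0, 0); cg <- call_geno(0, 2)
  expect_equal(c(fg, mg, cg), c(2L, 0L, 0L))
  expect_equal(classify_trio(fg, mg, cg), "violation")
  # and a deletion homozygote is a no-call
  expect_true(is.na(call_geno(2, 2)))
})

test_that("simulation is fully deterministic given the config seed", {
  cfg <- sim_config(n_families = 30, n_snps = 120, n_sv = 5, seed = 77)
  s1 <- simulate_trio_cohorts(cfg)
  s2 <- simulate_trio_cohorts(cfg)
  expect_identical(s1$discovery$calls, s2$discovery$calls)
  expect_identical(s1$validation$calls, s2$validation$calls)
  expect_identical(s1$truth, s2$truth)
  # and the on-disk artefacts are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_ped_map(s1$discovery, file.path(d1, "a.ped"), file.path(d1, "a.map"))
  write_ped_map(s2$discovery, file.path(d2, "a.ped"), file.path(d2, "a.map"))
  expect_identical(readLines(file.path(d1, "a.ped")),
                   readLines(file.path(d2, "a.ped")))
  s3 <- simulate_trio_cohorts(sim_config(n_families = 30, n_snps = 120,
                                         n_sv = 5, seed = 78))
  expect_false(identical(s1$discovery$calls, s3$discovery$calls))
})

test_that("the two cohorts share SV truth but contain independent individuals", {
  cfg <- sim_config(n_families = 50, n_snps = 200, n_sv = 8, seed = 9)
  sim <- simulate_trio_cohorts(cfg)
  expect_identical(sim$discovery$manifest$locus_id,
                   sim$validation$manifest$locus_id)
  expect_length(intersect(colnames(sim$discovery$calls),
                          colnames(sim$validation$calls)), 0)
  expect_false(identical(unname(sim$discovery$calls),
                         unname(sim$validation$calls)))
})

test_that("observed NMI frequency at planted loci matches the enumeration oracle", {
  # q = 0.3, balanced real alleles, 400 families: the per-locus NMI
  # frequency aggregated over SV loci must sit within 3 Monte-Carlo SDs of
  # the exhaustive-enumeration expectation over all parental
  # deletion-configurations (including the background miscall channel).
  cfg <- sim_config(n_families = 400, n_snps = 80, n_sv = 20,
                    q_range = c(0.3, 0.3), sv_ref_freq_range = c(0.5, 0.5),
                    seed = 640)
  sim <- simulate_trio_cohorts(cfg)
  nmi <- nmi_frequencies(sim$discovery)
  sv <- sim$truth$is_sv
  expected <- oracle_nmi_freq(0.3, 0.5, cfg$background_error)
  n_inf <- sum(nmi$n_informative[sv])
  p_hat <- sum(nmi$n_violations[sv]) / n_inf
  se <- sqrt(expected[["nmi_freq"]] * (1 - expected[["nmi_freq"]]) / n_inf)
  expect_lt(abs(p_hat - expected[["nmi_freq"]]), 3 * se)
  # the informative fraction also matches the oracle
  frac_inf <- n_inf / (sum(sv) * cfg$n_families)
  se_inf <- sqrt(expected[["p_informative"]] *
                 (1 - expected[["p_informative"]]) / (sum(sv) * cfg$n_families))
  expect_lt(abs(frac_inf - expected[["p_informative"]]), 3 * se_inf)
})

test_that("a planted_fold of 1 is statistically indistinguishable from background", {
  genome <- tibble::tibble(chrom = "1", length = 3e7)
  man <- nmisv:::simulate_manifest(3000, genome, seed = 55)
  cand <- withr::with_seed(56, sample(man$locus_id, 300))
  hits <- withr::with_seed(57, vapply(1:30, function(i) {
    trk <- simulate_tracks(man, cand, genome,
                           tibble::tibble(class_label = "flat",
                                          n_intervals = 2500,
                                          mean_length = 800,
                                          planted_fold = 1))
    res <- enrich_features(cand, man, trk$tracks)
    !is.na(res$p_adj) && res$p_adj < 0.05
  }, logical(1)))
  expect_lte(mean(hits), 0.1)
})

test_that("an infeasible planted fold errors out", {
  genome <- tibble::tibble(chrom = "1", length = 1e6)
  man <- nmisv:::simulate_manifest(500, genome, seed = 60)
  cand <- man$locus_id[1:50]
  expect_error(
    simulate_tracks(man, cand, genome,
                    tibble::tibble(class_label = "dense", n_intervals = 300,
                                   mean_length = 1000, planted_fold = 3),
                    seed = 61),
    "infeasible")
})

test_that("simulated DEG tables honour their generative rates", {
  d <- simulate_deg_table(list(n_genes = 20000, overall_de_rate = 0.05,
                               target_set_size = 2000, target_de_rate = 0.2,
                               frac_low_expr = 0.1, frac_sex = 0.05),
                          seed = 70)
  expr <- d$expression
  expect_equal(nrow(expr), 20000)
  is_t <- expr$gene_id %in% d$targets
  expect_equal(sum(is_t), 2000)
  # binomial 3-sigma checks on the realised rates
  expect_lt(abs(mean(expr$is_de[!is_t]) - 0.05),
            3 * sqrt(0.05 * 0.95 / sum(!is_t)))
  expect_lt(abs(mean(expr$is_de[is_t]) - 0.2),
            3 * sqrt(0.2 * 0.8 / sum(is_t)))
  expect_lt(abs(mean(expr$max_group_mean < 1) - 0.1 - 0.9 * mean(stats::plnorm(1, 1.5, 1))),
            0.02)
  expect_lt(abs(mean(expr$chrom %in% c("X", "Y")) - 0.05),
            3 * sqrt(0.05 * 0.95 / 20000))
})
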