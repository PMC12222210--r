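test_that("windows are half-open, centred and clipped at zero", {
  loci <- tibble::tibble(locus_id = c("a", "b", "c"), chrom = "1",
                         pos = c(1001L, 500L, 42L))
  w <- make_windows(loci, flank_bp = 1000)
  expect_equal(w$start, c(0L, 0L, 0L))
  expect_equal(w$end, c(2001L, 1500L, 1042L))
  expect_equal(w$end[1] - w$start[1], 2001L)  # 2*flank + 1, unclipped
  w0 <- make_windows(loci, flank_bp = 0)
  expect_equal(w0$end - w0$start, rep(1L, 3))  # exactly the SNP base
  expect_equal(w0$start[1], 1000L)             # pos 1001 -> 0-based 1000
})

test_that("overlap counting honours half-open boundaries", {
  win <- tibble::tibble(chrom = "1", start = 0L, end = 2001L, locus_id = "a")
  trk <- tibble::tibble(chrom = "1", start = 2000L, end = 3000L)
  expect_equal(count_overlaps(win, trk), 1L)   # 1-bp overlap counts
  win2 <- tibble::tibble(chrom = "1", start = 0L, end = 2000L, locus_id = "a")
  expect_equal(count_overlaps(win2, trk), 0L)  # abutting does not
  # one window counts once however many intervals it touches
  trk2 <- tibble::tibble(chrom = "1", start = c(0L, 10L, 1999L),
                         end = c(5L, 30L, 2500L))
  expect_equal(count_overlaps(win, trk2), 1L)
})

test_that("overlap counting equals the pairwise oracle on random fixtures", {
  withr::local_seed(4242)
  for (i in 1:30) {
    win <- random_intervals(sample(1:120, 1))
    win$locus_id <- paste0("w", seq_len(nrow(win)))
    trk <- random_intervals(sample(1:120, 1))
    expect_equal(count_overlaps(win, trk), oracle_count_overlaps(win, trk))
  }
})

test_that("null sets are reproducible, exclude candidates and cover the pool", {
  bg <- sprintf("L%03d", 1:50)
  cand <- bg[1:10]
  e1 <- sample_null_sets(bg, cand, set_size = 15, n_sets = 20, seed = 5)
  e2 <- sample_null_sets(bg, cand, set_size = 15, n_sets = 20, seed = 5)
  expect_identical(e1$sets, e2$sets)
  expect_false(any(cand %in% e1$sets))
  expect_true(all(apply(e1$sets, 2, anyDuplicated) == 0))  # without replacement
  # set_size equal to the whole remainder: every set is the remainder
  full <- sample_null_sets(bg, cand, set_size = 40, n_sets = 5, seed = 1)
  expect_true(all(apply(full$sets, 2, function(s) setequal(s, setdiff(bg, cand)))))
  expect_error(sample_null_sets(bg, cand, set_size = 41, n_sets = 2, seed = 1),
               "need 41")
})

test_that("ensemble mean overlap matches the background overlap probability", {
  withr::local_seed(31)
  n_bg <- 5000
  bg <- sprintf("L%04d", 1:n_bg)
  flags <- stats::setNames(runif(n_bg) < 0.22, bg)
  ens <- sample_null_sets(bg, character(), set_size = 400, n_sets = 100,
                          seed = 7)
  counts <- ensemble_counts(ens, flags)
  pi_bg <- mean(flags)
  se <- sqrt(400 * pi_bg * (1 - pi_bg)) / sqrt(100)
  expect_lt(abs(mean(counts) - 400 * pi_bg), 3 * se)
})

test_that("the enrichment statistic behaves at its fixed points", {
  nc <- rep(50L, 100)
  r <- enrichment_test(50L, nc, set_size = 500)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_raw, 1)
  expect_equal(r$ratio, 1)       # the no-enrichment reference ratio
  expect_equal(r$direction, "ns")
  # symmetry: relabelling overlap/non-overlap cells leaves p unchanged
  nc2 <- c(40L, 60L, rep(50L, 98))
  a <- enrichment_test(80L, nc2, set_size = 500)
  b <- enrichment_test(500L - 80L, 500L - nc2, set_size = 500)
  expect_equal(a$p_raw, b$p_raw)
  expect_equal(a$chi2, b$chi2)
})

test_that("low counts suppress the p-value but keep ratio and direction", {
  r <- enrichment_test(3L, rep(1L, 100), set_size = 500, min_count = 5)
  expect_true(r$low_count_flag)
  expect_true(is.na(r$p_raw) && is.na(r$p_adj))
  expect_equal(r$direction, "enriched")
  r2 <- enrichment_test(0L, rep(0L, 100), set_size = 500)
  expect_true(r2$low_count_flag)
  expect_equal(r2$direction, "ns")
})

test_that("Bonferroni-adjusted p >= BH-adjusted p >= raw p across a family", {
  withr::local_seed(61)
  man <- tibble::tibble(locus_id = sprintf("L%04d", 1:2000), chrom = "1",
                        pos = sort(sample.int(5e6, 2000)))
  cand <- sample(man$locus_id, 300)
  tracks <- lapply(1:6, function(i) random_intervals(800, chroms = "1",
                                                     max_pos = 5e6,
                                                     max_len = 3000))
  names(tracks) <- paste0("class", 1:6)
  bon <- enrich_features(cand, man, tracks, n_sets = 50, seed = 13,
                         correction = "bonferroni")
  bh <- enrich_features(cand, man, tracks, n_sets = 50, seed = 13,
                        correction = "bh")
  ok <- !is.na(bon$p_raw)
  expect_true(all(bon$p_adj[ok] >= bh$p_adj[ok] - 1e-12))
  expect_true(all(bh$p_adj[ok] >= bh$p_raw[ok] - 1e-12))
  expect_equal(bon$p_raw, bh$p_raw)  # same ensemble, same raw p
})

test_that("under a pure null the observed counts are exchangeable with the ensemble", {
  withr::local_seed(71)
  n_bg <- 4000
  bg <- sprintf("L%04d", 1:n_bg)
  flags <- stats::setNames(runif(n_bg) < 0.15, bg)
  # 100 "observed" candidate draws vs one 100-set ensemble
  obs <- replicate(100, sum(flags[sample(bg, 300)]))
  ens <- sample_null_sets(bg, character(), set_size = 300, n_sets = 100,
                          seed = 3)
  counts <- ensemble_counts(ens, flags)
  ks <- suppressWarnings(stats::ks.test(obs, counts))
  expect_gt(ks$p.value, 0.01)
})

test_that("exact locus matching joins by id or by position and deduplicates", {
  loci <- tibble::tibble(locus_id = c("rs1", "rs2", "rs3"),
                         chrom = c("1", "1", "2"), pos = c(100L, 200L, 300L))
  sites_id <- tibble::tibble(locus_id = c("rs2", "rs9"))
  expect_equal(exact_match_overlap(loci, sites_id), 1L)
  expect_equal(exact_match_overlap(loci, tibble::tibble(locus_id = "zz")), 0L)
  expect_equal(exact_match_overlap(loci, loci), 3L)  # loci subset of sites
  # mixed keying: ids only on one side -> positional join, cross-checked
  # against a brute-force pairwise comparison
  sites_pos <- tibble::tibble(chrom = c("chr1", "2", "7"),
                              pos = c(200L, 300L, 1L))
  brute <- sum(vapply(seq_len(nrow(loci)), function(i) {
    any(sub("^chr", "", sites_pos$chrom) == loci$chrom[i] &
        sites_pos$pos == loci$pos[i])
  }, logical(1)))
  expect_equal(exact_match_overlap(loci, sites_pos), brute)
  expect_warning(exact_match_overlap(loci, sites_id[c(1, 1), ]), "dedup")
})

test_that("exact-match enrichment runs per group plus overall", {
  withr::local_seed(81)
  man <- tibble::tibble(locus_id = sprintf("L%04d", 1:3000), chrom = "1",
                        pos = seq_len(3000) * 100L)
  cand <- sample(man$locus_id, 200)
  sites <- tibble::tibble(locus_id = sample(man$locus_id, 900),
                          tissue = sample(c("brain", "lung", "liver"), 900,
                                          replace = TRUE))
  res <- enrich_exact(cand, man, sites, group_col = "tissue", n_sets = 50,
                      seed = 2)
  expect_setequal(res$class_label, c("overall", "brain", "lung", "liver"))
  overall <- res$observed[res$class_label == "overall"]
  expect_equal(overall, sum(cand %in% sites$locus_id))
})

test_that("a planted 2-fold track is called enriched with a ratio near 2", {
  genome <- tibble::tibble(chrom = c("1", "2"), length = c(4e7, 4e7))
  man <- nmisv:::simulate_manifest(8000, genome, seed = 91)
  cand <- withr::with_seed(92, sample(man$locus_id, 500))
  trk <- simulate_tracks(man, cand, genome,
                         tibble::tibble(class_label = "planted",
                                        n_intervals = 4000,
                                        mean_length = 1000,
                                        planted_fold = 2),
                         seed = 93)
  res <- enrich_features(cand, man, trk$tracks, seed = 94)
  expect_equal(res$direction, "enriched")
  expect_lt(res$p_adj, 0.05)
  expect_gt(res$ratio, 1.6)
  expect_lt(res$ratio, 2.4)
})

test_that("a fold-0 track avoids candidate windows entirely", {
  genome <- tibble::tibble(chrom = "1", length = 2e7)
  man <- nmisv:::simulate_manifest(2000, genome, seed = 101)
  cand <- withr::with_seed(102, sample(man$locus_id, 200))
  trk <- simulate_tracks(man, cand, genome,
                         tibble::tibble(class_label = "avoided",
                                        n_intervals = 1500,
                                        mean_length = 800,
                                        planted_fold = 0),
                         seed = 103)
  res <- enrich_features(cand, man, trk$tracks, seed = 104)
  expect_equal(res$observed, 0L)
  expect_equal(res$direction, "depleted")
})
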