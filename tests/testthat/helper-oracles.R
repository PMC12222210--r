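# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (enumeration / pairwise loops) and share no code with
# the package internals they verify.

# Brute-force Mendelian classification: enumerate every transmissible
# allele pair (one allele from each parent) and ask whether any produces
# the child genotype. Genotypes 0/1/2/NA; alleles 0 = ref, 1 = alt.
oracle_classify <- function(father, mother, child) {
  if (anyNA(c(father, mother, child))) return("incomplete")
  transmissible <- function(g) switch(as.character(g),
                                      "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  for (a in transmissible(father)) {
    for (b in transmissible(mother)) {
      if (a + b == child) return("consistent")
    }
  }
  "violation"
}

# O(n*m) pairwise window-vs-track overlap count (half-open intervals).
oracle_count_overlaps <- function(windows, track) {
  n <- 0L
  for (i in seq_len(nrow(windows))) {
    hit <- any(track$chrom == windows$chrom[i] &
               track$start < windows$end[i] &
               track$end > windows$start[i])
    if (hit) n <- n + 1L
  }
  n
}

# Exact expected NMI frequency under the null-allele + background-miscall
# generative model, by enumerating the 3-allele trio genotype space (alleles
# ref/alt/deletion with probabilities (f_ref*(1-q), (1-f_ref)*(1-q), q)),
# the Mendelian transmissions, the hemizygote/homozygote call map, and the
# 4-state uniform miscall channel. Returns P(called violation) /
# P(all three calls present).
oracle_nmi_freq <- function(q, f_ref = 0.5, error = 0) {
  p_allele <- c(f_ref * (1 - q), (1 - f_ref) * (1 - q), q)
  call_geno <- function(a1, a2) {            # allele codes 0/1/2 (2 = del)
    if (a1 == 2 && a2 == 2) return(3L)       # 3 = missing call
    if (a1 == 2) return(if (a2 == 1) 2L else 0L)
    if (a2 == 2) return(if (a1 == 1) 2L else 0L)
    as.integer(a1 + a2)
  }
  # joint distribution over clean called trio states (4 x 4 x 4)
  joint <- array(0, dim = c(4, 4, 4))
  for (f1 in 0:2) for (f2 in 0:2) for (m1 in 0:2) for (m2 in 0:2) {
    pr <- p_allele[f1 + 1] * p_allele[f2 + 1] *
          p_allele[m1 + 1] * p_allele[m2 + 1]
    if (pr == 0) next
    fg <- call_geno(f1, f2); mg <- call_geno(m1, m2)
    for (cf in c(f1, f2)) for (cm in c(m1, m2)) {
      cg <- call_geno(cf, cm)
      joint[fg + 1, mg + 1, cg + 1] <- joint[fg + 1, mg + 1, cg + 1] + pr / 4
    }
  }
  # miscall channel: keep with 1 - e, each of the 3 other states with e / 3
  chan <- matrix(error / 3, 4, 4)
  diag(chan) <- 1 - error
  p_viol <- 0; p_inf <- 0
  for (fg in 0:3) for (mg in 0:3) for (cg in 0:3) {
    pr <- joint[fg + 1, mg + 1, cg + 1]
    if (pr == 0) next
    for (fo in 0:3) for (mo in 0:3) for (co in 0:3) {
      pro <- pr * chan[fg + 1, fo + 1] * chan[mg + 1, mo + 1] *
             chan[cg + 1, co + 1]
      if (pro == 0 || fo == 3 || mo == 3 || co == 3) next
      p_inf <- p_inf + pro
      st <- oracle_classify(fo, mo, co)
      if (st == "violation") p_viol <- p_viol + pro
    }
  }
  c(p_violation = p_viol, p_informative = p_inf,
    nmi_freq = p_viol / p_inf)
}

# Random interval fixtures on a small chromosome set.
random_intervals <- function(n, chroms = c("1", "2"), max_pos = 10000,
                             max_len = 400) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len)
}

# Tiny deterministic trio cohort built directly from matrices.
tiny_cohort <- function(calls, chrom = "1") {
  n_loci <- nrow(calls)
  n_trios <- ncol(calls) / 3
  ids <- c(paste0("fa", seq_len(n_trios)), paste0("mo", seq_len(n_trios)),
           paste0("ch", seq_len(n_trios)))
  colnames(calls) <- ids
  manifest <- tibble::tibble(locus_id = paste0("L", seq_len(n_loci)),
                             chrom = chrom, pos = seq_len(n_loci) * 1000L)
  rownames(calls) <- manifest$locus_id
  trios <- tibble::tibble(father = paste0("fa", seq_len(n_trios)),
                          mother = paste0("mo", seq_len(n_trios)),
                          child = paste0("ch", seq_len(n_trios)))
  trio_cohort(manifest, trios, calls)
}

# Direct NmiTable builder for concordance tests (no cohort needed).
nmi_table_from <- function(freqs, n_informative = 100) {
  k <- round(freqs * n_informative)
  tibble::tibble(locus_id = paste0("L", seq_along(freqs)), chrom = "1",
                 pos = seq_along(freqs) * 1000L,
                 n_informative = n_informative, n_violations = k,
                 nmi_freq = k / n_informative, undefined = FALSE)
}
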