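---
title: "Tagging structural variants through non-Mendelian inheritance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tagging structural variants through non-Mendelian inheritance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmisv)
library(dplyr)
```

## The problem

SNP genotyping arrays assume that both chromosomes hybridise to the probe.
When a structural variant — most simply a deletion — removes the sequence
under a probe on one homologue, that allele produces no signal and the
caller reports the individual as *homozygous* for the remaining allele; a
deletion on both homologues produces a no-call. In family trios these
miscalls surface as apparent violations of Mendelian inheritance: a child
can appear to carry an allele absent from both called parental genotypes.
Standard quality control treats such loci as assay failures and discards
them, which systematically removes exactly the loci that tag segregating
structural variants.

`nmisv` turns this artefact into a detection signal. It classifies every
(locus, trio) combination as Mendelian-consistent, violating, or
uninformative; aggregates violations into per-locus non-Mendelian
inheritance (NMI) frequencies per cohort; filters candidates that recur at
high frequency in two independent cohorts; and asks whether the candidate
loci co-locate with genomic features — heterochromatin bands, histone
marks, repeat classes, transcription-factor binding sites, eQTLs — more
often than same-size random SNP sets drawn from the same array background.

## Mendelian classification

For biallelic autosomal genotypes coded HOM\_REF / HET / HOM\_ALT, a trio is
a violation exactly when no pair of transmitted alleles (one per parent)
can produce the child's genotype. Of the 27 fully-called combinations, 12
are violations; any trio with a missing call is *uninformative* and never
enters numerator or denominator. The implementation is a vectorised rule
set; the test suite checks it against a brute-force oracle that enumerates
all allele transmissions for all 64 input combinations, and verifies
father/mother symmetry. Only autosomal rules are implemented; X/Y/MT loci
are dropped before classification.

Two modelling conventions deserve note, because the frequency filters
depend on them:

* **Denominator.** The per-locus NMI frequency is violations divided by
  *informative trios at that locus* (all three calls present). This is the
  only denominator that is well defined per locus under missing data.
* **Unit.** One trio contributes one Mendelian check per locus; the child's
  genotype is the unit of observation.

## Candidate filtering and the assay-error argument

Candidates must satisfy three filters, applied in an auditable sequence
(per-step in/out counts are retained and exposed via `tidy()`):

1. NMI frequency ≥ 2% in the discovery cohort (`f_disc_min`). Two percent
   is both the approximate population frequency of the phenotype of
   interest and 40× the array's technical error rate, so it is a
   conservative floor against genotyping error.
2. NMI frequency ≥ 15% in *both* cohorts (`f_both_min`) — recurrence in two
   independently ascertained populations.
3. Absence from a blacklist of loci already catalogued as common structural
   variants in reference populations (matched by locus id).

The binomial error model quantifies why recurrence cannot plausibly be
technical: with a per-assay failure probability of 0.05% (the platform QC
bound), the probability that one locus fails in exactly 7 of 380 trials is

```{r binom}
binomial_error_probability(error_rate = 5e-4, n = 380, k = 7, tail = "pmf")
```

about $1.4\times10^{-9}$. The error rate is an explicit argument because
the point and upper-tail versions, and the sensitivity to the assumed rate,
are worth inspecting: at a rate of 5% rather than 0.05% the probability
would be ~11 orders of magnitude larger, so the distinction matters and the
package defaults to 0.0005. `min_count_at_frequency()` converts a frequency
threshold to a family count using floor rounding (0.02 × 380 = 7.6 → 7), a
reporting convention rather than a canonical choice, and says so in its
output name.

## Feature enrichment against a resampled null

The central statistic compares candidate loci against the array background
they came from, not against the genome at large — array probes are
ascertained non-uniformly, so a genome-wide null would be confounded.

1. Every manifest locus gets a ±1 kb window (`make_windows()`): a 1-based
   SNP at position $p$ becomes the 0-based half-open interval
   $[p-1-1000,\,p+1000)$, width 2,001 bp unless clipped at the chromosome
   start. This function is the single point where coordinate conventions
   convert; everything downstream is 0-based half-open (BED convention).
2. A null ensemble of 100 same-size SNP sets is drawn uniformly without
   replacement from the background manifest *excluding* the candidates
   (`sample_null_sets()`); sets are independent across draws and fully
   reproducible from one seed.
3. Per feature class, a window counts at most once no matter how many
   intervals it touches (within-class intervals are merged first), and
   overlap requires ≥ 1 bp (`count_overlaps()`, backed by interval trees).
4. Per class, the observed candidate count $O$ is tested against the null
   mean $E$ with a 1-df two-cell goodness of fit,
   $X^2 = (O-E)^2/E + (O-E)^2/(N-E)$ with $N$ the set size, upper-tail
   $\chi^2_1$ p-value. The reported **ratio** $O/E$ equals 1 under no
   enrichment. Because the exact contingency construction behind such
   published analyses is rarely stated, an empirical permutation p (rank of
   $O$ among the null counts, two-sided) is always reported alongside, so
   the two routes can be compared.

Multiplicity is corrected within an explicit family of classes —
Bonferroni for band/repeat/TF families, Benjamini–Hochberg jointly across
a histone-mark family — and any class with observed or expected count ≤ 5
is flagged and its p suppressed, since the chi-square approximation is
unreliable there (direction and ratio are still reported).

For site lists keyed by locus (eQTL catalogues), matching is exact — by
locus id, falling back to (chromosome, position) — rather than windowed
(`enrich_exact()`), optionally per tissue bin plus an overall test.

### Calibration

The test's size and the ratio's calibration are checked empirically in the
suite: across 1,000 simulated null feature classes the uncorrected
rejection rate at $\alpha=0.05$ stays within 5% ± 2%, and the mean ratio is
1 within three standard errors. A planted 2.0-fold track (candidate set of
2,468 over a 100,000-locus background, the scale of the motivating use
case) is recovered with mean ratio inside [1.8, 2.2] across 20 seeds and is
always called enriched after Bonferroni correction.

## Term enrichment and the DEG test

`hypergeom_enrichment()` is the standard one-sided hypergeometric
over-representation test with BH correction — the in-package equivalent of
portal-based gene-ontology analysis. Annotations arrive as a plain
term-to-gene table; results carry $k, K, n, N$, the fold $(k/n)/(K/N)$ and
both raw and BH-adjusted p. Absolute term-level results from live ontology
portals are database-version dependent and are deliberately not treated as
reproduction targets; the suite instead proves the statistic against a
Fisher-exact oracle and an independent combinatorial summation.
`random_geneset_baseline()` supports both disjoint ("partition") and
independent ("resample") control gene sets — published descriptions of
"sampling without replacement" are ambiguous between the two, so both are
provided and the partition mode is the default reading.
`genes_in_regions()` implements the "any overlap of the gene body" rule
for assigning genes to region classes such as dense heterochromatin bands.

`target_deg_test()` asks whether a designated target gene set (e.g. genes
under the binding sites of specific transcription factors) is
differentially expressed more often than the transcriptome-wide rate:
expected DE targets $= (D/G)\,T$, fold $=$ target rate / overall rate, and
a two-cell goodness of fit on (DE, not-DE) among targets. Genes must pass a
strict expression floor (max group mean > 1) and sit on autosomes,
matching the scope of the upstream NMI analysis. Because the two-cell and
2×2 constructions are both defensible here, the 2×2 chi-square (with and
without Yates correction) is reported alongside; the rates and fold, not
the p-value, are the quantities a user should consider reproducible.

## The synthetic-data generator

Restricted genotype cohorts cannot ship with a package, so `nmisv`
generates every input with known ground truth, and the generator is
first-class, tested code:

* **Trios** (`simulate_trio_cohorts()`): parents drawn in Hardy–Weinberg
  proportions from per-locus allele frequencies, children by Mendelian
  transmission. At planted SV loci a third, deletion allele at frequency
  $q$ enters the pool; a hemizygote is *called* homozygous for its
  remaining real allele and a deletion homozygote is called missing —
  the minimal generative model of how deletions under probes create NMI.
  Background miscalls replace each call independently with probability
  5e-4 (the 0.05% technical error narrative) by a uniformly random
  different state among the four call states, missing included.
* **Defaults as study conditions**: two cohorts of 400 families on a
  10,000-SNP manifest with 50 planted SVs, $q \sim U(0.3, 0.5)$ and
  surviving-allele frequency $\sim U(0.4, 0.6)$ at SV loci. The latter is
  a design choice worth spelling out: closed-form enumeration of the
  three-allele trio space shows the expected NMI frequency at $q = 0.25$
  falls from 0.17 at a balanced surviving allele to 0.06 at frequency 0.1
  — a hemizygote miscall only violates Mendelian expectations when the
  other parent is informative. Array SNPs are ascertained to be common, so
  intermediate frequencies at assayed loci are the realistic regime; with
  these defaults expected NMI frequencies are 0.18–0.25 and the 15%
  two-cohort filter is attainable. The same enumeration (including the
  miscall channel) serves as the oracle the simulation is tested against.
* **Tracks** (`simulate_tracks()`): background intervals uniform over the
  synthetic genome; the empirical background window-overlap rate
  $\hat\pi_0$ is measured on non-candidate windows and each candidate
  window receives an extra interval (centred on its SNP) with probability
  $\hat\pi_0(f-1)/(1-\hat\pi_0)$ so the expected overlap ratio equals the
  planted fold $f$; folds below 1 first resample background intervals away
  from candidate windows. Infeasible folds error out rather than
  silently saturate.
* **DEG tables** (`simulate_deg_table()`): Bernoulli DE flags at an
  overall rate for non-targets and an elevated rate for targets
  (defaults 0.048 and 0.082, the regime of the motivating analysis), plus
  log-normal expression with configurable fractions below the floor and
  on sex chromosomes.

A single master seed determines the entire dataset; per-stage seeds are
derived deterministically from the master seed and the stage name, so each
pipeline stage is individually reproducible and reruns are byte-identical.

### What the generator does and does not emulate

It emulates the features that drive the statistics: shared SV truth across
independent cohorts, per-assay background error, feature tracks with a
controlled overlap fold, and DE tables with a controlled excess. It does
*not* model linkage disequilibrium, population stratification,
sex-chromosome inheritance, dosage (CNV) effects, batch structure, or the
clustering of real genomic features. Passing tests therefore demonstrate
that the statistical machinery is calibrated and recovers planted truth
under a clean generative model — not that any particular biological
dataset will yield a particular result.

## Numerical and design choices

* Chromosome names are normalised once (leading `chr` stripped) at I/O
  boundaries; positions are 1-based in manifests and converted to 0-based
  half-open intervals in exactly one function.
* PED reading designates the reference allele as the lexicographically
  smaller allele observed at each locus — deterministic and file-local;
  NMI classification is symmetric in allele labels so the choice is
  immaterial, and the PED writer emits letters consistent with it so round
  trips are exact.
* Ratios are reported even where p-values are suppressed (low counts,
  degenerate expectations); `NA` p-values propagate through correction
  rather than being invented.
* All randomised analyses take explicit integer seeds, use an isolated RNG
  scope, and record the seed in result attributes and output headers.
* Problem sizes in the test suite (e.g. 1,000 null classes, 20 planted-fold
  seeds, two 400-family cohorts at 10,000 loci) were chosen as the smallest
  scales at which the Monte-Carlo tolerances quoted above are meaningful.

## Known limitations

* NMI cannot distinguish a true structural variant from recurrent de novo
  mutation or locus-specific assay failure shared across cohorts; the
  binomial model argues the last is improbable but cannot exclude it.
* Only biallelic autosomal SNPs are handled; multi-allelic records are
  rejected and X-linked rules are out of scope.
* The in-memory genotype matrix targets ≤ ~10⁶ loci × ~10⁴ individuals;
  there is no streaming path.
* The enrichment null resamples loci, not genomic positions: it conditions
  on the array's ascertainment but cannot correct for window-to-window
  dependence induced by very long features (a window counts once per
  class, which mitigates but does not remove this).

## A worked run

```{r pipeline, eval = FALSE}
out <- run_pipeline(sim_config(seed = 1), outdir = "nmisv-run")
glance(out$candidates)
autoplot(out$enrichment)
```

The output directory then contains the PED/MAP cohorts, per-cohort NMI
tables, the candidate set with its filter provenance, per-class enrichment
results with ratios against the 100-set null, term and DEG enrichment
tables, and `run_manifest.json` with the config hash, seeds and per-stage
row counts needed to reproduce the run bit for bit.
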