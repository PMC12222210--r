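#' Read a PLINK text PED/MAP pair into a trio cohort
#'
#' MAP rows are `(chrom, locus_id, cM, pos)`; PED rows are
#' `(family, individual, father, mother, sex, phenotype)` followed by two
#' allele columns per locus, alleles in `A/C/G/T` with `0` for missing.
#' Allele pairs are converted to genotype codes against a per-locus
#' reference allele, designated as the lexicographically smaller of the
#' alleles observed at that locus across the whole file (a deterministic,
#' file-local convention; Mendelian-violation classification is symmetric in
#' the allele labels, so any consistent choice is equivalent). Individuals
#' whose father and mother are both present in the file define the trios;
#' individuals lacking parents are founders.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [trio_cohort()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- readr::read_tsv(
    map_path, col_names = c("chrom", "locus_id", "cm", "pos"),
    col_types = "ccdd", progress = FALSE
  )
  manifest <- tibble(locus_id = map$locus_id, chrom = map$chrom,
                     pos = as.integer(map$pos))
  n_loci <- nrow(manifest)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty PED file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  expect_len <- 6L + 2L * n_loci
  lens <- lengths(toks)
  if (any(lens != expect_len)) {
    i <- which(lens != expect_len)[1]
    abort(sprintf(
      "PED line %d has %d fields; expected %d for %d MAP loci",
      i, lens[i], expect_len, n_loci))
  }
  ped <- do.call(rbind, toks)
  fam <- ped[, 1]; ind <- ped[, 2]; fa <- ped[, 3]; mo <- ped[, 4]
  if (anyDuplicated(ind)) abort("duplicate individual ids in PED")
  al <- ped[, -(1:6), drop = FALSE]           # individuals x (2 * loci)
  bad <- !(al %in% c("A", "C", "G", "T", "0"))
  if (any(bad)) {
    i <- which(rowSums(matrix(bad, nrow = nrow(al))) > 0)[1]
    abort(sprintf("unknown allele symbol on PED line %d (alleles must be A/C/G/T/0)", i))
  }
  a1 <- t(al[, seq(1, ncol(al), by = 2), drop = FALSE])  # loci x individuals
  a2 <- t(al[, seq(2, ncol(al), by = 2), drop = FALSE])

  calls <- matrix(NA_integer_, nrow = n_loci, ncol = nrow(ped),
                  dimnames = list(manifest$locus_id, ind))
  for (l in seq_len(n_loci)) {
    obs <- sort(unique(c(a1[l, ], a2[l, ])))
    obs <- obs[obs != "0"]
    if (length(obs) > 2) {
      abort(sprintf("locus %s has more than two alleles in PED", manifest$locus_id[l]))
    }
    if (length(obs) == 0) next  # all missing
    ref <- obs[1]  # lexicographically smaller observed allele
    miss <- a1[l, ] == "0" | a2[l, ] == "0"
    g <- (a1[l, ] != ref) + (a2[l, ] != ref)
    g[miss] <- NA_integer_
    calls[l, ] <- as.integer(g)
  }

  has_both <- fa %in% ind & mo %in% ind
  trios <- tibble(family = fam[has_both], father = fa[has_both],
                  mother = mo[has_both], child = ind[has_both])
  pedigree <- tibble(individual = ind, family = fam, father = fa, mother = mo,
                     sex = ped[, 5], phenotype = ped[, 6])
  trio_cohort(manifest, trios, calls, pedigree)
}

#' Write a trio cohort as a PLINK text PED/MAP pair
#'
#' Genotype codes are emitted as allele letters taken from `ref_allele` /
#' `alt_allele` columns of the cohort manifest when present, otherwise
#' `A`/`C`. The reference letter is forced to be the lexicographically
#' smaller of the pair so that [read_ped_map()] reconstructs identical
#' genotype codes.
#'
#' @param cohort A [trio_cohort()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `ped_path`.
#' @export
write_ped_map <- function(cohort, ped_path, map_path) {
  man <- cohort$manifest
  ref <- if ("ref_allele" %in% names(man)) man$ref_allele else rep("A", nrow(man))
  alt <- if ("alt_allele" %in% names(man)) man$alt_allele else rep("C", nrow(man))
  swap <- alt < ref
  tmp <- ref[swap]; ref[swap] <- alt[swap]; alt[swap] <- tmp
  readr::write_tsv(
    tibble(chrom = man$chrom, locus_id = man$locus_id, cm = 0, pos = man$pos),
    map_path, col_names = FALSE, progress = FALSE
  )
  ped <- cohort$pedigree
  missing_cols <- setdiff(c("sex", "phenotype"), names(ped))
  for (mc in missing_cols) ped[[mc]] <- "0"
  if (!"family" %in% names(ped)) ped$family <- ped$individual
  calls <- cohort$calls[, ped$individual, drop = FALSE]
  con <- file(ped_path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(ped))) {
    g <- calls[, i]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, alt, ref))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2L, alt, ref))
    writeLines(paste(c(ped$family[i], ped$individual[i], ped$father[i],
                       ped$mother[i], ped$sex[i], ped$phenotype[i],
                       as.vector(rbind(al1, al2))), collapse = "\t"), con)
  }
  invisible(ped_path)
}

#' Read a BED3/BED4 file of genomic intervals
#'
#' Intervals use the BED convention: 0-based half-open `[start, end)`.
#' Column 4, when present, is taken as the interval / class name.
#' Chromosome names are normalised (a leading `"chr"` is stripped) and the
#' result is sorted by `(chrom, start, end)`.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @return Tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(toks) < 3)) {
    abort(sprintf("BED line %d has fewer than 3 tab-separated columns",
                  which(lengths(toks) < 3)[1]))
  }
  chrom <- norm_chrom(vapply(toks, `[[`, "", 1))
  start <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("non-numeric coordinates on BED line %d",
                  which(is.na(start) | is.na(end))[1]))
  }
  name <- vapply(toks, function(t) if (length(t) >= 4) t[[4]] else NA_character_, "")
  if (any(end <= start)) {
    abort(sprintf("BED line %d: end <= start (intervals are half-open, end must exceed start)",
                  which(end <= start)[1]))
  }
  if (any(start < 0)) abort("BED start coordinates must be >= 0")
  arrange(tibble(chrom = chrom, start = start, end = end, name = name),
          .data$chrom, .data$start, .data$end)
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  x <- as_tibble(intervals)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(x) && !all(is.na(x$name))) cols <- c(cols, "name")
  readr::write_tsv(x[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a results table as deterministic TSV
#'
#' Columns are written in their existing order with a header row; numeric
#' columns are formatted to 10 significant digits so identical results yield
#' byte-identical files. A `# seed:` header comment records the seed when the
#' table carries one as an attribute.
#'
#' @param results A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_tsv <- function(results, path) {
  x <- as_tibble(results)
  for (nm in names(x)[vapply(x, is.double, logical(1))]) {
    x[[nm]] <- ifelse(is.na(x[[nm]]), NA_character_, sprintf("%.10g", x[[nm]]))
  }
  hdr <- character()
  if (!is.null(attr(results, "seed"))) {
    hdr <- sprintf("# seed: %s", attr(results, "seed"))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x)) {
    body <- do.call(paste, c(lapply(x, function(col) {
      col <- as.character(col); col[is.na(col)] <- "NA"; col
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read back a results TSV written by [write_results_tsv()]
#'
#' @param path Path to the TSV.
#' @return A tibble with column types guessed by readr.
#' @export
read_results_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", na = "NA", progress = FALSE,
                  show_col_types = FALSE)
}

#' Read biallelic genotypes from a VCF into a trio cohort
#'
#' Optional convenience input (requires the vcfR package): biallelic records
#' only, GT field only; `./.` becomes missing. Trios are assembled from a
#' separate pedigree table.
#'
#' @param vcf_path Path to a VCF file.
#' @param pedigree Tibble with columns `individual`, `father`, `mother`
#'   (ids of `"0"` mean unknown).
#' @return A [trio_cohort()].
#' @export
read_vcf_trios <- function(vcf_path, pedigree) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf_trios() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) abort("multi-allelic VCF records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  calls <- apply(gt, 2, code)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  rownames(calls) <- ids
  manifest <- tibble(locus_id = ids, chrom = norm_chrom(fix$CHROM),
                     pos = as.integer(fix$POS))
  pedigree <- as_tibble(pedigree)
  has_both <- pedigree$father %in% pedigree$individual &
    pedigree$mother %in% pedigree$individual
  trios <- tibble(father = pedigree$father[has_both],
                  mother = pedigree$mother[has_both],
                  child = pedigree$individual[has_both])
  trio_cohort(manifest, trios, calls, pedigree)
}
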