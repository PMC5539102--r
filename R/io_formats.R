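## Readers and writers for every external representation the pipeline
## touches: PED pedigrees, VCF genotypes, GTF gene annotation,
## samtools-mpileup base strings, and the 8-column allele-count table.

#' Read a PED-like pedigree into a table of trios
#'
#' Expects whitespace-separated columns `family`, `individual`, `father`,
#' `mother`, `sex` (a sixth phenotype column, if present, is ignored).
#' One trio is emitted per child whose father and mother identifiers are
#' both non-missing (`0` marks a missing parent).  Rows with exactly one
#' missing parent are skipped with a warning; rows with both parents
#' missing are founders and are skipped silently.
#'
#' @param path path to the pedigree file.  Lines starting with `#` and
#'   blank lines are ignored.
#' @return data.frame with columns `family`, `child_id`, `father_id`,
#'   `mother_id`, `child_sex` (`"female"`, `"male"` or `"unknown"`).
#' @export
#' @examples
#' ped <- tempfile()
#' writeLines("F1 NA12878 NA12891 NA12892 2", ped)
#' read_pedigree(ped)
read_pedigree <- function(path) {
  if (!file.exists(path)) {
    stop_rad(paste0("pedigree file not found: ", path), "radase_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- list()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 5) {
      stop_rad(sprintf("malformed pedigree line %d: expected >= 5 columns, got %d",
                       i, length(f)), "radase_parse_error")
    }
    father <- f[3]
    mother <- f[4]
    if (father == "0" && mother == "0") next    # founder
    if (father == "0" || mother == "0") {
      warning(sprintf("pedigree line %d: child '%s' has a missing parent id; family skipped",
                      i, f[2]), call. = FALSE)
      next
    }
    if (anyDuplicated(f[2:4])) {
      warning(sprintf("pedigree line %d: child/father/mother ids not distinct; family skipped",
                      i), call. = FALSE)
      next
    }
    sex <- switch(f[5], "1" = "male", "2" = "female", "unknown")
    out[[length(out) + 1L]] <- data.frame(
      family = f[1], child_id = f[2], father_id = father,
      mother_id = mother, child_sex = sex, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(family = character(), child_id = character(),
                      father_id = character(), mother_id = character(),
                      child_sex = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read genotypes for selected individuals from a VCF
#'
#' Only biallelic SNP records (single-nucleotide REF and ALT) are
#' retained; multiallelic and non-SNP records are dropped and counted in
#' the `"n_dropped"` attribute of the result.  Phase separators (`|`) are
#' ignored: parent-of-origin is always re-derived from trio genotypes,
#' never taken from the file.  Haploid genotype calls are treated as
#' homozygous.
#'
#' @param vcf_path path to a VCF (v4.x) file with GT fields.
#' @param individual_ids individuals to extract; default all samples.
#' @return long data.frame with columns `chrom` (normalised), `pos`,
#'   `ref`, `alt`, `individual`, `allele1`, `allele2` (both `NA` for a
#'   missing genotype), plus attribute `n_dropped`.
#' @export
read_genotypes <- function(vcf_path, individual_ids = NULL) {
  if (!file.exists(vcf_path)) {
    stop_rad(paste0("VCF file not found: ", vcf_path), "radase_io_error")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% NUCLEOTIDES & fix$ALT %in% NUCLEOTIDES
  n_dropped <- sum(!keep)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (is.null(individual_ids)) individual_ids <- samples
  missing_ids <- setdiff(individual_ids, samples)
  if (length(missing_ids) > 0) {
    stop_rad(paste0("individuals absent from VCF header: ",
                    paste(missing_ids, collapse = ", ")),
             "radase_io_error")
  }
  gt <- gt[keep, individual_ids, drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  n_sites <- nrow(fix)
  n_ind <- length(individual_ids)
  gt_flat <- as.vector(gt)                       # site-major within individual
  parts <- strsplit(ifelse(is.na(gt_flat), ".", gt_flat), "[/|]")
  a1_idx <- vapply(parts, function(p) p[1], character(1))
  a2_idx <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1],
                   character(1))
  ref <- rep(fix$REF, times = n_ind)
  alt <- rep(fix$ALT, times = n_ind)
  decode <- function(idx) {
    out <- rep(NA_character_, length(idx))
    out[idx == "0"] <- ref[idx == "0"]
    out[idx == "1"] <- alt[idx == "1"]
    out
  }
  a1 <- decode(a1_idx)
  a2 <- decode(a2_idx)
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_
  out <- data.frame(
    chrom = rep(norm_chrom(fix$CHROM), times = n_ind),
    pos = rep(as.integer(fix$POS), times = n_ind),
    ref = ref, alt = alt,
    individual = rep(individual_ids, each = n_sites),
    allele1 = a1, allele2 = a2,
    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Parse one samtools-mpileup base-column string
#'
#' Implements the mpileup read-base grammar: `.`/`,` count to the
#' reference base, letters count to their nucleotide (case-folded),
#' `^` consumes the following mapping-quality character, `$` is
#' consumed, `+n`/`-n` indel runs are consumed without contributing base
#' counts (each run increments `indel_count`), and `*` (a deleted base)
#' and `<`/`>` (reference skips) are counted as neither reference nor
#' nucleotide.
#'
#' @param ref_base the reference base at the site (A/C/G/T).
#' @param base_string the mpileup base column for one site and sample.
#' @return list with `ref_count`, `base_counts` (named integer vector
#'   over A/C/G/T/N), `indel_count` and `deletion_count` (the `*`, `<`,
#'   `>` symbols).
#' @export
#' @examples
#' parse_pileup_base_string("A", ".,Gg^F.$,")
parse_pileup_base_string <- function(ref_base, base_string) {
  stopifnot(length(ref_base) == 1, length(base_string) == 1)
  ref_base <- toupper(ref_base)
  chars <- strsplit(base_string, "", fixed = TRUE)[[1]]
  n <- length(chars)
  ref_count <- 0L
  base_counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  indel_count <- 0L
  deletion_count <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      if (i == n) {
        stop_rad("dangling '^' at end of pileup base string",
                 "radase_parse_error")
      }
      i <- i + 2L                       # skip mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "." || ch == ",") {
      ref_count <- ref_count + 1L
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      if (j == i + 1L) {
        stop_rad("indel marker not followed by a length", "radase_parse_error")
      }
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n) {
        stop_rad("truncated indel run in pileup base string",
                 "radase_parse_error")
      }
      indel_count <- indel_count + 1L
      i <- j + len
    } else if (ch %in% c("*", "<", ">")) {
      deletion_count <- deletion_count + 1L
      i <- i + 1L
    } else if (toupper(ch) %in% names(base_counts)) {
      b <- toupper(ch)
      base_counts[b] <- base_counts[b] + 1L
      i <- i + 1L
    } else {
      stop_rad(sprintf("unexpected character '%s' in pileup base string", ch),
               "radase_parse_error")
    }
  }
  list(ref_count = ref_count, base_counts = base_counts,
       indel_count = indel_count, deletion_count = deletion_count)
}

#' Convert a multi-sample mpileup file to allele-count records
#'
#' Sites are matched by (chrom, pos) against `sites`, which supplies the
#' ref/alt designation; the alt count is the parsed count of the alt
#' nucleotide and `other_count` collects all remaining nucleotide calls.
#' Deleted bases and reference skips contribute to no allele (a
#' convention for indel-adjacent reads, logged once per file).
#'
#' @param path mpileup output (`samtools mpileup` default text format).
#' @param individual_ids sample names, one per mpileup sample column
#'   triplet, in file order.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return data.frame of allele-count records (see [read_allele_counts()]).
#' @export
read_pileup_counts <- function(path, individual_ids, sites) {
  lines <- readLines(path, warn = FALSE)
  key <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  pos_key <- paste(norm_chrom(sites$chrom), sites$pos, sep = ":")
  out <- list()
  n_del <- 0L
  for (ln in lines) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 + 3 * length(individual_ids)) {
      stop_rad("mpileup line has fewer columns than expected for the sample list",
               "radase_parse_error")
    }
    idx <- match(paste(norm_chrom(f[1]), f[2], sep = ":"), pos_key)
    if (is.na(idx)) next
    for (s in seq_along(individual_ids)) {
      bases <- f[3 + 3 * (s - 1) + 2]
      p <- parse_pileup_base_string(f[3], bases)
      n_del <- n_del + p$deletion_count
      alt_nuc <- sites$alt[idx]
      alt_count <- unname(p$base_counts[alt_nuc])
      other_count <- sum(p$base_counts) - alt_count
      out[[length(out) + 1L]] <- data.frame(
        chrom = norm_chrom(f[1]), pos = as.integer(f[2]),
        ref = sites$ref[idx], alt = sites$alt[idx],
        individual = individual_ids[s],
        ref_count = p$ref_count, alt_count = alt_count,
        other_count = other_count, stringsAsFactors = FALSE)
    }
  }
  if (n_del > 0) {
    rad_log(n_del, " deleted/skipped base symbols ignored while parsing pileup")
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), individual = character(),
                      ref_count = integer(), alt_count = integer(),
                      other_count = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read a tab-separated allele-count table
#'
#' Requires the columns `chrom`, `pos`, `ref`, `alt`, `individual`,
#' `ref_count`, `alt_count`, `other_count`.  Records are validated
#' (ACGT alleles, ref != alt, pos >= 1, non-negative counts, no
#' duplicate site-individual pairs); validation failures name the
#' offending row or key.
#'
#' @param tsv_path path to the counts table.
#' @return validated data.frame with normalised chromosome names.
#' @export
read_allele_counts <- function(tsv_path) {
  df <- rad_read_tsv(tsv_path)
  required <- c("chrom", "pos", "ref", "alt", "individual",
                "ref_count", "alt_count", "other_count")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop_rad(paste0("counts table missing columns: ",
                    paste(miss, collapse = ", ")), "radase_io_error")
  }
  df <- df[required]
  df$chrom <- norm_chrom(df$chrom)
  validate_allele_counts(df)
}

validate_allele_counts <- function(df) {
  first_bad <- function(cond) which(cond)[1]
  for (col in c("ref", "alt")) check_nucleotides(df[[col]], col)
  if (any(df$ref == df$alt)) {
    stop_rad(sprintf("row %d: ref equals alt", first_bad(df$ref == df$alt)),
             "radase_validation_error")
  }
  if (any(df$pos < 1)) {
    stop_rad(sprintf("row %d: position < 1", first_bad(df$pos < 1)),
             "radase_validation_error")
  }
  counts <- df[c("ref_count", "alt_count", "other_count")]
  bad <- is.na(counts) | counts < 0
  if (any(bad)) {
    stop_rad(sprintf("row %d: negative or missing read count",
                     first_bad(rowSums(bad) > 0)),
             "radase_validation_error")
  }
  k <- paste(site_key(df$chrom, df$pos, df$ref, df$alt), df$individual)
  if (anyDuplicated(k)) {
    stop_rad(paste0("duplicate (site, individual) rows: ",
                    k[which(duplicated(k))[1]]),
             "radase_validation_error")
  }
  df
}

#' Read gene spans from a GTF file
#'
#' Imports gene-level features and returns them as a `GRanges` gene
#' index (1-based, closed intervals, the native convention of both GTF
#' and `GRanges`).  Overlap queries are strand-agnostic and use the full
#' gene-body span, introns included.
#'
#' @param gtf_path path to a GTF (GENCODE dialect) file.
#' @return `GRanges` with a `gene_id` metadata column and normalised
#'   chromosome names.
#' @export
read_gene_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) {
    stop_rad(paste0("annotation file not found: ", gtf_path), "radase_io_error")
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  genes <- gr[!is.na(gr$type) & gr$type == "gene"]
  if (length(genes) == 0) {
    stop_rad("no gene features in annotation", "radase_io_error")
  }
  if (is.null(genes$gene_id)) {
    stop_rad("gene features lack a gene_id attribute", "radase_io_error")
  }
  GenomeInfoDb::seqlevels(genes) <- norm_chrom(GenomeInfoDb::seqlevels(genes))
  genes
}

site_query <- function(genes, chrom, pos) {
  chrom <- norm_chrom(chrom)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  suppressWarnings(GenomicRanges::findOverlaps(
    q, genes, ignore.strand = TRUE))
}

#' Query the gene index by position
#'
#' `genes_overlapping` returns the `gene_id`s overlapping each queried
#' position (a list, one character vector per query); `site_in_gene`
#' returns a logical vector.
#'
#' @param genes a gene index from [read_gene_annotation()].
#' @param chrom,pos vectors of positions (1-based).
#' @return list of character vectors / logical vector.
#' @export
genes_overlapping <- function(genes, chrom, pos) {
  hits <- site_query(genes, chrom, pos)
  out <- rep(list(character(0)), length(pos))
  if (length(hits) > 0) {
    sp <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    out[as.integer(names(sp))] <- lapply(sp, unique)
  }
  out
}

#' @rdname genes_overlapping
#' @export
site_in_gene <- function(genes, chrom, pos) {
  lengths(genes_overlapping(genes, chrom, pos)) > 0
}
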