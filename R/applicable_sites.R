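## Applicability filtering and parent-of-origin inference.
##
## A SNP is "applicable" for a child when (1) the child is heterozygous
## and the site lies in a genic region, (2) at least one parent is
## homozygous, (3) every heterozygous individual examined shows the same
## dimorphic nucleotide pair, (4) more than 10 reads map to the site and
## (5) any third allele accounts for less than 10% of the mapped reads.

#' Infer the parental origin of a heterozygous child's alleles
#'
#' Given unphased trio genotypes, decides which child allele was
#' transmitted by the father and which by the mother.  The assignment is
#' determinable exactly when only one transmission pattern is Mendelian
#' consistent -- in particular whenever at least one parent is
#' homozygous.  When both parents are heterozygous both assignments are
#' possible and `determinable` is `FALSE`.
#'
#' @param child_gt,father_gt,mother_gt length-2 character vectors of
#'   nucleotides (unordered allele pairs).  The child must be
#'   heterozygous and no genotype may be missing.
#' @return list with `paternal_allele`, `maternal_allele` and
#'   `determinable`.
#' @export
#' @examples
#' infer_origin(c("A", "G"), c("A", "A"), c("G", "G"))
infer_origin <- function(child_gt, father_gt, mother_gt) {
  stopifnot(length(child_gt) == 2, length(father_gt) == 2,
            length(mother_gt) == 2)
  if (anyNA(c(child_gt, father_gt, mother_gt))) {
    stop_rad("infer_origin requires complete trio genotypes",
             "radase_validation_error")
  }
  if (child_gt[1] == child_gt[2]) {
    stop_rad("infer_origin requires a heterozygous child",
             "radase_validation_error")
  }
  x <- child_gt[1]
  y <- child_gt[2]
  v1 <- (x %in% father_gt) && (y %in% mother_gt)   # paternal x, maternal y
  v2 <- (y %in% father_gt) && (x %in% mother_gt)   # paternal y, maternal x
  if (!v1 && !v2) {
    stop_rad(sprintf(
      "Mendelian inconsistency: child %s/%s, father %s/%s, mother %s/%s",
      x, y, father_gt[1], father_gt[2], mother_gt[1], mother_gt[2]),
      "radase_mendelian_error")
  }
  if (v1 && v2) {
    return(list(paternal_allele = NA_character_,
                maternal_allele = NA_character_, determinable = FALSE))
  }
  if (v1) {
    list(paternal_allele = x, maternal_allele = y, determinable = TRUE)
  } else {
    list(paternal_allele = y, maternal_allele = x, determinable = TRUE)
  }
}

is_het <- function(a1, a2) !is.na(a1) & !is.na(a2) & a1 != a2
is_hom <- function(a1, a2) !is.na(a1) & !is.na(a2) & a1 == a2

#' Check the five applicability criteria for one (site, child) record
#'
#' @param ref_count,alt_count,other_count mapped-read counts at the site.
#' @param child_gt,father_gt,mother_gt length-2 allele vectors (any `NA`
#'   marks the genotype missing, in which case no verdict is computed
#'   and the site is reported unavailable for this child).
#' @param genic is the site inside a gene body?
#' @param het_pairs_at_site optional character vector of sorted allele
#'   pairs (`"A/G"`) observed in the other heterozygous individuals
#'   examined at this site, used for the dimorphic-pattern criterion.
#' @param config thresholds, see [rad_config()].
#' @return list with `applicable`, `failed_criteria` (character vector,
#'   empty when applicable), `unavailable`, and the origin assignment
#'   (`paternal_allele`, `maternal_allele`, `determinable`).
#' @export
check_applicability <- function(ref_count, alt_count, other_count,
                                child_gt, father_gt, mother_gt,
                                genic = TRUE, het_pairs_at_site = NULL,
                                config = rad_config()) {
  if (anyNA(c(child_gt, father_gt, mother_gt))) {
    return(list(applicable = NA, failed_criteria = character(0),
                unavailable = TRUE, paternal_allele = NA_character_,
                maternal_allele = NA_character_, determinable = NA))
  }
  failed <- character(0)
  child_het <- child_gt[1] != child_gt[2]
  if (!child_het) failed <- c(failed, "not_heterozygous")
  if (!genic) failed <- c(failed, "not_genic")
  hom_parent <- father_gt[1] == father_gt[2] || mother_gt[1] == mother_gt[2]
  if (!hom_parent) failed <- c(failed, "no_homozygous_parent")
  pat <- NA_character_
  mat <- NA_character_
  det <- FALSE
  if (child_het) {
    org <- tryCatch(infer_origin(child_gt, father_gt, mother_gt),
                    radase_mendelian_error = function(e) NULL)
    if (is.null(org)) {
      failed <- c(failed, "mendelian_inconsistent")
    } else {
      pat <- org$paternal_allele
      mat <- org$maternal_allele
      det <- org$determinable
    }
    own_pair <- paste(sort(child_gt), collapse = "/")
    if (!is.null(het_pairs_at_site) &&
        any(het_pairs_at_site != own_pair)) {
      failed <- c(failed, "pattern_mismatch")
    }
  }
  total <- ref_count + alt_count + other_count
  if (total <= config$min_depth) failed <- c(failed, "low_depth")
  if (total > 0 && other_count / total >= config$max_third_frac) {
    failed <- c(failed, "third_allele_excess")
  }
  list(applicable = length(failed) == 0, failed_criteria = failed,
       unavailable = FALSE, paternal_allele = pat, maternal_allele = mat,
       determinable = det)
}

geno_lookup <- function(genotypes) {
  k <- paste(site_key(genotypes$chrom, genotypes$pos, genotypes$ref,
                      genotypes$alt), genotypes$individual)
  stats::setNames(seq_len(nrow(genotypes)), k)
}

#' Build the per-(site, child) applicability table for a trio cohort
#'
#' Applies [check_applicability()] to every allele-count record
#' belonging to a child of the loaded trios.  The dimorphic-pattern
#' criterion compares, per site, the unordered allele pairs of all
#' heterozygous children (and, when `extra_genotypes` is supplied, of
#' heterozygous population individuals too).
#'
#' @param counts allele-count records (see [read_allele_counts()]).
#' @param genotypes long genotype table (see [read_genotypes()]) holding
#'   all trio members.
#' @param trios trio table from [read_pedigree()].
#' @param genes gene index from [read_gene_annotation()], or `NULL` to
#'   skip the genic criterion.
#' @param config thresholds, see [rad_config()].
#' @param extra_genotypes optional genotype table of additional
#'   individuals included in the dimorphic-pattern comparison.
#' @return data.frame, one row per (site, child) count record, with the
#'   verdict, the comma-separated failed criteria and the origin
#'   assignment.
#' @export
applicability_table <- function(counts, genotypes, trios, genes = NULL,
                                config = rad_config(),
                                extra_genotypes = NULL) {
  child_rows <- counts$individual %in% trios$child_id
  cc <- counts[child_rows, , drop = FALSE]
  empty <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), individual = character(), family = character(),
    applicable = logical(), failed_criteria = character(),
    unavailable = logical(), paternal_allele = character(),
    maternal_allele = character(), determinable = logical(),
    ref_count = integer(), alt_count = integer(), other_count = integer(),
    stringsAsFactors = FALSE)
  if (nrow(cc) == 0) return(empty)

  ## fully vectorised over the (site, child) records
  gk <- paste(site_key(genotypes$chrom, genotypes$pos, genotypes$ref,
                       genotypes$alt), genotypes$individual)
  sk <- site_key(cc$chrom, cc$pos, cc$ref, cc$alt)
  trio_of <- match(cc$individual, trios$child_id)
  idx <- function(id) match(paste(sk, id), gk)
  jc <- idx(trios$child_id[trio_of])
  jf <- idx(trios$father_id[trio_of])
  jm <- idx(trios$mother_id[trio_of])
  gA1 <- genotypes$allele1
  gA2 <- genotypes$allele2
  gt_missing <- function(j) is.na(j) | is.na(gA1[j]) | is.na(gA2[j])
  unavailable <- gt_missing(jc) | gt_missing(jf) | gt_missing(jm)

  c1 <- gA1[jc]; c2 <- gA2[jc]
  f1 <- gA1[jf]; f2 <- gA2[jf]
  m1 <- gA1[jm]; m2 <- gA2[jm]
  child_het <- !unavailable & c1 != c2
  hom_parent <- !unavailable & (f1 == f2 | m1 == m2)

  ## Mendelian transmission: which child allele can each parent supply?
  in_gt <- function(a, g1, g2) !is.na(a) & (a == g1 | a == g2)
  v1 <- in_gt(c1, f1, f2) & in_gt(c2, m1, m2)   # paternal c1, maternal c2
  v2 <- in_gt(c2, f1, f2) & in_gt(c1, m1, m2)   # paternal c2, maternal c1
  mendel_bad <- child_het & !v1 & !v2
  determinable <- child_het & xor(v1, v2)
  paternal <- ifelse(determinable, ifelse(v1, c1, c2), NA_character_)
  maternal <- ifelse(determinable, ifelse(v1, c2, c1), NA_character_)

  ## dimorphic-pattern criterion over all heterozygous individuals examined
  het_pool <- genotypes[genotypes$individual %in% trios$child_id, ,
                        drop = FALSE]
  if (!is.null(extra_genotypes)) {
    het_pool <- rbind(het_pool, extra_genotypes[names(het_pool)])
  }
  het_pool <- het_pool[is_het(het_pool$allele1, het_pool$allele2), ,
                       drop = FALSE]
  pool_pos <- paste(norm_chrom(het_pool$chrom), het_pool$pos)
  pool_pair <- paste(pmin(het_pool$allele1, het_pool$allele2),
                     pmax(het_pool$allele1, het_pool$allele2), sep = "/")
  n_pairs <- tapply(pool_pair, pool_pos, function(x) length(unique(x)))
  mismatch_pos <- names(n_pairs)[n_pairs > 1]
  pattern_mismatch <- child_het &
    paste(norm_chrom(cc$chrom), cc$pos) %in% mismatch_pos

  genic <- if (is.null(genes)) rep(TRUE, nrow(cc)) else {
    site_in_gene(genes, cc$chrom, cc$pos)
  }
  total <- cc$ref_count + cc$alt_count + cc$other_count
  low_depth <- total <= config$min_depth
  third_excess <- total > 0 & cc$other_count / total >= config$max_third_frac

  crit <- cbind(not_heterozygous = !unavailable & !child_het,
                not_genic = !unavailable & !genic,
                no_homozygous_parent = !unavailable & !hom_parent,
                pattern_mismatch = pattern_mismatch,
                mendelian_inconsistent = mendel_bad,
                low_depth = !unavailable & low_depth,
                third_allele_excess = !unavailable & third_excess)
  failed <- apply(crit, 1, function(x) {
    paste(colnames(crit)[x], collapse = ",")
  })
  applicable <- ifelse(unavailable, NA, !nzchar(failed))
  out <- data.frame(
    chrom = norm_chrom(cc$chrom), pos = cc$pos, ref = cc$ref, alt = cc$alt,
    individual = cc$individual, family = trios$family[trio_of],
    applicable = applicable, failed_criteria = failed,
    unavailable = unavailable, paternal_allele = paternal,
    maternal_allele = maternal,
    determinable = ifelse(unavailable, NA, determinable),
    ref_count = cc$ref_count, alt_count = cc$alt_count,
    other_count = cc$other_count, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_non_child_records") <- sum(!child_rows)
  out
}
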