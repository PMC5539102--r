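## Population-scale analysis: per-individual applicability across a
## cohort, the ASE fraction / biallelic percentage, and the r=a versus
## r!=a chi-square discrimination between imprinting/RME-consistent and
## genetic-variation-dependent ASE.

#' Chi-square test of reference-biased versus alternative-biased counts
#'
#' The population-scale discrimination test: a 1-df goodness-of-fit of
#' the number of ref-biased individuals against the number of
#' alt-biased individuals.  Balance (`p > alpha`) is consistent with
#' imprinting or RME (verdict `r_eq_a`); skew toward one allele marks
#' genetic-variation-dependent ASE (`r_ne_a`).  Vectorised.
#'
#' @param n_ref_biased,n_alt_biased counts of applicable individuals
#'   biased toward each allele; each pair must sum to at least 1.
#' @param alpha significance threshold (default 0.05).
#' @return list with `chi2`, `p` and `verdict`.
#' @export
#' @examples
#' r_equals_a_test(24, 26)
r_equals_a_test <- function(n_ref_biased, n_alt_biased, alpha = 0.05) {
  n <- n_ref_biased + n_alt_biased
  if (any(n < 1)) {
    stop_rad("r = a test undefined when both bias counts are zero",
             "radase_validation_error")
  }
  chi2 <- (n_ref_biased - n_alt_biased)^2 / n
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p,
       verdict = ifelse(p > alpha, "r_eq_a", "r_ne_a"))
}

#' Summarise population-scale ASE per site
#'
#' For every site present in the cohort counts, each cohort individual
#' is screened with the per-individual applicability criteria
#' (heterozygous, depth > `min_depth`, third-allele fraction <
#' `max_third_frac`); for sites on chromosome X only female individuals
#' are considered, which requires `sex` metadata.  Each applicable
#' individual is then called ref-biased, alt-biased (ASE under the
#' configured definition, stringent by default) or biallelic.  A site
#' with at most `min_cohort` applicable individuals gets verdict
#' `not_enough_individuals`; one whose ASE fraction is below
#' `min_ase_fraction` gets `below_ase_fraction`; otherwise the r=a test
#' decides between `r_eq_a` and `r_ne_a`.
#'
#' @param counts cohort allele-count records.
#' @param genotypes cohort genotype table (see [read_genotypes()]).
#' @param sex optional data.frame with columns `individual` and `sex`
#'   (`"female"`/`"male"`); required when any site is on chromosome X.
#' @param config thresholds, see [rad_config()].
#' @return data.frame, one row per site, with the bias tallies,
#'   `ase_fraction`, `biallelic_percent`, `chi2_ra`, `p_ra`, `verdict`.
#' @export
summarize_population <- function(counts, genotypes, sex = NULL,
                                 config = rad_config()) {
  cc <- counts
  chrx <- is_chrx(cc$chrom)
  if (any(chrx)) {
    if (is.null(sex)) {
      stop_rad("chromosome-X sites present but no sex metadata supplied",
               "radase_validation_error")
    }
    female <- sex$individual[sex$sex == "female"]
    cc <- cc[!chrx | cc$individual %in% female, , drop = FALSE]
  }
  lut <- geno_lookup(genotypes)
  j <- lut[paste(site_key(cc$chrom, cc$pos, cc$ref, cc$alt), cc$individual)]
  a1 <- genotypes$allele1[j]
  a2 <- genotypes$allele2[j]
  het <- !is.na(j) & is_het(a1, a2)
  total <- cc$ref_count + cc$alt_count + cc$other_count
  third_ok <- total > 0 & cc$other_count / total < config$max_third_frac
  applicable <- het & total > config$min_depth & third_ok

  aa <- cc[applicable, , drop = FALSE]
  status <- character(0)
  biased <- character(0)
  if (nrow(aa) > 0) {
    calls <- call_ase(aa$ref_count, aa$alt_count, config)
    ase <- if (config$population_ase == "stringent") {
      calls$status == "ase_stringent"
    } else {
      calls$status %in% c("ase_stringent", "ase_loose")
    }
    status <- ifelse(ase, "ase", "biallelic")
    biased <- calls$biased_allele
  }

  key_all <- site_key(cc$chrom, cc$pos, cc$ref, cc$alt)
  keys <- unique(site_key(counts$chrom, counts$pos, counts$ref, counts$alt))
  key_app <- key_all[applicable]
  tab <- function(kk, cond) {
    t <- table(factor(kk[cond], levels = keys))
    as.integer(t)
  }
  n_applicable <- tab(key_app, rep(TRUE, length(key_app)))
  n_ref <- tab(key_app, status == "ase" & biased == "ref")
  n_alt <- tab(key_app, status == "ase" & biased == "alt")
  n_biallelic <- n_applicable - n_ref - n_alt

  first <- counts[match(keys, site_key(counts$chrom, counts$pos,
                                       counts$ref, counts$alt)), ,
                  drop = FALSE]
  ase_fraction <- ifelse(n_applicable > 0,
                         (n_ref + n_alt) / n_applicable, NA_real_)
  biallelic_percent <- ifelse(n_applicable > 0,
                              100 * n_biallelic / n_applicable, NA_real_)
  chi2_ra <- rep(NA_real_, length(keys))
  p_ra <- rep(NA_real_, length(keys))
  verdict <- rep(NA_character_, length(keys))
  not_enough <- n_applicable <= config$min_cohort
  verdict[not_enough] <- "not_enough_individuals"
  low_frac <- !not_enough & ase_fraction < config$min_ase_fraction
  verdict[low_frac] <- "below_ase_fraction"
  testable <- !not_enough & !low_frac & (n_ref + n_alt) >= 1
  if (any(testable)) {
    t <- r_equals_a_test(n_ref[testable], n_alt[testable],
                         alpha = config$ra_alpha)
    chi2_ra[testable] <- t$chi2
    p_ra[testable] <- t$p
    verdict[testable] <- t$verdict
  }
  out <- data.frame(
    chrom = norm_chrom(first$chrom), pos = first$pos, ref = first$ref, alt = first$alt,
    n_applicable = n_applicable, n_ref_biased = n_ref,
    n_alt_biased = n_alt, n_biallelic = n_biallelic,
    ase_fraction = ase_fraction, biallelic_percent = biallelic_percent,
    chi2_ra = chi2_ra, p_ra = p_ra, verdict = verdict,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join trio-stage categories with population-scale verdicts
#'
#' Left-and-right outer join on the site key.  The interpretive call
#' combines the two: Category 1-1 or 1-2 with `r_eq_a` is read as
#' imprinting (paternal or maternal expression per the trio labels);
#' Category 2-2 with `r_eq_a` as RME; any category with `r_ne_a` as
#' genetic-variation-dependent.  Category/verdict combinations the
#' two stages interpret differently (Category 2-1 with `r_eq_a`, or
#' Categories 1-1 / 2-2 with `r_ne_a`) are flagged `discordant`, never
#' silently overwritten.
#'
#' @param category_calls table from [classify_sites()] (optionally with
#'   the [rme_gene_exclusion()] flag; excluded sites are kept and
#'   marked).
#' @param population_summaries table from [summarize_population()].
#' @return joined data.frame with `category`, `verdict`,
#'   `interpretation` and `discordant`; sites absent from one table
#'   carry `NA` on that side.
#' @export
reconcile_with_categories <- function(category_calls, population_summaries) {
  ck <- site_key(category_calls$chrom, category_calls$pos,
                 category_calls$ref, category_calls$alt)
  pk <- site_key(population_summaries$chrom, population_summaries$pos,
                 population_summaries$ref, population_summaries$alt)
  keys <- union(ck, pk)
  ci <- match(keys, ck)
  pi <- match(keys, pk)
  coord <- function(col) {
    ifelse(!is.na(ci), category_calls[[col]][ci],
           population_summaries[[col]][pi])
  }
  category <- category_calls$category[ci]
  labels <- category_calls$labels[ci]
  verdict <- population_summaries$verdict[pi]
  parent_word <- function(lab) {
    first <- substr(strsplit(lab, ",")[[1]][1], 1, 1)
    if (first == "P") "paternal expression" else "maternal expression"
  }
  interpretation <- rep(NA_character_, length(keys))
  discordant <- rep(FALSE, length(keys))
  for (i in seq_along(keys)) {
    cat_i <- category[i]
    v_i <- verdict[i]
    if (is.na(cat_i) || is.na(v_i)) next
    if (v_i %in% c("not_enough_individuals", "below_ase_fraction")) {
      interpretation[i] <- paste0("inconclusive (", v_i, ")")
    } else if (v_i == "r_ne_a") {
      interpretation[i] <- "genetic-variation-dependent"
      discordant[i] <- cat_i %in% c("C1-1", "C2-2")
    } else if (cat_i %in% c("C1-1", "C1-2")) {
      interpretation[i] <- paste0(parent_word(labels[i]), " (imprinting)")
    } else if (cat_i == "C2-2") {
      interpretation[i] <- "RME"
    } else {                            # C2-1 with r_eq_a
      interpretation[i] <- "discordant"
      discordant[i] <- TRUE
    }
  }
  out <- data.frame(
    chrom = coord("chrom"), pos = coord("pos"), ref = coord("ref"),
    alt = coord("alt"), category = category, labels = labels,
    verdict = verdict, interpretation = interpretation,
    discordant = discordant, stringsAsFactors = FALSE)
  if (!is.null(category_calls$excluded_by_rme_gene)) {
    out$excluded_by_rme_gene <- category_calls$excluded_by_rme_gene[ci]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
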