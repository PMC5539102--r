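## Run configuration and the two pipeline stages (trio categorisation,
## population-scale discrimination).

#' Pipeline run configuration
#'
#' Gathers every threshold of the method, all at their canonical
#' defaults: loose ASE at chi-square `p < 0.05`; stringent ASE at
#' `p < 1e-3` with higher/lower allele ratio `> 2` and ASE score
#' (`-log10 p`) `> 3`; site depth strictly greater than 10 reads;
#' third-allele fraction strictly below 10%; population sites require
#' strictly more than 10 applicable individuals and an ASE fraction of
#' at least 95%; the r=a test is read at `alpha = 0.05`.  Every
#' threshold is overridable.
#'
#' @param loose_p,stringent_p chi-square p-value thresholds
#'   (`stringent_p <= loose_p`).
#' @param min_ratio higher/lower allele-count ratio must exceed this.
#' @param min_score ASE score must exceed this.
#' @param min_depth total mapped reads must exceed this.
#' @param max_third_frac third-allele fraction must stay below this.
#' @param min_cohort applicable cohort individuals must exceed this.
#' @param min_ase_fraction cohort ASE fraction must reach this.
#' @param ra_alpha significance level of the r=a test.
#' @param yates apply the Yates continuity correction to the allelic
#'   chi-square?
#' @param population_ase `"stringent"` or `"loose"`: which ASE
#'   definition calls the per-individual bias at population scale.
#' @param ped,vcf,gtf,counts,cohort_counts,sex,out_dir optional file
#'   paths consumed by [run_trio_stage()] / [run_population_stage()].
#' @param seed optional seed recorded with the run.
#' @return a `rad_config` list.
#' @export
rad_config <- function(loose_p = 0.05, stringent_p = 1e-3, min_ratio = 2,
                       min_score = 3, min_depth = 10,
                       max_third_frac = 0.10, min_cohort = 10,
                       min_ase_fraction = 0.95, ra_alpha = 0.05,
                       yates = FALSE, population_ase = "stringent",
                       ped = NULL, vcf = NULL, gtf = NULL, counts = NULL,
                       cohort_counts = NULL, sex = NULL, out_dir = NULL,
                       seed = NULL) {
  num <- c(loose_p = loose_p, stringent_p = stringent_p,
           min_ratio = min_ratio, min_score = min_score,
           min_depth = min_depth, max_third_frac = max_third_frac,
           min_cohort = min_cohort, min_ase_fraction = min_ase_fraction,
           ra_alpha = ra_alpha)
  if (any(!is.finite(num)) || any(num < 0)) {
    stop_rad("thresholds must be non-negative finite numbers",
             "radase_config_error")
  }
  if (stringent_p > loose_p) {
    stop_rad("stringent_p must not exceed loose_p", "radase_config_error")
  }
  if (!population_ase %in% c("stringent", "loose")) {
    stop_rad("population_ase must be 'stringent' or 'loose'",
             "radase_config_error")
  }
  structure(list(loose_p = loose_p, stringent_p = stringent_p,
                 min_ratio = min_ratio, min_score = min_score,
                 min_depth = min_depth, max_third_frac = max_third_frac,
                 min_cohort = min_cohort,
                 min_ase_fraction = min_ase_fraction, ra_alpha = ra_alpha,
                 yates = yates, population_ase = population_ase,
                 ped = ped, vcf = vcf, gtf = gtf, counts = counts,
                 cohort_counts = cohort_counts, sex = sex,
                 out_dir = out_dir, seed = seed),
            class = "rad_config")
}

#' @export
print.rad_config <- function(x, ...) {
  cat("radase run configuration\n")
  cat(sprintf("  loose p < %g; stringent p < %g, ratio > %g, score > %g\n",
              x$loose_p, x$stringent_p, x$min_ratio, x$min_score))
  cat(sprintf("  depth > %g reads; third allele < %g%%\n",
              x$min_depth, 100 * x$max_third_frac))
  cat(sprintf("  cohort > %g applicable; ASE fraction >= %g%%; r=a alpha %g\n",
              x$min_cohort, 100 * x$min_ase_fraction, x$ra_alpha))
  invisible(x)
}

require_path <- function(path, what) {
  if (is.null(path)) {
    stop_rad(paste0("configuration lacks a ", what, " path"),
             "radase_config_error")
  }
  if (!file.exists(path)) {
    stop_rad(paste0(what, " file not found: ", path), "radase_config_error")
  }
  path
}

sort_records <- function(df) {
  cols <- intersect(c("chrom", "pos", "individual"), names(df))
  df <- df[do.call(order, df[cols]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

write_stage_tables <- function(tables, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (name in names(tables)) {
    rad_write_tsv(sort_records(tables[[name]]),
                  file.path(out_dir, paste0(name, ".tsv")))
  }
  invisible(NULL)
}

#' Run the trio stage: applicability, ASE calling, categorisation
#'
#' Reads the pedigree, genotypes, annotation and allele counts named in
#' the configuration, applies the applicability criteria per (site,
#' child), calls ASE, categorises the eligible sites and applies the
#' RME-gene exclusion.  Writes `applicability.tsv`, `ase.tsv`,
#' `categories.tsv` and `categories_retained.tsv` plus `trio_report.txt`
#' when `out_dir` is set.
#'
#' @param config a [rad_config()] with `ped`, `vcf`, `gtf` and `counts`
#'   paths set.
#' @return list with `applicability`, `ase`, `categories` (flagged),
#'   `retained` and `report` (named counts for every stage, in which
#'   every dropped record appears in exactly one counter).  When no
#'   site is applicable for any child the tables are empty and
#'   `report$empty` is `TRUE`.
#' @export
run_trio_stage <- function(config = rad_config()) {
  require_path(config$ped, "pedigree")
  require_path(config$vcf, "genotype VCF")
  require_path(config$gtf, "gene annotation")
  require_path(config$counts, "allele counts")
  trios <- read_pedigree(config$ped)
  members <- unique(c(trios$child_id, trios$father_id, trios$mother_id))
  genotypes <- read_genotypes(config$vcf, members)
  genes <- read_gene_annotation(config$gtf)
  counts <- read_allele_counts(config$counts)

  app <- applicability_table(counts, genotypes, trios, genes, config)
  if (nrow(app) == 0) {
    warning("no allele-count records belong to a child of the loaded trios",
            call. = FALSE)
  }
  ase <- ase_table(app, config)
  cats <- classify_sites(ase)
  cats <- rme_gene_exclusion(cats, genes)
  retained <- cats[!cats$excluded_by_rme_gene, , drop = FALSE]

  n_app <- sum(app$applicable %in% TRUE)
  report <- list(
    n_count_records = nrow(counts),
    n_non_child_records = nrow(counts) - nrow(app),
    n_child_records = nrow(app),
    n_unavailable = sum(app$unavailable %in% TRUE),
    n_not_applicable = sum(app$applicable %in% FALSE),
    n_applicable = n_app,
    n_ase_loose = sum(ase$status %in% c("ase_loose", "ase_stringent")),
    n_ase_stringent = sum(ase$status == "ase_stringent"),
    n_sites_lt2_applicable = attr(cats, "n_sites_lt2_applicable"),
    n_sites_not_all_ase = attr(cats, "n_sites_not_all_ase"),
    n_sites_categorised = nrow(cats),
    category_counts = table(factor(cats$category,
                                   levels = CATEGORY_LEVELS[1:4])),
    n_excluded_rme_gene = sum(cats$excluded_by_rme_gene),
    n_sites_retained = nrow(retained),
    empty = n_app == 0)
  if (report$empty) {
    rad_log("no applicable (site, child) records; trio stage result is empty")
  }
  write_stage_tables(list(applicability = app, ase = ase,
                          categories = cats,
                          categories_retained = retained),
                     config$out_dir)
  if (!is.null(config$out_dir)) {
    writeLines(format_trio_report(report),
               file.path(config$out_dir, "trio_report.txt"))
  }
  list(applicability = app, ase = ase, categories = cats,
       retained = retained, report = report)
}

format_trio_report <- function(r) {
  c(sprintf("count records:            %d", r$n_count_records),
    sprintf("  non-child records:      %d", r$n_non_child_records),
    sprintf("  child records:          %d", r$n_child_records),
    sprintf("    genotype unavailable: %d", r$n_unavailable),
    sprintf("    not applicable:       %d", r$n_not_applicable),
    sprintf("    applicable:           %d", r$n_applicable),
    sprintf("ASE sites (loose):        %d", r$n_ase_loose),
    sprintf("ASE sites (stringent):    %d", r$n_ase_stringent),
    sprintf("sites categorised:        %d", r$n_sites_categorised),
    sprintf("  %s", paste(names(r$category_counts),
                          as.integer(r$category_counts),
                          sep = "=", collapse = "  ")),
    sprintf("excluded by RME gene:     %d", r$n_excluded_rme_gene),
    sprintf("sites retained:           %d", r$n_sites_retained))
}

#' Run the population stage: cohort summary and reconciliation
#'
#' Reads the cohort counts, genotypes and sex metadata named in the
#' configuration, summarises population-scale ASE per site and joins
#' the verdicts with the trio-stage categories.  Writes
#' `population.tsv` and `reconciliation.tsv` when `out_dir` is set.
#'
#' @param config a [rad_config()] with `vcf`, `cohort_counts` and
#'   (when chromosome-X sites are present) `sex` paths set.
#' @param categories a trio-stage category table; when `NULL` it is
#'   read from `out_dir/categories.tsv`.
#' @return list with `population`, `reconciliation` and `report`.
#' @export
run_population_stage <- function(config = rad_config(), categories = NULL) {
  require_path(config$vcf, "genotype VCF")
  require_path(config$cohort_counts, "cohort allele counts")
  counts <- read_allele_counts(config$cohort_counts)
  cohort_ids <- unique(counts$individual)
  genotypes <- read_genotypes(config$vcf, cohort_ids)
  sex <- if (!is.null(config$sex)) rad_read_tsv(config$sex) else NULL
  if (is.null(categories)) {
    path <- file.path(config$out_dir %||% ".", "categories.tsv")
    require_path(path, "trio-stage category table")
    categories <- rad_read_tsv(path)
  }
  pop <- summarize_population(counts, genotypes, sex, config)
  rec <- reconcile_with_categories(categories, pop)
  report <- list(
    n_sites = nrow(pop),
    verdict_counts = table(pop$verdict),
    n_discordant = sum(rec$discordant, na.rm = TRUE))
  write_stage_tables(list(population = pop, reconciliation = rec),
                     config$out_dir)
  list(population = pop, reconciliation = rec, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
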