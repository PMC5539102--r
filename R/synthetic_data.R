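## Synthetic trio and cohort generator with recorded ground truth.
##
## Mechanisms: imprinting_paternal / imprinting_maternal (the expressed
## allele follows parental origin), cis_ase_ref / cis_ase_alt (the
## expressed allele follows sequence identity), rme (the expressed
## allele is drawn uniformly per individual, the clonal-LCL picture of
## random monoallelic expression) and biallelic.  Depth follows a
## negative binomial; third-allele reads are added at a configurable
## error rate.  All randomness flows through explicit seeds.

SIM_MECHANISMS <- c("imprinting_paternal", "imprinting_maternal",
                    "cis_ase_ref", "cis_ase_alt", "rme", "biallelic")

ALLELE_PAIRS <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"),
                     c("A", "C"), c("G", "T"), c("C", "A"), c("T", "G"),
                     c("A", "T"), c("C", "G"), c("T", "A"), c("G", "C"))

#' Configuration for a synthetic study
#'
#' The defaults describe the demonstration study: seven trios (the
#' family-panel scale the RAD design targets), a cohort of 100
#' individuals, expressed-allele fraction 0.95, negative-binomial depth
#' with mean 100 (size 25, about 20% coefficient of variation), no
#' third-allele error, and allele frequency 0.5.  RME sites are
#' allocated more generously than the other mechanisms because, with a
#' seven-child panel, the chance that random per-child allele choices
#' reveal the Group-4 signature is the least favourable recovery event,
#' so a larger number of sites is needed for a stable rate estimate.
#'
#' @param n_trios number of parent-offspring trios.
#' @param cohort_size number of population individuals.
#' @param sites named integer vector of site counts per mechanism.
#' @param bias expressed-allele fraction, in `[0.5, 1]`.
#' @param depth_mean,depth_size negative-binomial depth parameters.
#' @param error_rate third-allele read fraction, in `[0, 0.1)`.
#' @param allele_freq alternative-allele frequency, in `(0, 1)`.
#' @param force_informative force every trio to an informative
#'   configuration (child heterozygous, at least one parent homozygous).
#' @param force_rad force reciprocal parental-origin configurations
#'   (alternating paternal-reference / paternal-alternative trios) at
#'   imprinting sites, the RAD analogue of a reciprocal cross.
#' @return a `rad_sim_config` list.
#' @export
sim_config <- function(n_trios = 7, cohort_size = 100,
                       sites = c(imprinting_paternal = 30,
                                 imprinting_maternal = 30,
                                 cis_ase_ref = 30, cis_ase_alt = 30,
                                 rme = 300, biallelic = 30),
                       bias = 0.95, depth_mean = 100, depth_size = 25,
                       error_rate = 0, allele_freq = 0.5,
                       force_informative = TRUE, force_rad = TRUE) {
  if (bias < 0.5 || bias > 1) {
    stop_rad("bias must lie in [0.5, 1]", "radase_config_error")
  }
  if (error_rate < 0 || error_rate >= 0.1) {
    stop_rad("error_rate must lie in [0, 0.1)", "radase_config_error")
  }
  if (allele_freq <= 0 || allele_freq >= 1) {
    stop_rad("allele_freq must lie in (0, 1)", "radase_config_error")
  }
  bad <- setdiff(names(sites), SIM_MECHANISMS)
  if (length(bad) > 0) {
    stop_rad(paste0("unknown mechanism(s): ", paste(bad, collapse = ", ")),
             "radase_config_error")
  }
  structure(list(n_trios = n_trios, cohort_size = cohort_size,
                 sites = sites, bias = bias, depth_mean = depth_mean,
                 depth_size = depth_size, error_rate = error_rate,
                 allele_freq = allele_freq,
                 force_informative = force_informative,
                 force_rad = force_rad),
            class = "rad_sim_config")
}

## Rejection-sample 0/1 allele matrices for n_sites x n_trios cells.
## rad_target: matrix of NA / 0 / 1 forcing the child's paternal allele.
sim_trio_alleles <- function(n_sites, n_trios, freq, informative,
                             rad_target = NULL) {
  ncell <- n_sites * n_trios
  if (is.null(rad_target)) rad_target <- matrix(NA, n_sites, n_trios)
  F1 <- F2 <- M1 <- M2 <- CP <- CM <- matrix(0L, n_sites, n_trios)
  todo <- rep(TRUE, ncell)
  for (iter in seq_len(10000)) {
    k <- sum(todo)
    if (k == 0) break
    f1 <- stats::rbinom(k, 1, freq)
    f2 <- stats::rbinom(k, 1, freq)
    m1 <- stats::rbinom(k, 1, freq)
    m2 <- stats::rbinom(k, 1, freq)
    cp <- ifelse(stats::runif(k) < 0.5, f1, f2)
    cm <- ifelse(stats::runif(k) < 0.5, m1, m2)
    ok <- rep(TRUE, k)
    if (informative) {
      ok <- ok & (cp != cm) & ((f1 == f2) | (m1 == m2))
    }
    tgt <- rad_target[todo]
    ok <- ok & (is.na(tgt) | cp == tgt)
    idx <- which(todo)[ok]
    F1[idx] <- f1[ok]; F2[idx] <- f2[ok]
    M1[idx] <- m1[ok]; M2[idx] <- m2[ok]
    CP[idx] <- cp[ok]; CM[idx] <- cm[ok]
    todo[idx] <- FALSE
  }
  if (any(todo)) {
    stop("internal error: trio genotype rejection sampling did not converge")
  }
  list(F1 = F1, F2 = F2, M1 = M1, M2 = M2, CP = CP, CM = CM)
}

#' Simulate trio genotypes at one biallelic site
#'
#' Parental genotypes are drawn at Hardy-Weinberg proportions for the
#' given alternative-allele frequency; each child allele is drawn from
#' one parent, and the transmission is recorded as the true parental
#' origin.  Optionally every trio is forced to an informative
#' configuration, and reciprocal parental-origin (RAD) configurations
#' are forced by alternating the child's paternal allele between
#' reference and alternative across trios.
#'
#' @param n_trios number of trios.
#' @param allele_freq alternative-allele frequency in `(0, 1)`.
#' @param seed optional RNG seed (deterministic output given a seed).
#' @param force_informative,force_rad see [sim_config()].
#' @param chrom,pos,ref,alt site coordinates and alleles.
#' @return list with `trios` (pedigree table), `genotypes` (long
#'   genotype table for all trio members) and `origins` (per child, the
#'   true paternal and maternal allele).
#' @export
simulate_trio_genotypes <- function(n_trios, allele_freq = 0.5, seed = NULL,
                                    force_informative = FALSE,
                                    force_rad = FALSE, chrom = "1",
                                    pos = 1000L, ref = "A", alt = "G") {
  if (allele_freq <= 0 || allele_freq >= 1) {
    stop_rad("allele_freq must lie in (0, 1)", "radase_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  tgt <- if (force_rad) {
    matrix(rep_len(c(0L, 1L), n_trios), 1, n_trios)
  } else {
    NULL
  }
  al <- sim_trio_alleles(1, n_trios, allele_freq,
                         informative = force_informative || force_rad,
                         rad_target = tgt)
  nuc <- function(x) ifelse(x == 1L, alt, ref)
  id <- function(role) sprintf("%s_%02d", role, seq_len(n_trios))
  trios <- data.frame(
    family = sprintf("F%02d", seq_len(n_trios)),
    child_id = id("child"), father_id = id("father"),
    mother_id = id("mother"),
    child_sex = rep_len(c("female", "male"), n_trios),
    stringsAsFactors = FALSE)
  geno_row <- function(ind, a1, a2) {
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               individual = ind, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  }
  genotypes <- rbind(
    geno_row(trios$child_id, nuc(al$CP[1, ]), nuc(al$CM[1, ])),
    geno_row(trios$father_id, nuc(al$F1[1, ]), nuc(al$F2[1, ])),
    geno_row(trios$mother_id, nuc(al$M1[1, ]), nuc(al$M2[1, ])))
  origins <- data.frame(
    chrom = chrom, pos = pos, child_id = trios$child_id,
    paternal_allele = nuc(al$CP[1, ]), maternal_allele = nuc(al$CM[1, ]),
    stringsAsFactors = FALSE)
  list(trios = trios, genotypes = genotypes, origins = origins)
}

#' Simulate allele read counts for genotyped individuals
#'
#' One count record is produced per input genotype row.  Depth is drawn
#' from a negative binomial (`depth_mean`, `depth_size`); third-allele
#' reads are added at `error_rate`; the remaining reads split
#' binomially with the expressed allele at fraction `bias`.  For
#' heterozygous individuals the expressed allele follows the mechanism;
#' at imprinting sites an individual without a recorded parental origin
#' (a population sample) has its origin drawn uniformly, which is what
#' makes imprinting and RME indistinguishable at population scale.
#' Homozygous individuals express their only allele.
#'
#' @param geno data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `individual`, `allele1`, `allele2` and optionally
#'   `paternal_allele` / `maternal_allele`.
#' @param mechanism one of the mechanisms (recycled over rows):
#'   `r paste(SIM_MECHANISMS, collapse = ", ")`.
#' @param bias expressed-allele fraction in `[0.5, 1]`.
#' @param depth_mean,depth_size negative-binomial depth parameters.
#' @param error_rate third-allele read fraction in `[0, 0.1)`.
#' @param seed optional RNG seed.
#' @return list with `counts` (allele-count records) and `truth`
#'   (per record, the mechanism and the expressed allele).
#' @export
simulate_counts <- function(geno, mechanism = "biallelic", bias = 0.95,
                            depth_mean = 100, depth_size = 25,
                            error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (bias < 0.5 || bias > 1) {
    stop_rad("bias must lie in [0.5, 1]", "radase_config_error")
  }
  n <- nrow(geno)
  mechanism <- rep_len(mechanism, n)
  stopifnot(all(mechanism %in% SIM_MECHANISMS))
  het <- is_het(geno$allele1, geno$allele2)
  pat <- if (!is.null(geno$paternal_allele)) geno$paternal_allele else {
    rep(NA_character_, n)
  }
  mat <- if (!is.null(geno$maternal_allele)) geno$maternal_allele else {
    rep(NA_character_, n)
  }
  ## unknown parental origin at a het site: draw it uniformly
  need_origin <- het & is.na(pat) &
    mechanism %in% c("imprinting_paternal", "imprinting_maternal")
  if (any(need_origin)) {
    flip <- stats::runif(sum(need_origin)) < 0.5
    pat[need_origin] <- ifelse(flip, geno$allele1[need_origin],
                               geno$allele2[need_origin])
    mat[need_origin] <- ifelse(flip, geno$allele2[need_origin],
                               geno$allele1[need_origin])
  }
  expressed <- rep(NA_character_, n)
  expressed[het & mechanism == "imprinting_paternal"] <-
    pat[het & mechanism == "imprinting_paternal"]
  expressed[het & mechanism == "imprinting_maternal"] <-
    mat[het & mechanism == "imprinting_maternal"]
  expressed[het & mechanism == "cis_ase_ref"] <-
    geno$ref[het & mechanism == "cis_ase_ref"]
  expressed[het & mechanism == "cis_ase_alt"] <-
    geno$alt[het & mechanism == "cis_ase_alt"]
  rme_rows <- het & mechanism == "rme"
  if (any(rme_rows)) {
    pick <- stats::runif(sum(rme_rows)) < 0.5
    expressed[rme_rows] <- ifelse(pick, geno$ref[rme_rows],
                                  geno$alt[rme_rows])
  }
  p_ref <- rep(0.5, n)
  is_exp_ref <- !is.na(expressed) & expressed == geno$ref
  is_exp_alt <- !is.na(expressed) & expressed == geno$alt
  p_ref[is_exp_ref] <- bias
  p_ref[is_exp_alt] <- 1 - bias
  hom <- !het & !is.na(geno$allele1)
  p_ref[hom & geno$allele1 == geno$ref] <- 1
  p_ref[hom & geno$allele1 == geno$alt] <- 0
  depth <- stats::rnbinom(n, mu = depth_mean, size = depth_size)
  other <- stats::rbinom(n, depth, error_rate)
  rem <- depth - other
  ref_count <- stats::rbinom(n, rem, p_ref)
  counts <- data.frame(
    chrom = geno$chrom, pos = geno$pos, ref = geno$ref, alt = geno$alt,
    individual = geno$individual, ref_count = ref_count,
    alt_count = rem - ref_count, other_count = other,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    chrom = geno$chrom, pos = geno$pos, individual = geno$individual,
    mechanism = mechanism, expressed_allele = expressed,
    paternal_allele = pat, maternal_allele = mat,
    stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Simulate a population cohort at independent sites
#'
#' Cohort genotypes are drawn at Hardy-Weinberg proportions per site and
#' counts are generated with [simulate_counts()].  Useful on its own for
#' calibration studies of the r=a test (e.g. a pure-imprinting cohort,
#' where the per-individual biased allele is independent of ref/alt).
#'
#' @param n_sites number of independent sites (placed on chromosome 1).
#' @param cohort_size number of individuals.
#' @param mechanism mechanism for every site (or a per-site vector).
#' @inheritParams simulate_counts
#' @param allele_freq alternative-allele frequency.
#' @return list with `sites`, `genotypes`, `counts`, `sex`, `truth`.
#' @export
simulate_population_cohort <- function(n_sites, cohort_size,
                                       mechanism = "imprinting_paternal",
                                       allele_freq = 0.5, bias = 0.95,
                                       depth_mean = 100, depth_size = 25,
                                       error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mechanism <- rep_len(mechanism, n_sites)
  pair <- ALLELE_PAIRS[(seq_len(n_sites) - 1) %% length(ALLELE_PAIRS) + 1]
  sites <- data.frame(
    chrom = "1", pos = 1000L * seq_len(n_sites),
    ref = vapply(pair, `[`, character(1), 1),
    alt = vapply(pair, `[`, character(1), 2),
    mechanism = mechanism, stringsAsFactors = FALSE)
  ids <- sprintf("pop_%04d", seq_len(cohort_size))
  idx <- rep(seq_len(n_sites), each = cohort_size)
  ncell <- n_sites * cohort_size
  a1 <- stats::rbinom(ncell, 1, allele_freq)
  a2 <- stats::rbinom(ncell, 1, allele_freq)
  geno <- data.frame(
    chrom = sites$chrom[idx], pos = sites$pos[idx], ref = sites$ref[idx],
    alt = sites$alt[idx], individual = rep(ids, times = n_sites),
    allele1 = ifelse(a1 == 1, sites$alt[idx], sites$ref[idx]),
    allele2 = ifelse(a2 == 1, sites$alt[idx], sites$ref[idx]),
    stringsAsFactors = FALSE)
  sim <- simulate_counts(geno, mechanism = sites$mechanism[idx],
                         bias = bias, depth_mean = depth_mean,
                         depth_size = depth_size, error_rate = error_rate)
  sex <- data.frame(individual = ids,
                    sex = rep_len(c("female", "male"), cohort_size),
                    stringsAsFactors = FALSE)
  list(sites = sites, genotypes = geno, counts = sim$counts, sex = sex,
       truth = sim$truth)
}

write_sim_vcf <- function(path, sites, geno) {
  ids <- unique(geno$individual)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  if (nrow(sites) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  gt <- matrix("./.", nrow(sites), length(ids))
  si <- match(site_key(geno$chrom, geno$pos, geno$ref, geno$alt),
              site_key(sites$chrom, sites$pos, sites$ref, sites$alt))
  ii <- match(geno$individual, ids)
  c1 <- ifelse(geno$allele1 == geno$alt, 1L, 0L)
  c2 <- ifelse(geno$allele2 == geno$alt, 1L, 0L)
  keep <- !is.na(si) & !is.na(ii) & !is.na(c1) & !is.na(c2)
  gt[cbind(si[keep], ii[keep])] <-
    paste(pmin(c1, c2)[keep], pmax(c1, c2)[keep], sep = "/")
  left <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                ".", "PASS", ".", "GT", sep = "\t")
  body <- paste(left, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

write_sim_gtf <- function(path, genes) {
  if (nrow(genes) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf(
    '%s\tradase_sim\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_name "%s";',
    genes$chrom, genes$start, genes$end, genes$gene_id, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a complete study and write its input bundle
#'
#' Generates trio genotypes, cohort genotypes, allele counts for
#' children and cohort, gene annotation and sex metadata, and writes
#' them in the exact dialects the package readers consume (PED, VCF,
#' GTF, TSV), alongside ground-truth tables.  Genes hold three
#' consecutive sites each and the first gene is laid out to contain
#' both an imprinting-destined and an RME-destined site, so the
#' RME-gene exclusion rule is exercised end-to-end.  At imprinting
#' sites, reciprocal (RAD) trio configurations are forced when the
#' configuration requests them.
#'
#' @param config a [sim_config()] list.
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed (mandatory; the whole bundle is deterministic
#'   given the seed).
#' @return list with the file `paths` and the in-memory objects
#'   (`trios`, `sites`, `genes`, `genotypes`, `counts_children`,
#'   `counts_cohort`, `sex`, `origins`, `truth`).
#' @export
simulate_study <- function(config = sim_config(), out_dir, seed) {
  stopifnot(inherits(config, "rad_sim_config"))
  if (missing(seed) || is.null(seed)) {
    stop_rad("simulate_study requires an explicit seed", "radase_config_error")
  }
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_trios <- config$n_trios
  counts_per_mech <- config$sites[config$sites > 0]
  mechanisms <- rep(names(counts_per_mech), counts_per_mech)
  ## put one imprinting and one rme site first so they share gene 1
  imp_i <- which(grepl("^imprinting", mechanisms))[1]
  rme_i <- which(mechanisms == "rme")[1]
  if (!is.na(imp_i) && !is.na(rme_i)) {
    mechanisms <- c(mechanisms[c(imp_i, rme_i)],
                    mechanisms[-c(imp_i, rme_i)])
  }
  n_sites <- length(mechanisms)

  gene_of <- if (n_sites > 0) (seq_len(n_sites) - 1) %/% 3 + 1 else integer(0)
  chrom_of_gene <- function(g) as.character((g - 1) %% 7 + 1)
  start_of_gene <- function(g) 1000000L * (((g - 1) %/% 7) + 1L)
  within <- if (n_sites > 0) (seq_len(n_sites) - 1) %% 3 else integer(0)
  pair <- ALLELE_PAIRS[(seq_len(n_sites) - 1) %% length(ALLELE_PAIRS) + 1]
  sites <- data.frame(
    chrom = chrom_of_gene(gene_of),
    pos = start_of_gene(gene_of) + 500L + 1000L * within,
    ref = vapply(pair, `[`, character(1), 1),
    alt = vapply(pair, `[`, character(1), 2),
    gene_id = sprintf("SIMG%04d", gene_of),
    mechanism = mechanisms, stringsAsFactors = FALSE)
  genes <- unique(data.frame(
    gene_id = sites$gene_id, chrom = sites$chrom,
    start = start_of_gene(gene_of), end = start_of_gene(gene_of) + 4000L,
    stringsAsFactors = FALSE))

  id <- function(role) sprintf("%s_%02d", role, seq_len(n_trios))
  trios <- data.frame(
    family = sprintf("F%02d", seq_len(n_trios)),
    child_id = id("child"), father_id = id("father"),
    mother_id = id("mother"),
    child_sex = rep_len(c("female", "male"), n_trios),
    stringsAsFactors = FALSE)

  ## trio genotypes, RAD-forced at imprinting sites
  rad_target <- matrix(NA_integer_, n_sites, n_trios)
  if (config$force_rad && n_sites > 0) {
    imp <- grepl("^imprinting", sites$mechanism)
    rad_target[imp, ] <- matrix(rep(rep_len(c(0L, 1L), n_trios),
                                    each = sum(imp)),
                                sum(imp), n_trios)
  }
  al <- if (n_sites > 0) {
    sim_trio_alleles(n_sites, n_trios, config$allele_freq,
                     informative = config$force_informative,
                     rad_target = rad_target)
  } else {
    NULL
  }
  site_idx <- rep(seq_len(n_sites), times = n_trios)
  nuc <- function(m) ifelse(as.vector(m) == 1L, sites$alt[site_idx],
                            sites$ref[site_idx])
  long_geno <- function(ids_by_trio, m1, m2) {
    data.frame(chrom = sites$chrom[site_idx], pos = sites$pos[site_idx],
               ref = sites$ref[site_idx], alt = sites$alt[site_idx],
               individual = rep(ids_by_trio, each = n_sites),
               allele1 = nuc(m1), allele2 = nuc(m2),
               stringsAsFactors = FALSE)
  }
  geno_trio <- if (n_sites > 0) {
    rbind(long_geno(trios$child_id, al$CP, al$CM),
          long_geno(trios$father_id, al$F1, al$F2),
          long_geno(trios$mother_id, al$M1, al$M2))
  } else {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), individual = character(),
               allele1 = character(), allele2 = character(),
               stringsAsFactors = FALSE)
  }
  child_geno <- geno_trio[geno_trio$individual %in% trios$child_id, ,
                          drop = FALSE]
  child_geno$paternal_allele <- nuc(if (n_sites > 0) al$CP else NULL)
  child_geno$maternal_allele <- nuc(if (n_sites > 0) al$CM else NULL)
  origins <- data.frame(
    chrom = child_geno$chrom, pos = child_geno$pos,
    child_id = child_geno$individual,
    paternal_allele = child_geno$paternal_allele,
    maternal_allele = child_geno$maternal_allele,
    stringsAsFactors = FALSE)

  sim_child <- simulate_counts(
    child_geno, mechanism = sites$mechanism[match(
      site_key(child_geno$chrom, child_geno$pos, child_geno$ref,
               child_geno$alt),
      site_key(sites$chrom, sites$pos, sites$ref, sites$alt))],
    bias = config$bias, depth_mean = config$depth_mean,
    depth_size = config$depth_size, error_rate = config$error_rate)

  ## cohort
  cohort_ids <- sprintf("pop_%04d", seq_len(config$cohort_size))
  cidx <- rep(seq_len(n_sites), each = config$cohort_size)
  ncell <- n_sites * config$cohort_size
  ca1 <- stats::rbinom(ncell, 1, config$allele_freq)
  ca2 <- stats::rbinom(ncell, 1, config$allele_freq)
  geno_cohort <- data.frame(
    chrom = sites$chrom[cidx], pos = sites$pos[cidx],
    ref = sites$ref[cidx], alt = sites$alt[cidx],
    individual = rep(cohort_ids, times = n_sites),
    allele1 = ifelse(ca1 == 1, sites$alt[cidx], sites$ref[cidx]),
    allele2 = ifelse(ca2 == 1, sites$alt[cidx], sites$ref[cidx]),
    stringsAsFactors = FALSE)
  sim_cohort <- simulate_counts(
    geno_cohort, mechanism = sites$mechanism[cidx],
    bias = config$bias, depth_mean = config$depth_mean,
    depth_size = config$depth_size, error_rate = config$error_rate)

  sex <- data.frame(
    individual = c(trios$child_id, trios$father_id, trios$mother_id,
                   cohort_ids),
    sex = c(trios$child_sex, rep("male", n_trios), rep("female", n_trios),
            rep_len(c("female", "male"), config$cohort_size)),
    stringsAsFactors = FALSE)

  paths <- list(
    ped = file.path(out_dir, "trios.ped"),
    vcf = file.path(out_dir, "genotypes.vcf"),
    gtf = file.path(out_dir, "genes.gtf"),
    counts_children = file.path(out_dir, "counts_children.tsv"),
    counts_cohort = file.path(out_dir, "counts_cohort.tsv"),
    sex = file.path(out_dir, "sex.tsv"),
    truth_sites = file.path(out_dir, "truth_sites.tsv"),
    truth_origins = file.path(out_dir, "truth_origins.tsv"))
  ped_lines <- sprintf("%s %s %s %s %s", trios$family, trios$child_id,
                       trios$father_id, trios$mother_id,
                       ifelse(trios$child_sex == "female", "2", "1"))
  founders <- c(sprintf("%s %s 0 0 1", trios$family, trios$father_id),
                sprintf("%s %s 0 0 2", trios$family, trios$mother_id))
  writeLines(c(ped_lines, founders), paths$ped)
  write_sim_vcf(paths$vcf, sites, rbind(geno_trio, geno_cohort))
  write_sim_gtf(paths$gtf, genes)
  rad_write_tsv(sim_child$counts, paths$counts_children)
  rad_write_tsv(sim_cohort$counts, paths$counts_cohort)
  rad_write_tsv(sex, paths$sex)
  rad_write_tsv(sites, paths$truth_sites)
  rad_write_tsv(origins, paths$truth_origins)

  list(paths = paths, config = config, trios = trios, sites = sites,
       genes = genes, genotypes = rbind(geno_trio, geno_cohort),
       counts_children = sim_child$counts,
       counts_cohort = sim_cohort$counts, sex = sex, origins = origins,
       truth = rbind(sim_child$truth, sim_cohort$truth))
}
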