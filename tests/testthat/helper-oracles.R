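## Independent oracles and in-code fixtures shared by the test files.

## Survival function of the 1-df chi-square distribution via the
## complementary error function (closed form, independent of pchisq).
chisq_sf_oracle <- function(x) {
  pracma::erfc(sqrt(x / 2))
}

## Same quantity by numerical integration of the density, used to
## corroborate the erfc route on a few points.
chisq_sf_integrate <- function(x) {
  vapply(x, function(xi) {
    stats::integrate(function(t) exp(-t / 2) / sqrt(2 * pi * t),
                     xi, Inf, rel.tol = 1e-12)$value
  }, numeric(1))
}

## Brute-force subset classifier: tests containment of the defining
## pairs for Group 4, Group 1 and Group 3, in that order.
oracle_category <- function(labels) {
  has_pair <- function(a, b) {
    if (a == b) sum(labels == a) >= 2 else all(c(a, b) %in% labels)
  }
  g4 <- has_pair("P_r", "M_a") || has_pair("P_a", "M_r")
  g1 <- has_pair("P_r", "P_a") || has_pair("M_r", "M_a")
  g3 <- has_pair("P_r", "M_r") || has_pair("P_a", "M_a")
  if (g4) return("C2-2")
  if (g1 && g3) stop("oracle reached G1+G3 without G4")
  if (g1) return("C1-1")
  if (g3) return("C2-1")
  "C1-2"
}

## Brute-force origin oracle: enumerate the four parental transmission
## combinations and collect the assignments consistent with the child.
oracle_origin <- function(child, father, mother) {
  assignments <- list()
  for (fa in father) {
    for (ma in mother) {
      if (identical(sort(c(fa, ma)), sort(child))) {
        assignments[[paste(fa, ma)]] <- c(paternal = fa, maternal = ma)
      }
    }
  }
  assignments <- unique(assignments)
  if (length(assignments) == 0) return(list(consistent = FALSE))
  if (length(assignments) == 1) {
    list(consistent = TRUE, determinable = TRUE,
         paternal = assignments[[1]][["paternal"]],
         maternal = assignments[[1]][["maternal"]])
  } else {
    list(consistent = TRUE, determinable = FALSE)
  }
}

## Random mpileup base-string generator with known expected counts.
gen_pileup_string <- function(n_events, ref = "A") {
  nucs <- setdiff(c("A", "C", "G", "T"), ref)
  s <- character(0)
  expect <- list(ref = 0L, bases = c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L),
                 indels = 0L, dels = 0L)
  for (i in seq_len(n_events)) {
    if (stats::runif(1) < 0.3) s <- c(s, "^", sample(letters, 1))
    kind <- sample(c("ref", "base", "del"), 1, prob = c(0.5, 0.4, 0.1))
    if (kind == "ref") {
      s <- c(s, sample(c(".", ","), 1))
      expect$ref <- expect$ref + 1L
    } else if (kind == "base") {
      b <- sample(nucs, 1)
      s <- c(s, sample(c(b, tolower(b)), 1))
      expect$bases[b] <- expect$bases[b] + 1L
    } else {
      s <- c(s, "*")
      expect$dels <- expect$dels + 1L
    }
    if (stats::runif(1) < 0.2) {
      len <- sample(1:3, 1)
      run <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      s <- c(s, sample(c("+", "-"), 1), as.character(len), run)
      expect$indels <- expect$indels + 1L
    }
    if (stats::runif(1) < 0.2) s <- c(s, "$")
  }
  list(string = paste(s, collapse = ""), expect = expect)
}

## One-site cohort builder for population-stage tests.
make_cohort <- function(n, site = list(chrom = "1", pos = 100L,
                                       ref = "A", alt = "G"),
                        het = rep(TRUE, n),
                        ref_count = rep(50L, n), alt_count = rep(1L, n),
                        other_count = rep(0L, n)) {
  ids <- sprintf("ind_%03d", seq_len(n))
  geno <- data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref,
                     alt = site$alt, individual = ids,
                     allele1 = site$ref,
                     allele2 = ifelse(het, site$alt, site$ref),
                     stringsAsFactors = FALSE)
  counts <- data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref,
                       alt = site$alt, individual = ids,
                       ref_count = ref_count, alt_count = alt_count,
                       other_count = other_count, stringsAsFactors = FALSE)
  list(geno = geno, counts = counts, ids = ids)
}

## Minimal in-code file fixtures -------------------------------------------

write_test_vcf <- function(path, records,
                           samples = c("NA19240", "NA12878")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

write_test_gtf <- function(path, lines) {
  writeLines(lines, path)
  path
}

gtf_gene <- function(chrom, start, end, gene_id) {
  sprintf('%s\ttest\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s";',
          chrom, start, end, gene_id)
}

## One shared full-scale demonstration run (simulate + trio + population),
## computed lazily once per test session.
.demo_cache <- new.env(parent = emptyenv())

get_demo_run <- function(seed = 1) {
  if (is.null(.demo_cache$run)) {
    dir <- tempfile("radase-demo-")
    sim <- simulate_study(sim_config(), dir, seed = seed)
    cfg <- rad_config(ped = sim$paths$ped, vcf = sim$paths$vcf,
                      gtf = sim$paths$gtf,
                      counts = sim$paths$counts_children,
                      cohort_counts = sim$paths$counts_cohort,
                      sex = sim$paths$sex,
                      out_dir = file.path(dir, "out"))
    trio <- suppressMessages(run_trio_stage(cfg))
    pop <- suppressMessages(run_population_stage(cfg,
                                                 categories = trio$categories))
    .demo_cache$run <- list(dir = dir, sim = sim, cfg = cfg, trio = trio,
                            pop = pop)
  }
  .demo_cache$run
}

df_key <- function(df) site_key(df$chrom, df$pos, df$ref, df$alt)
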