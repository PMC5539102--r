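test_that("simulated trios are deterministic, Mendelian and Hardy-Weinberg", {
  a <- simulate_trio_genotypes(50, seed = 3, force_informative = TRUE)
  b <- simulate_trio_genotypes(50, seed = 3, force_informative = TRUE)
  expect_identical(a, b)

  ## every child allele traces to the stated parent
  g <- a$genotypes
  for (i in seq_len(nrow(a$trios))) {
    tr <- a$trios[i, ]
    gt <- function(id) unlist(g[g$individual == id, c("allele1", "allele2")])
    org <- a$origins[a$origins$child_id == tr$child_id, ]
    expect_true(org$paternal_allele %in% gt(tr$father_id))
    expect_true(org$maternal_allele %in% gt(tr$mother_id))
    expect_setequal(gt(tr$child_id),
                    c(org$paternal_allele, org$maternal_allele))
  }

  ## unforced children are heterozygous at about the 2pq rate
  big <- simulate_trio_genotypes(10000, allele_freq = 0.5, seed = 4)
  ch <- big$genotypes[big$genotypes$individual %in% big$trios$child_id, ]
  expect_equal(mean(ch$allele1 != ch$allele2), 0.5, tolerance = 0.02)
})

test_that("forced RAD configurations alternate the paternal allele", {
  a <- simulate_trio_genotypes(2, seed = 8, force_rad = TRUE,
                               ref = "A", alt = "G")
  expect_equal(a$origins$paternal_allele, c("A", "G"))
  ## and remain informative
  g <- a$genotypes
  for (i in 1:2) {
    tr <- a$trios[i, ]
    gt <- function(id) unlist(g[g$individual == id, c("allele1", "allele2")])
    expect_true(gt(tr$child_id)[1] != gt(tr$child_id)[2])
    expect_true(gt(tr$father_id)[1] == gt(tr$father_id)[2] ||
                  gt(tr$mother_id)[1] == gt(tr$mother_id)[2])
  }
})

test_that("count simulation respects mechanism, bias and depth", {
  geno <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
                     individual = "c", allele1 = "A", allele2 = "G",
                     paternal_allele = "A", maternal_allele = "G",
                     stringsAsFactors = FALSE)
  ## complete paternal silencing of the maternal allele
  sim <- simulate_counts(geno, "imprinting_paternal", bias = 1,
                         depth_mean = 100, error_rate = 0, seed = 1)
  expect_equal(sim$counts$alt_count, 0L)
  expect_equal(sim$counts$other_count, 0L)
  expect_equal(sim$truth$expressed_allele, "A")

  ## biallelic at great depth is near 50:50
  deep <- simulate_counts(geno, "biallelic", depth_mean = 10000,
                          depth_size = 1e9, seed = 2)
  frac <- deep$counts$ref_count /
    (deep$counts$ref_count + deep$counts$alt_count)
  expect_equal(frac, 0.5, tolerance = 0.03)

  ## third-allele reads appear at roughly the error rate
  err <- simulate_counts(geno[rep(1, 500), ], "biallelic",
                         depth_mean = 100, error_rate = 0.05, seed = 3)
  tot <- with(err$counts, ref_count + alt_count + other_count)
  expect_lt(abs(sum(err$counts$other_count) / sum(tot) - 0.05), 0.005)

  expect_error(simulate_counts(geno, "biallelic", bias = 0.3),
               class = "radase_config_error")
})

test_that("a simulated study bundle is complete, consistent and re-readable", {
  cfg <- sim_config(n_trios = 4, cohort_size = 12,
                    sites = c(imprinting_paternal = 3, rme = 3,
                              cis_ase_ref = 2, biallelic = 1))
  dir <- tempfile()
  sim <- simulate_study(cfg, dir, seed = 99)
  expect_true(all(file.exists(unlist(sim$paths))))

  ## truth covers every requested site
  expect_equal(nrow(sim$sites), 9)
  tab <- table(sim$sites$mechanism)
  expect_equal(as.integer(tab[c("imprinting_paternal", "rme",
                                "cis_ase_ref", "biallelic")]),
               c(3L, 3L, 2L, 1L))

  ## the first gene holds both an imprinting and an RME site
  g1 <- sim$sites$gene_id[1]
  mech_g1 <- sim$sites$mechanism[sim$sites$gene_id == g1]
  expect_true(any(grepl("imprinting", mech_g1)) && any(mech_g1 == "rme"))

  ## files re-read through the package readers
  trios <- read_pedigree(sim$paths$ped)
  expect_equal(nrow(trios), 4)
  g <- read_genotypes(sim$paths$vcf)
  expect_equal(attr(g, "n_dropped"), 0)
  genes <- read_gene_annotation(sim$paths$gtf)
  expect_true(all(site_in_gene(genes, sim$sites$chrom, sim$sites$pos)))
  cnt <- read_allele_counts(sim$paths$counts_children)
  expect_equal(nrow(cnt), 9 * 4)

  ## re-read genotypes agree with the in-memory truth
  key <- paste(df_key(g), g$individual)
  mem <- sim$genotypes
  m <- match(paste(df_key(mem), mem$individual), key)
  expect_false(anyNA(m))
  expect_equal(paste(pmin(g$allele1, g$allele2)[m],
                     pmax(g$allele1, g$allele2)[m]),
               paste(pmin(mem$allele1, mem$allele2),
                     pmax(mem$allele1, mem$allele2)))

  ## Mendelian consistency of every emitted trio genotype
  app <- applicability_table(cnt, g, trios, genes)
  expect_false(any(grepl("mendelian_inconsistent", app$failed_criteria)))

  ## seeds make the bundle reproducible
  sim2 <- simulate_study(cfg, tempfile(), seed = 99)
  expect_equal(sim2$counts_children, sim$counts_children)
  expect_equal(sim2$genotypes, sim$genotypes)
  expect_error(simulate_study(cfg, tempfile()), "seed")
})

test_that("an empty study request still writes valid files", {
  cfg <- sim_config(n_trios = 2, cohort_size = 3,
                    sites = c(imprinting_paternal = 0, rme = 0))
  sim <- simulate_study(cfg, tempfile(), seed = 1)
  expect_true(all(file.exists(unlist(sim$paths))))
  expect_equal(nrow(sim$sites), 0)
  expect_equal(nrow(read_pedigree(sim$paths$ped)), 2)
  expect_equal(nrow(read_allele_counts(sim$paths$counts_children)), 0)
})

test_that("generator rejects out-of-range parameters", {
  expect_error(sim_config(bias = 0.4), class = "radase_config_error")
  expect_error(sim_config(error_rate = 0.2), class = "radase_config_error")
  expect_error(sim_config(allele_freq = 0), class = "radase_config_error")
  expect_error(sim_config(sites = c(nonsense = 5)),
               class = "radase_config_error")
})
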