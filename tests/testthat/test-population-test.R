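test_that("r=a test matches the survival oracle and is symmetric", {
  t1 <- r_equals_a_test(24, 26)
  expect_equal(t1$chi2, 0.08)
  expect_equal(t1$p, chisq_sf_oracle(0.08), tolerance = 1e-10)
  expect_equal(t1$verdict, "r_eq_a")

  t2 <- r_equals_a_test(45, 5)
  expect_equal(t2$chi2, 32)
  expect_equal(t2$p, 1.54e-8, tolerance = 1e-2)
  expect_equal(t2$verdict, "r_ne_a")

  t3 <- r_equals_a_test(25, 25)
  expect_equal(t3$chi2, 0)
  expect_equal(t3$p, 1)
  expect_equal(t3$verdict, "r_eq_a")

  sw <- r_equals_a_test(5, 45)
  expect_equal(sw$chi2, t2$chi2)
  expect_equal(sw$p, t2$p)
  expect_error(r_equals_a_test(0, 0), "undefined")
})

test_that("population summary applies cohort-size and ASE-fraction gates", {
  ## exactly 10 applicable heterozygotes: strictly more than 10 required
  ch <- make_cohort(10)
  pop <- summarize_population(ch$counts, ch$geno)
  expect_equal(pop$n_applicable, 10L)
  expect_equal(pop$verdict, "not_enough_individuals")

  ## 100 applicable, 96 monoallelic: 0.96 >= 0.95 proceeds to the test
  ch <- make_cohort(100, ref_count = c(rep(50L, 96), rep(25L, 4)),
                    alt_count = c(rep(1L, 96), rep(25L, 4)))
  pop <- summarize_population(ch$counts, ch$geno)
  expect_equal(pop$n_applicable, 100L)
  expect_equal(pop$ase_fraction, 0.96)
  expect_equal(pop$biallelic_percent, 4)
  expect_equal(pop$verdict, "r_ne_a")       # every ASE call is ref-biased

  ## 100 applicable, 90 monoallelic: below the 95% fraction
  ch <- make_cohort(100, ref_count = c(rep(50L, 90), rep(25L, 10)),
                    alt_count = c(rep(1L, 90), rep(25L, 10)))
  pop <- summarize_population(ch$counts, ch$geno)
  expect_equal(pop$verdict, "below_ase_fraction")

  ## tallies are consistent by construction
  expect_equal(pop$n_ref_biased + pop$n_alt_biased + pop$n_biallelic,
               pop$n_applicable)
  expect_equal(pop$ase_fraction + pop$biallelic_percent / 100, 1)
})

test_that("chromosome-X sites use female individuals only", {
  ch <- make_cohort(52, site = list(chrom = "chrX", pos = 500L,
                                    ref = "A", alt = "G"))
  sex <- data.frame(individual = ch$ids,
                    sex = c(rep("female", 12), rep("male", 40)),
                    stringsAsFactors = FALSE)
  pop <- summarize_population(ch$counts, ch$geno, sex)
  expect_equal(pop$n_applicable, 12L)
  expect_equal(pop$verdict, "r_ne_a")
  expect_error(summarize_population(ch$counts, ch$geno, sex = NULL),
               "sex metadata")
})

test_that("homozygous, shallow and third-allele-heavy individuals are screened out", {
  ch <- make_cohort(40, het = c(rep(TRUE, 30), rep(FALSE, 10)),
                    ref_count = c(rep(50L, 28), 6L, 45L, rep(50L, 10)),
                    alt_count = c(rep(1L, 28), 4L, 45L, rep(0L, 10)),
                    other_count = c(rep(0L, 28), 0L, 10L, rep(0L, 10)))
  pop <- summarize_population(ch$counts, ch$geno)
  ## 30 het minus one low-depth minus one with a 10% third allele
  expect_equal(pop$n_applicable, 28L)
})

test_that("r!=a power grows with cohort size for a cis-regulated site", {
  rates <- vapply(c(20, 50, 100), function(n) {
    sim <- simulate_population_cohort(60, n, "cis_ase_ref", seed = 100 + n)
    pop <- summarize_population(sim$counts, sim$genotypes, sim$sex)
    mean(pop$verdict == "r_ne_a")
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})

test_that("an RME site splits biased individuals evenly between alleles", {
  sim <- simulate_population_cohort(1, 200, "rme", seed = 9)
  pop <- summarize_population(sim$counts, sim$genotypes, sim$sex)
  n_ase <- pop$n_ref_biased + pop$n_alt_biased
  expect_gt(n_ase, 50)
  expect_lt(abs(pop$n_ref_biased - pop$n_alt_biased), 4 * sqrt(n_ase / 4))
})

test_that("reconciliation joins categories with verdicts and flags discord", {
  cats <- data.frame(
    chrom = c("6", "X", "15", "2", "3"), pos = c(1L, 2L, 3L, 4L, 5L),
    ref = "A", alt = "G", n_applicable = 2L,
    labels = c("P_a,P_r", "M_r,P_a,P_a", "P_r,P_r", "P_r,M_r", "M_r,M_a"),
    groups_present = "G1",
    category = c("C1-1", "C2-2", "C1-2", "C2-1", "C1-1"),
    stringsAsFactors = FALSE)
  pops <- data.frame(
    chrom = c("6", "X", "15", "2", "9"), pos = c(1L, 2L, 3L, 4L, 9L),
    ref = "A", alt = "G", n_applicable = 50L, n_ref_biased = 25L,
    n_alt_biased = 24L, n_biallelic = 1L, ase_fraction = 0.98,
    biallelic_percent = 2, chi2_ra = 0.02, p_ra = 0.88,
    verdict = c("r_eq_a", "r_eq_a", "r_ne_a", "r_ne_a", "r_eq_a"),
    stringsAsFactors = FALSE)
  rec <- reconcile_with_categories(cats, pops)
  get <- function(chrom) rec[rec$chrom == chrom, ]
  expect_equal(get("6")$interpretation, "paternal expression (imprinting)")
  expect_equal(get("X")$interpretation, "RME")
  expect_equal(get("15")$interpretation, "genetic-variation-dependent")
  expect_equal(get("2")$interpretation, "genetic-variation-dependent")
  expect_false(get("6")$discordant)
  ## a site missing on one side stays, with explicit NA
  expect_true(is.na(get("3")$verdict))
  expect_true(is.na(get("9")$category))
  ## C1-1 with r_ne_a would be discordant
  pops2 <- pops
  pops2$verdict[1] <- "r_ne_a"
  expect_true(reconcile_with_categories(cats, pops2)$discordant[
    reconcile_with_categories(cats, pops2)$chrom == "6"])
})
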