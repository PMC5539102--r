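test_that("parent-of-origin inference covers the canonical configurations", {
  o <- infer_origin(c("A", "G"), c("A", "A"), c("G", "G"))
  expect_true(o$determinable)
  expect_equal(o$paternal_allele, "A")
  expect_equal(o$maternal_allele, "G")

  ## G cannot come from the homozygous-A father
  o <- infer_origin(c("A", "G"), c("A", "A"), c("A", "G"))
  expect_true(o$determinable)
  expect_equal(o$paternal_allele, "A")
  expect_equal(o$maternal_allele, "G")

  o <- infer_origin(c("A", "G"), c("A", "G"), c("A", "G"))
  expect_false(o$determinable)

  expect_error(infer_origin(c("A", "G"), c("A", "A"), c("A", "A")),
               class = "radase_mendelian_error")
})

test_that("origin inference agrees with the exhaustive transmission oracle", {
  gts <- list(c("A", "A"), c("A", "G"), c("G", "G"))
  for (f in gts) for (m in gts) {
    oracle <- oracle_origin(c("A", "G"), f, m)
    if (!oracle$consistent) {
      expect_error(infer_origin(c("A", "G"), f, m),
                   class = "radase_mendelian_error")
    } else {
      got <- infer_origin(c("A", "G"), f, m)
      expect_equal(got$determinable, oracle$determinable)
      if (oracle$determinable) {
        expect_equal(got$paternal_allele, unname(oracle$paternal))
        expect_equal(got$maternal_allele, unname(oracle$maternal))
      }
    }
  }
})

test_that("applicability verdicts list every violated criterion", {
  het <- c("A", "G")
  homA <- c("A", "A")
  v <- check_applicability(30, 10, 0, het, homA, c("G", "G"))
  expect_true(v$applicable)
  expect_length(v$failed_criteria, 0)
  expect_equal(v$paternal_allele, "A")

  ## depth strictly greater than 10: exactly 10 fails, 11 passes
  v <- check_applicability(6, 4, 0, het, homA, c("G", "G"))
  expect_false(v$applicable)
  expect_true("low_depth" %in% v$failed_criteria)
  v <- check_applicability(7, 4, 0, het, homA, c("G", "G"))
  expect_true(v$applicable)

  ## third allele strictly below 10%: exactly 10% fails
  v <- check_applicability(45, 45, 10, het, homA, c("G", "G"))
  expect_false(v$applicable)
  expect_equal(v$failed_criteria, "third_allele_excess")

  ## both parents heterozygous
  v <- check_applicability(30, 10, 0, het, het, het)
  expect_equal(v$failed_criteria, "no_homozygous_parent")

  ## intergenic, homozygous child
  v <- check_applicability(30, 10, 0, homA, homA, homA, genic = FALSE)
  expect_true(all(c("not_heterozygous", "not_genic") %in% v$failed_criteria))

  ## dimorphic-pattern mismatch against another heterozygous child
  v <- check_applicability(30, 10, 0, het, homA, c("G", "G"),
                           het_pairs_at_site = c("A/G", "A/C"))
  expect_equal(v$failed_criteria, "pattern_mismatch")

  ## missing parental genotype: no verdict, site unavailable
  v <- check_applicability(30, 10, 0, het, c(NA, NA), c("G", "G"))
  expect_true(v$unavailable)
  expect_true(is.na(v$applicable))
})

test_that("applicability is monotone in depth at fixed proportions", {
  het <- c("A", "G")
  homA <- c("A", "A")
  homG <- c("G", "G")
  prev_low <- TRUE
  for (mult in 1:30) {
    v <- check_applicability(2 * mult, 1 * mult, 0, het, homA, homG)
    low <- "low_depth" %in% v$failed_criteria
    expect_true(!low || prev_low)     # once depth passes it never fails again
    prev_low <- low
  }
})

test_that("applicability ignores the direction of the allele counts", {
  het <- c("A", "G")
  cfgs <- list(c(40, 2, 0), c(2, 40, 0), c(5, 5, 1), c(100, 0, 9))
  for (x in cfgs) {
    a <- check_applicability(x[1], x[2], x[3], het, c("A", "A"), c("G", "G"))
    b <- check_applicability(x[2], x[1], x[3], het, c("A", "A"), c("G", "G"))
    expect_equal(a$applicable, b$applicable)
    expect_equal(sort(a$failed_criteria), sort(b$failed_criteria))
  }
})

test_that("the vectorised applicability table matches the per-record check", {
  ## one trio, all 9 ordered parental genotype pairs for a het child
  gts <- list(c("A", "A"), c("A", "G"), c("G", "G"))
  trios <- data.frame(family = "F1", child_id = "c", father_id = "f",
                      mother_id = "m", child_sex = "female",
                      stringsAsFactors = FALSE)
  i <- 0
  for (fg in gts) for (mg in gts) {
    i <- i + 1
    geno <- data.frame(
      chrom = "1", pos = 100L * i, ref = "A", alt = "G",
      individual = c("c", "f", "m"),
      allele1 = c("A", fg[1], mg[1]), allele2 = c("G", fg[2], mg[2]),
      stringsAsFactors = FALSE)
    counts <- data.frame(chrom = "1", pos = 100L * i, ref = "A", alt = "G",
                         individual = "c", ref_count = 30L, alt_count = 10L,
                         other_count = 0L, stringsAsFactors = FALSE)
    tab <- applicability_table(counts, geno, trios, genes = NULL)
    oracle <- oracle_origin(c("A", "G"), fg, mg)
    if (!oracle$consistent) {
      expect_match(tab$failed_criteria, "mendelian_inconsistent")
    } else if (oracle$determinable) {
      expect_equal(tab$paternal_allele, unname(oracle$paternal))
      expect_equal(tab$maternal_allele, unname(oracle$maternal))
      expect_true(tab$determinable)
    } else {
      expect_false(tab$determinable)
      expect_match(tab$failed_criteria, "no_homozygous_parent")
    }
  }
})

test_that("pattern mismatch is detected across children of different trios", {
  trios <- data.frame(family = c("F1", "F2"),
                      child_id = c("c1", "c2"), father_id = c("f1", "f2"),
                      mother_id = c("m1", "m2"),
                      child_sex = "female", stringsAsFactors = FALSE)
  geno <- data.frame(
    chrom = "1", pos = 100L, ref = "A", alt = "G",
    individual = c("c1", "f1", "m1", "c2", "f2", "m2"),
    allele1 = c("A", "A", "G", "A", "A", "C"),
    allele2 = c("G", "A", "G", "C", "A", "C"),
    stringsAsFactors = FALSE)
  counts <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                       individual = c("c1", "c2"), ref_count = 30L,
                       alt_count = 10L, other_count = 0L,
                       stringsAsFactors = FALSE)
  tab <- applicability_table(counts, geno, trios, genes = NULL)
  expect_true(all(grepl("pattern_mismatch", tab$failed_criteria)))
})
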