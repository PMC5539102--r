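## Per-(site, individual) ASE calling: chi-square against a balanced
## 50:50 expectation, the ratio / ASE-score gates, and the P/M x r/a
## pattern label.

#' Chi-square test of allelic balance
#'
#' One-degree-of-freedom goodness-of-fit of the two allele counts
#' against an expected 50:50 split: `chi2 = (ref - alt)^2 / n`.  No
#' continuity correction is applied unless `correct = TRUE` (Yates).
#' Vectorised over count pairs.
#'
#' @param ref_count,alt_count non-negative read counts; each pair must
#'   sum to at least 1.
#' @param correct apply the Yates continuity correction?
#' @return list with numeric vectors `chi2` and `p`.
#' @export
#' @examples
#' allelic_chi_square(30, 10)
allelic_chi_square <- function(ref_count, alt_count, correct = FALSE) {
  n <- ref_count + alt_count
  if (any(n < 1)) {
    stop_rad("allelic chi-square undefined when both counts are zero",
             "radase_validation_error")
  }
  d <- abs(ref_count - alt_count)
  if (correct) d <- pmax(d - 1, 0)
  chi2 <- d^2 / n
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Call allele-specific expression for count records
#'
#' Applies the chi-square test and the two calling thresholds: a site is
#' `ase_stringent` when `p < stringent_p`, the higher/lower allele ratio
#' exceeds `min_ratio` and the ASE score (`-log10 p`) exceeds
#' `min_score`; `ase_loose` when `p < loose_p` but not stringent;
#' otherwise `biallelic`.  A zero lower count gives an infinite ratio,
#' which passes the ratio gate (complete monoallelic expression).
#' Third-allele reads must already be excluded from the two counts.
#' Vectorised.
#'
#' @inheritParams allelic_chi_square
#' @param config thresholds, see [rad_config()].
#' @return data.frame with `chi2`, `p`, `ase_score`, `ratio`, `status`
#'   and `biased_allele` (`"ref"`, `"alt"` or `"none"`).
#' @export
#' @examples
#' call_ase(c(40, 10), c(10, 10))
call_ase <- function(ref_count, alt_count, config = rad_config()) {
  ts <- allelic_chi_square(ref_count, alt_count, correct = config$yates)
  score <- -log10(ts$p)
  hi <- pmax(ref_count, alt_count)
  lo <- pmin(ref_count, alt_count)
  ratio <- ifelse(lo == 0, Inf, hi / lo)
  stringent <- ts$p < config$stringent_p & ratio > config$min_ratio &
    score > config$min_score
  loose <- !stringent & ts$p < config$loose_p
  status <- ifelse(stringent, "ase_stringent",
                   ifelse(loose, "ase_loose", "biallelic"))
  biased <- ifelse(ref_count > alt_count, "ref",
                   ifelse(alt_count > ref_count, "alt", "none"))
  data.frame(chi2 = ts$chi2, p = ts$p, ase_score = score, ratio = ratio,
             status = status, biased_allele = biased,
             stringsAsFactors = FALSE)
}

pattern_label <- function(biased_allele, ref, alt, paternal_allele) {
  nuc <- ifelse(biased_allele == "ref", ref, alt)
  parent <- ifelse(nuc == paternal_allele, "P", "M")
  ra <- ifelse(biased_allele == "ref", "r", "a")
  paste(parent, ra, sep = "_")
}

#' Attach the P/M x r/a pattern label to a stringent ASE call
#'
#' The label's first character records the parental origin of the
#' biased allele (`P` paternal, `M` maternal); the subscript records its
#' reference/alternative identity.  Labelling is refused for biallelic
#' or loose calls and for sites whose parental origin is not
#' determinable.
#'
#' @param call a one-row result of [call_ase()].
#' @param origin an origin assignment from [infer_origin()].
#' @param ref,alt the site's reference and alternative nucleotides.
#' @return one of `"P_r"`, `"P_a"`, `"M_r"`, `"M_a"`.
#' @export
label_site <- function(call, origin, ref, alt) {
  if (call$status != "ase_stringent") {
    stop_rad("pattern labels are only defined for stringent ASE calls",
             "radase_validation_error")
  }
  if (!isTRUE(origin$determinable)) {
    stop_rad("pattern labels require a determinable parental origin",
             "radase_validation_error")
  }
  pattern_label(call$biased_allele, ref, alt, origin$paternal_allele)
}

#' Build the per-(site, child) ASE table from an applicability table
#'
#' Runs [call_ase()] on every applicable record (third-allele reads are
#' excluded from the test denominator) and labels the stringent calls of
#' origin-determinable children.
#'
#' @param app an applicability table from [applicability_table()].
#' @param config thresholds, see [rad_config()].
#' @return `app` restricted to applicable records, augmented with the
#'   [call_ase()] columns and `label` (`NA` where not labellable).
#' @export
ase_table <- function(app, config = rad_config()) {
  ok <- !is.na(app$applicable) & app$applicable
  a <- app[ok, , drop = FALSE]
  if (nrow(a) == 0) {
    return(cbind(a, data.frame(chi2 = numeric(), p = numeric(),
                               ase_score = numeric(), ratio = numeric(),
                               status = character(),
                               biased_allele = character(),
                               label = character(),
                               stringsAsFactors = FALSE)))
  }
  calls <- call_ase(a$ref_count, a$alt_count, config)
  out <- cbind(a, calls)
  labellable <- out$status == "ase_stringent" & !is.na(out$determinable) &
    out$determinable
  out$label <- NA_character_
  out$label[labellable] <- pattern_label(
    out$biased_allele[labellable], out$ref[labellable], out$alt[labellable],
    out$paternal_allele[labellable])
  rownames(out) <- NULL
  out
}
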