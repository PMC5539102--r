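#' @keywords internal
"_PACKAGE"

NUCLEOTIDES <- c("A", "C", "G", "T")
PATTERN_LABELS <- c("P_r", "P_a", "M_r", "M_a")
CATEGORY_LEVELS <- c("C1-1", "C1-2", "C2-1", "C2-2", "unclassifiable")

#' Normalise chromosome names
#'
#' Strips a leading `chr`/`Chr` prefix and upper-cases the sex-chromosome
#' and mitochondrial names so that `"chrX"`, `"ChrX"` and `"X"` compare
#' equal.  Pseudoautosomal regions are not special-cased.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalised names.
#' @export
#' @examples
#' norm_chrom(c("chr6", "X", "chrx"))
norm_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  sex <- tolower(x) %in% c("x", "y", "mt", "m")
  x[sex] <- toupper(x[sex])
  x
}

is_chrx <- function(chrom) norm_chrom(chrom) == "X"

#' Site key string
#'
#' Canonical `chrom:pos:ref:alt` key used to join tables produced by the
#' different pipeline stages.  Chromosome names are normalised first.
#'
#' @param chrom,pos,ref,alt site coordinates and alleles.
#' @return character vector of keys.
#' @export
site_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), pos, ref, alt, sep = ":")
}

#' Write / read a pipeline result table
#'
#' All tabular outputs share one dialect: tab-separated, header row, `.`
#' for missing values, no quoting, rows sorted by the caller.  Reading a
#' written table back reproduces the records.
#'
#' @param df a data.frame.
#' @param path file path.
#' @return `rad_write_tsv` returns `path` invisibly; `rad_read_tsv`
#'   returns a data.frame.
#' @export
rad_write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname rad_write_tsv
#' @export
rad_read_tsv <- function(path) {
  utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

rad_log <- function(...) {
  message("[radase] ", ...)
}

stop_rad <- function(msg, class) {
  stop(structure(class = c(class, "radase_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_nucleotides <- function(x, what) {
  bad <- !(x %in% NUCLEOTIDES)
  if (any(bad)) {
    stop_rad(sprintf("%s contains non-ACGT values: %s", what,
                     paste(unique(x[bad]), collapse = ", ")),
             "radase_validation_error")
  }
  invisible(TRUE)
}
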