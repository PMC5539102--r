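## Pairwise pattern groups and per-site categories.
##
## The 10 unordered combinations of the four pattern labels partition
## into four groups: Group 1 (same parent, reciprocal ref/alt -- the RAD
## signature of imprinting), Group 2 (identical labels, no RAD), Group 3
## (same ref/alt identity, reciprocal parent -- sequence-dependent RAD)
## and Group 4 (reciprocal in both coordinates -- the RME signature).

#' Group an unordered pair of pattern labels
#'
#' @param label_a,label_b labels among `"P_r"`, `"P_a"`, `"M_r"`,
#'   `"M_a"`; order is irrelevant.
#' @return one of `"G1"`, `"G2"`, `"G3"`, `"G4"`.
#' @export
#' @examples
#' pair_group("P_r", "P_a")  # RAD toward the paternal allele
pair_group <- function(label_a, label_b) {
  stopifnot(all(c(label_a, label_b) %in% PATTERN_LABELS))
  if (label_a == label_b) return("G2")
  same_parent <- substr(label_a, 1, 1) == substr(label_b, 1, 1)
  same_ra <- substr(label_a, 3, 3) == substr(label_b, 3, 3)
  if (same_parent) "G1" else if (same_ra) "G3" else "G4"
}

groups_of <- function(labels) {
  idx <- utils::combn(length(labels), 2)
  sort(unique(mapply(pair_group, labels[idx[1, ]], labels[idx[2, ]])))
}

#' Categorise one site from its children's pattern labels
#'
#' Requires the labels of at least two applicable children, all of whom
#' showed stringent ASE.  The category is decided from the groups
#' present among all unordered label pairs: Group 4 anywhere means
#' Category 2-2 (RME-consistent); Group 1 without Group 3 means
#' Category 1-1 (imprinting-consistent RAD); Group 3 without Group 1
#' means Category 2-1 (sequence-dependent RAD); only Group 2 means
#' Category 1-2 (consistent bias, no RAD, mechanism uncertain).  A label
#' set showing Group 1 and Group 3 but not Group 4 is provably
#' impossible and is asserted against.
#'
#' @param labels character vector (length >= 2) of pattern labels, one
#'   per applicable child.
#' @return list with `labels`, `groups_present` and `category` (one of
#'   `"C1-1"`, `"C1-2"`, `"C2-1"`, `"C2-2"`).
#' @export
#' @examples
#' classify_site(c("P_a", "P_r"))$category  # "C1-1"
classify_site <- function(labels) {
  if (length(labels) < 2) {
    stop_rad("site categorisation needs labels from at least two applicable children",
             "radase_insufficient_evidence")
  }
  g <- groups_of(labels)
  if (all(c("G1", "G3") %in% g) && !("G4" %in% g)) {
    stop("internal error: Group 1 and Group 3 present without Group 4; ",
         "this label configuration should be unreachable")
  }
  category <- if ("G4" %in% g) {
    "C2-2"
  } else if ("G1" %in% g) {
    "C1-1"
  } else if ("G3" %in% g) {
    "C2-1"
  } else {
    "C1-2"
  }
  list(labels = labels, groups_present = g, category = category)
}

#' Categorise every eligible site of an ASE table
#'
#' A site enters categorisation only when it has at least two applicable
#' children and every applicable child shows stringent ASE (a site with
#' an applicable-but-biallelic child is dropped, with the drop recorded
#' in the attributes).
#'
#' @param ase an ASE table from [ase_table()].
#' @return data.frame with one row per categorised site: coordinates,
#'   `n_applicable`, `labels` and `groups_present` (comma strings),
#'   `category`.  Attributes `n_sites_lt2_applicable` and
#'   `n_sites_not_all_ase` count the dropped sites.
#' @export
classify_sites <- function(ase) {
  key <- site_key(ase$chrom, ase$pos, ase$ref, ase$alt)
  sp <- split(seq_len(nrow(ase)), key)
  rows <- list()
  n_lt2 <- 0L
  n_not_all <- 0L
  for (k in names(sp)) {
    idx <- sp[[k]]
    if (length(idx) < 2) { n_lt2 <- n_lt2 + 1L; next }
    if (any(ase$status[idx] != "ase_stringent") ||
        anyNA(ase$label[idx])) {
      n_not_all <- n_not_all + 1L
      next
    }
    cl <- classify_site(ase$label[idx])
    i1 <- idx[1]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ase$chrom[i1], pos = ase$pos[i1], ref = ase$ref[i1],
      alt = ase$alt[i1], n_applicable = length(idx),
      labels = paste(cl$labels, collapse = ","),
      groups_present = paste(cl$groups_present, collapse = ","),
      category = cl$category, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), n_applicable = integer(),
               labels = character(), groups_present = character(),
               category = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sites_lt2_applicable") <- n_lt2
  attr(out, "n_sites_not_all_ase") <- n_not_all
  out
}

#' Exclude non-RME calls inside RME genes
#'
#' Any non-Category-2-2 site lying within a gene that also contains a
#' Category-2-2 site is flagged `excluded_by_rme_gene` (random
#' monoallelic expression elsewhere in the gene makes the imprinting /
#' cis interpretation unsafe).  Category-2-2 sites themselves are
#' retained, as are sites overlapping no gene (which are logged: the
#' rule cannot apply to them).  A site overlapping several genes is
#' excluded if any of them contains a Category-2-2 site.  The operation
#' is idempotent.
#'
#' @param category_calls a table from [classify_sites()].
#' @param genes gene index from [read_gene_annotation()].
#' @return `category_calls` with a logical `excluded_by_rme_gene`
#'   column; the retained set is the subset with the flag `FALSE`.
#' @export
rme_gene_exclusion <- function(category_calls, genes) {
  if (nrow(category_calls) == 0) {
    category_calls$excluded_by_rme_gene <- logical(0)
    return(category_calls)
  }
  gl <- genes_overlapping(genes, category_calls$chrom, category_calls$pos)
  orphans <- lengths(gl) == 0
  if (any(orphans)) {
    rad_log(sum(orphans),
            " categorised site(s) overlap no gene; RME-gene exclusion not applied to them")
  }
  rme_genes <- unique(unlist(gl[category_calls$category == "C2-2"]))
  category_calls$excluded_by_rme_gene <-
    category_calls$category != "C2-2" &
    vapply(gl, function(g) any(g %in% rme_genes), logical(1))
  category_calls
}
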