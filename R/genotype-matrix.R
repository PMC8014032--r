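#' Construct a codominant genotype matrix
#'
#' A `genotype_matrix` holds diploid, codominant genotype calls for a set of
#' samples at a set of marker loci (SSR fragment sizes or SNP bases). Each
#' call is an unordered allele pair; internally every call is stored as a
#' canonical string `"a/b"` with the two allele labels sorted, so two calls
#' are the same genotype if and only if their canonical strings are equal.
#' Missing calls are `NA`. Allele labels are opaque strings: SSR fragment
#' sizes are compared as labels, never parsed numerically, because every
#' statistic in the package only needs equality of genotypes.
#'
#' @param calls character matrix (samples x loci) of `"a/b"` calls, or `NA`
#'   for missing. A call with a missing separator, an empty allele, or only
#'   one allele is rejected: ploidy is fixed at two and single-allele cells
#'   are not imputed.
#' @param marker_type `"SSR"` or `"SNP"`. Informational; does not change any
#'   computation.
#' @param pair_sep separator between the two allele labels within a call.
#' @return an object of class `genotype_matrix`: the canonicalized character
#'   matrix with `sample_ids` as row names, `locus_ids` as column names and a
#'   `marker_type` attribute.
#' @seealso [read_genotypes()], [subset_loci()], [pair_difference()]
#' @export
#' @examples
#' g <- genotype_matrix(
#'   matrix(c("A/T", "T/A", "C/C", "C/G"), nrow = 2,
#'          dimnames = list(c("s1", "s2"), c("L1", "L2"))),
#'   marker_type = "SNP")
#' g["s2", "L1"]  # canonicalized to "A/T"
genotype_matrix <- function(calls, marker_type = c("SNP", "SSR"),
                            pair_sep = "/") {
  marker_type <- match.arg(marker_type)
  if (!is.matrix(calls) || !is.character(calls)) {
    stop_format("`calls` must be a character matrix")
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("L%02d", seq_len(ncol(calls)))
  }
  if (anyDuplicated(rownames(calls))) {
    stop_format("duplicate sample ids: ",
                paste(unique(rownames(calls)[duplicated(rownames(calls))]),
                      collapse = ", "))
  }
  if (anyDuplicated(colnames(calls))) {
    stop_format("duplicate locus ids: ",
                paste(unique(colnames(calls)[duplicated(colnames(calls))]),
                      collapse = ", "))
  }
  canon <- canonicalize_calls(calls, pair_sep)
  structure(canon, class = "genotype_matrix", marker_type = marker_type,
            pair_sep = pair_sep)
}

# Sort the two allele labels of every non-missing call so that unordered
# pairs compare by string equality. Errors name the offending cell.
canonicalize_calls <- function(calls, pair_sep) {
  out <- calls
  idx <- which(!is.na(calls))
  if (length(idx)) {
    parts <- strsplit(calls[idx], pair_sep, fixed = TRUE)
    bad <- vapply(parts, function(p) {
      length(p) != 2L || any(!nzchar(p))
    }, logical(1))
    if (any(bad)) {
      first <- idx[which(bad)[1L]]
      rc <- arrayInd(first, dim(calls))
      stop_format("unparseable genotype call ", dQuote(calls[first]),
                  " at sample ", dQuote(rownames(calls)[rc[1L]]),
                  ", locus ", dQuote(colnames(calls)[rc[2L]]),
                  " (expected two alleles separated by ",
                  dQuote(pair_sep), ")")
    }
    out[idx] <- vapply(parts, function(p) {
      paste(sort(p), collapse = pair_sep)
    }, character(1))
  }
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%s), %d missing call%s\n",
              nrow(x), ncol(x), attr(x, "marker_type"),
              sum(is.na(x)), if (sum(is.na(x)) == 1L) "" else "s"))
  n <- min(nrow(x), 6L)
  print(unclass(x)[seq_len(n), , drop = FALSE], quote = FALSE, ...)
  if (nrow(x) > n) cat(sprintf("... %d more samples\n", nrow(x) - n))
  invisible(x)
}

#' Sample and locus identifiers of a genotype matrix
#' @param x a [genotype_matrix()].
#' @return character vector of ids.
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname sample_ids
#' @export
locus_ids <- function(x) colnames(x)

#' Restrict a genotype matrix to a subset of loci
#'
#' Used by the nested-inclusion analyses that shrink a marker panel while
#' watching the appraisal statistics respond. Sample order is preserved and
#' the input is unchanged.
#'
#' @param x a [genotype_matrix()].
#' @param keep character vector of locus ids to retain; must be a non-empty,
#'   duplicate-free subset of `locus_ids(x)`.
#' @return a `genotype_matrix` over the loci in `keep`, in the order given.
#' @export
#' @examples
#' g <- make_population(table1_specs(4)[1, ], seed = 1)
#' ncol(subset_loci(g, locus_ids(g)[1:3]))
subset_loci <- function(x, keep) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (length(keep) == 0L) stop("`keep` must name at least one locus")
  if (anyDuplicated(keep)) stop("`keep` contains duplicate locus ids")
  unknown <- setdiff(keep, colnames(x))
  if (length(unknown)) {
    stop("unknown locus id(s): ", paste(unknown, collapse = ", "))
  }
  out <- unclass(x)[, keep, drop = FALSE]
  structure(out, class = "genotype_matrix",
            marker_type = attr(x, "marker_type"),
            pair_sep = attr(x, "pair_sep"))
}

# m >= 2 is required for every appraisal statistic.
assert_appraisable <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (nrow(x) < 2L) {
    stop_validity("appraisal needs at least 2 samples, got ", nrow(x))
  }
  invisible(x)
}
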