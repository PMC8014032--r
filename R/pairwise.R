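#' Variety difference degree between two samples
#'
#' Compares two samples locus by locus. Only loci called in both samples
#' (the overlap) enter the comparison; a locus counts as different when the
#' unordered allele pairs are unequal — heterozygote comparison is strict
#' set equality, so partial allele sharing (A/T vs A/A) is a difference.
#' When the two samples share no called locus the comparison is undefined:
#' `n_overlap` is 0 and `pct_diff` is `NaN`; how such a pair is classified
#' is a downstream policy (see [classify_pair()]).
#'
#' @param x a [genotype_matrix()].
#' @param i,j distinct sample ids present in `x`.
#' @return a `pair_difference`: list with `n_diff` (loci with unequal
#'   calls), `n_overlap` (loci called in both samples) and
#'   `pct_diff = n_diff / n_overlap`.
#' @export
#' @examples
#' g <- make_population(table1_specs(1)[21, ], seed = 3)
#' pair_difference(g, sample_ids(g)[1], sample_ids(g)[206])
pair_difference <- function(x, i, j) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (identical(i, j)) stop("`i` and `j` must be different samples")
  for (id in c(i, j)) {
    if (!id %in% rownames(x)) stop("unknown sample id: ", id)
  }
  a <- unclass(x)[i, ]
  b <- unclass(x)[j, ]
  both <- !is.na(a) & !is.na(b)
  n_overlap <- sum(both)
  n_diff <- sum(a[both] != b[both])
  structure(list(n_diff = n_diff, n_overlap = n_overlap,
                 pct_diff = n_diff / n_overlap),
            class = "pair_difference")
}

#' @export
print.pair_difference <- function(x, ...) {
  if (x$n_overlap == 0L) {
    cat("pair_difference: UNDEFINED (no overlapping called loci)\n")
  } else {
    cat(sprintf("pair_difference: %d/%d overlapping loci differ (%.4f)\n",
                x$n_diff, x$n_overlap, x$pct_diff))
  }
  invisible(x)
}

#' All pairwise variety difference degrees
#'
#' Global traversal of every unordered sample pair. The result stores two
#' symmetric integer matrices (`n_diff`, `n_overlap`) with `NA` diagonals;
#' percentage differences are derived on demand. Pairs with zero overlap
#' are undefined, not zero.
#'
#' @param x a [genotype_matrix()] with at least 2 samples.
#' @return a `difference_matrix`: list with symmetric matrices `n_diff` and
#'   `n_overlap`, plus `m` and `n_loci`.
#' @seealso [as.data.frame.difference_matrix()] for the long pair table.
#' @export
difference_matrix <- function(x) {
  assert_appraisable(x)
  calls <- unclass(x)
  m <- nrow(calls)
  nd <- matrix(0L, m, m, dimnames = list(rownames(calls), rownames(calls)))
  nov <- nd
  for (l in seq_len(ncol(calls))) {
    v <- calls[, l]
    ok <- !is.na(v)
    both <- outer(ok, ok, `&`)
    neq <- both & outer(v, v, `!=`)
    nov <- nov + both
    nd <- nd + neq
  }
  diag(nd) <- NA_integer_
  diag(nov) <- NA_integer_
  structure(list(n_diff = nd, n_overlap = nov, m = m,
                 n_loci = ncol(calls)),
            class = "difference_matrix")
}

#' @export
print.difference_matrix <- function(x, ...) {
  und <- sum(x$n_overlap[upper.tri(x$n_overlap)] == 0L)
  cat(sprintf(paste0("difference_matrix: %d samples, %d loci, %d unordered",
                     " pairs (%d undefined)\n"),
              x$m, x$n_loci, choose2(x$m), und))
  invisible(x)
}

#' Long-format pair table of a difference matrix
#'
#' One row per unordered sample pair, suitable for TSV export.
#'
#' @param x a [difference_matrix()].
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return data.frame with columns `sample_i`, `sample_j`, `n_diff`,
#'   `n_overlap`, `pct_diff` (`NaN` for undefined pairs).
#' @export
as.data.frame.difference_matrix <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  ut <- which(upper.tri(x$n_diff), arr.ind = TRUE)
  ids <- rownames(x$n_diff)
  data.frame(sample_i = ids[ut[, 1L]], sample_j = ids[ut[, 2L]],
             n_diff = x$n_diff[ut], n_overlap = x$n_overlap[ut],
             pct_diff = x$n_diff[ut] / x$n_overlap[ut],
             stringsAsFactors = FALSE)
}
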