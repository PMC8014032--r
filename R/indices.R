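#' Probability-based variety discrimination power
#'
#' The probability that two samples drawn without replacement from the
#' population belong to different repeated groups:
#' \deqn{\mathrm{P\text{-}VDP} = 1 - \frac{\sum_i \binom{R_i}{2} T_i}
#'   {\binom{m}{2}}}{P-VDP = 1 - sum_i C(R_i,2) T_i / C(m,2)}
#' where category i holds \eqn{T_i} groups of \eqn{R_i} samples each and m
#' is the total sample count. The statistic is only valid when the
#' partition was built under the perfect-match rule on complete data: with
#' a looser threshold the grouped samples are not all mutually identical,
#' and with missing data the groups themselves cannot be established
#' reliably, so either condition raises a validity error.
#'
#' @param partition a `vdp_partition` from [build_partition()] or
#'   [partition_from_sizes()].
#' @return numeric in \[0, 1\]: 1 when every sample is its own variety, 0
#'   when all samples collapse into one group.
#' @export
#' @examples
#' p_vdp(partition_from_sizes(c(2, 2, 1)))  # 1 - 2/10
p_vdp <- function(partition) {
  stopifnot(inherits(partition, "vdp_partition"))
  if (!isTRUE(partition$perfect_match)) {
    stop_validity("P-VDP requires the variety threshold to be set as ",
                  "perfect match (any differing locus separates); this ",
                  "partition was built under a partial-match rule")
  }
  if (!isTRUE(partition$complete_data)) {
    stop_validity("P-VDP is not valid for loci combinations with missing ",
                  "data; use C-VDP or R-VDP instead")
  }
  tab <- partition$categories
  1 - sum(choose2(tab$R) * tab$T) / choose2(partition$m)
}

#' Comparison-based variety discrimination power
#'
#' The proportion of ordered sample pairs classified as different
#' varieties by global traversal:
#' \deqn{\mathrm{C\text{-}VDP} = \frac{\sum_{i \ne j} d_{ij}}{m(m-1)}}{
#'   C-VDP = sum_{i != j} d_ij / (m (m - 1))}
#' with \eqn{d_{ij} = 1} when samples i and j are classified as different
#' varieties under the threshold rule, else 0. Unlike P-VDP it needs no
#' grouping, so it remains usable under partial-match thresholds and (with
#' a policy for zero-overlap pairs) under missing data, where excluded
#' loci can only push it downward (a type-II underestimation).
#'
#' @param x a [genotype_matrix()] (at least 2 samples) or a
#'   [difference_matrix()].
#' @param rule a [threshold_rule()].
#' @param undefined policy for zero-overlap pairs; see [classify_pair()].
#' @return numeric in \[0, 1\].
#' @export
c_vdp <- function(x, rule = threshold_rule("count", 1),
                  undefined = c("error", "same", "different")) {
  undefined <- match.arg(undefined)
  stopifnot(inherits(rule, "threshold_rule"))
  dm <- if (inherits(x, "difference_matrix")) x else difference_matrix(x)
  ut <- upper.tri(dm$n_diff)
  nd <- dm$n_diff[ut]
  nov <- dm$n_overlap[ut]
  if (any(nov == 0L) && undefined == "error") {
    stop_validity(sum(nov == 0L), " undefined comparisons (no ",
                  "overlapping called loci); set `undefined` policy")
  }
  value <- switch(rule$metric, count = nd, percentage = nd / nov)
  different <- value >= rule$M
  different[nov == 0L] <- undefined == "different"
  # each unordered pair contributes d_ij and d_ji
  2 * sum(different) / (dm$m * (dm$m - 1))
}

#' Comparison-based VDP from a partition (discrimination-chain form)
#'
#' When every same-variety comparison follows the discrimination chain —
#' as it always does under perfect match — C-VDP can be computed from the
#' repeated-group tabulation alone:
#' \deqn{\mathrm{C\text{-}VDP} = 1 - \frac{2 \sum_i \binom{R_i}{2} T_i}
#'   {m(m-1)}}{C-VDP = 1 - 2 sum_i C(R_i,2) T_i / (m (m - 1))}
#' which is algebraically identical to P-VDP on the same partition.
#'
#' @param partition a `vdp_partition`.
#' @return numeric in \[0, 1\], equal to `p_vdp(partition)` whenever the
#'   latter is valid.
#' @export
c_vdp_chain <- function(partition) {
  stopifnot(inherits(partition, "vdp_partition"))
  tab <- partition$categories
  m <- partition$m
  1 - 2 * sum(choose2(tab$R) * tab$T) / (m * (m - 1))
}

#' Ratio-based variety discrimination power
#'
#' The number of repeated groups over the number of samples:
#' \deqn{\mathrm{R\text{-}VDP} = \frac{D + \sum_k G_k}{m} = \frac{t}{m}}{
#'   R-VDP = (D + sum_k G_k) / m = t / m}
#' where D counts singleton groups and \eqn{G_k} the groups in each
#' multi-sample category. The parsimony principle behind it: every extra
#' group is one more distinguishable variety. Its floor is 1/m (all
#' samples in one group), not 0.
#'
#' @param partition a `vdp_partition`.
#' @return numeric in \[1/m, 1\].
#' @export
#' @examples
#' r_vdp(partition_from_sizes(c(rep(1, 6), rep(5, 40))))  # 46/206
r_vdp <- function(partition) {
  stopifnot(inherits(partition, "vdp_partition"))
  (partition$D + sum(partition$G)) / partition$m
}

#' Per-locus genotype-class frequencies
#'
#' Frequencies of the distinct unordered diploid genotypes at each locus,
#' computed over the non-missing calls at that locus (missing calls shrink
#' the denominator; they are not a class).
#'
#' @param x a [genotype_matrix()].
#' @return a `locus_frequencies`: list with one element per locus, each a
#'   list of `freq` (named numeric, summing to 1 when any call exists) and
#'   `n_called`.
#' @export
locus_frequencies <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  calls <- unclass(x)
  out <- lapply(seq_len(ncol(calls)), function(l) {
    v <- calls[, l]
    v <- v[!is.na(v)]
    counts <- table(v)
    freq <- as.numeric(counts) / length(v)
    names(freq) <- names(counts)
    list(freq = freq, n_called = length(v))
  })
  names(out) <- colnames(calls)
  structure(out, class = "locus_frequencies")
}

#' Per-locus probability of discrimination power
#'
#' The probability that two individuals drawn at random have different
#' genotypes at locus j: \deqn{DP_j = 1 - \sum_k g_{jk}^2}{DP_j = 1 -
#' sum_k g_jk^2} over the genotype-class frequencies \eqn{g_{jk}}. A
#' monomorphic locus has DP 0.
#'
#' @param freqs a [locus_frequencies()].
#' @param j locus id or index.
#' @return numeric in \[0, 1).
#' @export
locus_dp <- function(freqs, j) {
  stopifnot(inherits(freqs, "locus_frequencies"))
  f <- freqs[[j]]
  if (is.null(f)) stop("unknown locus: ", j)
  if (f$n_called == 0L) {
    stop_validity("locus ", if (is.character(j)) j else names(freqs)[j],
                  " has no called samples; DP is undefined")
  }
  1 - sum(f$freq^2)
}

#' Total probability of discrimination power of a loci combination
#'
#' Combines the per-locus DP values by the multiplication law:
#' \deqn{TDP = 1 - \prod_j (1 - DP_j)}{TDP = 1 - prod_j (1 - DP_j)}
#' i.e. the probability that two random individuals differ at one or more
#' loci, assuming independence across loci. Frequencies at each locus are
#' taken over its called samples, so TDP tolerates missing data; a locus
#' with no called sample at all is an error.
#'
#' @param x a [genotype_matrix()] with at least 2 samples.
#' @return numeric in \[0, 1).
#' @export
#' @examples
#' g <- make_population(table1_specs(1)[21, ], seed = 5)
#' tdp(g)  # about 0.09: 205 identical samples swamp the panel
tdp <- function(x) {
  assert_appraisable(x)
  freqs <- locus_frequencies(x)
  dp <- vapply(seq_along(freqs), function(j) locus_dp(freqs, j), numeric(1))
  1 - prod(1 - dp)
}
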