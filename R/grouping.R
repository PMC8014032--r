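#' Variety threshold rule
#'
#' Defines when two samples count as different varieties: when their
#' pairwise difference reaches the minimum difference `M`, measured either
#' as a count of differing loci or as a fraction of the overlapping loci.
#' `threshold_rule("count", 1)` is the "perfect match" rule — any single
#' differing locus separates two varieties, and only exact genotype matches
#' are grouped together.
#'
#' @param metric `"count"` (number of differing loci) or `"percentage"`
#'   (fraction of overlapping loci that differ).
#' @param M minimum difference declaring "different variety": an integer
#'   >= 1 for `"count"`, a fraction in (0, 1] for `"percentage"`.
#' @return a `threshold_rule` object.
#' @export
#' @examples
#' threshold_rule("count", 2)       # >= 2 differing loci separates
#' threshold_rule("percentage", .3) # >= 30% of overlap differing separates
threshold_rule <- function(metric = c("count", "percentage"), M = 1) {
  metric <- match.arg(metric)
  if (metric == "count") {
    if (length(M) != 1L || is.na(M) || M < 1 || M != as.integer(M)) {
      stop("for the count metric `M` must be an integer >= 1")
    }
    M <- as.integer(M)
  } else {
    if (length(M) != 1L || is.na(M) || M <= 0 || M > 1) {
      stop("for the percentage metric `M` must lie in (0, 1]")
    }
  }
  structure(list(metric = metric, M = M), class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("threshold_rule: different variety when %s >= %s\n",
              switch(x$metric, count = "number of differing loci",
                     percentage = "fraction of differing loci"),
              format(x$M)))
  invisible(x)
}

# Does this rule, on panels of `n_loci` loci, separate any nonzero
# difference (the perfect-match condition the probability-based index
# requires)?
is_perfect_match <- function(rule, n_loci) {
  (rule$metric == "count" && rule$M == 1L) ||
    (rule$metric == "percentage" && n_loci >= 1L && rule$M <= 1 / n_loci)
}

#' Classify a sample pair as same or different variety
#'
#' Applies a [threshold_rule()] to a [pair_difference()]. A pair with no
#' overlapping called loci has no defined difference; by default this is an
#' error, but the policy can force such pairs to either class.
#'
#' @param diff a [pair_difference()].
#' @param rule a [threshold_rule()].
#' @param undefined policy for zero-overlap pairs: `"error"` (default),
#'   `"same"`, or `"different"`.
#' @return `"same"` or `"different"`.
#' @export
classify_pair <- function(diff, rule,
                          undefined = c("error", "same", "different")) {
  stopifnot(inherits(diff, "pair_difference"),
            inherits(rule, "threshold_rule"))
  undefined <- match.arg(undefined)
  if (diff$n_overlap == 0L) {
    if (undefined == "error") {
      stop_validity("pair has no overlapping called loci; the comparison ",
                    "is undefined (set `undefined` to \"same\" or ",
                    "\"different\" to force a class)")
    }
    return(undefined)
  }
  value <- switch(rule$metric, count = diff$n_diff,
                  percentage = diff$pct_diff)
  if (value >= rule$M) "different" else "same"
}

#' Partition samples into repeated groups under a variety threshold
#'
#' Classifies every unordered pair with the rule, then groups samples by
#' the discrimination chain: if A and B are the same variety and B and C
#' are the same variety, A and C join the same repeated group. Groups are
#' therefore the connected components of the same-variety relation
#' (computed by union-find), which under the perfect-match rule on
#' complete data coincide with sets of identical genotype vectors.
#'
#' @param x a [genotype_matrix()] with at least 2 samples, or a
#'   [difference_matrix()] already computed from one.
#' @param rule a [threshold_rule()].
#' @param undefined policy for zero-overlap pairs, as in [classify_pair()];
#'   under the default `"error"` policy the offending pairs are listed.
#' @return a `vdp_partition`; see [tabulate_partition()] for its category
#'   table (group size \eqn{R_i} vs number of groups \eqn{T_i}), singleton
#'   count D, group total t and per-category group counts.
#' @export
#' @examples
#' g <- make_population(table1_specs(2)[21, ], seed = 1)
#' p <- build_partition(g, threshold_rule("count", 1))
#' p$D; p$t  # 6 singletons, 106 groups
build_partition <- function(x, rule = threshold_rule("count", 1),
                            undefined = c("error", "same", "different")) {
  undefined <- match.arg(undefined)
  stopifnot(inherits(rule, "threshold_rule"))
  if (inherits(x, "genotype_matrix")) {
    complete <- !anyNA(unclass(x))
    dm <- difference_matrix(x)
  } else if (inherits(x, "difference_matrix")) {
    dm <- x
    complete <- all(dm$n_overlap[upper.tri(dm$n_overlap)] == dm$n_loci)
  } else {
    stop("`x` must be a genotype_matrix or a difference_matrix")
  }
  m <- dm$m
  ids <- rownames(dm$n_diff)
  ut <- upper.tri(dm$n_diff)
  nov <- dm$n_overlap[ut]
  nd <- dm$n_diff[ut]
  if (any(nov == 0L) && undefined == "error") {
    idx <- which(ut, arr.ind = TRUE)[nov == 0L, , drop = FALSE]
    pairs <- paste0(ids[idx[, 1L]], "~", ids[idx[, 2L]])
    if (length(pairs) > 10L) {
      pairs <- c(pairs[1:10], sprintf("... (%d total)", sum(nov == 0L)))
    }
    stop_validity("undefined comparisons (no overlapping called loci): ",
                  paste(pairs, collapse = ", "))
  }
  value <- switch(rule$metric, count = nd, percentage = nd / nov)
  same <- !(value >= rule$M)            # NaN (undefined) drops to policy
  same[nov == 0L] <- undefined == "same"

  # union-find with path halving over the same-variety pairs
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(ut, arr.ind = TRUE)[same, , drop = FALSE]
  for (k in seq_len(nrow(idx))) {
    ri <- find(idx[k, 1L])
    rj <- find(idx[k, 2L])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(m), find, integer(1))
  membership <- match(roots, unique(roots))
  names(membership) <- ids

  new_vdp_partition(membership, rule = rule, complete_data = complete,
                    perfect_match = is_perfect_match(rule, dm$n_loci))
}

# Assemble a vdp_partition (groups + category tabulation) from a
# membership vector. Invariants: sum(R_i * T_i) = m, sum(T_i) = t,
# D + sum(G_k) = t.
new_vdp_partition <- function(membership, rule = NULL, complete_data = NA,
                              perfect_match = NA) {
  groups <- split(names(membership), membership)
  names(groups) <- NULL
  sizes <- lengths(groups)
  cat_tab <- table(sizes)
  categories <- data.frame(R = as.integer(names(cat_tab)),
                           T = as.integer(cat_tab))
  stopifnot(sum(categories$R * categories$T) == length(membership))
  structure(list(
    membership = membership,
    groups = groups,
    sizes = sizes,
    categories = categories,
    D = sum(sizes == 1L),
    t = length(groups),
    p = sum(categories$R >= 2L),
    G = categories$T[categories$R >= 2L],
    m = length(membership),
    rule = rule,
    complete_data = complete_data,
    perfect_match = perfect_match
  ), class = "vdp_partition")
}

#' Category tabulation of a repeated-group partition
#'
#' Summarises a partition the way the appraisal statistics consume it:
#' groups of equal size \eqn{R_i} form one category holding \eqn{T_i}
#' groups; D counts singleton groups, t all groups, p the categories with
#' \eqn{R \ge 2}, and `G` the group counts of those categories.
#'
#' @param partition a `vdp_partition` from [build_partition()].
#' @return list with `categories` (data.frame of R, T), `D`, `t`, `p`,
#'   `G`, `m`.
#' @export
tabulate_partition <- function(partition) {
  stopifnot(inherits(partition, "vdp_partition"))
  partition[c("categories", "D", "t", "p", "G", "m")]
}

#' @export
print.vdp_partition <- function(x, ...) {
  cat(sprintf(paste0("vdp_partition: %d samples in %d repeated groups ",
                     "(%d singletons)\n"), x$m, x$t, x$D))
  tab <- x$categories
  cat("  category table (group size R : number of groups T):\n")
  cat(paste0("    ", paste(sprintf("%d:%d", tab$R, tab$T), collapse = "  ")),
      "\n")
  if (isTRUE(x$perfect_match) && isTRUE(x$complete_data)) {
    cat("  built under perfect match on complete data\n")
  }
  invisible(x)
}

#' Build a partition directly from repeated-group sizes
#'
#' Convenience constructor for working with published group structures
#' (e.g. a benchmark row "6 singletons plus 100 groups of 2") without
#' simulating genotypes. Sample ids are generated.
#'
#' @param sizes integer vector of group sizes (each >= 1).
#' @param perfect_match,complete_data validity flags to record; default
#'   `TRUE`, matching the idealised group structures such tables describe.
#' @return a `vdp_partition`.
#' @export
#' @examples
#' p <- partition_from_sizes(c(rep(1, 6), rep(2, 100)))
#' r_vdp(p)  # 106/206
partition_from_sizes <- function(sizes, perfect_match = TRUE,
                                 complete_data = TRUE) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1L, all(sizes >= 1L))
  membership <- rep(seq_along(sizes), sizes)
  names(membership) <- sprintf("S%03d", seq_along(membership))
  new_vdp_partition(membership, rule = threshold_rule("count", 1),
                    complete_data = complete_data,
                    perfect_match = perfect_match)
}
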