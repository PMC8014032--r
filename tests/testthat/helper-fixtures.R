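# Fixture builders and independent oracles used across the suite.

snp_classes <- c("A/A", "A/C", "A/G", "A/T", "C/C", "C/G", "C/T",
                 "G/G", "G/T", "T/T")

# Bare call grid of a genotype matrix (dim/dimnames only), for identity
# comparisons that should ignore class and provenance attributes.
raw_calls <- function(g) {
  x <- unclass(g)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

# Random complete-data genotype matrix; optionally mask calls.
random_matrix <- function(m, n_loci, seed, missing_rate = 0) {
  withr::with_seed(seed, {
    calls <- matrix(sample(snp_classes, m * n_loci, replace = TRUE),
                    nrow = m,
                    dimnames = list(sprintf("s%02d", seq_len(m)),
                                    sprintf("L%02d", seq_len(n_loci))))
    if (missing_rate > 0) {
      calls[sample(length(calls), round(missing_rate * length(calls)))] <-
        NA_character_
    }
    genotype_matrix(calls, marker_type = "SNP")
  })
}

# Oracle: group sizes by exact genotype-vector identity (valid for the
# perfect-match rule on complete data), independent of union-find.
hash_group_sizes <- function(g) {
  key <- apply(unclass(g), 1L, paste, collapse = "|")
  unname(sort(as.integer(table(key))))
}

# Oracle: probability two samples drawn without replacement fall in
# different groups, by enumerating all unordered pairs of a membership
# vector.
enumerate_pvdp <- function(membership) {
  m <- length(membership)
  pairs <- combn(m, 2)
  mean(membership[pairs[1, ]] != membership[pairs[2, ]])
}

# Oracle: per-locus difference count between two samples by explicit
# per-locus enumeration.
enumerate_pair <- function(g, i, j) {
  a <- unclass(g)[i, ]
  b <- unclass(g)[j, ]
  nd <- 0L; nov <- 0L
  for (l in seq_along(a)) {
    if (!is.na(a[l]) && !is.na(b[l])) {
      nov <- nov + 1L
      if (a[l] != b[l]) nd <- nd + 1L
    }
  }
  list(n_diff = nd, n_overlap = nov)
}

# All 84 benchmark specs in one frame.
all_table1_specs <- function() {
  do.call(rbind, lapply(1:4, table1_specs))
}
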