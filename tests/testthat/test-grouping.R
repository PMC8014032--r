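test_that("threshold_rule validates its arguments", {
  expect_error(threshold_rule("count", 0), "integer >= 1")
  expect_error(threshold_rule("count", 1.5), "integer >= 1")
  expect_error(threshold_rule("percentage", 0), "\\(0, 1\\]")
  expect_error(threshold_rule("percentage", 1.2), "\\(0, 1\\]")
  expect_equal(threshold_rule("count", 3)$M, 3L)
})

test_that("classify_pair applies count and percentage thresholds", {
  mk <- function(nd, nov) structure(
    list(n_diff = nd, n_overlap = nov, pct_diff = nd / nov),
    class = "pair_difference")
  m1 <- threshold_rule("count", 1)
  expect_equal(classify_pair(mk(0, 10), m1), "same")
  expect_equal(classify_pair(mk(1, 10), m1), "different")
  expect_equal(classify_pair(mk(2, 10), threshold_rule("count", 3)), "same")
  expect_equal(classify_pair(mk(3, 10), threshold_rule("percentage", 0.25)),
               "different")
  und <- mk(0, 0)
  expect_error(classify_pair(und, m1), "undefined")
  expect_equal(classify_pair(und, m1, undefined = "same"), "same")
  expect_equal(classify_pair(und, m1, undefined = "different"), "different")
})

test_that("chain grouping merges through intermediate samples", {
  # d(A,B)=1, d(B,C)=1, d(A,C)=2: under M=2 the A-C pair alone is
  # "different" but the chain through B merges all three
  g <- genotype_matrix(rbind(A = c("A/A", "C/C", "G/G"),
                             B = c("A/C", "C/C", "G/G"),
                             C = c("A/C", "C/G", "G/G")))
  p <- build_partition(g, threshold_rule("count", 2))
  expect_equal(p$t, 1L)
  expect_equal(sort(p$groups[[1]]), c("A", "B", "C"))
  # under perfect match all three separate
  expect_equal(build_partition(g, threshold_rule("count", 1))$t, 3L)
})

test_that("partition tabulation satisfies the category invariants", {
  p <- partition_from_sizes(c(1, 1, 1, 2, 2))
  expect_equal(p$D, 3L)
  expect_equal(p$t, 5L)
  expect_equal(p$p, 1L)
  expect_equal(p$G, 2L)
  expect_equal(p$categories, data.frame(R = c(1L, 2L), T = c(3L, 2L)))
  tab <- tabulate_partition(p)
  expect_equal(sum(tab$categories$R * tab$categories$T), p$m)
  expect_equal(sum(tab$categories$T), tab$t)
  expect_equal(tab$D + sum(tab$G), tab$t)

  single <- partition_from_sizes(8)
  expect_equal(single$D, 0L)
  expect_equal(single$t, 1L)
  expect_equal(single$p, 1L)

  # benchmark structure: 106 singletons + 10 groups of 10
  p11 <- partition_from_sizes(c(rep(1, 106), rep(10, 10)))
  expect_equal(p11$m, 206L)
  expect_equal(p11$categories, data.frame(R = c(1L, 10L), T = c(106L, 10L)))
})

test_that("all-identical samples collapse into one group", {
  g <- genotype_matrix(matrix("A/A", 5, 3,
                              dimnames = list(letters[1:5], NULL)))
  p <- build_partition(g)
  expect_equal(p$t, 1L)
  expect_equal(p$D, 0L)
})

test_that("partition equals hash-grouping oracle under perfect match", {
  for (seed in 1:25) {
    g <- random_matrix(m = 5 + seed %% 20, n_loci = 3, seed = seed)
    p <- build_partition(g, threshold_rule("count", 1))
    expect_equal(sort(unname(p$sizes)), hash_group_sizes(g))
  }
})

test_that("grouping is invariant to sample order", {
  g <- random_matrix(30, 2, seed = 9)
  p <- build_partition(g, threshold_rule("count", 2))
  for (k in 1:5) {
    perm <- withr::with_seed(k, sample(sample_ids(g)))
    calls <- unclass(g)[perm, , drop = FALSE]
    pp <- build_partition(genotype_matrix(calls), threshold_rule("count", 2))
    expect_equal(sort(unname(pp$sizes)), sort(unname(p$sizes)))
    # same groups as sets of ids
    norm <- function(x) sort(vapply(x$groups, function(gr)
      paste(sort(gr), collapse = ","), character(1)))
    expect_equal(norm(pp), norm(p))
  }
})

test_that("raising the count threshold never increases the group count", {
  for (seed in 1:10) {
    g <- random_matrix(25, 4, seed = 100 + seed)
    t_by_M <- vapply(1:4, function(M) {
      build_partition(g, threshold_rule("count", M))$t
    }, integer(1))
    expect_true(all(diff(t_by_M) <= 0L))
  }
})

test_that("undefined comparisons error by default, listing pairs", {
  g <- genotype_matrix(rbind(a = c("A/A", NA), b = c(NA, "C/C"),
                             c = c("A/A", "C/C")))
  expect_error(build_partition(g), class = "vdp_validity_error")
  expect_error(build_partition(g), "a~b")
  p_same <- build_partition(g, undefined = "same")
  expect_equal(p_same$t, 1L)  # a~b forced same chains everything via c
  p_diff <- build_partition(g, undefined = "different")
  expect_equal(p_diff$t, 1L)  # both still chain to c at zero differences
})

test_that("benchmark row recovery: 6 singletons plus 100 pairs", {
  g <- make_population(table1_specs(2)[21, ], seed = 4)
  p <- build_partition(g, threshold_rule("count", 1))
  expect_equal(p$D, 6L)
  expect_equal(p$t, 106L)
  expect_equal(p$m, 206L)
  expect_equal(p$categories, data.frame(R = c(1L, 2L), T = c(6L, 100L)))
})
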