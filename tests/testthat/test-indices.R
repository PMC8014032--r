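test_that("p_vdp matches pair enumeration and its closed form", {
  # groups [2,2,1] of m=5: 1 - 2/10 by hand; also by enumerating pairs
  p <- partition_from_sizes(c(2, 2, 1))
  expect_equal(p_vdp(p), 0.8)
  expect_equal(p_vdp(p), enumerate_pvdp(p$membership))

  expect_equal(p_vdp(partition_from_sizes(rep(1, 9))), 1)
  expect_equal(p_vdp(partition_from_sizes(12)), 0)

  # random partitions vs the brute-force oracle
  for (seed in 1:20) {
    sizes <- withr::with_seed(seed, sample(1:6, sample(2:10, 1),
                                           replace = TRUE))
    p <- partition_from_sizes(sizes)
    expect_equal(p_vdp(p), enumerate_pvdp(p$membership))
  }
})

test_that("p_vdp enforces its validity conditions", {
  g <- random_matrix(10, 6, seed = 2)
  p_partial <- build_partition(g, threshold_rule("count", 2))
  expect_error(p_vdp(p_partial), class = "vdp_validity_error")
  expect_error(p_vdp(p_partial), "perfect match")

  masked <- inject_missing(random_matrix(10, 10, seed = 2), 0.2, seed = 3)
  p_missing <- build_partition(masked, threshold_rule("count", 1))
  expect_error(p_vdp(p_missing), "missing")
})

test_that("c_vdp counts ordered pairs classified as different", {
  # 4 samples, exactly one same-variety unordered pair -> 1 - 2/12
  g <- genotype_matrix(rbind(a = c("A/A", "C/C"), b = c("A/A", "C/C"),
                             c = c("A/C", "C/G"), d = c("G/G", "T/T")))
  expect_equal(c_vdp(g, threshold_rule("count", 1)), 1 - 2 / 12)
  # all pairs different
  g4 <- make_population(list(D = 8, R = 1, T = 0), seed = 1)
  expect_equal(c_vdp(g4), 1)
})

test_that("c_vdp_chain equals the probability form on any partition", {
  for (seed in 1:15) {
    sizes <- withr::with_seed(seed, sample(1:8, sample(2:12, 1),
                                           replace = TRUE))
    p <- partition_from_sizes(sizes)
    expect_equal(c_vdp_chain(p), p_vdp(p))
  }
  expect_equal(c_vdp_chain(partition_from_sizes(c(2, 2, 1))), 0.8)
  expect_equal(c_vdp_chain(partition_from_sizes(7)), 0)
})

test_that("r_vdp is the group count over the sample count", {
  expect_equal(r_vdp(partition_from_sizes(c(rep(1, 6), rep(5, 40)))),
               46 / 206)
  expect_equal(r_vdp(partition_from_sizes(rep(1, 11))), 1)
  expect_equal(r_vdp(partition_from_sizes(9)), 1 / 9)  # floor is 1/m
})

test_that("locus frequencies sum to 1 over called samples", {
  g <- random_matrix(30, 6, seed = 8, missing_rate = 0.25)
  fr <- locus_frequencies(g)
  for (l in locus_ids(g)) {
    expect_equal(sum(fr[[l]]$freq), 1, tolerance = 1e-12)
    expect_equal(fr[[l]]$n_called, sum(!is.na(unclass(g)[, l])))
  }
})

test_that("locus_dp is one minus the sum of squared class frequencies", {
  mono <- genotype_matrix(matrix("A/A", 6, 1))
  expect_equal(locus_dp(locus_frequencies(mono), 1), 0)

  half <- genotype_matrix(matrix(rep(c("A/A", "C/C"), 3), ncol = 1))
  expect_equal(locus_dp(locus_frequencies(half), 1), 0.5)

  # 205:1 split, the class structure behind the terminal benchmark TDP
  skew <- genotype_matrix(matrix(c(rep("A/A", 205), "C/C"), ncol = 1))
  expect_equal(locus_dp(locus_frequencies(skew), 1), 410 / 42436)

  empty <- genotype_matrix(matrix(NA_character_, 3, 1))
  expect_error(locus_dp(locus_frequencies(empty), 1),
               class = "vdp_validity_error")
})

test_that("tdp combines loci by the multiplication law", {
  mono <- genotype_matrix(matrix("A/A", 6, 3))
  expect_equal(tdp(mono), 0)

  two <- genotype_matrix(cbind(rep(c("A/A", "C/C"), 4),
                               rep(c("G/G", "T/T"), each = 4)))
  expect_equal(tdp(two), 1 - 0.5^2)  # two loci, DP = 0.5 each

  g <- make_population(table1_specs(1)[21, ], seed = 6)
  expect_equal(tdp(g), 1 - (1 - 410 / 42436)^10)
})

test_that("probability and comparison forms agree under perfect match", {
  for (seed in 1:50) {
    g <- random_matrix(m = 4 + seed %% 15, n_loci = 1 + seed %% 5,
                       seed = 300 + seed)
    p <- build_partition(g, threshold_rule("count", 1))
    expect_identical(p_vdp(p), c_vdp(g, threshold_rule("count", 1)))
  }
})

test_that("indices respect their bounds on random inputs", {
  for (seed in 1:10) {
    g <- random_matrix(20, 5, seed = 500 + seed)
    p <- build_partition(g)
    expect_gte(p_vdp(p), 0); expect_lte(p_vdp(p), 1)
    expect_gte(c_vdp(g), 0); expect_lte(c_vdp(g), 1)
    expect_gte(r_vdp(p), 1 / 20); expect_lte(r_vdp(p), 1)
    expect_gte(tdp(g), 0); expect_lt(tdp(g), 1)
  }
})

test_that("adding loci never decreases the indices at perfect match", {
  rule <- threshold_rule("count", 1)
  for (seed in 1:10) {
    g <- random_matrix(18, 8, seed = 600 + seed)
    sub <- subset_loci(g, locus_ids(g)[1:4])
    expect_lte(c_vdp(sub, rule), c_vdp(g, rule))
    expect_lte(r_vdp(build_partition(sub, rule)),
               r_vdp(build_partition(g, rule)))
    expect_lte(tdp(sub), tdp(g))
  }
})

test_that("injecting missing data only underestimates C-VDP and R-VDP", {
  rule <- threshold_rule("count", 1)
  for (seed in 1:10) {
    g <- random_matrix(18, 10, seed = 700 + seed)
    masked <- inject_missing(g, 0.3, seed = 800 + seed)
    expect_lte(c_vdp(masked, rule), c_vdp(g, rule))
    expect_lte(r_vdp(build_partition(masked, rule)),
               r_vdp(build_partition(g, rule)))
  }
})

test_that("vdp() returns a coherent appraisal object", {
  g <- make_population(table1_specs(3)[21, ], seed = 2)
  fit <- vdp(g)
  vals <- coef(fit)
  expect_named(vals, c("p_vdp", "c_vdp", "r_vdp", "tdp"))
  expect_equal(unname(vals["p_vdp"]), unname(vals["c_vdp"]))
  expect_equal(unname(vals["r_vdp"]), 46 / 206)
  expect_output(print(fit), "R-VDP")
  expect_output(print(summary(fit)), "category table")

  # partial-match rule: p_vdp skipped with a note, not an error
  fit2 <- vdp(g, rule = threshold_rule("count", 2))
  expect_true(is.na(coef(fit2)["p_vdp"]))
  expect_match(fit2$notes, "perfect match")
})
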