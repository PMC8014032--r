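# Benchmark group structures for gradient variety difference degree:
# four arrays of 21 populations, each of 206 samples typed at 10
# four-allele SNP loci. D singleton varieties plus T repeated groups of R
# identical samples; D + R*T = 206 in every row. Array 1 grows the size of
# a single repeated group (convergence toward one variety); arrays 2-4
# grow the number of repeated groups at fixed sizes 2, 5 and 10
# (convergence toward many varieties).
table1_rows <- local({
  a1 <- cbind(D = c(204, 196, 186, 176, 166, 156, 146, 136, 126, 116, 106,
                    96, 86, 76, 66, 56, 46, 36, 26, 16, 1),
              R = c(2, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120,
                    130, 140, 150, 160, 170, 180, 190, 205),
              T = rep(1L, 21))
  a2 <- cbind(D = c(204, 196, 186, 176, 166, 156, 146, 136, 126, 116, 106,
                    96, 86, 76, 66, 56, 46, 36, 26, 16, 6),
              R = rep(2L, 21),
              T = c(1, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65,
                    70, 75, 80, 85, 90, 95, 100))
  a3 <- cbind(D = c(201, 196, 186, 176, 166, 156, 146, 136, 126, 116, 106,
                    96, 86, 76, 66, 56, 46, 36, 26, 16, 6),
              R = rep(5L, 21),
              T = c(1, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24, 26, 28,
                    30, 32, 34, 36, 38, 40))
  a4 <- cbind(D = c(206, 196, 186, 176, 166, 156, 146, 136, 126, 116, 106,
                    96, 86, 76, 66, 56, 46, 36, 26, 16, 6),
              R = rep(10L, 21),
              T = 0:20)
  list(a1, a2, a3, a4)
})

#' Benchmark population specifications (gradient variety difference)
#'
#' Returns the 21 population specifications of one benchmark array: a
#' gradient of variety difference degree over populations of 206 samples,
#' 10 SNP loci with four allelic variants each. Row k of an array gives D
#' singleton varieties plus T repeated groups of R identical samples.
#'
#' @param array_id which array, 1 to 4. Array 1 varies the repeated-group
#'   size R (one group converging toward a single variety); arrays 2, 3
#'   and 4 vary the group count T at fixed R = 2, 5, 10.
#' @return data.frame with 21 rows and columns `array_id`, `row_no`, `D`,
#'   `R`, `T`, `m`, `n_loci`, `alleles_per_locus`. Each row satisfies
#'   `D + R*T == m`.
#' @export
#' @examples
#' table1_specs(2)[21, ]  # 6 singletons + 100 pairs
table1_specs <- function(array_id) {
  if (!(length(array_id) == 1L && array_id %in% 1:4)) {
    stop("`array_id` must be 1, 2, 3 or 4")
  }
  rows <- table1_rows[[array_id]]
  data.frame(array_id = as.integer(array_id), row_no = 1:21,
             D = as.integer(rows[, "D"]), R = as.integer(rows[, "R"]),
             T = as.integer(rows[, "T"]), m = 206L, n_loci = 10L,
             alleles_per_locus = 4L)
}

# The 10 unordered diploid genotype classes of a locus with allele set
# `alleles` (4 alleles -> C(4,2) + 4 = 10 classes).
genotype_classes <- function(alleles = c("A", "C", "G", "T"),
                             pair_sep = "/") {
  idx <- which(upper.tri(diag(length(alleles)), diag = TRUE), arr.ind = TRUE)
  sorted <- cbind(pmin(alleles[idx[, 1L]], alleles[idx[, 2L]]),
                  pmax(alleles[idx[, 1L]], alleles[idx[, 2L]]))
  paste(sorted[, 1L], sorted[, 2L], sep = pair_sep)
}

#' Simulate a benchmark population from a group-structure specification
#'
#' Builds a genotype matrix of `m` samples realising the specified group
#' structure: `D` singleton varieties followed by `T` groups of `R`
#' identical samples, each variety a distinct 10-locus diploid genotype
#' vector. Two distinctness regimes control how distinct the varieties
#' are:
#' \describe{
#'   \item{`"all_loci"`}{any two varieties differ at every locus. Each
#'     variety then needs its own genotype class at every locus, so at
#'     most 10 varieties (the unordered diploid classes of a four-allele
#'     locus) are representable; more is a capacity error.}
#'   \item{`"at_least_one"`}{varieties get unique genotype vectors and so
#'     differ at one or more loci — sufficient for every partition-based
#'     statistic, which only sees the group structure.}
#' }
#' `"auto"` picks `"all_loci"` when it fits (needed to reproduce the
#' locus-level class structure behind TDP on array 1's terminal
#' population) and falls back to `"at_least_one"` otherwise.
#'
#' @param spec one row of [table1_specs()], or any list/data.frame row
#'   with fields `D`, `R`, `T` (and optionally `m`, `n_loci`,
#'   `alleles_per_locus`).
#' @param seed integer seed; the population is a deterministic function of
#'   `spec`, `seed` and `distinctness`.
#' @param distinctness `"auto"`, `"all_loci"` or `"at_least_one"`.
#' @return a [genotype_matrix()] of `m` samples x `n_loci` loci with no
#'   missing calls.
#' @export
#' @examples
#' g <- make_population(table1_specs(4)[11, ], seed = 1)
#' build_partition(g)$D  # recovers 106 singletons
make_population <- function(spec, seed,
                            distinctness = c("auto", "all_loci",
                                             "at_least_one")) {
  distinctness <- match.arg(distinctness)
  D <- as.integer(spec$D); R <- as.integer(spec$R); T <- as.integer(spec$T)
  stopifnot(length(D) == 1L, length(R) == 1L, length(T) == 1L,
            D >= 0L, R >= 1L, T >= 0L)
  n_loci <- if (!is.null(spec$n_loci)) as.integer(spec$n_loci) else 10L
  n_alleles <- if (!is.null(spec$alleles_per_locus)) {
    as.integer(spec$alleles_per_locus)
  } else 4L
  m <- D + R * T
  if (!is.null(spec$m) && as.integer(spec$m) != m) {
    stop("inconsistent spec: D + R*T = ", m, " but m = ", spec$m)
  }
  n_var <- D + T
  classes <- genotype_classes(c("A", "C", "G", "T")[seq_len(n_alleles)])
  if (distinctness == "auto") {
    distinctness <- if (n_var <= length(classes)) "all_loci"
                    else "at_least_one"
  }
  if (distinctness == "all_loci" && n_var > length(classes)) {
    stop_validity("all_loci distinctness supports at most ",
                  length(classes), " varieties (one genotype class each ",
                  "per locus); spec needs ", n_var,
                  " - use distinctness = \"at_least_one\"")
  }
  variety <- with_seed(seed, {
    if (distinctness == "all_loci") {
      # a distinct class per variety at every locus
      vapply(seq_len(n_loci), function(l) sample(classes, n_var),
             character(n_var))
    } else {
      v <- matrix(sample(classes, n_var * n_loci, replace = TRUE),
                  nrow = n_var)
      # unique genotype vector per variety; collisions are vanishingly
      # rare (10^-10 scale) but resampled for correctness
      repeat {
        dup <- which(duplicated(apply(v, 1L, paste, collapse = " ")))
        if (!length(dup)) break
        v[dup, ] <- sample(classes, length(dup) * n_loci, replace = TRUE)
      }
      v
    }
  })
  variety <- matrix(variety, nrow = n_var, ncol = n_loci)
  copies <- c(rep(1L, D), rep(R, T))
  calls <- variety[rep(seq_len(n_var), copies), , drop = FALSE]
  dimnames(calls) <- list(sprintf("S%03d", seq_len(m)),
                          sprintf("L%02d", seq_len(n_loci)))
  genotype_matrix(calls, marker_type = "SNP")
}

#' Inject missing calls at a fixed per-sample rate
#'
#' Masks calls to emulate genotyping dropout. By default every sample
#' loses the same quota of calls, `round(rate * n_loci)`, at positions
#' drawn uniformly within the sample — missing data created per sample at
#' a fixed proportion. A global mode instead draws
#' `round(rate * m * n_loci)` positions uniformly over the whole grid, as
#' a sensitivity check on the masking model.
#'
#' @param x a [genotype_matrix()].
#' @param rate fraction of calls to mask, in \[0, 1).
#' @param seed integer seed; the mask is deterministic given it.
#' @param mode `"per_sample"` (default) or `"global"`.
#' @return a new `genotype_matrix` with the mask applied; `x` is
#'   unchanged. `rate = 0` returns `x` as is.
#' @export
#' @examples
#' g <- make_population(table1_specs(2)[5, ], seed = 1)
#' sum(is.na(inject_missing(g, 0.3, seed = 9)))  # 3 calls/sample * 206
inject_missing <- function(x, rate, seed,
                           mode = c("per_sample", "global")) {
  stopifnot(inherits(x, "genotype_matrix"))
  mode <- match.arg(mode)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate >= 1) {
    stop("`rate` must lie in [0, 1)")
  }
  if (rate == 0) return(x)
  calls <- unclass(x)
  n_loci <- ncol(calls)
  with_seed(seed, {
    if (mode == "per_sample") {
      k <- round(rate * n_loci)
      for (r in seq_len(nrow(calls))) {
        calls[r, sample.int(n_loci, k)] <- NA_character_
      }
    } else {
      total <- round(rate * length(calls))
      calls[sample.int(length(calls), total)] <- NA_character_
    }
  })
  structure(calls, class = "genotype_matrix",
            marker_type = attr(x, "marker_type"),
            pair_sep = attr(x, "pair_sep"))
}

#' Nested locus subsets of decreasing size
#'
#' Draws one random ordering of the loci and truncates it at each
#' requested size, so every subset contains all smaller ones — the
#' nested-inclusion design used to study how appraisal statistics respond
#' as a marker panel shrinks. Within each subset loci keep their original
#' column order, so a subset of the full panel size is the input matrix
#' itself.
#'
#' @param x a [genotype_matrix()].
#' @param sizes strictly descending subset sizes, each in
#'   \[1, `ncol(x)`\].
#' @param seed integer seed fixing the locus ordering.
#' @return list of [genotype_matrix()] objects, one per size, named by
#'   size.
#' @export
#' @examples
#' chain <- nested_subsets(make_population(table1_specs(3)[9, ], seed = 1),
#'                         sizes = c(8, 4, 2), seed = 11)
#' all(locus_ids(chain[["2"]]) %in% locus_ids(chain[["4"]]))
nested_subsets <- function(x, sizes, seed) {
  stopifnot(inherits(x, "genotype_matrix"))
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || any(is.na(sizes))) {
    stop("`sizes` must be a non-empty integer vector")
  }
  if (any(diff(sizes) >= 0L)) {
    stop("`sizes` must be strictly descending")
  }
  if (sizes[1L] > ncol(x) || sizes[length(sizes)] < 1L) {
    stop("`sizes` must lie within [1, ", ncol(x), "]")
  }
  order <- with_seed(seed, sample(colnames(x)))
  out <- lapply(sizes, function(k) {
    subset_loci(x, colnames(x)[colnames(x) %in% order[seq_len(k)]])
  })
  names(out) <- sizes
  out
}
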