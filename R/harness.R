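index_value <- function(method, x, dm, part, rule, undefined) {
  switch(method,
         p_vdp = p_vdp(part),
         c_vdp = c_vdp(dm, rule, undefined = undefined),
         r_vdp = r_vdp(part),
         tdp = tdp(x))
}

#' Sensitivity curve of an appraisal statistic over ordered populations
#'
#' Evaluates one appraisal statistic on an ordered series of populations
#' (e.g. the 21 populations of a benchmark array, ordered by growing
#' repetition). Discrimination should fall along the series; how evenly
#' and steeply the curve falls is the statistic's discrimination
#' sensitivity, summarised by the OLS slope of value against the 1-based
#' population index.
#'
#' @param populations ordered list of [genotype_matrix()] objects (at
#'   least 2).
#' @param method `"p_vdp"`, `"c_vdp"`, `"r_vdp"` or `"tdp"`.
#' @param rule a [threshold_rule()]. `p_vdp` demands the perfect-match
#'   rule and complete data; a mismatch is a validity error.
#' @param undefined zero-overlap pair policy; see [classify_pair()].
#' @return a `sensitivity_curve`: list with `x` (1-based index), `y`
#'   (values), `method`, `rule` and `slope`.
#' @export
#' @examples
#' pops <- lapply(seq_len(21), function(k)
#'   make_population(table1_specs(4)[k, ], seed = k))
#' sensitivity_curve(pops, "r_vdp")$slope  # -0.0437
sensitivity_curve <- function(populations,
                              method = c("p_vdp", "c_vdp", "r_vdp", "tdp"),
                              rule = threshold_rule("count", 1),
                              undefined = c("error", "same", "different")) {
  method <- match.arg(method)
  undefined <- match.arg(undefined)
  stopifnot(is.list(populations))
  if (length(populations) < 2L) stop("need at least 2 populations")
  y <- vapply(populations, function(g) {
    assert_appraisable(g)
    dm <- if (method %in% c("p_vdp", "c_vdp", "r_vdp")) {
      difference_matrix(g)
    }
    part <- if (method %in% c("p_vdp", "r_vdp")) {
      build_partition(dm, rule, undefined = undefined)
    }
    index_value(method, g, dm, part, rule, undefined)
  }, numeric(1))
  x <- seq_along(y)
  structure(list(x = x, y = y, method = method, rule = rule,
                 slope = ols_slope_xy(x, y)),
            class = "sensitivity_curve")
}

ols_slope_xy <- function(x, y) {
  if (length(y) < 2L) stop("OLS slope needs at least 2 points")
  unname(stats::coef(stats::lm(y ~ x))[2L])
}

#' Ordinary least-squares slope of a sensitivity curve
#'
#' @param curve a [sensitivity_curve()], or a numeric vector of values
#'   (then regressed on `x`, defaulting to the 1-based index).
#' @param x abscissa used when `curve` is a bare numeric vector.
#' @return the OLS slope, per index unit.
#' @export
ols_slope <- function(curve, x = seq_along(curve)) {
  if (inherits(curve, "sensitivity_curve")) {
    return(ols_slope_xy(curve$x, curve$y))
  }
  ols_slope_xy(x, as.numeric(curve))
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("sensitivity_curve: %s over %d populations, slope %.4g\n",
              toupper(gsub("_", "-", x$method)), length(x$y), x$slope))
  print(data.frame(index = x$x, value = x$y), row.names = FALSE)
  invisible(x)
}

#' @export
plot.sensitivity_curve <- function(x, ...) {
  plot(x$x, x$y, type = "b", pch = 19,
       xlab = "population index", ylab = "appraisal value",
       main = sprintf("%s (slope %.4f)",
                      toupper(gsub("_", "-", x$method)), x$slope), ...)
  graphics::abline(stats::lm(x$y ~ x$x), lty = 2, col = "grey40")
  invisible(x)
}

#' Threshold sweep over nested locus subsets
#'
#' Grid evaluation of the threshold-sensitive statistics (C-VDP, R-VDP)
#' across variety thresholds and nested subsets of the marker panel. The
#' probability-based statistic is pinned to perfect match and TDP ignores
#' the threshold entirely, so requesting either is a validity error.
#'
#' @param x a [genotype_matrix()].
#' @param methods subset of `"c_vdp"`, `"r_vdp"`.
#' @param M_values minimum-difference thresholds to sweep (count metric).
#' @param subset_sizes strictly descending locus-subset sizes (default:
#'   the full panel only).
#' @param seed integer seed for the nested subset draw.
#' @param undefined zero-overlap pair policy.
#' @return long-format data.frame with columns `n_loci`, `M`, `method`,
#'   `value`.
#' @export
threshold_sweep <- function(x, methods = c("c_vdp", "r_vdp"),
                            M_values = 1:4, subset_sizes = ncol(x),
                            seed = 1L,
                            undefined = c("error", "same", "different")) {
  assert_appraisable(x)
  undefined <- match.arg(undefined)
  bad <- setdiff(methods, c("c_vdp", "r_vdp"))
  if (length(bad)) {
    stop_validity("threshold sweeps apply only to c_vdp and r_vdp (the ",
                  "variety threshold of P-VDP must be perfect match, and ",
                  "TDP does not use a threshold): ",
                  paste(bad, collapse = ", "))
  }
  subsets <- if (length(subset_sizes) == 1L && subset_sizes == ncol(x)) {
    stats::setNames(list(x), ncol(x))
  } else {
    nested_subsets(x, subset_sizes, seed)
  }
  rows <- list()
  for (nm in names(subsets)) {
    dm <- difference_matrix(subsets[[nm]])
    for (M in M_values) {
      rule <- threshold_rule("count", M)
      part <- if ("r_vdp" %in% methods) {
        build_partition(dm, rule, undefined = undefined)
      }
      for (meth in methods) {
        val <- switch(meth, c_vdp = c_vdp(dm, rule, undefined = undefined),
                      r_vdp = r_vdp(part))
        rows[[length(rows) + 1L]] <-
          data.frame(n_loci = as.integer(nm), M = M, method = meth,
                     value = val, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Missing-data stability sweep
#'
#' Masks the panel at each missing rate, evaluates the missing-tolerant
#' statistics over nested locus subsets, and measures each statistic's
#' stability as the Pearson correlation between its series at a given
#' rate and its complete-data (rate 0) series, paired by subset size.
#' Cells whose value is undefined at some rate (e.g. zero-overlap pairs
#' in tiny subsets under the default policy) are `NA` and are dropped
#' pairwise from the correlation. The probability-based statistic cannot
#' be used with missing data and is refused.
#'
#' @param x a [genotype_matrix()] without missing calls.
#' @param rates missing-data rates to test; 0 is prepended when absent.
#' @param methods subset of `"tdp"`, `"c_vdp"`, `"r_vdp"`.
#' @param rule a [threshold_rule()] for the VDP statistics.
#' @param seed integer seed; masks and subset draw derive from it.
#' @param subset_sizes strictly descending locus-subset sizes (default:
#'   full panel down to 1 locus).
#' @param undefined zero-overlap pair policy; the default `"error"`
#'   records `NA` for affected cells instead of failing the sweep.
#' @return a `missing_sweep`: list with `table` (long data.frame: `rate`,
#'   `n_loci`, `method`, `value`) and `correlations` (data.frame:
#'   `method`, `rate`, `r`).
#' @export
missing_sweep <- function(x, rates = seq(0, 0.5, by = 0.1),
                          methods = c("tdp", "c_vdp", "r_vdp"),
                          rule = threshold_rule("count", 1), seed = 1L,
                          subset_sizes = seq(ncol(x), 1L),
                          undefined = c("error", "same", "different")) {
  assert_appraisable(x)
  undefined <- match.arg(undefined)
  bad <- setdiff(methods, c("tdp", "c_vdp", "r_vdp"))
  if (length(bad)) {
    stop_validity("P-VDP cannot be used for loci combinations with ",
                  "missing data; allowed methods are tdp, c_vdp, r_vdp (",
                  "got: ", paste(bad, collapse = ", "), ")")
  }
  if (!0 %in% rates) rates <- c(0, rates)
  rates <- sort(unique(rates))
  rows <- list()
  for (ri in seq_along(rates)) {
    masked <- inject_missing(x, rates[ri], seed = seed + ri)
    subsets <- nested_subsets(masked, subset_sizes, seed)
    for (nm in names(subsets)) {
      g <- subsets[[nm]]
      dm <- if (any(c("c_vdp", "r_vdp") %in% methods)) {
        difference_matrix(g)
      }
      for (meth in methods) {
        val <- tryCatch({
          part <- if (meth == "r_vdp") {
            build_partition(dm, rule, undefined = undefined)
          }
          index_value(meth, g, dm, part, rule, undefined)
        }, vdp_validity_error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <-
          data.frame(rate = rates[ri], n_loci = as.integer(nm),
                     method = meth, value = val, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  cors <- do.call(rbind, lapply(methods, function(meth) {
    base <- tab[tab$method == meth & tab$rate == 0, ]
    base <- base[order(base$n_loci), ]
    data.frame(method = meth, rate = rates, r = vapply(rates, function(rt) {
      cur <- tab[tab$method == meth & tab$rate == rt, ]
      cur <- cur[order(cur$n_loci), ]
      stopifnot(identical(cur$n_loci, base$n_loci))
      ok <- !is.na(cur$value) & !is.na(base$value)
      if (sum(ok) < 2L || stats::sd(cur$value[ok]) == 0 ||
          stats::sd(base$value[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(base$value[ok], cur$value[ok])
    }, numeric(1)), stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, correlations = cors, rule = rule,
                 seed = seed), class = "missing_sweep")
}

#' @export
print.missing_sweep <- function(x, ...) {
  cat("missing_sweep: stability vs the complete-data series\n")
  wide <- stats::reshape(x$correlations, idvar = "method",
                         timevar = "rate", direction = "wide")
  names(wide) <- sub("^r\\.", "rate ", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}
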