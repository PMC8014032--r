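#' Appraise a loci combination's variety discrimination power
#'
#' One-stop appraisal of a genotype matrix: computes the pairwise
#' difference matrix once, builds the repeated-group partition under the
#' threshold rule, and evaluates the requested statistics. P-VDP is
#' skipped (with a note) rather than failing when its validity conditions
#' — perfect-match threshold and complete data — do not hold.
#'
#' @param x a [genotype_matrix()] with at least 2 samples.
#' @param methods statistics to compute, a subset of `"p_vdp"`, `"c_vdp"`,
#'   `"r_vdp"`, `"tdp"`.
#' @param rule a [threshold_rule()].
#' @param undefined policy for zero-overlap pairs; see [classify_pair()].
#' @return an object of class `vdp`: the index values plus the partition
#'   and provenance (rule, m, number of loci). `coef()` extracts the named
#'   value vector; `summary()` adds the category table.
#' @export
#' @examples
#' g <- make_population(table1_specs(3)[21, ], seed = 2)
#' fit <- vdp(g)
#' coef(fit)
vdp <- function(x, methods = c("p_vdp", "c_vdp", "r_vdp", "tdp"),
                rule = threshold_rule("count", 1),
                undefined = c("error", "same", "different")) {
  assert_appraisable(x)
  undefined <- match.arg(undefined)
  methods <- match.arg(methods, several.ok = TRUE)
  dm <- difference_matrix(x)
  part <- build_partition(dm, rule, undefined = undefined)
  values <- numeric(0)
  notes <- character(0)
  for (meth in methods) {
    val <- switch(meth,
      p_vdp = tryCatch(p_vdp(part), vdp_validity_error = function(e) {
        notes <<- c(notes, paste0("p_vdp skipped: ", conditionMessage(e)))
        NA_real_
      }),
      c_vdp = c_vdp(dm, rule, undefined = undefined),
      r_vdp = r_vdp(part),
      tdp = tdp(x))
    values[meth] <- val
  }
  structure(list(values = values, partition = part, rule = rule,
                 m = nrow(x), n_loci = ncol(x), notes = notes,
                 marker_type = attr(x, "marker_type")),
            class = "vdp")
}

#' @export
print.vdp <- function(x, digits = 6, ...) {
  cat(sprintf("Variety discrimination power: %d samples, %d %s loci\n",
              x$m, x$n_loci, x$marker_type))
  cat(sprintf("  rule: different variety when %s >= %s\n",
              switch(x$rule$metric, count = "differing loci",
                     percentage = "fraction differing"),
              format(x$rule$M)))
  lbl <- c(p_vdp = "P-VDP", c_vdp = "C-VDP", r_vdp = "R-VDP", tdp = "TDP")
  for (meth in names(x$values)) {
    cat(sprintf("  %-5s = %s\n", lbl[[meth]],
                format(x$values[[meth]], digits = digits)))
  }
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' @export
coef.vdp <- function(object, ...) object$values

#' @export
summary.vdp <- function(object, ...) {
  structure(list(fit = object, tab = tabulate_partition(object$partition)),
            class = "summary.vdp")
}

#' @export
print.summary.vdp <- function(x, ...) {
  print(x$fit)
  tab <- x$tab
  cat(sprintf("  repeated groups: t = %d (D = %d singletons, p = %d ",
              tab$t, tab$D, tab$p))
  cat("multi-sample categories)\n")
  cat("  category table (R : T): ",
      paste(sprintf("%d:%d", tab$categories$R, tab$categories$T),
            collapse = "  "), "\n")
  invisible(x)
}
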