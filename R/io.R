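#' Describe the layout of a delimited genotype table
#'
#' Genotype exports from SSR capillary-electrophoresis and SNP (e.g. KASP)
#' platforms are delimited text with one row per sample, but differ in how a
#' diploid call is laid out. Two layouts are supported:
#' \describe{
#'   \item{`"single"`}{one column per locus, alleles joined by `pair_sep`
#'     (default `"155/161"` style);}
#'   \item{`"two_column"`}{two adjacent columns per locus, one allele each,
#'     with the locus id repeated in the header for both columns.}
#' }
#' A call is missing when, in the `"single"` layout, the cell equals
#' `missing_code`, or, in the `"two_column"` layout, either allele cell
#' equals `missing_code` or is empty.
#'
#' @param delimiter field separator (default tab).
#' @param missing_code string marking a missing allele/call (default `"NA"`).
#' @param pair_sep allele separator within a call for the `"single"` layout.
#' @param layout `"single"` or `"two_column"`.
#' @return a `genotype_dialect` list used by [read_genotypes()] and
#'   [write_genotypes()].
#' @export
genotype_dialect <- function(delimiter = "\t", missing_code = "NA",
                             pair_sep = "/",
                             layout = c("single", "two_column")) {
  layout <- match.arg(layout)
  stopifnot(nzchar(delimiter), nzchar(missing_code), nzchar(pair_sep))
  structure(list(delimiter = delimiter, missing_code = missing_code,
                 pair_sep = pair_sep, layout = layout),
            class = "genotype_dialect")
}

#' Read a genotype matrix from delimited text
#'
#' The first header field names the sample-id column; the remaining header
#' fields name the loci (repeated in consecutive pairs for the
#' `"two_column"` layout). Ragged rows, duplicate ids and unparseable calls
#' raise a format error naming the offending row or column.
#'
#' @param path file path of the delimited table.
#' @param dialect a [genotype_dialect()].
#' @param marker_type `"SNP"` or `"SSR"`, stored on the result.
#' @return a [genotype_matrix()].
#' @export
#' @examples
#' g <- make_population(table1_specs(2)[21, ], seed = 7)
#' f <- tempfile(fileext = ".tsv")
#' write_genotypes(g, f)
#' identical(unclass(read_genotypes(f)), unclass(g))
read_genotypes <- function(path, dialect = genotype_dialect(),
                           marker_type = c("SNP", "SSR")) {
  marker_type <- match.arg(marker_type)
  stopifnot(inherits(dialect, "genotype_dialect"))
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop_format(path, ": empty file, header expected")
  fields <- strsplit(lines, dialect$delimiter, fixed = TRUE)
  header <- fields[[1L]]
  widths <- lengths(fields)
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1L]
    stop_format(path, ": ragged row ", bad, " (", widths[bad],
                " fields, header has ", length(header), ")")
  }
  body <- fields[-1L]
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_format(path, ": duplicate sample id ",
                dQuote(ids[duplicated(ids)][1L]))
  }
  loci_header <- header[-1L]

  if (dialect$layout == "single") {
    loci <- loci_header
    cells <- do.call(rbind, lapply(body, function(f) f[-1L]))
    if (is.null(cells) || length(loci) == 0L) {
      cells <- matrix(character(), nrow = length(ids), ncol = length(loci))
    }
  } else {
    if (length(loci_header) %% 2L != 0L) {
      stop_format(path, ": two_column layout needs an even number of ",
                  "allele columns, got ", length(loci_header))
    }
    odd <- seq(1L, length(loci_header), by = 2L)
    if (!all(loci_header[odd] == loci_header[odd + 1L])) {
      stop_format(path, ": two_column header must repeat each locus id ",
                  "in adjacent columns")
    }
    loci <- loci_header[odd]
    cells <- matrix(NA_character_, nrow = length(ids), ncol = length(loci))
    for (r in seq_along(body)) {
      a1 <- body[[r]][1L + odd]
      a2 <- body[[r]][2L + odd]
      miss <- a1 == dialect$missing_code | a2 == dialect$missing_code |
        !nzchar(a1) | !nzchar(a2)
      cells[r, !miss] <- paste(a1[!miss], a2[!miss], sep = dialect$pair_sep)
    }
  }
  if (anyDuplicated(loci)) {
    stop_format(path, ": duplicate locus id ",
                dQuote(loci[duplicated(loci)][1L]))
  }
  if (dialect$layout == "single" && length(loci)) {
    # a cell is missing when it equals the missing code outright or when
    # either allele field carries the missing code
    esc <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
    half_missing <- grepl(paste0("(^|", esc(dialect$pair_sep), ")",
                                 esc(dialect$missing_code),
                                 "($|", esc(dialect$pair_sep), ")"),
                          cells)
    cells[half_missing | cells == dialect$missing_code] <- NA_character_
  }
  dimnames(cells) <- list(ids, loci)
  genotype_matrix(cells, marker_type = marker_type,
                  pair_sep = dialect$pair_sep)
}

#' Write a genotype matrix as delimited text
#'
#' Allele pairs are emitted in canonical sorted order and missing calls as
#' the dialect's missing code, so a written file read back with the same
#' dialect reproduces the matrix exactly.
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @param dialect a [genotype_dialect()].
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, dialect = genotype_dialect()) {
  stopifnot(inherits(x, "genotype_matrix"),
            inherits(dialect, "genotype_dialect"))
  calls <- unclass(x)
  if (dialect$layout == "single") {
    header <- c("sample_id", colnames(calls))
    body <- calls
    body[is.na(body)] <- dialect$missing_code
    if (attr(x, "pair_sep") != dialect$pair_sep) {
      body[] <- gsub(attr(x, "pair_sep"), dialect$pair_sep, body,
                     fixed = TRUE)
    }
    rows <- apply(cbind(rownames(calls), body), 1L, paste,
                  collapse = dialect$delimiter)
  } else {
    header <- c("sample_id", rep(colnames(calls), each = 2L))
    rows <- vapply(seq_len(nrow(calls)), function(r) {
      cells <- calls[r, ]
      parts <- rep(dialect$missing_code, 2L * length(cells))
      ok <- which(!is.na(cells))
      if (length(ok)) {
        al <- strsplit(cells[ok], attr(x, "pair_sep"), fixed = TRUE)
        parts[2L * ok - 1L] <- vapply(al, `[[`, character(1), 1L)
        parts[2L * ok] <- vapply(al, `[[`, character(1), 2L)
      }
      paste(c(rownames(calls)[r], parts), collapse = dialect$delimiter)
    }, character(1))
    if (nrow(calls) == 0L) rows <- character()
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = dialect$delimiter), rows), con)
  invisible(path)
}
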