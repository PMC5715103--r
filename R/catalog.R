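#' Parse RepeatMasker `.out` annotation output into an STR catalogue
#'
#' Reads the standard RepeatMasker `.out` dialect (two header lines and one
#' blank line, then whitespace-delimited columns: SW score, %div, %del,
#' %ins, query sequence, begin, end, (left), strand, repeat name,
#' repeat class/family, ...). Rows whose class/family is not in
#' `keep_classes` are skipped. Simple-repeat names of the form
#' `"(MOTIF)n"` yield the repeat motif; rows whose motif contains
#' characters outside A/C/G/T (RepeatMasker occasionally emits ambiguity
#' codes) are skipped with a warning.
#'
#' RepeatMasker coordinates are 1-based inclusive; the catalogue is
#' returned in 0-based half-open convention. A strand value of `"C"`
#' (RepeatMasker's complement marker) is mapped to `"-"`.
#'
#' @param path Path to a `.out` file (plain text or gzip), or a character
#'   vector of lines via `lines`.
#' @param lines Optional character vector of raw `.out` lines; overrides
#'   `path`.
#' @param keep_classes Character vector of repeat class/family labels to
#'   retain. Default `"Simple_repeat"`, the RepeatMasker label for
#'   microsatellites.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `motif`, `period`, `strand`, `pct_div`, `pct_del`,
#'   `pct_ins`, `repeat_class`.
#' @examples
#' out <- c("   SW   perc perc perc  query ...", "score  div. del. ins.",
#'          "",
#'          "  463 0.0 0.0 0.0 chr2 74144317 74144336 (168000000) + (TAAA)n Simple_repeat 1 20 (0) 1")
#' parse_repeatmasker(lines = out)
#' @export
parse_repeatmasker <- function(path = NULL, lines = NULL,
                               keep_classes = "Simple_repeat") {
  if (is.null(lines)) {
    stopifnot(!is.null(path))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
  }
  if (length(lines) == 0L) {
    return(empty_catalog())
  }
  # header: RepeatMasker emits 2 header lines + 1 blank; be tolerant and
  # drop any leading lines that do not start with a numeric SW score
  first_tok <- vapply(strsplit(trimws(lines), "\\s+"),
                      function(x) if (length(x)) x[[1]] else "", "")
  is_data <- grepl("^[0-9]+$", first_tok)
  line_no <- seq_along(lines)
  # everything after the first data line must be data or blank
  lines <- lines[is_data]
  line_no <- line_no[is_data]
  if (length(lines) == 0L) return(empty_catalog())

  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  bad <- which(nf < 11L)
  if (length(bad)) {
    stop(sprintf("malformed RepeatMasker row at line %d: expected >= 11 columns, got %d",
                 line_no[bad[1]], nf[bad[1]]))
  }
  col <- function(i) vapply(toks, `[[`, "", i)
  pct_div <- suppressWarnings(as.numeric(col(2)))
  pct_del <- suppressWarnings(as.numeric(col(3)))
  pct_ins <- suppressWarnings(as.numeric(col(4)))
  begin   <- suppressWarnings(as.numeric(col(6)))
  end     <- suppressWarnings(as.numeric(col(7)))
  bad <- which(is.na(pct_div) | is.na(pct_del) | is.na(pct_ins) |
                 is.na(begin) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed RepeatMasker row at line %d: non-numeric divergence or coordinate field",
                 line_no[bad[1]]))
  }
  repeat_class <- col(11)
  keep <- repeat_class %in% keep_classes
  if (!any(keep)) return(empty_catalog())

  name <- col(10)[keep]
  motif <- toupper(sub("^\\(([A-Za-z]+)\\)n$", "\\1", name))
  # names not in (MOTIF)n form keep their raw label and will fail the
  # ACGT check below
  ok <- grepl("^[ACGT]+$", motif)
  if (any(!ok)) {
    warning(sprintf("skipped %d record(s) with non-ACGT motif (e.g. %s)",
                    sum(!ok), name[!ok][1]))
  }
  strand <- col(9)[keep]
  strand[strand == "C"] <- "-"
  out <- data.frame(
    chrom = col(5)[keep],
    start = begin[keep] - 1,      # 1-based inclusive -> 0-based half-open
    end = end[keep],
    motif = motif,
    period = nchar(motif),
    strand = strand,
    pct_div = pct_div[keep],
    pct_del = pct_del[keep],
    pct_ins = pct_ins[keep],
    repeat_class = repeat_class[keep],
    stringsAsFactors = FALSE
  )
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_catalog <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             motif = character(), period = integer(), strand = character(),
             pct_div = numeric(), pct_del = numeric(), pct_ins = numeric(),
             repeat_class = character(), stringsAsFactors = FALSE)
}

#' GC content of a repeat motif, in percent
#'
#' @param motif Character vector of motifs over A/C/G/T.
#' @return Numeric vector: `100 * (G + C) / length` per motif.
#' @examples
#' gc_percent(c("TG", "TAAA", "CAAAA"))  # 50, 0, 20
#' @export
gc_percent <- function(motif) {
  if (any(!nzchar(motif)) || any(is.na(motif))) {
    stop("empty motif")
  }
  if (any(!grepl("^[ACGT]+$", motif))) {
    stop("motif must be non-empty over A/C/G/T")
  }
  gc <- nchar(gsub("[AT]", "", motif))
  100 * gc / nchar(motif)
}

#' Summarize an STR catalogue
#'
#' Tallies repeat classes, motif periods and binned motif GC content.
#' GC bins are half-open `[k*w, (k+1)*w)` keyed by bin start.
#'
#' @param catalog A catalogue `data.frame` from [parse_repeatmasker()].
#' @param gc_bin_width Width of the GC-percent bins (default 10).
#' @return A list with `class_counts`, `period_counts`, `gc_histogram`
#'   (named integer vectors) and `n_total`.
#' @export
summarize_catalog <- function(catalog, gc_bin_width = 10) {
  stopifnot(nrow(catalog) > 0, gc_bin_width > 0)
  gc <- gc_percent(catalog$motif)
  bin <- floor(gc / gc_bin_width) * gc_bin_width
  class_counts <- table(catalog$repeat_class)
  list(
    class_counts = stats::setNames(as.integer(class_counts), names(class_counts)),
    period_counts = tab_int(catalog$period),
    gc_histogram = tab_int(bin),
    n_total = nrow(catalog)
  )
}

tab_int <- function(x) {
  t <- table(x)
  stats::setNames(as.integer(t), names(t))
}

#' Filter an STR catalogue by period and sequence divergence
#'
#' Mono-nucleotide repeats are dropped first (capillary platforms cannot
#' resolve 1-bp allele differences), then loci failing the divergence rule.
#' Mode `"any"` excludes a locus when any of `pct_div`, `pct_del`,
#' `pct_ins` strictly exceeds `max_pct`; mode `"sum"` excludes when their
#' sum does.
#'
#' @param catalog A catalogue `data.frame`.
#' @param exclude_mono Drop period-1 loci first (default `TRUE`).
#' @param max_pct Divergence threshold in percent (default 5).
#' @param combine `"any"` (default) or `"sum"`.
#' @return A list with `catalog` (the survivors) and `report`, a list of
#'   `n_input`, `n_excluded_mono`, `n_excluded_divergent`, `n_kept` that
#'   always partitions the input.
#' @export
filter_catalog <- function(catalog, exclude_mono = TRUE, max_pct = 5,
                           combine = c("any", "sum")) {
  combine <- match.arg(combine)
  n_input <- nrow(catalog)
  mono <- if (exclude_mono) catalog$period == 1L else rep(FALSE, n_input)
  rest <- catalog[!mono, , drop = FALSE]
  div_fail <- if (combine == "any") {
    rest$pct_div > max_pct | rest$pct_del > max_pct | rest$pct_ins > max_pct
  } else {
    rest$pct_div + rest$pct_del + rest$pct_ins > max_pct
  }
  kept <- rest[!div_fail, , drop = FALSE]
  rownames(kept) <- NULL
  list(
    catalog = kept,
    report = list(
      n_input = n_input,
      n_excluded_mono = sum(mono),
      n_excluded_divergent = sum(div_fail),
      n_kept = nrow(kept)
    )
  )
}

#' Write / read a filtered catalogue as BED-like TSV
#'
#' Columns: chrom, start, end, motif, period, pct_div, pct_del, pct_ins,
#' strand (and repeat_class). Coordinates stay 0-based half-open.
#'
#' @param catalog A catalogue `data.frame`.
#' @param path Output file.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          motif = "character",
                                          strand = "character"))
  out
}
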