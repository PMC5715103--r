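#' Read-level filter for STR expression quantification
#'
#' Keeps only alignments usable for STR read counting: properly paired
#' (SAM flag bit 0x2 set), not secondary (0x100), not a PCR/optical
#' duplicate (0x400), not supplementary/chimeric (0x800), and uniquely
#' mapped (`alignment_hits == 1`, from an HI/NH-style tag).
#'
#' @param flag Integer vector of SAM bitwise flags.
#' @param alignment_hits Integer vector of reported alignments per read.
#' @return Logical vector.
#' @examples
#' keep_alignment(99, 1)    # TRUE: paired, proper pair, unique
#' keep_alignment(1123, 1)  # FALSE: duplicate bit set
#' @export
keep_alignment <- function(flag, alignment_hits) {
  stopifnot(all(flag >= 0), all(alignment_hits >= 1))
  bit_set <- function(f, b) bitwAnd(as.integer(f), b) != 0L
  bit_set(flag, 0x2L) &
    !bit_set(flag, 0x100L) &
    !bit_set(flag, 0x400L) &
    !bit_set(flag, 0x800L) &
    alignment_hits == 1L
}

#' Parse SAM records into the fields the read filter needs
#'
#' Minimal SAM text reader: extracts the bitwise FLAG and the reported
#' alignment count from an `HI:i:` or `NH:i:` tag (whichever is present;
#' `NH` preferred as the conventional total; absent tags count as 1).
#' Header lines (`@`) are ignored; headerless fixtures are fine. Only the
#' two fields used by [keep_alignment()] are returned; full SAM/BAM work
#' should go through Rsamtools on binary files.
#'
#' @param path SAM file path.
#' @return `data.frame` with `qname`, `flag`, `alignment_hits`.
#' @export
read_sam_lite <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  toks <- strsplit(lines, "\t")
  bad <- which(lengths(toks) < 11L)
  if (length(bad)) stop(sprintf("malformed SAM record at line %d", bad[1]))
  tag_val <- function(x, tag) {
    hit <- grep(paste0("^", tag, ":i:"), x, value = TRUE)
    if (length(hit)) as.integer(sub(".*:", "", hit[1])) else NA_integer_
  }
  hits <- vapply(toks, function(x) {
    v <- tag_val(x, "NH")
    if (is.na(v)) v <- tag_val(x, "HI")
    if (is.na(v)) 1L else v
  }, 1L)
  data.frame(
    qname = vapply(toks, `[[`, "", 1),
    flag = as.integer(vapply(toks, `[[`, "", 2)),
    alignment_hits = hits,
    stringsAsFactors = FALSE
  )
}

#' Parse a lobSTR-style ALLREADS field
#'
#' The ALLREADS format field lists each observed allele and its supporting
#' read count as semicolon-separated `allele|count` pairs, e.g.
#' `"-2|10;0|25;2|3"`. Allele labels are integers (bp offsets from the
#' reference allele, or repeat counts, depending on the caller
#' configuration); the pipeline carries them through unchanged.
#'
#' @param field Character scalar; `"."` or `""` mean no reads.
#' @return Named integer vector (names = allele labels, values = reads).
#' @examples
#' parse_allreads("-2|10;0|25;2|3")
#' @export
parse_allreads <- function(field) {
  stopifnot(length(field) == 1L)
  if (is.na(field) || field == "." || field == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  pairs <- strsplit(field, ";", fixed = TRUE)[[1]]
  ok <- grepl("^-?[0-9]+\\|[0-9]+$", pairs)
  if (any(!ok)) {
    stop(sprintf("malformed ALLREADS token: '%s'", pairs[!ok][1]))
  }
  parts <- strsplit(pairs, "|", fixed = TRUE)
  stats::setNames(as.integer(vapply(parts, `[[`, "", 2)),
                  vapply(parts, `[[`, "", 1))
}

#' Format an allele-read mapping back to ALLREADS syntax
#' @param reads Named integer vector as returned by [parse_allreads()].
#' @return Character scalar (`"."` for empty).
#' @export
format_allreads <- function(reads) {
  if (!length(reads)) return(".")
  paste(sprintf("%s|%d", names(reads), as.integer(reads)), collapse = ";")
}

#' Drop weakly supported STR alleles
#'
#' Alleles supported by fewer than `min_reads` reads are removed; a locus
#' is considered expressed in a sample only if at least one allele
#' survives. Idempotent.
#'
#' @param reads Named integer vector allele -> read count.
#' @param min_reads Minimum reads per allele (default 10).
#' @return Named integer vector of surviving alleles.
#' @export
filter_alleles <- function(reads, min_reads = 10L) {
  stopifnot(min_reads >= 1L)
  reads[reads >= min_reads]
}

#' Normalize STR read counts against sequencing depth
#'
#' `"fpkm"`: reads * 1e9 / (locus_length_bp * total_mapped_reads);
#' `"rpm"`: reads * 1e6 / total_mapped_reads. The FPKM length term is the
#' STR locus span.
#'
#' @param reads Total surviving reads at the locus (post
#'   [filter_alleles()]).
#' @param total_mapped_reads Total mapped reads in the sample (> 0).
#' @param locus_length_bp Locus span in bp (required for fpkm).
#' @param scheme `"fpkm"` (default) or `"rpm"`.
#' @return Numeric expression value.
#' @export
normalize_expression <- function(reads, total_mapped_reads,
                                 locus_length_bp = NULL,
                                 scheme = c("fpkm", "rpm")) {
  scheme <- match.arg(scheme)
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
  if (scheme == "fpkm") {
    if (is.null(locus_length_bp) || any(locus_length_bp <= 0)) {
      stop("locus_length_bp must be > 0 for fpkm")
    }
    reads * 1e9 / (as.numeric(locus_length_bp) * as.numeric(total_mapped_reads))
  } else {
    reads * 1e6 / total_mapped_reads
  }
}

#' Distinct alleles observed for a locus across samples
#'
#' @param profiles A list of named integer vectors (already
#'   allele-filtered), one per sample/condition.
#' @return Integer vector of distinct allele labels, ascending.
#' @export
observed_alleles <- function(profiles) {
  labs <- unlist(lapply(profiles, names), use.names = FALSE)
  sort(unique(as.integer(labs)))
}

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-[(target - housekeeping)_treated - (target - housekeeping)_control]`
#' with a single housekeeping gene (e.g. 18S rRNA).
#'
#' @param target_treated,hk_treated Ct of target and housekeeping gene in
#'   the treated/tumor sample.
#' @param target_control,hk_control Same for the control sample.
#' @return Fold change (numeric).
#' @export
rel_expr_ddct <- function(target_treated, hk_treated,
                          target_control, hk_control) {
  cts <- c(target_treated, hk_treated, target_control, hk_control)
  if (length(hk_treated) != 1L || length(hk_control) != 1L) {
    stop("delta-delta-Ct uses exactly one housekeeping gene; use rel_expr_dct for geometric-mean normalization")
  }
  stopifnot(all(is.finite(cts)), all(cts > 0))
  ddct <- (target_treated - hk_treated) - (target_control - hk_control)
  2^(-ddct)
}

#' Relative expression by the delta-Ct method
#'
#' `2^-(target - geomean(housekeeping))`; with several housekeeping genes
#' (e.g. HPRT1 and RPL32) the geometric mean of their Ct values is used.
#'
#' @param target_ct Target Ct.
#' @param hk_cts Numeric vector of housekeeping Cts (length >= 1).
#' @return `2^-dCt` (numeric).
#' @export
rel_expr_dct <- function(target_ct, hk_cts) {
  stopifnot(length(hk_cts) >= 1L, all(is.finite(c(target_ct, hk_cts))),
            all(c(target_ct, hk_cts) > 0))
  geo <- exp(mean(log(hk_cts)))
  2^(-(target_ct - geo))
}

#' Read lobSTR-style VCF calls into per-sample allele-read profiles
#'
#' Expects a VCF with an `ALLREADS` FORMAT key; one profile per
#' (locus, sample). Loci are keyed `CHROM:POS` (1-based as printed).
#'
#' @param path VCF path.
#' @return `data.frame` with `locus_id`, `sample_id`, `allreads` (raw
#'   field); parse per row with [parse_allreads()].
#' @export
read_str_calls <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- grep("^#CHROM", lines, value = TRUE)
  if (!length(hdr)) stop("missing #CHROM header line")
  cols <- strsplit(hdr, "\t")[[1]]
  samples <- cols[-(1:9)]
  lines <- lines[!startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    ar_i <- match("ALLREADS", keys)
    if (is.na(ar_i)) next
    for (j in seq_along(samples)) {
      vals <- strsplit(f[9 + j], ":", fixed = TRUE)[[1]]
      out[[length(out) + 1L]] <- data.frame(
        locus_id = paste0(f[1], ":", f[2]),
        sample_id = samples[j],
        allreads = if (ar_i <= length(vals)) vals[ar_i] else ".",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(locus_id = character(), sample_id = character(),
                      allreads = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
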