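#' Reverse, complement and reverse-complement of a motif
#'
#' @param motif Character scalar or vector over A/C/G/T.
#' @return Character vector of the same length.
#' @keywords internal
#' @export
reverse_motif <- function(motif) {
  vapply(strsplit(motif, ""), function(x) paste(rev(x), collapse = ""), "")
}

#' @rdname reverse_motif
#' @export
complement_motif <- function(motif) {
  chartr("ACGT", "TGCA", motif)
}

#' @rdname reverse_motif
#' @export
revcomp_motif <- function(motif) {
  reverse_motif(complement_motif(motif))
}

#' Equivalence set of a repeat motif
#'
#' Two STR records from different pipelines may report the same repeat on
#' opposite strands or read in opposite directions. Mode `"paper"` treats a
#' motif as equivalent to its reverse and its reverse complement. Mode
#' `"extended"` additionally closes the set under complement and all cyclic
#' rotations of each member (a repeat tract has no privileged phase).
#'
#' @param motif Character scalar over A/C/G/T.
#' @param mode `"paper"` (default) or `"extended"`.
#' @return Character vector of distinct equivalent motifs (includes the
#'   input).
#' @examples
#' motif_equivalents("TG")          # TG, GT, CA
#' motif_equivalents("AT")          # AT, TA
#' @export
motif_equivalents <- function(motif, mode = c("paper", "extended")) {
  mode <- match.arg(mode)
  stopifnot(length(motif) == 1L)
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over A/C/G/T")
  base <- c(motif, reverse_motif(motif), revcomp_motif(motif))
  if (mode == "extended") {
    base <- c(base, complement_motif(motif))
    base <- unique(unlist(lapply(base, rotations_of)))
  }
  unique(base)
}

rotations_of <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(m, k + 1L, n), substr(m, 1L, k))
  }, "")
}

#' Read a polymorphic-STR call set
#'
#' Accepts a BED-like TSV (`chrom`, `start`, `end`, `motif`,
#' `is_polymorphic`; 0-based half-open) or a VCF whose INFO field carries
#' the motif (`MOTIF=` key, configurable) and a polymorphic flag key
#' (default `POLY`, flag-style: present means polymorphic). VCF `POS` is
#' 1-based; an `END` INFO key, if present, gives the 1-based inclusive end,
#' otherwise the REF allele length defines the span.
#'
#' @param path File path. Format chosen by extension (`.vcf` / `.vcf.gz`
#'   vs anything else = TSV).
#' @param poly_key INFO key marking a polymorphic call (VCF only).
#' @param motif_key INFO key carrying the motif (VCF only).
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open),
#'   `motif`, `is_polymorphic`.
#' @export
read_callset <- function(path, poly_key = "POLY", motif_key = "MOTIF") {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), motif = character(),
                        is_polymorphic = logical()))
    }
    toks <- strsplit(lines, "\t")
    chrom <- vapply(toks, `[[`, "", 1)
    pos <- as.numeric(vapply(toks, `[[`, "", 2))
    ref <- vapply(toks, `[[`, "", 4)
    info <- vapply(toks, `[[`, "", 8)
    get_info <- function(key) {
      m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
      has <- grepl(paste0("(^|;)", key, "(=|;|$)"), info)
      val <- rep(NA_character_, length(info))
      idx <- grepl("=", m)
      val[has & grepl(paste0("(^|;)", key, "="), info)] <-
        sub(".*=", "", m[idx])
      list(has = has, val = val)
    }
    mot <- get_info(motif_key)
    endi <- get_info("END")
    end1 <- ifelse(is.na(endi$val), pos + nchar(ref) - 1, as.numeric(endi$val))
    poly <- get_info(poly_key)$has
    data.frame(chrom = chrom, start = pos - 1, end = end1,
               motif = toupper(mot$val), is_polymorphic = poly,
               stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character",
                                     motif = "character"))
  }
}

#' Cross-match an STR catalogue against a polymorphic call set
#'
#' A catalogue locus is *matched* when at least one call on the same
#' chromosome overlaps it by at least `min_overlap` bp and the two motifs'
#' equivalence sets (see [motif_equivalents()]) intersect. When several
#' calls satisfy both conditions, attributes are transferred from the call
#' with the largest overlap, ties broken by smaller call start.
#'
#' Both inputs must be 0-based half-open on the same assembly; mixed
#' conventions are undetectable by construction.
#'
#' @param catalog Catalogue `data.frame` (`chrom`, `start`, `end`,
#'   `motif`).
#' @param callset Call-set `data.frame` (`chrom`, `start`, `end`, `motif`,
#'   `is_polymorphic`).
#' @param mode Motif-equivalence mode passed to [motif_equivalents()].
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return `data.frame` with one row per catalogue locus: `locus_id`
#'   (row index as `chrom:start-end`), `matched`, `matched_polymorphic`,
#'   `overlap_bp`.
#' @export
cross_match <- function(catalog, callset, mode = c("paper", "extended"),
                        min_overlap = 1L) {
  mode <- match.arg(mode)
  locus_id <- sprintf("%s:%d-%d", catalog$chrom,
                      as.integer(catalog$start), as.integer(catalog$end))
  ans <- data.frame(locus_id = locus_id,
                    matched = FALSE, matched_polymorphic = FALSE,
                    overlap_bp = 0L, stringsAsFactors = FALSE)
  if (nrow(catalog) == 0L || nrow(callset) == 0L) {
    if (nrow(catalog) > 0L) warning("no catalogue locus matched any call")
    return(ans)
  }
  # half-open -> IRanges 1-based inclusive: [start+1, end]
  g_cat <- GenomicRanges::GRanges(catalog$chrom,
                                  IRanges::IRanges(catalog$start + 1, catalog$end))
  g_call <- GenomicRanges::GRanges(callset$chrom,
                                   IRanges::IRanges(callset$start + 1, callset$end))
  hits <- GenomicRanges::findOverlaps(g_cat, g_call,
                                      minoverlap = as.integer(min_overlap))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi)) {
    # motif equivalence on the hit pairs only
    eq_cache <- new.env(parent = emptyenv())
    equiv <- function(m) {
      if (is.null(eq_cache[[m]])) eq_cache[[m]] <- motif_equivalents(m, mode)
      eq_cache[[m]]
    }
    ok <- vapply(seq_along(qi), function(k) {
      any(equiv(catalog$motif[qi[k]]) %in% equiv(callset$motif[si[k]]))
    }, TRUE)
    qi <- qi[ok]; si <- si[ok]
  }
  if (length(qi)) {
    ov <- pmin(catalog$end[qi], callset$end[si]) -
      pmax(catalog$start[qi], callset$start[si])
    # best call per locus: largest overlap, then smallest call start
    ord <- order(qi, -ov, callset$start[si])
    qi <- qi[ord]; si <- si[ord]; ov <- ov[ord]
    first <- !duplicated(qi)
    ans$matched[qi[first]] <- TRUE
    ans$overlap_bp[qi[first]] <- as.integer(ov[first])
    ans$matched_polymorphic[qi[first]] <- callset$is_polymorphic[si[first]]
  }
  if (!any(ans$matched)) warning("no catalogue locus matched any call")
  ans
}

#' Summarize a cross-match annotation
#'
#' @param annotations Output of [cross_match()].
#' @return A list: `fraction_matched`, `fraction_polymorphic_among_matched`
#'   (0 with `degenerate = TRUE` when nothing matched), `n`.
#' @export
xref_summary <- function(annotations) {
  n <- nrow(annotations)
  if (n == 0L) stop("empty annotation set")
  n_matched <- sum(annotations$matched)
  degenerate <- n_matched == 0L
  list(
    fraction_matched = n_matched / n,
    fraction_polymorphic_among_matched =
      if (degenerate) 0 else sum(annotations$matched_polymorphic) / n_matched,
    degenerate = degenerate,
    n = n
  )
}
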