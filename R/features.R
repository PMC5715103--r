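#' @name feature_classes
#' @title Genomic feature classes and their precedence
#' @description Classes assigned to STR loci, most specific first:
#' `CDS > UTR5 > UTR3 > intron > promoter > intergenic`. A locus takes the
#' highest-precedence class attained anywhere in its overlap with any
#' transcript; promoter applies only when no transcript overlaps.
#' @keywords internal
NULL

FEATURE_PRECEDENCE <- c(CDS = 6, UTR5 = 5, UTR3 = 4, intron = 3,
                        promoter = 2, intergenic = 1)

#' Read gene models from BED12
#'
#' BED12: chrom, start, end, name, score, strand, thickStart, thickEnd,
#' itemRgb, blockCount, blockSizes, blockStarts. Thick span is the CDS
#' (equal start/end for non-coding transcripts); blocks are exons.
#'
#' @param path BED12 file path.
#' @return Gene-model `data.frame`: `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end`, `exon_starts`,
#'   `exon_ends` (comma-separated absolute 0-based half-open coordinates).
#' @export
read_gene_models_bed12 <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stopifnot(ncol(b) >= 12)
  n <- nrow(b)
  ex_s <- character(n); ex_e <- character(n)
  for (i in seq_len(n)) {
    sizes <- as.numeric(strsplit(sub(",$", "", b[i, 11]), ",")[[1]])
    offs <- as.numeric(strsplit(sub(",$", "", b[i, 12]), ",")[[1]])
    s <- b[i, 2] + offs
    ex_s[i] <- paste(s, collapse = ",")
    ex_e[i] <- paste(s + sizes, collapse = ",")
  }
  data.frame(gene_id = b[, 4], chrom = b[, 1], strand = b[, 6],
             tx_start = b[, 2], tx_end = b[, 3],
             cds_start = b[, 7], cds_end = b[, 8],
             exon_starts = ex_s, exon_ends = ex_e,
             stringsAsFactors = FALSE)
}

parse_exons <- function(model_row) {
  cbind(start = as.numeric(strsplit(model_row$exon_starts, ",")[[1]]),
        end = as.numeric(strsplit(model_row$exon_ends, ",")[[1]]))
}

# overlap length of [a1,a2) and [b1,b2)
ov_len <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))

#' Classify STR loci against gene models
#'
#' Over all transcripts overlapping a locus, the locus is assigned the
#' highest-precedence class attained anywhere in the overlap
#' (CDS > UTR5 > UTR3 > intron). UTR5/UTR3 are the exonic sub-spans 5' and
#' 3' of the CDS, strand-aware. Exons of non-coding transcripts (equal CDS
#' start/end) take `noncoding_exon_class`. A locus overlapping no
#' transcript is `promoter` when it overlaps the strand-aware window of
#' `promoter_bp` immediately upstream of any TSS, else `intergenic`.
#'
#' @param loci `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param models Gene-model `data.frame` as from
#'   [read_gene_models_bed12()].
#' @param promoter_bp Promoter window upstream of the TSS (default 2000).
#' @param noncoding_exon_class Class for exonic overlap with non-coding
#'   transcripts (default `"UTR3"`).
#' @return Character vector of classes, one per locus.
#' @export
classify_loci <- function(loci, models, promoter_bp = 2000,
                          noncoding_exon_class = "UTR3") {
  stopifnot(noncoding_exon_class %in% names(FEATURE_PRECEDENCE))
  n <- nrow(loci)
  out <- character(n)
  missing_chr <- setdiff(unique(loci$chrom), unique(models$chrom))
  if (length(missing_chr)) {
    warning(sprintf("chromosome(s) absent from gene models: %s",
                    paste(missing_chr, collapse = ", ")))
  }
  for (i in seq_len(n)) {
    out[i] <- classify_one(loci$chrom[i], loci$start[i], loci$end[i],
                           models, promoter_bp, noncoding_exon_class)
  }
  out
}

classify_one <- function(chrom, s, e, models, promoter_bp, nc_class) {
  mm <- models[models$chrom == chrom, , drop = FALSE]
  best <- 0
  best_class <- NA_character_
  bump <- function(cl) {
    if (FEATURE_PRECEDENCE[[cl]] > best) {
      best <<- FEATURE_PRECEDENCE[[cl]]; best_class <<- cl
    }
  }
  tx_hit <- FALSE
  for (j in seq_len(nrow(mm))) {
    m <- mm[j, , drop = FALSE]
    if (ov_len(s, e, m$tx_start, m$tx_end) == 0) next
    tx_hit <- TRUE
    ex <- parse_exons(m)
    coding <- m$cds_end > m$cds_start
    exonic_ov <- 0
    for (k in seq_len(nrow(ex))) {
      seg <- ov_len(s, e, ex[k, 1], ex[k, 2])
      if (seg == 0) next
      exonic_ov <- exonic_ov + seg
      if (!coding) {
        bump(nc_class)
      } else {
        if (ov_len(max(s, ex[k, 1]), min(e, ex[k, 2]),
                   m$cds_start, m$cds_end) > 0) bump("CDS")
        # exonic, upstream of CDS start (genomic left)
        left <- ov_len(max(s, ex[k, 1]), min(e, ex[k, 2]),
                       m$tx_start, m$cds_start)
        right <- ov_len(max(s, ex[k, 1]), min(e, ex[k, 2]),
                        m$cds_end, m$tx_end)
        if (left > 0) bump(if (m$strand == "+") "UTR5" else "UTR3")
        if (right > 0) bump(if (m$strand == "+") "UTR3" else "UTR5")
      }
    }
    if (exonic_ov < ov_len(s, e, m$tx_start, m$tx_end)) bump("intron")
  }
  if (!tx_hit) {
    for (j in seq_len(nrow(mm))) {
      m <- mm[j, , drop = FALSE]
      win <- if (m$strand == "+") {
        c(m$tx_start - promoter_bp, m$tx_start)
      } else {
        c(m$tx_end, m$tx_end + promoter_bp)
      }
      if (ov_len(s, e, win[1], win[2]) > 0) {
        bump("promoter")
        break
      }
    }
    if (best == 0) bump("intergenic")
  }
  best_class
}

#' Feature-class composition in percent
#'
#' @param classes Character vector of feature classes.
#' @return Named numeric vector of percentages summing to 100.
#' @export
composition <- function(classes) {
  if (!length(classes)) stop("empty class vector")
  t <- table(classes)
  stats::setNames(100 * as.vector(t) / length(classes), names(t))
}
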