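# Independent brute-force oracles used across the suite. These are written
# against the definitions, not the package internals, so each check has two
# routes to the same answer.

# per-base feature classifier: label every base of [s, e) independently and
# take the highest-precedence label
oracle_precedence <- c(CDS = 6, UTR5 = 5, UTR3 = 4, intron = 3,
                       promoter = 2, intergenic = 1)

# per-base labels of one model over a base-position vector (0 = none)
oracle_model_labels <- function(pos, m, exons, promoter_bp, nc_class) {
  lab <- numeric(length(pos))
  in_tx <- pos >= m$tx_start & pos < m$tx_end
  in_ex <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(exons))) {
    in_ex <- in_ex | (pos >= exons[k, 1] & pos < exons[k, 2])
  }
  in_ex <- in_ex & in_tx
  lab[in_tx & !in_ex] <- oracle_precedence[["intron"]]
  if (m$cds_end <= m$cds_start) {
    lab[in_ex] <- oracle_precedence[[nc_class]]
  } else {
    left <- if (m$strand == "+") "UTR5" else "UTR3"
    right <- if (m$strand == "+") "UTR3" else "UTR5"
    lab[in_ex & pos < m$cds_start] <- oracle_precedence[[left]]
    lab[in_ex & pos >= m$cds_end] <- oracle_precedence[[right]]
    lab[in_ex & pos >= m$cds_start & pos < m$cds_end] <-
      oracle_precedence[["CDS"]]
  }
  in_prom <- if (m$strand == "+") {
    pos >= m$tx_start - promoter_bp & pos < m$tx_start
  } else {
    pos >= m$tx_end & pos < m$tx_end + promoter_bp
  }
  lab[!in_tx & in_prom] <- oracle_precedence[["promoter"]]
  lab
}

oracle_classify <- function(loci, models, promoter_bp = 2000,
                            nc_class = "UTR3") {
  exons <- lapply(seq_len(nrow(models)), function(j) {
    cbind(as.numeric(strsplit(models$exon_starts[j], ",")[[1]]),
          as.numeric(strsplit(models$exon_ends[j], ",")[[1]]))
  })
  vapply(seq_len(nrow(loci)), function(i) {
    pos <- seq(loci$start[i], loci$end[i] - 1)
    best <- rep(0, length(pos))
    for (j in seq_len(nrow(models))) {
      if (models$chrom[j] != loci$chrom[i]) next
      best <- pmax(best, oracle_model_labels(pos, models[j, ], exons[[j]],
                                             promoter_bp, nc_class))
    }
    top <- max(best, oracle_precedence[["intergenic"]])
    names(oracle_precedence)[match(top, oracle_precedence)]
  }, "")
}

# all-pairs O(n*m) cross-match scan
oracle_cross_match <- function(catalog, callset, mode = "paper",
                               min_overlap = 1) {
  n <- nrow(catalog)
  out <- data.frame(
    locus_id = sprintf("%s:%d-%d", catalog$chrom,
                       as.integer(catalog$start), as.integer(catalog$end)),
    matched = FALSE, matched_polymorphic = FALSE, overlap_bp = 0L,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    best_ov <- -1L
    best_start <- NA
    best_poly <- NA
    eq_i <- motif_equivalents(catalog$motif[i], mode)
    for (j in seq_len(nrow(callset))) {
      if (callset$chrom[j] != catalog$chrom[i]) next
      ov <- min(catalog$end[i], callset$end[j]) -
        max(catalog$start[i], callset$start[j])
      if (ov < min_overlap) next
      if (!any(eq_i %in% motif_equivalents(callset$motif[j], mode))) next
      if (ov > best_ov || (ov == best_ov && callset$start[j] < best_start)) {
        best_ov <- ov
        best_start <- callset$start[j]
        best_poly <- callset$is_polymorphic[j]
      }
    }
    if (best_ov >= min_overlap) {
      out$matched[i] <- TRUE
      out$overlap_bp[i] <- as.integer(best_ov)
      out$matched_polymorphic[i] <- best_poly
    }
  }
  out
}

# all-pairs scan, vectorized over calls per locus (same contract as
# oracle_cross_match; usable at 10^3 x 10^3)
oracle_cross_match_fast <- function(catalog, callset, mode = "paper",
                                    min_overlap = 1) {
  umot <- unique(c(catalog$motif, callset$motif))
  eq <- lapply(umot, motif_equivalents, mode = mode)
  names(eq) <- umot
  compat <- outer(umot, umot,
                  Vectorize(function(a, b) any(eq[[a]] %in% eq[[b]])))
  dimnames(compat) <- list(umot, umot)
  n <- nrow(catalog)
  out <- data.frame(
    locus_id = sprintf("%s:%d-%d", catalog$chrom,
                       as.integer(catalog$start), as.integer(catalog$end)),
    matched = FALSE, matched_polymorphic = FALSE, overlap_bp = 0L,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ov <- pmin(catalog$end[i], callset$end) -
      pmax(catalog$start[i], callset$start)
    cand <- which(callset$chrom == catalog$chrom[i] & ov >= min_overlap &
                    compat[catalog$motif[i], callset$motif])
    if (!length(cand)) next
    best <- cand[order(-ov[cand], callset$start[cand])][1]
    out$matched[i] <- TRUE
    out$overlap_bp[i] <- as.integer(ov[best])
    out$matched_polymorphic[i] <- callset$is_polymorphic[best]
  }
  out
}

# random gene models on a small contig, exons tiled inside the tx span
random_gene_models <- function(n_genes, chrom_len = 10000,
                               chroms = c("chrA", "chrB")) {
  rows <- lapply(seq_len(n_genes), function(g) {
    chrom <- sample(chroms, 1)
    tx_s <- sample.int(chrom_len - 900, 1)
    tx_e <- tx_s + sample(200:800, 1)
    n_ex <- sample(1:4, 1)
    cuts <- sort(sample(seq(tx_s, tx_e - 1), 2 * n_ex))
    ex_s <- cuts[seq(1, 2 * n_ex, 2)]
    ex_e <- cuts[seq(2, 2 * n_ex, 2)]
    ex_s[1] <- tx_s; ex_e[n_ex] <- tx_e
    coding <- runif(1) < 0.7
    if (coding) {
      cds <- sort(sample(seq(tx_s, tx_e), 2))
      if (cds[1] == cds[2]) cds[2] <- cds[2] + 1
    } else {
      cds <- c(tx_s, tx_s)
    }
    data.frame(gene_id = sprintf("g%02d", g), chrom = chrom,
               strand = sample(c("+", "-"), 1),
               tx_start = tx_s, tx_end = tx_e,
               cds_start = cds[1], cds_end = cds[2],
               exon_starts = paste(ex_s, collapse = ","),
               exon_ends = paste(ex_e, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# random STR catalogue as a plain data.frame (no .out round trip)
random_catalog <- function(n, chroms = c("chr1", "chr2"),
                           max_pos = 100000) {
  period <- sample(1:6, n, replace = TRUE)
  motif <- vapply(period, function(p) {
    paste(sample(c("A", "C", "G", "T"), p, replace = TRUE), collapse = "")
  }, "")
  start <- sample.int(max_pos, n)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + period * sample(5:20, n, replace = TRUE),
    motif = motif,
    period = period,
    strand = sample(c("+", "-"), n, replace = TRUE),
    pct_div = round(runif(n, 0, 10), 1),
    pct_del = round(runif(n, 0, 10), 1),
    pct_ins = round(runif(n, 0, 10), 1),
    repeat_class = "Simple_repeat",
    stringsAsFactors = FALSE)
}
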