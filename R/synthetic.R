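#' Generate a synthetic RepeatMasker `.out` annotation with known truth
#'
#' Emits a syntactically valid `.out` file (two header lines, one blank
#' line, then 15-column records) whose per-row class, motif, period and
#' divergence values are recorded in a truth table, so
#' [parse_repeatmasker()] and [filter_catalog()] can be checked exactly.
#' Defaults emulate the genome-wide microsatellite annotation: 6.5% of
#' simple repeats are mono-nucleotide, and 42% of the remainder carry
#' more than 5% substitutions, deletions or insertions on some field, so
#' about 58% of the non-mono records survive the standard filters.
#' Divergence values are drawn pre-rounded to one decimal (the `.out`
#' print format), making the parse round-trip exact.
#'
#' @param n_loci Number of records.
#' @param seed Integer seed.
#' @param mono_frac Fraction of mono-nucleotide repeats (default 0.065).
#' @param high_div_frac Fraction of non-mono repeats with a divergence
#'   field above 5% (default 0.421).
#' @param period_mix Named probabilities for periods 2-6 of non-mono
#'   repeats; the default is di-nucleotide-heavy, as in the human genome.
#' @param other_class_frac Fraction of records from a non-simple-repeat
#'   class (`"LINE/L1"`), exercising class filtering (default 0.1).
#' @return A list: `out_lines` (character vector, the `.out` text) and
#'   `truth` (`data.frame` with the generated fields plus `is_mono`,
#'   `is_high_div`, `repeat_class`).
#' @export
gen_catalog <- function(n_loci = 1000L, seed = 1L,
                        mono_frac = 0.065, high_div_frac = 0.421,
                        period_mix = c(`2` = 0.55, `3` = 0.20, `4` = 0.15,
                                       `5` = 0.06, `6` = 0.04),
                        other_class_frac = 0.1) {
  set.seed(seed)
  stopifnot(abs(sum(period_mix) - 1) < 1e-9)
  other <- stats::runif(n_loci) < other_class_frac
  repeat_class <- ifelse(other, "LINE/L1", "Simple_repeat")
  mono <- !other & stats::runif(n_loci) < mono_frac
  period <- integer(n_loci)
  period[mono] <- 1L
  period[!mono] <- as.integer(sample(names(period_mix), sum(!mono),
                                     replace = TRUE, prob = period_mix))
  motif <- vapply(period, random_motif, "")
  high_div <- !other & !mono & stats::runif(n_loci) < high_div_frac
  div <- matrix(round(stats::runif(3 * n_loci, 0, 5), 1), ncol = 3)
  hi_field <- sample.int(3, n_loci, replace = TRUE)
  hi_val <- round(stats::runif(n_loci, 5.1, 30), 1)
  div[cbind(which(high_div), hi_field[high_div])] <- hi_val[high_div]
  chrom <- paste0("chr", sample.int(22, n_loci, replace = TRUE))
  units <- sample(5:30, n_loci, replace = TRUE)
  start <- sample.int(2e8, n_loci)        # 0-based
  end <- start + period * units
  strand <- sample(c("+", "-"), n_loci, replace = TRUE)
  name <- ifelse(other, "L1PA7", sprintf("(%s)n", motif))
  lines <- sprintf(
    "%6d %4.1f %4.1f %4.1f  %s %10d %10d (%d)  %s  %-12s %-14s %d %d (%d) %6d",
    sample(200:3000, n_loci, replace = TRUE),
    div[, 1], div[, 2], div[, 3], chrom, start + 1, end,
    2.5e8 - end, ifelse(strand == "-", "C", "+"), name, repeat_class,
    1L, period * units, 0L, seq_len(n_loci))
  header <- c(
    "   SW   perc perc perc  query                 position in query              matching            repeat                position in repeat",
    "score   div. del. ins.  sequence              begin end          (left)   repeat              class/family          begin end    (left)     ID",
    "")
  truth <- data.frame(chrom = chrom, start = start, end = end,
                      motif = motif, period = period, strand = strand,
                      pct_div = div[, 1], pct_del = div[, 2],
                      pct_ins = div[, 3], repeat_class = repeat_class,
                      is_mono = mono, is_high_div = high_div,
                      stringsAsFactors = FALSE)
  list(out_lines = c(header, lines), truth = truth)
}

random_motif <- function(period) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), period, replace = TRUE),
               collapse = "")
    # a motif that is a homopolymer of length > 1 is really period 1
    if (period == 1L || length(unique(strsplit(m, "")[[1]])) > 1L) return(m)
  }
}

#' Generate a polymorphic-STR call set from a catalogue, with truth
#'
#' Each catalogue locus is independently detected with probability
#' `detection_prob`; a detected call has its coordinates jittered within
#' guaranteed overlap, its motif replaced by a random reverse /
#' reverse-complement equivalent with probability 0.5, and is flagged
#' polymorphic with probability `polymorphic_prob`. Defaults mirror the
#' published cross-match outcome (75% detected, 99% of detected
#' polymorphic).
#'
#' @param catalog Catalogue `data.frame` (`chrom`, `start`, `end`,
#'   `motif`).
#' @param seed Integer seed.
#' @param detection_prob,polymorphic_prob Per-locus probabilities.
#' @param jitter Jitter call coordinates (default `TRUE`).
#' @return A list: `callset` (`data.frame` readable by [cross_match()])
#'   and `truth` (`detected`, `polymorphic` per catalogue locus).
#' @export
gen_callset <- function(catalog, seed = 1L, detection_prob = 0.75,
                        polymorphic_prob = 0.99, jitter = TRUE) {
  set.seed(seed)
  n <- nrow(catalog)
  detected <- stats::runif(n) < detection_prob
  polymorphic <- stats::runif(n) < polymorphic_prob
  idx <- which(detected)
  len <- catalog$end[idx] - catalog$start[idx]
  shift <- if (jitter && length(idx)) {
    vapply(len, function(l) sample(seq(-(l - 1), l - 1), 1L), 1)
  } else rep(0, length(idx))
  motif <- vapply(seq_along(idx), function(k) {
    m <- catalog$motif[idx[k]]
    if (stats::runif(1) < 0.5) sample(motif_equivalents(m), 1L) else m
  }, "")
  callset <- data.frame(
    chrom = catalog$chrom[idx],
    start = catalog$start[idx] + shift,
    end = catalog$end[idx] + shift,
    motif = motif,
    is_polymorphic = polymorphic[idx],
    stringsAsFactors = FALSE)
  list(callset = callset,
       truth = data.frame(detected = detected,
                          polymorphic = detected & polymorphic))
}

#' Write a call set as a minimal VCF
#'
#' One record per call: `POS = start + 1`, INFO carries `MOTIF=`, `END=`
#' (1-based inclusive) and a `POLY` flag for polymorphic calls; readable
#' back with [read_callset()].
#'
#' @param callset Call-set `data.frame`.
#' @param path Output path.
#' @export
write_callset_vcf <- function(callset, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"Repeat motif\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End coordinate (1-based inclusive)\">",
           "##INFO=<ID=POLY,Number=0,Type=Flag,Description=\"Predicted polymorphic\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("MOTIF=%s;END=%d%s", callset$motif,
                  as.integer(callset$end),
                  ifelse(callset$is_polymorphic, ";POLY", ""))
  rec <- sprintf("%s\t%d\t.\tN\t.\t.\tPASS\t%s", callset$chrom,
                 as.integer(callset$start + 1), info)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Generate a paired tumor/adjacent STR expression study with planted truth
#'
#' Null STRs draw tumor and adjacent values i.i.d. log-normal; planted
#' up-regulated STRs have their tumor values multiplied by `effect_fold`,
#' planted down-regulated STRs their adjacent values. Zeros are injected
#' at rate `sparsity`. Defaults match the discovery setting: 8
#' tumor/adjacent pairs, 4 up and 4 down candidates planted among nulls at
#' 8-fold effect.
#'
#' @param n_null Number of null STRs (default 200).
#' @param n_up,n_down Planted candidates per direction (default 4).
#' @param n_pairs Paired samples (default 8).
#' @param effect_fold Planted fold change (default 8).
#' @param meanlog,sdlog Log-normal noise parameters (default 1, 0.5; a
#'   typical within-pair variation of about 1.6-fold for an expressed
#'   locus).
#' @param sparsity Probability of zeroing any single value (default 0).
#' @param seed Integer seed.
#' @return A list: `pairs` (`data.frame` with `str_id`, `sample_id`,
#'   `tumor`, `adjacent`) and `truth` (`up`, `down` id vectors).
#' @export
gen_expression_study <- function(n_null = 200L, n_up = 4L, n_down = 4L,
                                 n_pairs = 8L, effect_fold = 8,
                                 meanlog = 1, sdlog = 0.5, sparsity = 0,
                                 seed = 1L) {
  set.seed(seed)
  n <- n_null + n_up + n_down
  ids <- sprintf("STR%04d", seq_len(n))
  up <- ids[seq_len(n_up)]
  down <- ids[n_up + seq_len(n_down)]
  samples <- sprintf("P%02d", seq_len(n_pairs))
  tumor <- matrix(stats::rlnorm(n * n_pairs, meanlog, sdlog), nrow = n)
  adjacent <- matrix(stats::rlnorm(n * n_pairs, meanlog, sdlog), nrow = n)
  tumor[ids %in% up, ] <- tumor[ids %in% up, ] * effect_fold
  adjacent[ids %in% down, ] <- adjacent[ids %in% down, ] * effect_fold
  if (sparsity > 0) {
    tumor[matrix(stats::runif(n * n_pairs) < sparsity, nrow = n)] <- 0
    adjacent[matrix(stats::runif(n * n_pairs) < sparsity, nrow = n)] <- 0
  }
  pairs <- data.frame(
    str_id = rep(ids, times = n_pairs),
    sample_id = rep(samples, each = n),
    tumor = as.vector(tumor),
    adjacent = as.vector(adjacent),
    stringsAsFactors = FALSE)
  list(pairs = pairs, truth = list(up = up, down = down))
}

#' Default cohort-generator configuration
#'
#' Arm sizes and allele frequencies default to the published cohort:
#' 1,153 cases / 1,210 controls, case allele-11 frequency 76% and
#' control 71% (full spectra from the printed allele counts), ages
#' centred at 63.1 / 61.8 years, family-history rates 34% / 10%,
#' aggressive-disease base rate 145/1061 with an allele-11-carrier odds
#' ratio of 2, and exponential survival with a protective hazard
#' multiplier for the 12/12 genotype.
#'
#' @return A named list of generator parameters.
#' @export
default_cohort_config <- function() {
  list(
    n_cases = 1153L, n_controls = 1210L,
    case_allele_freqs = c(`9` = 1, `10` = 9, `11` = 1757, `12` = 542,
                          `13` = 3) / 2312,
    control_allele_freqs = c(`10` = 7, `11` = 1730, `12` = 688,
                             `13` = 1) / 2426,
    age_mean_case = 63.1, age_mean_control = 61.8, age_sd = 8,
    fh_prob_case = 0.34, fh_prob_control = 0.10,
    p_aggressive_base = 145 / 1061, gleason_or = 2,
    base_hazard = 9e-4,                 # per month
    hazard_mult = c(`12/12` = 0.33),    # relative to all other genotypes
    pca_death_frac = 24 / 68,
    followup_months = c(60, 120)
  )
}

#' Generate a synthetic case-control cohort with known truth
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium within each arm
#' from arm-specific allele frequencies (an approximation: an arm
#' selected on genotype is not strictly in HWE, but adequate for recovery
#' and calibration studies). Ages are normal, family history Bernoulli,
#' Gleason scores are assigned to cases with allele-11-carrier enrichment
#' controlled by `gleason_or`, and survival times are exponential with
#' genotype-dependent hazards and uniform administrative censoring.
#'
#' @param cfg Configuration list, see [default_cohort_config()]; entries
#'   may be overridden via `...`.
#' @param seed Integer seed.
#' @param ... Named overrides of `cfg` entries.
#' @return Cohort `data.frame` (see [read_cohort()] for columns).
#' @export
gen_cohort <- function(cfg = default_cohort_config(), seed = 1L, ...) {
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(abs(sum(cfg$case_allele_freqs) - 1) < 1e-9,
            abs(sum(cfg$control_allele_freqs) - 1) < 1e-9)
  set.seed(seed)
  draw_arm <- function(n, freqs, status) {
    alleles <- as.integer(names(freqs))
    a1 <- sample(alleles, n, replace = TRUE, prob = freqs)
    a2 <- sample(alleles, n, replace = TRUE, prob = freqs)
    data.frame(status = status, a1 = pmin(a1, a2), a2 = pmax(a1, a2),
               genotype = genotype(a1, a2), stringsAsFactors = FALSE)
  }
  subj <- rbind(draw_arm(cfg$n_cases, cfg$case_allele_freqs, "case"),
                draw_arm(cfg$n_controls, cfg$control_allele_freqs,
                         "control"))
  n <- nrow(subj)
  subj$id <- sprintf("S%05d", seq_len(n))
  is_case <- subj$status == "case"
  subj$age <- round(stats::rnorm(
    n, ifelse(is_case, cfg$age_mean_case, cfg$age_mean_control),
    cfg$age_sd), 1)
  subj$family_history <- stats::runif(n) <
    ifelse(is_case, cfg$fh_prob_case, cfg$fh_prob_control)
  carries_11 <- subj$a1 == 11L | subj$a2 == 11L
  p_aggr <- stats::plogis(stats::qlogis(cfg$p_aggressive_base) +
                            log(cfg$gleason_or) * carries_11)
  aggressive <- stats::runif(n) < p_aggr
  subj$gleason <- NA_integer_
  subj$gleason[is_case] <- ifelse(aggressive[is_case],
                                  sample(8:10, sum(is_case), replace = TRUE),
                                  sample(6:7, sum(is_case), replace = TRUE))
  mult <- rep(1, n)
  for (g in names(cfg$hazard_mult)) {
    mult[subj$genotype == g] <- cfg$hazard_mult[[g]]
  }
  t_event <- stats::rexp(n, rate = cfg$base_hazard * mult)
  t_cens <- stats::runif(n, cfg$followup_months[1], cfg$followup_months[2])
  subj$time <- round(pmin(t_event, t_cens), 1)
  subj$event_all_cause <- t_event <= t_cens
  pca_death <- stats::runif(n) < cfg$pca_death_frac
  subj$event_pca_specific <- subj$event_all_cause & pca_death
  # survival follow-up only applies to cases in the study design
  subj$time[!is_case] <- NA_real_
  subj$event_all_cause[!is_case] <- NA
  subj$event_pca_specific[!is_case] <- NA
  subj[, c("id", "status", "a1", "a2", "genotype", "age",
           "family_history", "gleason", "time", "event_all_cause",
           "event_pca_specific")]
}
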