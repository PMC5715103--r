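#' Normalize an unordered allele pair into a genotype label
#'
#' Genotypes are stored as `"a1/a2"` with `a1 <= a2` (integer repeat
#' counts), so `11/12` and `12/11` are the same genotype.
#'
#' @param a1,a2 Integer allele labels (vectorized).
#' @return Character vector of normalized genotype labels.
#' @export
genotype <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

#' Split genotype labels back into allele pairs
#' @param g Character vector of `"a1/a2"` labels.
#' @return Integer matrix with columns `a1`, `a2`.
#' @export
genotype_alleles <- function(g) {
  parts <- strsplit(g, "/", fixed = TRUE)
  m <- cbind(a1 = as.integer(vapply(parts, `[[`, "", 1)),
             a2 = as.integer(vapply(parts, `[[`, "", 2)))
  m
}

#' Allele counts from a genotype count table
#'
#' Each homozygote contributes two copies of its allele, each heterozygote
#' one copy of each constituent allele; the total allele count is twice
#' the number of genotyped subjects.
#'
#' @param tab Genotype count table: `data.frame` with `group`, `genotype`
#'   (normalized labels), `count`.
#' @param group Group label to tabulate.
#' @return Named integer vector allele -> count, ascending allele order.
#' @export
allele_counts_from_genotypes <- function(tab, group) {
  g <- tab[tab$group == group, , drop = FALSE]
  if (!nrow(g)) stop(sprintf("unknown group '%s'", group))
  al <- genotype_alleles(g$genotype)
  counts <- tapply(c(g$count, g$count), c(al[, 1], al[, 2]), sum)
  alleles <- sort(as.integer(names(counts)))
  stats::setNames(as.integer(counts[as.character(alleles)]),
                  alleles)
}

#' Allele frequencies in percent
#'
#' @param counts Named integer vector allele -> count.
#' @return `data.frame` with `allele`, `count`, `pct` (exact percent) and
#'   `pct_display` (half-up rounded to integer, table style).
#' @export
allele_frequencies <- function(counts) {
  total <- sum(counts)
  stopifnot(total > 0)
  pct <- 100 * counts / total
  data.frame(allele = as.integer(names(counts)),
             count = as.integer(counts),
             pct = as.numeric(pct),
             pct_display = floor(pct + 0.5),
             row.names = NULL)
}

#' Crude (cross-product) odds ratio with Wald interval
#'
#' Cells: `a` = exposed cases, `b` = reference cases, `c` = exposed
#' controls, `d` = reference controls. When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and
#' flagged. Two zero cells on the same margin make the OR undefined.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `odds_ratio`, `ci_low`, `ci_high`, `p_value` (Wald z),
#'   `method`, `haldane` (logical).
#' @export
crude_or <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0)) {
    stop("odds ratio undefined: two zero cells on a margin")
  }
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  zstat <- log(or) / se
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       p_value = 2 * stats::pnorm(-abs(zstat)),
       method = if (haldane) "crude OR (Haldane-Anscombe)" else "crude OR",
       haldane = haldane)
}

#' Logistic-regression association with Wald intervals
#'
#' Binomial GLM via iteratively reweighted least squares
#' (`stats::glm`, convergence tolerance 1e-8, at most 50 iterations).
#' Genotype terms should be coded as indicator columns against the
#' reference genotype; covariates (age, family history) may be added.
#'
#' @param formula Model formula; response must be 0/1 or logical.
#' @param data `data.frame` of predictors and response.
#' @param conf_level Confidence level for Wald intervals.
#' @return `data.frame`, one row per non-intercept term: `term`,
#'   `estimate` (log odds), `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
fit_logistic <- function(formula, data, conf_level = 0.95) {
  fit <- stats::glm(formula, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 50))
  if (!fit$converged) stop("logistic regression did not converge")
  co <- summary(fit)$coefficients
  if (any(abs(co[, "Estimate"]) > 15)) {
    bad <- rownames(co)[abs(co[, "Estimate"]) > 15][1]
    stop(sprintf("separation suspected for term '%s'", bad))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  keep <- rownames(co) != "(Intercept)"
  est <- co[keep, "Estimate"]
  se <- co[keep, "Std. Error"]
  data.frame(term = rownames(co)[keep],
             estimate = unname(est),
             odds_ratio = unname(exp(est)),
             ci_low = unname(exp(est - z * se)),
             ci_high = unname(exp(est + z * se)),
             p_value = unname(co[keep, "Pr(>|z|)"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Restrict a cohort to a set of genotypes
#'
#' The association stage considers only the common genotypes (by default
#' 11/11, 11/12 and 12/12); rare genotypes are excluded before regression
#' while tabulation functions keep everything.
#'
#' @param subjects Cohort `data.frame` with a `genotype` column.
#' @param kept Genotype labels to keep.
#' @return A list: `subjects` (restricted) and `n_removed`.
#' @export
restrict_genotypes <- function(subjects,
                               kept = c("11/11", "11/12", "12/12")) {
  keep <- subjects$genotype %in% kept
  list(subjects = subjects[keep, , drop = FALSE],
       n_removed = sum(!keep))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Expected genotype counts are computed from the observed allele
#' frequencies (`n p_i^2` for homozygotes, `2 n p_i p_j` for
#' heterozygotes). Rare alleles are a problem for the chi-square
#' approximation, so pooling happens in two stages, both reported: an
#' allele whose largest expected genotype class (its heterozygote with
#' the commonest allele, `2 n p_a p_max`) falls below `pool_below` is
#' merged into a composite allele before expectations are formed, and
#' genotype classes whose expected count still falls below `pool_below`
#' are then merged into one residual class. Degrees of freedom are the
#' number of genotype classes used minus the number of (post-pooling)
#' alleles.
#'
#' @param counts Named integer vector genotype label (`"a/b"`) -> subject
#'   count, one group.
#' @param pool_below Pooling threshold (default 5); 0 disables both
#'   pooling stages.
#' @return A list: `chi2`, `df`, `p_value`, `pooled_alleles` (labels
#'   merged into the composite), `n_pooled_classes`, `expected`
#'   (post-allele-pooling expected genotype counts).
#' @export
hwe_test <- function(counts, pool_below = 5) {
  n <- sum(counts)
  stopifnot(n > 0)
  al <- genotype_alleles(names(counts))
  allele_counts <- tapply(c(counts, counts), c(al[, 1], al[, 2]), sum)
  if (length(allele_counts) < 2L) stop("not polymorphic")
  p_max <- max(allele_counts) / (2 * n)
  rare <- allele_counts * p_max < pool_below
  rare[which.max(allele_counts)] <- FALSE  # never pool the major allele
  pooled_alleles <- names(allele_counts)[rare]
  # relabel alleles, mapping all rare ones onto a composite label
  relab <- function(a) ifelse(as.character(a) %in% pooled_alleles,
                              "other", as.character(a))
  g_lab <- apply(cbind(relab(al[, 1]), relab(al[, 2])), 1, function(x) {
    paste(sort(x), collapse = "/")
  })
  obs <- tapply(counts, g_lab, sum)
  ac <- tapply(c(counts, counts), c(relab(al[, 1]), relab(al[, 2])), sum)
  p <- ac / (2 * n)
  alleles <- names(p)
  if (length(alleles) < 2L) stop("not polymorphic")
  exp_g <- c()
  obs_g <- c()
  for (i in seq_along(alleles)) {
    for (j in i:length(alleles)) {
      gl <- paste(sort(c(alleles[i], alleles[j])), collapse = "/")
      e <- if (i == j) n * p[[i]]^2 else 2 * n * p[[i]] * p[[j]]
      exp_g[gl] <- e
      obs_g[gl] <- if (gl %in% names(obs)) obs[[gl]] else 0
    }
  }
  pool <- exp_g < pool_below
  n_pooled <- sum(pool)
  if (n_pooled > 0L) {
    obs_use <- c(obs_g[!pool], pooled = sum(obs_g[pool]))
    exp_use <- c(exp_g[!pool], pooled = sum(exp_g[pool]))
  } else {
    obs_use <- obs_g
    exp_use <- exp_g
  }
  df <- length(obs_use) - length(alleles)
  if (df < 1L) stop("too few genotype classes after pooling for a HWE test")
  chi2 <- sum((obs_use - exp_use)^2 / exp_use)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       pooled_alleles = pooled_alleles, n_pooled_classes = n_pooled,
       expected = exp_g)
}

#' Heterozygosity index
#'
#' Fraction of subjects carrying two different alleles.
#'
#' @param counts Named integer vector genotype label -> subject count.
#' @return Numeric in \[0, 1\].
#' @export
heterozygosity <- function(counts) {
  n <- sum(counts)
  stopifnot(n > 0)
  al <- genotype_alleles(names(counts))
  sum(counts[al[, 1] != al[, 2]]) / n
}

#' Log odds-ratio statistic for use with [bootstrap_or()]
#'
#' Builds the function computing the log crude OR of `exposure` genotype
#' versus `reference` genotype (cases vs controls) from a cohort
#' `data.frame` with `status` (`"case"`/`"control"`) and `genotype`.
#' Returns `NA` on a resample with an empty cell (triggering a redraw).
#'
#' @param exposure,reference Genotype labels.
#' @return A function `subjects -> numeric`.
#' @export
genotype_logor_stat <- function(exposure = "11/12", reference = "11/11") {
  function(subjects) {
    a <- sum(subjects$status == "case" & subjects$genotype == exposure)
    b <- sum(subjects$status == "case" & subjects$genotype == reference)
    c <- sum(subjects$status == "control" & subjects$genotype == exposure)
    d <- sum(subjects$status == "control" & subjects$genotype == reference)
    if (a == 0 || b == 0 || c == 0 || d == 0) return(NA_real_)
    log((a * d) / (b * c))
  }
}

#' Stratified bootstrap of an association statistic
#'
#' Resamples subjects with replacement within the case and control strata,
#' recomputing `statistic` on each resample. Reports the percentile
#' confidence interval and a two-tailed sign-based p-value for the null
#' that the statistic (log-OR scale) is zero:
#' `p = 2 * min(frac <= 0, frac >= 0)`, floored at `2 / n_resamples`.
#' Resamples on which the statistic is undefined (e.g. an empty 2x2 cell)
#' are redrawn and counted. Fully reproducible for a fixed seed.
#'
#' @param subjects Cohort `data.frame` with a `status` column.
#' @param statistic Function `subjects -> numeric scalar` (e.g.
#'   [genotype_logor_stat()]); `NA` marks an undefined resample.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf_level Percentile interval level (default 0.95).
#' @param max_redraws Redraw budget across all resamples (default
#'   `10 * n_resamples`).
#' @return A list: `ci_low`, `ci_high`, `p_value`, `n_redrawn`,
#'   `statistics` (the resampled values).
#' @export
bootstrap_or <- function(subjects, statistic = genotype_logor_stat(),
                         n_resamples = 1000L, seed = 1L,
                         conf_level = 0.95,
                         max_redraws = 10L * n_resamples) {
  is_case <- subjects$status == "case"
  idx_case <- which(is_case)
  idx_ctrl <- which(!is_case)
  stopifnot(length(idx_case) > 0L, length(idx_ctrl) > 0L)
  set.seed(seed)
  stats_v <- numeric(n_resamples)
  n_redrawn <- 0L
  for (r in seq_len(n_resamples)) {
    repeat {
      take <- c(idx_case[sample.int(length(idx_case), replace = TRUE)],
                idx_ctrl[sample.int(length(idx_ctrl), replace = TRUE)])
      v <- statistic(subjects[take, , drop = FALSE])
      if (!is.na(v)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_redraws) stop("bootstrap redraw budget exhausted")
    }
    stats_v[r] <- v
  }
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(stats_v, c(alpha / 2, 1 - alpha / 2),
                               type = 7))
  p <- 2 * min(mean(stats_v <= 0), mean(stats_v >= 0))
  p <- max(p, 2 / n_resamples)
  p <- min(p, 1)
  list(ci_low = ci[1], ci_high = ci[2], p_value = p,
       n_redrawn = n_redrawn, statistics = stats_v)
}

#' Dichotomize Gleason score into aggressiveness groups
#'
#' Gleason sum below 8 is `"less_aggressive"`, 8 or above `"aggressive"`.
#'
#' @param gs Integer Gleason sums in 2..10 (vectorized; `NA` passes
#'   through).
#' @return Character vector.
#' @export
dichotomize_gleason <- function(gs) {
  ok <- is.na(gs) | (gs >= 2 & gs <= 10)
  if (any(!ok)) stop("Gleason score out of range 2..10")
  ifelse(is.na(gs), NA_character_,
         ifelse(gs >= 8, "aggressive", "less_aggressive"))
}

#' Kaplan-Meier curves and log-rank (Mantel-Cox) test
#'
#' Product-limit survival estimates per group and the log-rank chi-square
#' over distinct event times with standard tie handling (via the survival
#' package). For two groups the hazard ratio is estimated as
#' `(O1/E1) / (O2/E2)` from the observed and expected event counts of the
#' log-rank table.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1/TRUE = event, 0/FALSE = censored).
#' @param group Group labels.
#' @return A list: `curves` (`data.frame` of `group`, `time`, `surv`),
#'   `chi2`, `df`, `p_value`, `hazard_ratio` (first group level vs second;
#'   `NA` with >2 groups), `observed`, `expected`.
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("a group has zero subjects")
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (sum(event) == 0) stop("no events: log-rank test undefined")
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  strata_group <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = strata_group, time = sf$time,
                       surv = sf$surv, stringsAsFactors = FALSE)
  df <- length(sd$n) - 1
  hr <- if (length(sd$n) == 2L) {
    (sd$obs[1] / sd$exp[1]) / (sd$obs[2] / sd$exp[2])
  } else NA_real_
  list(curves = curves, chi2 = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       hazard_ratio = unname(hr),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic two-sided p-value;
#' used for genotype-expression comparisons.
#'
#' @param x,y Numeric samples.
#' @return A list: `D`, `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Read / write a cohort table
#'
#' One row per subject: `id`, `status` (`case`/`control`), `a1`, `a2`
#' (allele repeat counts), `genotype`, `age`, `family_history`, `gleason`
#' (cases only), `time`, `event_all_cause`, `event_pca_specific`.
#'
#' @param path CSV path.
#' @param subjects Cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
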