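test_that("allele counts from the published case genotype table match the printed allele block", {
  tab <- pca3_case_control_counts()
  cc <- allele_counts_from_genotypes(tab, "case")
  expect_equal(cc[["11"]], 1757L)
  expect_equal(cc[["12"]], 542L)
  expect_equal(cc[["10"]], 9L)
  expect_equal(cc[["9"]], 1L)
  expect_equal(cc[["13"]], 3L)
  expect_equal(sum(cc), 2L * sum(tab$count[tab$group == "case"]))
  expect_error(allele_counts_from_genotypes(tab, "nope"), "unknown group")
})

test_that("allele counting equals per-subject enumeration on random tables", {
  set.seed(47)
  for (i in 1:10) {
    gts <- genotype(sample(8:14, 12, TRUE), sample(8:14, 12, TRUE))
    tab <- data.frame(group = "g", genotype = gts,
                      count = sample(1:30, 12, TRUE))
    tab <- aggregate(count ~ group + genotype, tab, sum)
    got <- allele_counts_from_genotypes(tab, "g")
    # enumerate subjects one by one
    want <- integer(0)
    for (r in seq_len(nrow(tab))) {
      al <- genotype_alleles(tab$genotype[r])
      for (s in seq_len(tab$count[r])) {
        for (a in as.character(al)) {
          want[a] <- (if (a %in% names(want)) want[[a]] else 0L) + 1L
        }
      }
    }
    want <- want[order(as.integer(names(want)))]
    expect_equal(got, want)
    expect_equal(sum(got), 2L * sum(tab$count))
  }
})

test_that("allele frequencies normalize to 100 and use half-up display rounding", {
  f <- allele_frequencies(c(`11` = 3L, `12` = 1L))
  expect_equal(f$pct, c(75, 25))
  set.seed(53)
  for (i in 1:10) {
    counts <- setNames(sample(1:500, 4), as.character(9:12))
    ff <- allele_frequencies(counts)
    expect_equal(sum(ff$pct), 100, tolerance = 1e-9)
  }
  # half-up: 0.5 rounds away from zero, unlike round()
  expect_equal(allele_frequencies(c(`1` = 1L, `2` = 7L))$pct_display,
               c(13, 88))
})

test_that("crude OR follows the cross-product with Wald interval and Haldane fallback", {
  r <- crude_or(1, 1, 1, 1)
  expect_equal(r$odds_ratio, 1)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)

  t3 <- crude_or(392, 680, 461, 634)
  expect_equal(t3$odds_ratio, (392 * 634) / (680 * 461))
  expect_true(t3$ci_low <= t3$odds_ratio && t3$odds_ratio <= t3$ci_high)

  h <- crude_or(0, 10, 5, 10)
  expect_true(h$haldane)
  expect_equal(h$odds_ratio, (0.5 * 10.5) / (10.5 * 5.5))
  expect_error(crude_or(0, 0, 5, 10), "margin")

  # reciprocal identity
  set.seed(59)
  for (i in 1:20) {
    cells <- sample(1:200, 4)
    a <- do.call(crude_or, as.list(cells))$odds_ratio
    b <- do.call(crude_or, as.list(cells[c(2, 1, 4, 3)]))$odds_ratio
    expect_equal(a * b, 1, tolerance = 1e-12)
  }
})

test_that("unadjusted logistic regression reproduces the crude OR to 1e-6", {
  set.seed(61)
  for (i in 1:10) {
    cells <- sample(3:80, 4)  # a, b, c, d
    subjects <- data.frame(
      y = rep(c(1, 1, 0, 0), cells),
      x = rep(c(1, 0, 1, 0), cells))
    fit <- fit_logistic(y ~ x, subjects)
    want <- do.call(crude_or, as.list(cells))
    expect_equal(fit$odds_ratio, want$odds_ratio, tolerance = 1e-6)
  }
})

test_that("logistic fit reports covariate-adjusted terms and flags separation", {
  set.seed(67)
  n <- 500
  x <- rbinom(n, 1, 0.4)
  age <- rnorm(n, 60, 8)
  y <- rbinom(n, 1, plogis(-0.5 + log(0.6) * x + 0.02 * (age - 60)))
  fit <- fit_logistic(y ~ x + age, data.frame(y, x, age))
  expect_equal(nrow(fit), 2L)
  expect_true(fit$ci_low[1] < fit$odds_ratio[1] &&
                fit$odds_ratio[1] < fit$ci_high[1])
  sep <- data.frame(y = c(rep(0, 20), rep(1, 20)),
                    x = c(rep(0, 20), rep(1, 20)))
  expect_error(suppressWarnings(fit_logistic(y ~ x, sep)), "separation")
})

test_that("genotype restriction keeps the three common genotypes", {
  tab <- pca3_case_control_counts()
  cases <- tab[tab$group == "case", ]
  subjects <- data.frame(
    status = "case",
    genotype = rep(cases$genotype, cases$count))
  r <- restrict_genotypes(subjects)
  expect_equal(nrow(r$subjects), 680L + 392L + 73L)  # 1145
  expect_equal(r$n_removed, nrow(subjects) - 1145L)
  expect_equal(nrow(restrict_genotypes(subjects[0, ])$subjects), 0L)
  all_kept <- restrict_genotypes(subjects, kept = unique(subjects$genotype))
  expect_equal(nrow(all_kept$subjects), nrow(subjects))
})

test_that("HWE chi-square matches closed forms and a direct recomputation", {
  perfect <- c(`1/1` = 25L, `1/2` = 50L, `2/2` = 25L)
  h <- hwe_test(perfect)
  expect_equal(h$chi2, 0)
  expect_equal(h$p_value, 1)
  expect_equal(h$df, 1L)

  extreme <- c(`1/1` = 50L, `2/2` = 50L)
  h2 <- hwe_test(extreme)
  expect_equal(h2$chi2, 100)
  expect_equal(h2$df, 1L)

  expect_error(hwe_test(c(`1/1` = 30L)), "not polymorphic")

  set.seed(71)
  for (i in 1:10) {
    a1 <- sample(9:12, 200, TRUE)
    a2 <- sample(9:12, 200, TRUE)
    counts <- table(genotype(a1, a2))
    counts <- setNames(as.integer(counts), names(counts))
    h3 <- hwe_test(counts, pool_below = 0)  # no pooling: direct formula
    n <- sum(counts)
    al <- table(c(a1, a2)) / (2 * n)
    chi2 <- 0
    alleles <- as.integer(names(al))
    for (x in seq_along(alleles)) {
      for (y in x:length(alleles)) {
        e <- if (x == y) n * al[[x]]^2 else 2 * n * al[[x]] * al[[y]]
        gl <- genotype(alleles[x], alleles[y])
        o <- if (gl %in% names(counts)) counts[[gl]] else 0L
        chi2 <- chi2 + (o - e)^2 / e
      }
    }
    expect_equal(h3$chi2, chi2, tolerance = 1e-9)
    expect_equal(h3$df, 10L - 4L)
  }
})

test_that("heterozygosity is the fraction of heterozygous subjects", {
  expect_equal(heterozygosity(c(`11/11` = 1L, `11/12` = 1L)), 0.5)
  expect_equal(heterozygosity(c(`11/11` = 9L, `12/12` = 3L)), 0)
  set.seed(73)
  for (i in 1:10) {
    a1 <- sample(9:13, 100, TRUE); a2 <- sample(9:13, 100, TRUE)
    counts <- table(genotype(a1, a2))
    counts <- setNames(as.integer(counts), names(counts))
    expect_equal(heterozygosity(counts), mean(a1 != a2))
  }
})

test_that("bootstrap is seed-reproducible, collapses for constants, and floors p", {
  subj <- data.frame(status = rep(c("case", "control"), each = 50),
                     genotype = sample(c("11/11", "11/12"), 100, TRUE))
  const <- function(s) 1.7
  b <- bootstrap_or(subj, const, n_resamples = 200, seed = 9)
  expect_equal(b$ci_low, 1.7)
  expect_equal(b$ci_high, 1.7)
  expect_equal(b$p_value, 2 / 200)

  stat <- genotype_logor_stat("11/12", "11/11")
  b1 <- bootstrap_or(subj, stat, n_resamples = 100, seed = 5)
  b2 <- bootstrap_or(subj, stat, n_resamples = 100, seed = 5)
  expect_identical(b1$statistics, b2$statistics)
  expect_identical(b1$p_value, b2$p_value)
  expect_true(b1$ci_low <= b1$ci_high)
})

test_that("Gleason dichotomization splits at 8", {
  expect_equal(dichotomize_gleason(7), "less_aggressive")
  expect_equal(dichotomize_gleason(8), "aggressive")
  expect_equal(dichotomize_gleason(10), "aggressive")
  expect_equal(dichotomize_gleason(c(6, 9, NA)),
               c("less_aggressive", "aggressive", NA))
  expect_error(dichotomize_gleason(11), "range")
})

test_that("log-rank matches the hand-worked 4-event example", {
  # group A: events at t = 1 and 3; group B: events at t = 2 and 4.
  # Hand computation over the four event times gives O_A = 2,
  # E_A = 1/2 + 1/3 + 1/2 = 4/3, Var = 1/4 + 2/9 + 1/4 = 13/18,
  # chi2 = (2/3)^2 / (13/18) = 8/13, and HR = (2/(4/3)) / (2/(8/3)) = 2.
  time <- c(1, 3, 2, 4)
  event <- c(1, 1, 1, 1)
  group <- c("A", "A", "B", "B")
  r <- km_logrank(time, event, group)
  expect_equal(r$chi2, 8 / 13, tolerance = 1e-9)
  expect_equal(r$hazard_ratio, 2, tolerance = 1e-9)
  expect_equal(r$observed, c(2, 2))
  expect_equal(r$expected, c(4 / 3, 8 / 3), tolerance = 1e-9)
})

test_that("log-rank degenerate cases error and symmetric groups are null", {
  expect_error(km_logrank(c(5, 6, 7, 8), c(0, 0, 0, 0),
                          c("A", "A", "B", "B")), "no events")
  set.seed(79)
  time <- rexp(200, 0.05)
  event <- rbinom(200, 1, 0.7)
  r <- km_logrank(c(time, time), c(event, event),
                  rep(c("A", "B"), each = 200))
  expect_lt(r$chi2, 1e-9)
  expect_equal(r$hazard_ratio, 1, tolerance = 1e-9)
  # survival curves are monotone non-increasing step functions per group
  for (g in c("A", "B")) {
    s <- r$curves$surv[r$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("two-sample KS statistic equals a brute-force ECDF sweep", {
  x <- c(1, 2, 3)
  r <- ks_two_sample(x, x)
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  set.seed(83)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  grid <- sort(c(x, y))
  d_brute <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_equal(ks_two_sample(x, y)$D, d_brute, tolerance = 1e-12)
})
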