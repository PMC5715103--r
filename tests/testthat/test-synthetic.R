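test_that("generated annotation parses back to its truth table exactly", {
  g <- gen_catalog(n_loci = 150, seed = 101)
  cat <- parse_repeatmasker(lines = g$out_lines)
  truth <- g$truth[g$truth$repeat_class == "Simple_repeat", ]
  rownames(truth) <- NULL
  expect_equal(cat$chrom, truth$chrom)
  expect_equal(cat$start, truth$start)
  expect_equal(cat$end, truth$end)
  expect_equal(cat$motif, truth$motif)
  expect_equal(cat$strand, truth$strand)
  expect_equal(cat$pct_div, truth$pct_div)
  expect_equal(cat$pct_del, truth$pct_del)
  expect_equal(cat$pct_ins, truth$pct_ins)
})

test_that("generators are pure functions of their seed", {
  expect_identical(gen_catalog(50, seed = 7), gen_catalog(50, seed = 7))
  cat <- gen_catalog(50, seed = 7)$truth
  expect_identical(gen_callset(cat, seed = 3), gen_callset(cat, seed = 3))
  expect_identical(gen_expression_study(seed = 11),
                   gen_expression_study(seed = 11))
  expect_identical(gen_cohort(seed = 13), gen_cohort(seed = 13))
  expect_false(identical(gen_cohort(seed = 13), gen_cohort(seed = 14)))
})

test_that("filter_catalog on generated annotations honors the planted fractions", {
  g <- gen_catalog(n_loci = 4000, seed = 103, other_class_frac = 0)
  res <- filter_catalog(g$truth)
  expect_equal(res$report$n_excluded_mono, sum(g$truth$is_mono))
  expect_equal(res$report$n_excluded_divergent, sum(g$truth$is_high_div))
  # a divergence law concentrated above 5% keeps ~nothing
  g_hi <- gen_catalog(n_loci = 300, seed = 104, mono_frac = 0,
                      high_div_frac = 1, other_class_frac = 0)
  expect_equal(filter_catalog(g_hi$truth)$report$n_kept, 0L)
})

test_that("call-set detection and polymorphism rates land near their defaults", {
  g <- gen_catalog(n_loci = 4000, seed = 107, other_class_frac = 0,
                   mono_frac = 0)
  cs <- gen_callset(g$truth, seed = 107)
  ann <- cross_match(g$truth, cs$callset)
  s <- xref_summary(ann)
  # detection 0.75 and polymorphic 0.99 within 3 binomial s.e.
  se_det <- sqrt(0.75 * 0.25 / 4000)
  expect_lt(abs(s$fraction_matched - 0.75), 3 * se_det)
  n_det <- sum(ann$matched)
  se_pol <- sqrt(0.99 * 0.01 / n_det)
  expect_lt(abs(s$fraction_polymorphic_among_matched - 0.99), 3 * se_pol)
  # every detected locus is matched by its own jittered call
  expect_true(all(ann$matched[cs$truth$detected]))

  all_in <- gen_callset(g$truth[1:200, ], seed = 1, detection_prob = 1)
  expect_true(all(cross_match(g$truth[1:200, ], all_in$callset)$matched))
  empty_cs <- gen_callset(g$truth[1:50, ], seed = 1, detection_prob = 0)
  expect_warning(none <- cross_match(g$truth[1:50, ], empty_cs$callset),
                 "no catalogue locus")
  expect_false(any(none$matched))
})

test_that("expression-study truth is recovered at the planted effect and not under the null", {
  st <- gen_expression_study(seed = 211)
  sc <- score_all(st$pairs)
  cand <- select_candidates(sc, 4)
  expect_setequal(cand$top, st$truth$up)
  expect_setequal(cand$bottom, st$truth$down)

  null <- gen_expression_study(effect_fold = 1, seed = 212)
  sc0 <- score_all(null$pairs, log2_mode = TRUE)
  planted <- sc0$score[sc0$str_id %in% c(null$truth$up, null$truth$down)]
  rest <- sc0$score[!sc0$str_id %in% c(null$truth$up, null$truth$down)]
  expect_gt(ks_two_sample(planted, rest)$p_value, 0.01)
})

test_that("sparsity injects zero pairs that drop out of the score", {
  st <- gen_expression_study(n_null = 50, sparsity = 0.4, seed = 301)
  both_zero <- st$pairs$tumor == 0 & st$pairs$adjacent == 0
  expect_gt(sum(both_zero), 0)
  sc <- score_all(st$pairs)
  one <- st$pairs[st$pairs$str_id == sc$str_id[1], ]
  expect_equal(sc$n_expressed[1], sum(one$tumor > 0 | one$adjacent > 0))
})

test_that("generated cohorts reproduce the configured allele frequencies and pass HWE per arm", {
  subj <- gen_cohort(seed = 401)
  expect_equal(nrow(subj), 1153L + 1210L)
  cases <- subj[subj$status == "case", ]
  f11 <- mean(c(cases$a1, cases$a2) == 11)
  se <- sqrt(0.76 * 0.24 / (2 * nrow(cases)))
  expect_lt(abs(f11 - 0.76), 3 * se)

  # arm-wise HWE should typically hold (generated under HWE)
  counts <- table(cases$genotype)
  h <- hwe_test(setNames(as.integer(counts), names(counts)))
  expect_gt(h$p_value, 0.001)

  # Gleason only for cases; survival only followed for cases
  expect_true(all(is.na(subj$gleason[subj$status == "control"])))
  expect_true(all(!is.na(cases$gleason)))
  expect_true(all(is.na(subj$time[subj$status == "control"])))
  expect_true(all(cases$time >= 0))
  expect_true(all(cases$gleason %in% 6:10))
  expect_equal(dichotomize_gleason(cases$gleason) == "aggressive",
               cases$gleason >= 8)
})

test_that("cohort CSV round-trips through write_cohort / read_cohort", {
  subj <- gen_cohort(seed = 403, n_cases = 40L, n_controls = 50L)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(subj, path)
  back <- read_cohort(path)
  expect_equal(back$genotype, subj$genotype)
  expect_equal(back$age, subj$age)
  expect_equal(back$time, subj$time)
})
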