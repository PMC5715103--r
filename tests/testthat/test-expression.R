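test_that("keep_alignment matches the exhaustive flag/hits truth table", {
  base_flag <- 1L  # paired; irrelevant bits must not affect the rule
  bits <- c(0x2L, 0x100L, 0x400L, 0x800L)
  for (mask in 0:15) {
    flag <- base_flag
    for (b in seq_along(bits)) {
      if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) {
        flag <- flag + bits[b]
      }
    }
    for (hits in 1:2) {
      want <- (bitwAnd(flag, 0x2L) != 0L) &&
        (bitwAnd(flag, 0x100L) == 0L) &&
        (bitwAnd(flag, 0x400L) == 0L) &&
        (bitwAnd(flag, 0x800L) == 0L) &&
        hits == 1L
      expect_identical(keep_alignment(flag, hits), want,
                       label = sprintf("flag=%d hits=%d", flag, hits))
    }
  }
  expect_true(keep_alignment(99L, 1L))
  expect_false(keep_alignment(99L + 1024L, 1L))
})

test_that("read_sam_lite extracts flags and HI/NH hit counts from SAM text", {
  sam <- c(
    "@HD\tVN:1.6",
    paste("r1", "99", "chr1", "100", "60", "50M", "=", "200", "150",
          "ACGT", "IIII", "NH:i:1", sep = "\t"),
    paste("r2", "1123", "chr1", "300", "60", "50M", "=", "400", "150",
          "ACGT", "IIII", "HI:i:2", sep = "\t"),
    paste("r3", "99", "chr2", "10", "60", "50M", "=", "90", "130",
          "ACGT", "IIII", sep = "\t"))
  path <- tempfile(fileext = ".sam")
  on.exit(unlink(path))
  writeLines(sam, path)
  rec <- read_sam_lite(path)
  expect_equal(rec$flag, c(99L, 1123L, 99L))
  expect_equal(rec$alignment_hits, c(1L, 2L, 1L))
  expect_equal(keep_alignment(rec$flag, rec$alignment_hits),
               c(TRUE, FALSE, TRUE))
})

test_that("ALLREADS fields parse and round-trip", {
  expect_equal(parse_allreads("-2|10;0|25;2|3"),
               c(`-2` = 10L, `0` = 25L, `2` = 3L))
  expect_equal(length(parse_allreads(".")), 0L)
  expect_equal(length(parse_allreads("")), 0L)
  expect_error(parse_allreads("-2|10;x"), "'x'")

  set.seed(5)
  for (i in 1:100) {
    n <- sample(0:6, 1)
    reads <- setNames(as.integer(sample(0:500, n)),
                      as.character(sample(-10:10, n)))
    expect_equal(parse_allreads(format_allreads(reads)), reads)
  }
})

test_that("allele filtering keeps the >= 10 read boundary and is idempotent", {
  expect_equal(filter_alleles(c(`0` = 25L, `2` = 9L)), c(`0` = 25L))
  expect_equal(filter_alleles(c(`0` = 10L)), c(`0` = 10L))
  none <- filter_alleles(c(`0` = 3L, `2` = 9L))
  expect_equal(length(none), 0L)
  set.seed(9)
  for (i in 1:20) {
    r <- setNames(as.integer(sample(0:40, 5)), as.character(1:5))
    expect_equal(filter_alleles(filter_alleles(r)), filter_alleles(r))
  }
})

test_that("expression normalization follows the closed forms and their identity", {
  expect_equal(normalize_expression(100, 1e7, locus_length_bp = 1000), 10)
  expect_equal(normalize_expression(0, 1e7, locus_length_bp = 1000), 0)
  expect_equal(normalize_expression(0, 1e7, scheme = "rpm"), 0)
  expect_error(normalize_expression(10, 0, locus_length_bp = 100), "> 0")
  set.seed(13)
  for (i in 1:25) {
    reads <- sample(0:5000, 1)
    len <- sample(20:5000, 1)
    tot <- round(runif(1, 1e6, 1e8))
    fpkm <- normalize_expression(reads, tot, locus_length_bp = len)
    rpm <- normalize_expression(reads, tot, scheme = "rpm")
    expect_equal(rpm, fpkm * len / 1000)
    # linear in reads, inverse in depth
    expect_equal(normalize_expression(2 * reads, tot, locus_length_bp = len),
                 2 * fpkm)
    expect_equal(normalize_expression(reads, 2 * tot, locus_length_bp = len),
                 fpkm / 2)
  }
})

test_that("observed alleles are the ascending union over samples", {
  profiles <- list(c(`11` = 40L), c(`11` = 12L, `12` = 30L),
                   c(`9` = 15L, `13` = 11L, `10` = 22L))
  expect_equal(observed_alleles(profiles), c(9L, 10L, 11L, 12L, 13L))
  expect_equal(observed_alleles(list(c(`4` = 20L, `5` = 15L))), c(4L, 5L))
  expect_equal(length(observed_alleles(list())), 0L)
})

test_that("delta-delta-Ct and delta-Ct follow their formulas", {
  expect_equal(rel_expr_ddct(25, 15, 25, 15), 1)
  expect_equal(rel_expr_ddct(24, 15, 25, 15), 2)
  expect_error(rel_expr_ddct(24, c(15, 16), 25, 15), "one housekeeping")

  set.seed(21)
  for (i in 1:20) {
    ct <- runif(4, 10, 35)
    ddct <- (ct[1] - ct[2]) - (ct[3] - ct[4])
    expect_equal(log2(rel_expr_ddct(ct[1], ct[2], ct[3], ct[4])), -ddct)
  }

  expect_equal(rel_expr_dct(20, c(20, 20)), 1)
  expect_equal(rel_expr_dct(20, c(18, 22)), 2^-(20 - sqrt(18 * 22)))
  # single housekeeper reduces to plain delta-Ct
  expect_equal(rel_expr_dct(22, 18), 2^-(22 - 18))
})

test_that("lobSTR-style VCF ALLREADS fields are read per sample", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
           "chr9\t79400651\t.\tN\t.\t.\tPASS\t.\tGT:ALLREADS\t0/0:0|25;2|12\t0/1:.",
           "chr2\t74144317\t.\tN\t.\t.\tPASS\t.\tGT:ALLREADS\t0/0:-4|18\t0/0:0|40")
  path <- tempfile(fileext = ".vcf")
  on.exit(unlink(path))
  writeLines(vcf, path)
  calls <- read_str_calls(path)
  expect_equal(nrow(calls), 4L)
  pr <- parse_allreads(calls$allreads[calls$locus_id == "chr9:79400651" &
                                        calls$sample_id == "S1"])
  expect_equal(pr, c(`0` = 25L, `2` = 12L))
  expect_equal(length(parse_allreads(
    calls$allreads[calls$locus_id == "chr9:79400651" &
                     calls$sample_id == "S2"])), 0L)
})
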