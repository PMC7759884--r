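# Clean-read filter rules, their priority and monotonicity, summary
# statistics, and FASTQ round-trip/parse-error behaviour.

test_that("filter rules fire at the documented thresholds", {
  cfg <- qc_config()
  base <- strrep("A", 150)

  # 16 N in a 150 bp mate is 10.7% > 10% -> n_fraction
  n_mate <- paste0(strrep("N", 16), strrep("A", 134))
  p <- make_pairs(n_mate, base)
  expect_equal(filter_pairs(p, cfg)$reason, "n_fraction")
  # 15 N (10.0%) is not strictly greater -> keep
  p <- make_pairs(paste0(strrep("N", 15), strrep("A", 135)), base)
  expect_true(filter_pairs(p, cfg)$keep)

  # 21% of the 300 combined bases at Q2 -> low_quality
  p <- make_pairs(base, base)
  p$qual1 <- paste0(strrep("#", 63), strrep("D", 87))  # 63/300 = 21%
  expect_equal(filter_pairs(p, cfg)$reason, "low_quality")
  p$qual1 <- paste0(strrep("#", 60), strrep("D", 90))  # exactly 20% -> keep
  expect_true(filter_pairs(p, cfg)$keep)

  # adapter: any exact 12-base adapter substring in either mate
  ad <- substr(qc_config()$adapters[1], 3, 14)
  p <- make_pairs(base, paste0(strrep("T", 100), ad, strrep("T", 38)))
  expect_equal(filter_pairs(p, cfg)$reason, "adapter")

  # clean synthetic pair is kept
  expect_true(filter_pairs(make_pairs("ACGTACGTAC"), cfg)$keep)

  # priority: adapter outranks n_fraction outranks low_quality
  p <- make_pairs(paste0(ad, strrep("N", 30), strrep("A", 108)), base)
  p$qual1 <- strrep("#", 150)
  expect_equal(filter_pairs(p, cfg)$reason, "adapter")

  expect_error(filter_pairs(make_pairs("", "ACGT")), "empty read")
  expect_equal(filter_pair(as.list(make_pairs("ACGTACGT")[1, ])), "keep")
})

test_that("every pair lands in exactly one bucket and thresholds are monotone", {
  cfg <- simulation_config(host_length = 2e4, repeat_fraction = 0.2,
                           contaminants = list(), coverage = 15, seed = 21L)
  pairs <- simulate_sample(cfg)$pairs
  flags <- filter_pairs(pairs)
  expect_equal(sum(flags$keep) + sum(!is.na(flags$reason)), nrow(pairs))
  expect_true(all(is.na(flags$reason) == flags$keep))

  # relaxing any threshold never decreases kept pairs
  kept0 <- sum(flags$keep)
  relaxed <- list(
    qc_config(max_n_fraction = 0.5),
    qc_config(max_low_q_fraction = 0.5),
    qc_config(adapter_min_match = 25L),
    qc_config(low_q_threshold = 2L))
  for (cfg_r in relaxed)
    expect_gte(sum(filter_pairs(pairs, cfg_r)$keep), kept0)
})

test_that("qc_summary computes volumes, Q30 and GC", {
  p <- make_pairs("ACGT", "ACGT", qual_char = "I")  # Q40 everywhere
  flags <- filter_pairs(p)
  s <- qc_summary(p, flags)
  expect_equal(s$gc, 0.5)
  expect_equal(s$q30, 1.0)
  expect_equal(s$clean_bases, 8)
  expect_equal(s$clean_gb, 8e-9)
  expect_equal(s$raw_pairs, s$clean_pairs + sum(s$discarded))

  # mixed qualities: '5' is Q20 (below 30), 'I' is Q40
  p$qual1 <- "55II"
  s <- qc_summary(p, flags)
  expect_equal(s$q30, 6 / 8)

  # empty clean set: all zeros, no division error
  p2 <- make_pairs(strrep("N", 150))
  f2 <- filter_pairs(p2)
  s2 <- qc_summary(p2, f2)
  expect_equal(s2$clean_pairs, 0)
  expect_equal(s2$q30, 0)
  expect_equal(s2$gc, 0)
})

test_that("FASTQ round-trips byte-identically and errors name the record", {
  pairs <- make_pairs(c("ACGTACGTAC", "TTTTGGGGCC"),
                      c("GGGGTTTTAA", "ACACACACAC"))
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(pairs, f1, f2)
  back <- read_fastq(f1, f2)
  expect_equal(as.data.frame(back), as.data.frame(pairs[, names(back)]))
  g1 <- tempfile(); g2 <- tempfile()
  write_fastq(back, g1, g2)
  expect_identical(readLines(g1), readLines(f1))
  expect_identical(readLines(g2), readLines(f2))

  # interleaved round trip
  fi <- tempfile()
  write_fastq(pairs, fi)
  expect_equal(as.data.frame(read_fastq(fi)),
               as.data.frame(pairs[, names(back)]))

  # truncated final record
  lines <- readLines(f1)
  writeLines(lines[1:(length(lines) - 2)], g1)
  expect_error(read_fastq(g1, f2), "truncated.*record 2")

  # desynchronised mates
  writeLines(sub("^@p002", "@zzz", readLines(f2)), g2)
  expect_error(read_fastq(f1, g2), "desynchronised")

  # Phred+33 'I' decodes to Q40, '#' to Q2
  expect_equal(phred_scores("I#")[[1]], c(40L, 2L))
  # qualities outside Phred [0, 60] are rejected
  writeLines(c("@a/1", "AC", "+", "~~"), g1)
  writeLines(c("@a/2", "AC", "+", "II"), g2)
  expect_error(read_fastq(g1, g2), "Phred")
})
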