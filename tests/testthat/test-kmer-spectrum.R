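# Spectrum counting against a brute-force oracle, peak finding, and the
# four estimators with their algebraic identities.

test_that("counting matches hand-computed tiny cases", {
  h <- count_kmers("ACGTA", k = 3)
  # windows ACG, CGT, GTA; canonical: ACG (twice, CGT -> ACG), GTA (once)
  expect_equal(n_occurrences(h), 3)
  expect_equal(n_species(h), 2)
  expect_equal(h$depth, c(1L, 2L))
  expect_equal(h$species, c(1, 1))

  # windows containing N are skipped
  h <- count_kmers("ACGNT", k = 3)
  expect_equal(n_occurrences(h), 1)

  # reads shorter than k contribute nothing
  expect_equal(n_species(count_kmers(c("AC", "ACGTACGT"), k = 17)), 0)
  expect_error(count_kmers("ACGT", k = 4), "odd")
})

test_that("counting agrees with the brute-force oracle and is strand-invariant", {
  set.seed(31)
  reads <- vapply(1:200, function(i) random_dna(sample(20:80, 1), 0.45), "")
  reads[sample(200, 10)] <- sub("A", "N", reads[sample(200, 10)])
  for (k in c(5L, 17L)) {
    h <- count_kmers(reads, k)
    o <- kmer_hist_oracle(reads, k)
    expect_equal(h$depth, o$depth)
    expect_equal(h$species, o$species)
    # reverse-complementing every read leaves the histogram unchanged
    h_rc <- count_kmers(revcomp(reads), k)
    expect_equal(h_rc$depth, h$depth)
    expect_equal(h_rc$species, h$species)
  }
})

test_that("peak finding: error boundary, main peak, ties, failure modes", {
  h <- kmer_histogram(c(1, 2, 3, 50, 51), c(1000, 100, 50, 500, 400))
  p <- find_peaks(h)
  expect_true(p$error_boundary %in% 3:4)
  expect_equal(p$main_peak, 50)
  expect_equal(p$half_peak, 25)
  expect_equal(p$repeat_threshold, 90)
  expect_lt(p$error_boundary, p$main_peak)

  # plateau tie -> smallest depth
  h <- kmer_histogram(c(1, 2, 40, 41), c(1000, 10, 500, 500))
  expect_equal(find_peaks(h)$main_peak, 40)

  # monotonically decreasing histogram -> estimation error
  h <- kmer_histogram(1:6, c(1000, 500, 250, 100, 40, 10))
  expect_error(find_peaks(h), "no genomic peak|no local minimum")

  # smoothing is available but off by default
  h <- kmer_histogram(c(1, 2, 3, 49, 50, 51), c(900, 80, 20, 300, 280, 310))
  expect_equal(find_peaks(h)$main_peak, 51)
  expect_equal(find_peaks(h, smooth = TRUE)$main_peak, 50)
})

test_that("genome size, error revision, heterozygosity, repetitive rate", {
  # size = occurrences / peak
  h <- kmer_histogram(c(1, 2, 50), c(10, 10, (1e6 - 30) / 50))
  expect_equal(n_occurrences(h), 1e6)
  p <- find_peaks(h)
  expect_equal(p$main_peak, 50)
  expect_equal(estimate_genome_size(h, p), 20000)

  # error rate 0 -> revision is the identity
  h0 <- kmer_histogram(c(40, 50), c(10, 100))
  expect_equal(revise_genome_size(12345, h0), 12345)
  # forward formula reproduces the back-computed reference revision
  err <- 1 - 1816.81 / 1845.25
  expect_equal(round(revise_genome_size(1845.25, h0, error_rate = err), 2),
               1816.81)
  # depth-1 proportion of occurrences
  h1 <- kmer_histogram(c(1, 50), c(100, 198))  # 100 / (100 + 9900)
  expect_equal(estimate_error_rate(h1), 0.01)
  expect_equal(estimate_error_rate(h1, denominator = "species"),
               100 / 298)

  # a_half = 0 -> heterozygosity 0; Eq. round-trip to 1e-12
  h2 <- kmer_histogram(c(1, 2, 50), c(1000, 10, 500))
  p2 <- find_peaks(h2)
  het <- estimate_heterozygosity(h2, p2)
  expect_equal(het$a_half, 0)
  expect_equal(het$heterozygosity, 0)
  k <- 17
  for (a in c(0.01, 0.156682, 0.5, 1.2)) {
    hh <- a / (k * (2 - a))
    expect_equal(2 * hh * k / (1 + hh * k), a, tolerance = 1e-12)
  }
  # the published 0.50% back-solves to a_half ~ 0.156682
  expect_equal(round(0.156682 / (17 * (2 - 0.156682)), 5), 0.00500)

  # half-peak window picks up species at ~0.5x the peak
  h3 <- kmer_histogram(c(1, 2, 25, 50), c(1000, 10, 300, 700))
  p3 <- find_peaks(h3)
  het3 <- estimate_heterozygosity(h3, p3)
  expect_equal(het3$a_half, 300 / 1000)

  # repetitive rate: all mass at the peak -> 0; split case by hand
  h4 <- kmer_histogram(c(1, 2, 50), c(5, 5, 100))
  expect_equal(estimate_repetitive_rate(h4, find_peaks(h4)), 0)
  h5 <- kmer_histogram(c(50, 100), c(900, 100))
  r <- estimate_repetitive_rate(h5, find_peaks(h5))
  expect_equal(r, 100 * 100 / (50 * 900 + 100 * 100), tolerance = 1e-12)
})

test_that("peak and size are recovered from an error-free unique genome", {
  cfg <- simulation_config(host_length = 1e5, snp_rate = 0,
                           repeat_fraction = 0, contaminants = list(),
                           coverage = 50, base_error_rate = 0,
                           frac_adapter = 0, frac_n = 0, frac_low_q = 0,
                           seed = 33L, repeat_unit_lengths = 50:200)
  sim <- simulate_sample(cfg)
  h <- count_kmers(sim$pairs, 17)
  p <- find_peaks(h)
  # k-mer depth peak ~ coverage * (L - k + 1) / L = 44.6
  expect_lt(abs(p$main_peak - 50 * 134 / 150), 2)
  est <- genome_estimate(h, p)
  expect_lt(abs(est$genome_size - 1e5) / 1e5, 0.05)
  expect_lt(est$error_rate, 1e-3)
  expect_lt(est$repetitive_rate, 0.05)
})

test_that("histogram TSV round-trips", {
  h <- kmer_histogram(c(1, 5, 9), c(10, 20, 5))
  f <- tempfile(fileext = ".tsv")
  write_kmer_histogram(h, f)
  back <- read_kmer_histogram(f, k = 17)
  expect_equal(back$depth, h$depth)
  expect_equal(back$species, h$species)
})
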