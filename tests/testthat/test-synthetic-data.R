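# Generator properties: ground truth must be exact and reproducible,
# realised statistics must match the configured rates within binomial
# tolerance.

test_that("host genome honours snp_rate, GC and repeat targets", {
  cfg <- simulation_config(host_length = 1e6, snp_rate = 0.005,
                           repeat_fraction = 0.4, host_gc = 0.37,
                           seed = 11L)
  host <- simulate_host_genome(cfg)
  expect_equal(nchar(host$haplotype_a), 1e6)
  expect_equal(nchar(host$haplotype_b), 1e6)

  # SNP count within 3 sd of binomial(1e6, 0.005)
  n_snp <- length(host$truth$snp_positions)
  sd3 <- 3 * sqrt(1e6 * 0.005 * 0.995)
  expect_lt(abs(n_snp - 5000), sd3)

  # every recorded SNP position really differs, and only those
  a <- strsplit(host$haplotype_a, "")[[1]]
  b <- strsplit(host$haplotype_b, "")[[1]]
  diff <- which(a != b) - 1L
  expect_identical(diff, host$truth$snp_positions)

  # GC of the non-repeat portion within 0.37 +/- 0.01
  expect_lt(abs(host$truth$gc_unique - 0.37), 0.01)

  # realised repeat fraction reached the target
  expect_gte(host$truth$repeat_fraction, 0.4)
  ann <- host$truth$repeat_annotations
  expect_true(all(ann$start >= 0 & ann$end <= 1e6 & ann$start < ann$end))
  # annotations tile the claimed repeat bases exactly (no overlap)
  expect_equal(sum(ann$end - ann$start), round(1e6 * host$truth$repeat_fraction))
  ord <- order(ann$start)
  expect_true(all(ann$start[ord][-1] >= ann$end[ord][-nrow(ann)]))
  # annotated copies really are exact family copies
  fam <- ann$family[ord][1]
  copies <- ann[ann$family == fam, ]
  seqs <- substring(host$haplotype_a, copies$start + 1, copies$end)
  expect_length(unique(seqs), 1L)
})

test_that("snp_rate = 0 gives identical haplotypes", {
  cfg <- simulation_config(host_length = 2e4, snp_rate = 0,
                           repeat_fraction = 0.2, seed = 2L)
  host <- simulate_host_genome(cfg)
  expect_identical(host$haplotype_a, host$haplotype_b)
  expect_length(host$truth$snp_positions, 0L)
})

test_that("contaminant genome matches requested GC and is deterministic", {
  expect_false(grepl("[^GC]", simulate_contaminant_genome(500, gc = 1,
                                                          seed = 4L)))
  g <- simulate_contaminant_genome(2e5, gc = 0.65, seed = 5L)
  expect_lt(abs(gc_content(g) - 0.65), 0.01)
  expect_identical(g, simulate_contaminant_genome(2e5, gc = 0.65,
                                                  seed = 5L))
  expect_error(simulate_contaminant_genome(0, 0.5))
})

test_that("error-free reads are exact substrings of the source", {
  cfg <- simulation_config(host_length = 5000, snp_rate = 0,
                           repeat_fraction = 0, contaminants = list(),
                           coverage = 10, base_error_rate = 0,
                           frac_adapter = 0, frac_n = 0, frac_low_q = 0,
                           insert_mean = 300, seed = 6L,
                           repeat_unit_lengths = 50:200)
  g <- simulate_host_genome(cfg)$haplotype_a
  pairs <- simulate_reads(list(list(name = "host", seqs = g,
                                    abundance = 1)), cfg)
  both <- c(pairs$seq1, pairs$seq2)
  rc <- revcomp(g)
  hit <- vapply(both, function(r)
    grepl(r, g, fixed = TRUE) || grepl(r, rc, fixed = TRUE), TRUE)
  expect_true(all(hit))
})

test_that("read volume, abundance apportioning and label conservation", {
  cfg <- simulation_config(host_length = 1e5, repeat_fraction = 0.2,
                           contaminants = list(list(length = 2e4, gc = 0.65,
                                                    abundance = 0.05)),
                           coverage = 50, seed = 8L)
  sim <- simulate_sample(cfg)
  total_bases <- sum(nchar(sim$pairs$seq1) + nchar(sim$pairs$seq2))
  expect_lt(abs(total_bases - 50 * 1.2e5) / (50 * 1.2e5), 0.01)

  # each pair has exactly one origin label; counts sum to pair count
  tab <- table(sim$pairs$origin)
  expect_equal(sum(tab), nrow(sim$pairs))
  expect_setequal(names(tab), c("host", "contaminant-1"))

  # contaminant pair fraction within binomial 3 sd of 0.05
  frac <- tab[["contaminant-1"]] / nrow(sim$pairs)
  sd3 <- 3 * sqrt(0.05 * 0.95 / nrow(sim$pairs))
  expect_lt(abs(frac - 0.05), max(sd3, 0.01))
})

test_that("identical config and seed give byte-identical FASTQ", {
  cfg <- simulation_config(host_length = 2e4, repeat_fraction = 0.2,
                           contaminants = list(), coverage = 5, seed = 9L)
  run <- function() {
    sim <- simulate_sample(cfg)
    f1 <- tempfile(); f2 <- tempfile()
    write_fastq(sim$pairs, f1, f2)
    c(readLines(f1), readLines(f2))
  }
  expect_identical(run(), run())
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(repeat_fraction = 0.96), "unreachable")
  expect_error(simulation_config(snp_rate = 0.2), "snp_rate")
  expect_error(simulation_config(
    contaminants = list(list(length = 10, gc = 0.5, abundance = 1.2))),
    "fraction|abundance")
  expect_error(simulation_config(host_length = 100), "10 x|10.x")
  expect_error(simulation_config(read_length = 500), "insert_mean")
  # fragment longer than genome
  cfg <- simulation_config(host_length = 2e4, repeat_fraction = 0.2,
                           contaminants = list(), coverage = 1, seed = 1L)
  expect_error(simulate_reads(list(list(name = "tiny", seqs = strrep("A", 200),
                                        abundance = 1)), cfg),
               "fragment longer")
})
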