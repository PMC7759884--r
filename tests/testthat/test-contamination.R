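# GC-depth profiling, stray extraction, hit labelling, contaminant
# database and read decontamination.

test_that("density grid and stray extraction behave on point cases", {
  ctg <- data.frame(id = "c1", seq = strrep("ACAT", 200), length = 800L,
                    gc = 0.40, mean_depth = 50)
  d <- gc_depth_density(ctg)
  expect_equal(nrow(d$points), 1L)
  expect_equal(nrow(d$grid), 1L)
  expect_equal(d$grid$gc_bin, 40)
  expect_equal(d$grid$depth_bin, 50)

  # below min_length or NA depth -> excluded; empty input -> empty grid
  ctg$length <- 300L
  expect_equal(nrow(gc_depth_density(ctg)$points), 0L)
  expect_equal(nrow(gc_depth_density(ctg)$grid), 0L)

  pts <- data.frame(id = c("a", "b", "c"),
                    gc_pct = c(70, 57, 40), depth = c(5, 10, 50))
  reg <- list(stray_region(57, 80, 0, 10, label = "hi_gc"))
  ex <- extract_stray(pts, reg)
  # inside, and exactly-on-boundary, contigs are extracted (inclusive)
  expect_setequal(ex$id, c("a", "b"))
  expect_equal(unique(ex$region), "hi_gc")
  expect_equal(nrow(extract_stray(pts, list())), 0L)
  # a contig is assigned to every region containing it
  reg2 <- c(reg, list(stray_region(0, 100, 0, 14, label = "low_depth")))
  expect_equal(sum(extract_stray(pts, reg2)$id == "a"), 2L)

  expect_error(stray_region(80, 57, 0, 10), "gc_min")
})

test_that("hit parsing and best-hit labelling follow the tie rules", {
  rows <- c(
    "c1\tFungusX\t98.2\t500\t5\t1\t1\t500\t100\t600\t1e-30\t800\tFungusX",
    "c1\tPlantY\t97.0\t480\t8\t2\t1\t480\t50\t530\t1e-20\t800\tPlantY",
    "c2\tPlantY\t99.0\t900\t2\t0\t1\t900\t1\t900\t1e-80\t1500\tPlantY",
    "c3\tMicrobeZ\t90.0\t100\t9\t1\t1\t100\t1\t100\t1e-3\t120\tMicrobeZ")
  f <- tempfile()
  writeLines(rows, f)
  hits <- read_blast_tab(f)
  expect_equal(nrow(hits), 4L)
  map <- c(FungusX = "microbe", PlantY = "host", MicrobeZ = "microbe")
  lab <- label_contigs(hits, map, contig_ids = c("c1", "c2", "c3", "c4"))
  lab <- lab[order(lab$id), ]
  # equal bit scores: the smaller e-value (1e-30) wins
  expect_equal(lab$category, c("microbe", "host", "unknown", "unknown"))
  # c3's only hit fails the 1e-5 e-value cutoff -> unknown

  # malformed rows error with a line number
  writeLines(c(rows[1], "c9\tonly\tthree"), f)
  expect_error(read_blast_tab(f), "line 2")
  writeLines("c1\tS\txx\t500\t5\t1\t1\t500\t100\t600\t1e-30\t800", f)
  expect_error(read_blast_tab(f), "percent identity")
})

test_that("contaminant database: counting and union property", {
  expect_length(build_db(character(0))$kmers, 0L)
  db1 <- build_db("ACGTACGTACGTACGTACGT")  # 20 bp, k = 17 -> <= 4 k-mers
  expect_lte(length(db1$kmers), 4L)
  a <- random_dna(60, 0.5)
  b <- random_dna(60, 0.5)
  expect_setequal(build_db(c(a, b))$kmers,
                  union(build_db(a)$kmers, build_db(b)$kmers))
})

test_that("read filtering: empty db, monotonicity, partition", {
  set.seed(61)
  host <- random_dna(5000, 0.37)
  cont <- random_dna(2000, 0.65)
  reads_h <- tile_reads(host, 100L, 40L)
  reads_c <- tile_reads(cont, 100L, 40L)
  pairs <- make_pairs(c(reads_h, reads_c))

  empty <- build_db(character(0))
  expect_equal(nrow(filter_contaminant_reads(pairs, empty)$removed), 0L)

  db <- build_db(cont)
  res <- filter_contaminant_reads(pairs, db, 0.5)
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(pairs))
  expect_setequal(res$removed$seq1, reads_c)

  # enlarging the db never shrinks the removed set
  db_big <- build_db(c(cont, substr(host, 1, 300)))
  res_big <- filter_contaminant_reads(pairs, db_big, 0.5)
  expect_true(all(res$removed$id %in% res_big$removed$id))
  # raising the threshold never grows it
  res_strict <- filter_contaminant_reads(pairs, db, 0.9)
  expect_true(all(res_strict$removed$id %in% res$removed$id))

  # report arithmetic and percent formatting
  expect_equal(res$report$removed_bases + sum(nchar(res$kept$seq1) +
                 nchar(res$kept$seq2)), res$report$total_bases)
  expect_equal(format_percent(100 * 10.5 / 120.1), "8.7")
  expect_equal(format_percent(100 * 0.1 / 154.3), "0.06")
})

test_that("simulated mix separates in the GC-depth plane and filters cleanly", {
  cfg <- simulation_config(host_length = 6e4, repeat_fraction = 0.2,
                           host_gc = 0.37,
                           contaminants = list(list(length = 15000,
                                                    gc = 0.65,
                                                    abundance = 0.05)),
                           coverage = 40, seed = 63L)
  sim <- simulate_sample(cfg)
  clean <- sim$pairs[filter_pairs(sim$pairs)$keep, ]
  ctg <- annotate_gc_depth(build_unitigs(clean, assembly_config()),
                           clean, 41)
  d <- gc_depth_density(ctg, min_length = 300)
  share <- origin_share(ctg$seq[match(d$points$id, ctg$id)],
                        sim$contaminant_genomes[[1]])
  is_cont <- !is.na(share) & share >= 0.5
  expect_gt(sum(is_cont), 0)
  # contaminant mode: higher GC, lower depth than the host mode
  expect_gt(mean(d$points$gc_pct[is_cont]), mean(d$points$gc_pct[!is_cont]))
  expect_lt(mean(d$points$depth[is_cont]), mean(d$points$depth[!is_cont]))

  # db from the true contaminant genome: high precision and recall
  db <- build_db(sim$contaminant_genomes[[1]])
  res <- filter_contaminant_reads(clean, db, 0.5)
  truth_cont <- clean$origin == "contaminant-1"
  removed <- clean$id %in% res$removed$id
  recall <- sum(removed & truth_cont) / sum(truth_cont)
  precision <- sum(removed & truth_cont) / max(1, sum(removed))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
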