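# Ground-truthed simulation of a contaminated diploid sample: host genome
# with implanted exact repeats and SNP heterozygosity, microbial contaminant
# genomes of distinct GC, and error-bearing paired-end reads with explicit
# QC-rule violations. Coordinates are 0-based half-open internally.

#' Simulation configuration
#'
#' Defaults describe the sample the survey emulates: a ~Mb-scale diploid
#' plant genome with 0.5% SNP heterozygosity, 78% exact-repeat fraction and
#' 37% GC, one high-GC (65%) microbial contaminant at 5% read abundance,
#' 2 x 150 bp paired-end reads from ~350 bp inserts at 60-fold coverage,
#' 0.2% per-base substitution error, and ~11% of pairs carrying an explicit
#' quality-control violation (adapter, N-rich mate, or low-quality bases).
#'
#' @param host_length haploid host genome length in bases.
#' @param host_gc host GC fraction in `[0, 1]`.
#' @param snp_rate per-base probability that a site is heterozygous.
#' @param repeat_fraction target fraction of the host genome made of
#'   implanted exact repeat copies (max 0.95).
#' @param repeat_unit_lengths integer vector of allowed repeat unit lengths.
#' @param contaminants list of contaminant descriptors, each a list with
#'   `length` (bases), `gc` (fraction) and `abundance` (fraction of read
#'   pairs).
#' @param read_length read length in bases.
#' @param insert_mean,insert_sd insert size distribution (bases).
#' @param coverage total sequencing fold coverage over all genomes.
#' @param base_error_rate per-base substitution error probability.
#' @param adapter adapter sequence injected into adapter-violating reads.
#' @param frac_adapter,frac_n,frac_low_q fractions of read pairs that are
#'   made to violate, respectively, the adapter, N-ratio and low-quality
#'   filters.
#' @param seed integer seed fixing all randomness.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(host_length = 1e6,
                              host_gc = 0.37,
                              snp_rate = 0.005,
                              repeat_fraction = 0.78,
                              repeat_unit_lengths = 50:500,
                              contaminants = list(
                                list(length = 1e5, gc = 0.65,
                                     abundance = 0.05)),
                              read_length = 150L,
                              insert_mean = 350,
                              insert_sd = 35,
                              coverage = 60,
                              base_error_rate = 0.002,
                              adapter = paste0("AGATCGGAAGAGCACACGTCTGAAC",
                                               "TCCAGTCA"),
                              frac_adapter = 0.05,
                              frac_n = 0.02,
                              frac_low_q = 0.04,
                              seed = 1L) {
  cfg <- list(host_length = as.integer(host_length), host_gc = host_gc,
              snp_rate = snp_rate, repeat_fraction = repeat_fraction,
              repeat_unit_lengths = as.integer(repeat_unit_lengths),
              contaminants = contaminants,
              read_length = as.integer(read_length),
              insert_mean = insert_mean, insert_sd = insert_sd,
              coverage = coverage, base_error_rate = base_error_rate,
              adapter = adapter, frac_adapter = frac_adapter,
              frac_n = frac_n, frac_low_q = frac_low_q,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  fr <- c(cfg$host_gc, cfg$snp_rate, cfg$repeat_fraction,
          cfg$base_error_rate, cfg$frac_adapter, cfg$frac_n, cfg$frac_low_q)
  if (any(fr < 0 | fr > 1)) stop("all fractions must be in [0, 1]")
  if (cfg$snp_rate >= 0.1) stop("snp_rate must be < 0.1")
  if (cfg$repeat_fraction > 0.95)
    stop("configuration error: repeat_fraction > 0.95 is unreachable")
  ab <- vapply(cfg$contaminants, function(ct) ct$abundance, 0)
  if (length(ab) && sum(ab) >= 1)
    stop("contaminant abundances must sum to < 1")
  if (cfg$host_length < 10 * max(cfg$repeat_unit_lengths))
    stop("host_length must be >= 10 x max(repeat_unit_lengths)")
  if (cfg$read_length > cfg$insert_mean)
    stop("read_length must be <= insert_mean")
  if (cfg$coverage <= 0) stop("coverage must be > 0")
  invisible(cfg)
}

# Split a string of single bases (character vector) at `n_chunks` random
# points, returning a list of chunk index ranges covering 1..n.
chunk_breaks <- function(n, n_chunks) {
  if (n_chunks <= 1 || n == 0) return(list(c(1L, n)))
  cuts <- sort(sample.int(n + 1L, min(n_chunks - 1L, n), replace = FALSE)) - 1L
  bounds <- unique(c(0L, cuts, n))
  Map(function(a, b) c(a + 1L, b), head(bounds, -1), bounds[-1])
}

#' Simulate a diploid host genome with known truth
#'
#' Haplotype A is drawn base by base at the configured GC, with exact repeat
#' families (tandem and dispersed copies of randomly sampled units) implanted
#' until the realised repeat fraction reaches the target. Haplotype B is A
#' with substitutions at Bernoulli(`snp_rate`) positions, never to the same
#' base. All truth needed downstream (SNP positions, repeat annotations,
#' realised fractions) is returned.
#'
#' @param config a [simulation_config()].
#' @return list with `haplotype_a`, `haplotype_b` (strings) and `truth`, a
#'   list holding `snp_positions` (0-based), `repeat_annotations` (data frame
#'   with 0-based half-open `start`, `end`, `family`), `repeat_fraction`,
#'   `gc`, `gc_unique` and `length`.
#' @export
simulate_host_genome <- function(config = simulation_config()) {
  validate_simulation_config(config)
  with_seed(config$seed, {
    L <- config$host_length
    gc <- config$host_gc
    rep_target <- round(L * config$repeat_fraction)

    # sample repeat families until the repeat bases reach the target
    units <- character()
    copies <- integer()
    rep_bases <- 0L
    while (rep_bases < rep_target) {
      remaining <- rep_target - rep_bases
      ul <- sample(config$repeat_unit_lengths, 1L)
      nc <- sample(2:12, 1L)
      if (ul * 2L > remaining) {  # last family: land just past the target
        ul <- max(5L, ceiling(remaining / 2))
        nc <- max(2L, ceiling(remaining / ul))
      } else {
        nc <- min(nc, max(2L, floor(remaining / ul)))
      }
      units <- c(units, random_dna(ul, gc))
      copies <- c(copies, nc)
      rep_bases <- rep_bases + ul * nc
    }
    n_fam <- length(units)
    unique_len <- L - rep_bases
    if (unique_len < 0)
      stop("configuration error: repeat target leaves no unique sequence")

    # tokens: one per dispersed copy, one per tandem block
    tokens <- list()
    ann_fam <- integer()   # family per annotated copy, in token order
    ann_len <- integer()
    tok_fam_counts <- list()
    for (f in seq_len(n_fam)) {
      tandem <- n_fam > 0 && runif(1) < 0.5
      if (tandem) {
        tokens[[length(tokens) + 1L]] <-
          paste(rep(units[f], copies[f]), collapse = "")
        tok_fam_counts[[length(tokens)]] <- c(f, copies[f])
      } else {
        for (i in seq_len(copies[f])) {
          tokens[[length(tokens) + 1L]] <- units[f]
          tok_fam_counts[[length(tokens)]] <- c(f, 1L)
        }
      }
    }
    if (length(tokens)) {
      ord <- sample.int(length(tokens))
      tokens <- tokens[ord]
      tok_fam_counts <- tok_fam_counts[ord]
    }

    unique_seq <- random_dna(unique_len, gc)
    ranges <- chunk_breaks(unique_len, length(tokens) + 1L)

    parts <- character(0)
    ann <- list()
    pos <- 0L  # 0-based cursor
    for (i in seq_len(length(tokens) + 1L)) {
      if (i <= length(ranges)) {
        r <- ranges[[i]]
        if (r[2] >= r[1]) {
          chunk <- substr(unique_seq, r[1], r[2])
          parts <- c(parts, chunk)
          pos <- pos + nchar(chunk)
        }
      }
      if (i <= length(tokens)) {
        fam <- tok_fam_counts[[i]][1]
        ncopy <- tok_fam_counts[[i]][2]
        ul <- nchar(units[fam])
        for (ci in seq_len(ncopy)) {
          ann[[length(ann) + 1L]] <-
            data.frame(start = pos + (ci - 1L) * ul,
                       end = pos + ci * ul, family = fam)
        }
        parts <- c(parts, tokens[[i]])
        pos <- pos + nchar(tokens[[i]])
      }
    }
    hap_a <- paste(parts, collapse = "")
    stopifnot(nchar(hap_a) == L)

    # haplotype B: SNPs at Bernoulli(snp_rate) sites, always a different base
    chars <- strsplit(hap_a, "", fixed = TRUE)[[1]]
    snp_idx <- which(runif(L) < config$snp_rate)  # 1-based
    chars_b <- chars
    if (length(snp_idx)) {
      alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
      pick <- sample.int(3L, length(snp_idx), replace = TRUE)
      chars_b[snp_idx] <- mapply(function(b, p) alts[[b]][p],
                                 chars[snp_idx], pick)
    }
    hap_b <- paste(chars_b, collapse = "")

    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(start = integer(), end = integer(), family = integer())
    list(haplotype_a = hap_a, haplotype_b = hap_b,
         truth = list(
           snp_positions = snp_idx - 1L,
           repeat_annotations = annotations,
           repeat_fraction = rep_bases / L,
           gc = gc_content(hap_a),
           gc_unique = gc_content(unique_seq),
           length = L))
  })
}

#' Simulate a contaminant genome
#'
#' I.i.d. bases with `P(G or C) = gc`; a stand-in for a high-GC microbial
#' genome living alongside the host.
#'
#' @param length genome length in bases (> 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return a DNA string.
#' @export
simulate_contaminant_genome <- function(length, gc = 0.65, seed = 1L) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  with_seed(seed, random_dna(length, gc))
}

# inject substitution errors into reads; returns list(seqs, quals) where
# correct bases carry Q35 ('D') and erroneous bases Q2 ('#')
inject_errors <- function(seqs, error_rate) {
  n <- length(seqs)
  rl <- nchar(seqs)
  quals <- strrep("D", rl)
  if (error_rate <= 0) return(list(seqs = seqs, quals = quals))
  nerr <- rbinom(n, rl, error_rate)
  hit <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    qs <- rep("D", rl[i])
    pos <- sample.int(rl[i], nerr[i])
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      qs[p] <- "#"
    }
    seqs[i] <- paste(ch, collapse = "")
    quals[i] <- paste(qs, collapse = "")
  }
  list(seqs = seqs, quals = quals)
}

# overwrite a stretch of a string (1-based) with replacement text
splice <- function(x, at, repl) {
  paste0(substr(x, 1L, at - 1L), repl,
         substr(x, at + nchar(repl), nchar(x)))
}

#' Simulate paired-end reads from one or more genomes
#'
#' Fragments are sampled uniformly; host fragments come from a random
#' haplotype per fragment. Read 1 is the fragment start, read 2 the reverse
#' complement of the fragment end. Substitution errors are injected at
#' `base_error_rate` (Q2 at error positions, Q35 elsewhere), and disjoint
#' random subsets of pairs are corrupted to violate each QC rule: an adapter
#' stretch spliced into read 1, an N-rich mate, or >20% low-quality bases.
#' Total read bases are approximately `coverage` times the summed genome
#' lengths, apportioned across genomes by abundance.
#'
#' @param genomes list of genome descriptors, each a list with `name`,
#'   `seqs` (character vector: one sequence, or two haplotypes) and
#'   `abundance` (fraction of pairs; host abundance is the remainder).
#'   A single string or an unnamed list is accepted for convenience.
#' @param config a [simulation_config()] (supplies read geometry, error and
#'   violation rates, and the seed).
#' @return data frame of class `read_pairs` with columns `id`, `seq1`,
#'   `qual1`, `seq2`, `qual2`, `origin`.
#' @export
simulate_reads <- function(genomes, config = simulation_config()) {
  validate_simulation_config(config)
  if (is.character(genomes))
    genomes <- list(list(name = "host", seqs = genomes, abundance = 1))
  ab <- vapply(genomes, function(g) g$abundance, 0)
  if (abs(sum(ab) - 1) > 1e-8)
    stop("genome abundances must sum to 1")
  lens <- vapply(genomes, function(g) nchar(g$seqs[1]), 0)
  rl <- config$read_length
  for (i in seq_along(genomes)) {
    if (config$insert_mean > lens[i] || rl > lens[i])
      stop("fragment longer than genome '", genomes[[i]]$name, "'")
  }
  with_seed(config$seed + 1L, {
    total_bases <- config$coverage * sum(lens)
    n_pairs <- max(1L, round(total_bases / (2 * rl)))
    origin_i <- sample.int(length(genomes), n_pairs, replace = TRUE,
                           prob = ab)
    seq1 <- character(n_pairs)
    seq2 <- character(n_pairs)
    for (gi in seq_along(genomes)) {
      idx <- which(origin_i == gi)
      if (!length(idx)) next
      g <- genomes[[gi]]
      L <- lens[gi]
      m <- length(idx)
      ins <- pmin(L, pmax(rl, round(rnorm(m, config$insert_mean,
                                          config$insert_sd))))
      start <- floor(runif(m) * (L - ins + 1)) + 1L
      hap <- if (length(g$seqs) > 1)
        sample.int(length(g$seqs), m, replace = TRUE) else rep(1L, m)
      for (h in unique(hap)) {
        sel <- hap == h
        src <- g$seqs[h]
        seq1[idx[sel]] <- substring(src, start[sel], start[sel] + rl - 1L)
        seq2[idx[sel]] <- revcomp(substring(src,
                                            start[sel] + ins[sel] - rl,
                                            start[sel] + ins[sel] - 1L))
      }
    }
    e1 <- inject_errors(seq1, config$base_error_rate)
    e2 <- inject_errors(seq2, config$base_error_rate)
    seq1 <- e1$seqs; qual1 <- e1$quals
    seq2 <- e2$seqs; qual2 <- e2$quals

    # disjoint QC-violation subsets
    n_ad <- round(config$frac_adapter * n_pairs)
    n_n <- round(config$frac_n * n_pairs)
    n_lq <- round(config$frac_low_q * n_pairs)
    viol <- sample.int(n_pairs, min(n_pairs, n_ad + n_n + n_lq))
    ad_idx <- head(viol, n_ad)
    n_idx <- head(viol[-seq_len(n_ad)], n_n)
    lq_idx <- utils::tail(viol, max(0L, length(viol) - n_ad - n_n))
    for (i in ad_idx) {
      piece <- substr(config$adapter, 1L, min(20L, nchar(config$adapter)))
      at <- sample.int(rl - nchar(piece) + 1L, 1L)
      seq1[i] <- splice(seq1[i], at, piece)
    }
    for (i in n_idx) {
      n_n_bases <- floor(rl * 0.10) + 2L  # just over the 10% N threshold
      pos <- sort(sample.int(rl, n_n_bases))
      ch <- strsplit(seq1[i], "", fixed = TRUE)[[1]]
      qs <- strsplit(qual1[i], "", fixed = TRUE)[[1]]
      ch[pos] <- "N"; qs[pos] <- "#"
      seq1[i] <- paste(ch, collapse = "")
      qual1[i] <- paste(qs, collapse = "")
    }
    for (i in lq_idx) {
      n_low <- ceiling(0.21 * 2 * rl)  # just over 20% of combined bases
      pos <- sample.int(2L * rl, n_low)
      q <- paste0(qual1[i], qual2[i])
      qch <- strsplit(q, "", fixed = TRUE)[[1]]
      qch[pos] <- "#"
      qual1[i] <- paste(qch[1:rl], collapse = "")
      qual2[i] <- paste(qch[(rl + 1):(2 * rl)], collapse = "")
    }

    names_g <- vapply(seq_along(genomes), function(i) {
      nm <- genomes[[i]]$name
      if (is.null(nm)) if (i == 1) "host" else paste0("contaminant-", i - 1)
      else nm
    }, "")
    pairs <- data.frame(
      id = sprintf("pair%07d", seq_len(n_pairs)),
      seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
      origin = names_g[origin_i],
      stringsAsFactors = FALSE)
    class(pairs) <- c("read_pairs", "data.frame")
    pairs
  })
}

#' Simulate a full contaminated sample
#'
#' Convenience wrapper: host genome (diploid, per config), contaminant
#' genomes, and paired-end reads, with all ground truth retained.
#'
#' @param config a [simulation_config()].
#' @return list with `host` (output of [simulate_host_genome()]),
#'   `contaminant_genomes` (named character vector), `pairs`
#'   (a `read_pairs` data frame) and `config`.
#' @export
simulate_sample <- function(config = simulation_config()) {
  validate_simulation_config(config)
  host <- simulate_host_genome(config)
  genomes <- list(list(
    name = "host",
    seqs = c(host$haplotype_a, host$haplotype_b),
    abundance = 1 - sum(vapply(config$contaminants,
                               function(ct) ct$abundance, 0))))
  cont <- character(0)
  for (i in seq_along(config$contaminants)) {
    ct <- config$contaminants[[i]]
    nm <- paste0("contaminant-", i)
    g <- simulate_contaminant_genome(ct$length, ct$gc,
                                     seed = config$seed + 100L + i)
    cont[nm] <- g
    genomes[[length(genomes) + 1L]] <-
      list(name = nm, seqs = g, abundance = ct$abundance)
  }
  pairs <- simulate_reads(genomes, config)
  list(host = host, contaminant_genomes = cont, pairs = pairs,
       config = config)
}

#' Fabricate a taxonomy hit table for synthetic contigs
#'
#' Stands in for an external nucleotide-database search when analysing
#' simulated data: each contig is assigned to the reference genome with
#' which it shares the largest fraction of k-mers, and a 13-column tabular
#' hit row (12 standard columns plus a taxon label) is emitted when that
#' share reaches `min_share`. Contigs below the threshold get no row
#' (downstream labelling treats them as `unknown`).
#'
#' @param contigs `contigs` data frame (columns `id`, `seq`) or named
#'   character vector.
#' @param references named character vector of reference genomes; names are
#'   used as subject ids and taxon labels.
#' @param k k-mer size for the share computation.
#' @param min_share minimum k-mer share to report a hit.
#' @return data frame in 13-column tabular hit format.
#' @export
synthetic_hits <- function(contigs, references, k = 21L, min_share = 0.5) {
  if (is.data.frame(contigs)) {
    ids <- contigs$id
    seqs <- contigs$seq
  } else {
    ids <- names(contigs)
    seqs <- unname(contigs)
  }
  if (!length(ids)) return(empty_hits())
  shares <- vapply(names(references), function(nm) {
    db <- canonical_kmers_cpp(references[[nm]], as.integer(k))
    kmer_share_cpp(seqs, db, as.integer(k))
  }, numeric(length(ids)))
  shares <- matrix(shares, nrow = length(ids))
  best <- apply(shares, 1L, which.max)
  best_share <- shares[cbind(seq_along(ids), best)]
  keep <- !is.na(best_share) & best_share >= min_share
  if (!any(keep)) return(empty_hits())
  lens <- nchar(seqs[keep])
  data.frame(
    qseqid = ids[keep],
    sseqid = names(references)[best[keep]],
    pident = round(100 * best_share[keep], 2),
    length = lens, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = lens, sstart = 1L, send = lens,
    evalue = 1e-50,
    bitscore = round(2 * best_share[keep] * lens, 1),
    taxon = names(references)[best[keep]],
    stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             taxon = character(), stringsAsFactors = FALSE)
}

#' Write the simulation truth tables
#'
#' @param sim output of [simulate_sample()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(position = sim$host$truth$snp_positions),
            file.path(dir, "snp_positions.tsv"))
  write_tsv(sim$host$truth$repeat_annotations,
            file.path(dir, "repeat_annotations.tsv"))
  write_tsv(sim$pairs[, c("id", "origin")],
            file.path(dir, "read_origins.tsv"))
  invisible(dir)
}
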