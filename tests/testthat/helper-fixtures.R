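# Shared fixtures and independent oracles, all built in code.

# small clean read-pairs object built by hand
make_pairs <- function(seq1, seq2 = seq1, qual_char = "D") {
  df <- data.frame(
    id = sprintf("p%03d", seq_along(seq1)),
    seq1 = seq1, qual1 = strrep(qual_char, nchar(seq1)),
    seq2 = seq2, qual2 = strrep(qual_char, nchar(seq2)),
    stringsAsFactors = FALSE)
  class(df) <- c("read_pairs", "data.frame")
  df
}

# deterministic tiling reads: every window of length `len`, step `step`,
# alternating strand so both orientations occur
tile_reads <- function(genome, len = 100L, step = 1L) {
  n <- nchar(genome)
  starts <- seq(1L, n - len + 1L, by = step)
  reads <- substring(genome, starts, starts + len - 1L)
  flip <- seq_along(reads) %% 2L == 0L
  reads[flip] <- revcomp(reads[flip])
  reads
}

# brute-force canonical k-mer histogram: substring enumeration + string
# comparison, no rolling codes
kmer_hist_oracle <- function(reads, k) {
  grab <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    w <- substring(s, 1:(n - k + 1), k:n)
    w[!grepl("[^ACGT]", w)]
  }
  kmers <- unlist(lapply(toupper(reads), grab))
  if (!length(kmers)) return(NULL)
  canon <- pmin(kmers, revcomp(kmers))
  tab <- table(canon)
  hist <- table(as.integer(tab))
  kmer_histogram(as.integer(names(hist)), as.integer(hist), k = k)
}

# regex-backed SSR oracle: perfect tandem runs via backreferences,
# primitivity via a backreference too, then the shared output conventions
# (full units, smallest-unit-first greedy non-overlap)
ssr_oracle <- function(seq, min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  seq <- toupper(seq)
  cand <- list()
  for (u in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, min_repeats[u] - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    for (j in seq_along(m)) {
      reps <- lens[j] %/% u
      motif <- substr(seq, m[j], m[j] + u - 1L)
      if (grepl("^(.+?)\\1+$", motif, perl = TRUE)) next  # not primitive
      if (reps < min_repeats[u]) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = m[j], end = m[j] + reps * u - 1L, unit_length = u,
        repeats = reps, motif = motif, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(),
                      unit_length = integer(), repeats = integer(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  rec <- do.call(rbind, cand)
  rec <- rec[order(rec$start, rec$unit_length), , drop = FALSE]
  keep <- logical(nrow(rec))
  last_end <- 0L
  for (i in seq_len(nrow(rec))) {
    if (rec$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- rec$end[i]
    }
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random sequence with implanted tandem runs, for oracle equivalence
random_seq_with_ssrs <- function(n = 10000L, n_implants = 5L) {
  s <- strsplit(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                      collapse = ""), "")[[1]]
  for (i in seq_len(n_implants)) {
    u <- sample(1:6, 1)
    reps <- sample(4:15, 1)
    motif <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE),
                   collapse = "")
    run <- strsplit(strrep(motif, reps), "")[[1]]
    at <- sample.int(n - length(run), 1)
    s[at:(at + length(run) - 1L)] <- run
  }
  paste(s, collapse = "")
}

# fraction of a contig's k-mers found in a reference genome
origin_share <- function(seqs, reference, k = 21L) {
  db <- gsurvey:::canonical_kmers_cpp(reference, as.integer(k))
  gsurvey:::kmer_share_cpp(seqs, db, as.integer(k))
}
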