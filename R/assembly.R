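# Minimal de Bruijn unitig assembler: a conservative stand-in for a full
# short-read assembler. Contigs are maximal non-branching paths over
# canonical k-mers whose count clears a low-frequency threshold, so no
# bubble popping, no scaffolding, no gap filling.

#' Assembly configuration
#'
#' @param k odd k-mer size for the de Bruijn graph (default 41).
#' @param min_kmer_count k-mers seen fewer times are treated as sequencing
#'   error and dropped before path building (default 2).
#' @param min_contig_length_stats minimum contig length entering assembly
#'   statistics (default 100).
#' @param min_contig_length_profile minimum contig length entering GC-depth
#'   profiling (default 500).
#' @return list of class `assembly_config`.
#' @export
assembly_config <- function(k = 41L, min_kmer_count = 2L,
                            min_contig_length_stats = 100L,
                            min_contig_length_profile = 500L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  stopifnot(k >= 3L, k <= 63L, min_kmer_count >= 1L)
  structure(list(k = k, min_kmer_count = as.integer(min_kmer_count),
                 min_contig_length_stats =
                   as.integer(min_contig_length_stats),
                 min_contig_length_profile =
                   as.integer(min_contig_length_profile)),
            class = "assembly_config")
}

#' Assemble unitigs from reads
#'
#' Builds the canonical de Bruijn graph over `k`-mers with count at least
#' `min_kmer_count` and emits every maximal non-branching path once, in the
#' lexicographically smaller of its two orientations. Windows containing N
#' never enter the graph, so no contig contains an N.
#'
#' @param reads character vector of sequences or a `read_pairs` data frame.
#' @param config an [assembly_config()].
#' @return data frame of class `contigs` with columns `id`, `seq`,
#'   `length` (and `gc`, `mean_depth` after [annotate_gc_depth()]).
#' @export
build_unitigs <- function(reads, config = assembly_config()) {
  if (is.data.frame(reads)) reads <- c(reads$seq1, reads$seq2)
  seqs <- build_unitigs_cpp(reads, config$k, config$min_kmer_count)
  contigs <- data.frame(
    id = sprintf("utg%06d", seq_along(seqs)),
    seq = seqs, length = nchar(seqs),
    stringsAsFactors = FALSE)
  class(contigs) <- c("contigs", "data.frame")
  contigs
}

#' Assembly statistics
#'
#' Total length, contig count, maximum length, N50 and N-base fraction of
#' contigs at least `min_length` long. N50 is the length of the contig at
#' which the cumulative length, in descending length order, first reaches
#' half the total.
#'
#' @param contigs a `contigs` data frame (or anything with `seq`/`length`
#'   columns).
#' @param min_length minimum contig length included (default 100).
#' @return list of class `assembly_stats`: `total_length`, `n_contigs`,
#'   `max_length`, `n50`, `n_base_fraction`.
#' @export
contig_stats <- function(contigs, min_length = 100L) {
  len <- contigs$length[contigs$length >= min_length]
  if (!length(len)) {
    return(structure(list(total_length = 0, n_contigs = 0L, max_length = 0,
                          n50 = 0, n_base_fraction = 0),
                     class = "assembly_stats"))
  }
  seqs <- contigs$seq[contigs$length >= min_length]
  len <- sort(len, decreasing = TRUE)
  total <- sum(as.numeric(len))
  n50 <- len[which(cumsum(as.numeric(len)) >= total / 2)[1]]
  structure(list(
    total_length = total, n_contigs = length(len), max_length = len[1],
    n50 = n50,
    n_base_fraction = sum(count_chars(seqs, "[Nn]")) / total),
    class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "%d contigs | total %.0f bp | max %.0f bp | N50 %.0f bp | N bases %s%%\n",
    x$n_contigs, x$total_length, x$max_length, x$n50,
    format_percent(100 * x$n_base_fraction)))
  invisible(x)
}

#' Annotate contigs with GC content and mean k-mer depth
#'
#' GC is (G+C) over non-N length. Depth is the mean, over the contig's
#' N-free `k`-mer windows, of that k-mer's occurrence count in the reads —
#' a deterministic alignment-free proxy for per-base sequencing depth.
#' Contigs shorter than `k` get `NA` depth and are excluded from profiling.
#'
#' @param contigs a `contigs` data frame.
#' @param reads the read set the contigs were assembled from (character
#'   vector or `read_pairs` data frame).
#' @param k k-mer size of the read index; must match the assembly k so the
#'   contig's k-mers exist in the read index.
#' @return `contigs` with `gc` (fraction) and `mean_depth` columns added.
#' @export
annotate_gc_depth <- function(contigs, reads, k = 41L) {
  if (is.data.frame(reads)) reads <- c(reads$seq1, reads$seq2)
  contigs$gc <- gc_content(contigs$seq)
  contigs$mean_depth <- mean_kmer_depth_cpp(contigs$seq, reads,
                                            as.integer(k))
  contigs
}
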