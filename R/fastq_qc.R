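# Clean-read filtering for paired-end data. Whole pairs are kept or
# discarded (no trimming), with three mutually exclusive discard reasons
# applied in priority order: adapter, then N fraction, then low quality.

#' Quality-control configuration
#'
#' @param adapters character vector of adapter sequences; a read matches
#'   when it contains an exact substring of any adapter at least
#'   `adapter_min_match` bases long.
#' @param adapter_min_match minimum exact adapter match length (bases).
#' @param max_n_fraction per-mate N-fraction above which the pair is
#'   discarded (strictly greater).
#' @param low_q_threshold Phred score below which a base counts as
#'   low quality.
#' @param max_low_q_fraction fraction of low-quality bases, over both mates
#'   combined, above which the pair is discarded (strictly greater).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(adapters = c(
                        "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                        "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"),
                      adapter_min_match = 12L,
                      max_n_fraction = 0.10,
                      low_q_threshold = 5L,
                      max_low_q_fraction = 0.20) {
  stopifnot(max_n_fraction >= 0, max_n_fraction <= 1,
            max_low_q_fraction >= 0, max_low_q_fraction <= 1,
            adapter_min_match >= 1, low_q_threshold >= 0,
            low_q_threshold <= 60)
  structure(list(adapters = toupper(adapters),
                 adapter_min_match = as.integer(adapter_min_match),
                 max_n_fraction = max_n_fraction,
                 low_q_threshold = as.integer(low_q_threshold),
                 max_low_q_fraction = max_low_q_fraction),
            class = "qc_config")
}

# all distinct windows of length m across the configured adapters
adapter_probes <- function(config) {
  m <- config$adapter_min_match
  probes <- unlist(lapply(config$adapters, function(a) {
    if (nchar(a) < m) return(character(0))
    substring(a, seq_len(nchar(a) - m + 1L), m:nchar(a))
  }))
  unique(probes)
}

# regex character class for Phred+33 qualities strictly below `q`
lowq_class <- function(q) {
  if (q <= 0) return(NULL)
  sprintf("[%s-%s]", rawToChar(as.raw(33L)), rawToChar(as.raw(33L + q - 1L)))
}

#' Filter read pairs
#'
#' Applies the clean-read rules to every pair: discard with reason
#' `adapter` if either mate contains an exact >= `adapter_min_match` bp
#' substring of a configured adapter; else `n_fraction` if either mate has
#' an N fraction above `max_n_fraction`; else `low_quality` if the fraction
#' of bases below Phred `low_q_threshold` over both mates combined exceeds
#' `max_low_q_fraction`; else keep.
#'
#' @param pairs `read_pairs` data frame (columns `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param config a [qc_config()].
#' @return data frame with logical `keep` and character `reason`
#'   (`NA` for kept pairs), one row per input pair.
#' @export
filter_pairs <- function(pairs, config = qc_config()) {
  if (!nrow(pairs)) {
    return(data.frame(keep = logical(), reason = character()))
  }
  len1 <- nchar(pairs$seq1)
  len2 <- nchar(pairs$seq2)
  if (any(len1 == 0 | len2 == 0)) stop("empty read in pair")
  if (any(len1 != nchar(pairs$qual1) | len2 != nchar(pairs$qual2)))
    stop("sequence/quality length mismatch")

  adapter_hit <- rep(FALSE, nrow(pairs))
  for (p in adapter_probes(config)) {
    todo <- !adapter_hit
    if (!any(todo)) break
    adapter_hit[todo] <- grepl(p, pairs$seq1[todo], fixed = TRUE) |
      grepl(p, pairs$seq2[todo], fixed = TRUE)
  }

  n1 <- count_chars(pairs$seq1, "[Nn]")
  n2 <- count_chars(pairs$seq2, "[Nn]")
  n_hit <- (n1 / len1 > config$max_n_fraction) |
    (n2 / len2 > config$max_n_fraction)

  cls <- lowq_class(config$low_q_threshold)
  if (is.null(cls)) {
    lq_hit <- rep(FALSE, nrow(pairs))
  } else {
    low <- count_chars(pairs$qual1, cls) + count_chars(pairs$qual2, cls)
    lq_hit <- low / (len1 + len2) > config$max_low_q_fraction
  }

  reason <- rep(NA_character_, nrow(pairs))
  reason[lq_hit] <- "low_quality"
  reason[n_hit] <- "n_fraction"
  reason[adapter_hit] <- "adapter"
  data.frame(keep = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Filter a single read pair
#'
#' Scalar convenience around [filter_pairs()].
#'
#' @param pair list or one-row data frame with `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @param config a [qc_config()].
#' @return `"keep"` or `"discard:<reason>"`.
#' @export
filter_pair <- function(pair, config = qc_config()) {
  df <- as.data.frame(pair[c("seq1", "qual1", "seq2", "qual2")],
                      stringsAsFactors = FALSE)
  res <- filter_pairs(df, config)
  if (res$keep) "keep" else paste0("discard:", res$reason)
}

#' Sequencing summary statistics
#'
#' Raw/clean volumes, per-reason discard counts, Q30 fraction and GC
#' content of the clean bases (GC excludes N from the denominator).
#'
#' @param pairs `read_pairs` data frame.
#' @param flags output of [filter_pairs()] for the same pairs.
#' @return list of class `qc_stats`: `raw_pairs`, `raw_bases`,
#'   `clean_pairs`, `clean_bases`, `discarded` (named counts), `q30`,
#'   `gc`, `raw_gb`, `clean_gb`.
#' @export
qc_summary <- function(pairs, flags = filter_pairs(pairs)) {
  stopifnot(nrow(pairs) == nrow(flags))
  len <- nchar(pairs$seq1) + nchar(pairs$seq2)
  keep <- flags$keep
  reasons <- c("adapter", "n_fraction", "low_quality")
  discarded <- vapply(reasons,
                      function(r) sum(flags$reason == r, na.rm = TRUE), 0L)
  clean_bases <- sum(len[keep])
  if (clean_bases > 0) {
    q30 <- (sum(count_chars(pairs$qual1[keep], "[?-~]")) +
              sum(count_chars(pairs$qual2[keep], "[?-~]"))) / clean_bases
    gc <- gc_content_pooled(c(pairs$seq1[keep], pairs$seq2[keep]))
  } else {
    q30 <- 0
    gc <- 0
  }
  structure(list(
    raw_pairs = nrow(pairs), raw_bases = sum(len),
    clean_pairs = sum(keep), clean_bases = clean_bases,
    discarded = discarded, q30 = q30, gc = gc,
    raw_gb = sum(len) / 1e9, clean_gb = clean_bases / 1e9),
    class = "qc_stats")
}

#' @export
print.qc_stats <- function(x, ...) {
  cat(sprintf("raw:   %d pairs, %.2f Gb\n", x$raw_pairs, x$raw_gb))
  cat(sprintf("clean: %d pairs, %.2f Gb (Q30 %s%%, GC %s%%)\n",
              x$clean_pairs, x$clean_gb,
              format_percent(100 * x$q30), format_percent(100 * x$gc)))
  cat("discarded:",
      paste(names(x$discarded), x$discarded, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# ---- FASTQ IO --------------------------------------------------------------

parse_fastq_lines <- function(lines, path) {
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("truncated FASTQ record at end of ", path,
         " (record ", n %/% 4L + 1L, ")")
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("malformed FASTQ header in ", path,
                        " (record ", bad[1], ")")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("malformed FASTQ separator in ", path,
                        " (record ", bad[1], ")")
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) stop("sequence/quality length mismatch in ", path,
                        " (record ", bad[1], ": ", hdr[bad[1]], ")")
  qr <- range(utf8ToInt(paste(quals, collapse = "")))
  if (length(quals) && (qr[1] < 33L || qr[2] > 93L))
    stop("quality characters outside Phred+33 range [0, 60] in ", path)
  list(id = sub("^@", "", hdr), seq = seqs, qual = quals)
}

#' Read paired FASTQ files
#'
#' Reads 4-line Phred+33 FASTQ with mates in two synchronised files, or
#' interleaved in one file when `path2` is `NULL`. Mate ids must agree
#' after stripping a trailing `/1` / `/2`.
#'
#' @param path1 mate-1 FASTQ (or interleaved file).
#' @param path2 mate-2 FASTQ, or `NULL` for interleaved input.
#' @return `read_pairs` data frame with `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @export
read_fastq <- function(path1, path2 = NULL) {
  if (is.null(path2)) {
    all <- parse_fastq_lines(readLines(path1), path1)
    n <- length(all$id)
    if (n %% 2L != 0L) stop("interleaved FASTQ with odd record count: ",
                            path1)
    odd <- seq(1L, n, by = 2L)
    r1 <- lapply(all, `[`, odd)
    r2 <- lapply(all, `[`, odd + 1L)
  } else {
    r1 <- parse_fastq_lines(readLines(path1), path1)
    r2 <- parse_fastq_lines(readLines(path2), path2)
  }
  if (length(r1$id) != length(r2$id))
    stop("desynchronised mates: ", length(r1$id), " vs ", length(r2$id),
         " records")
  base1 <- sub("/[12]$", "", sub("\\s.*$", "", r1$id))
  base2 <- sub("/[12]$", "", sub("\\s.*$", "", r2$id))
  bad <- which(base1 != base2)
  if (length(bad))
    stop("desynchronised mates at record ", bad[1], ": '", r1$id[bad[1]],
         "' vs '", r2$id[bad[1]], "'")
  pairs <- data.frame(id = base1, seq1 = r1$seq, qual1 = r1$qual,
                      seq2 = r2$seq, qual2 = r2$qual,
                      stringsAsFactors = FALSE)
  class(pairs) <- c("read_pairs", "data.frame")
  pairs
}

#' Write paired FASTQ files
#'
#' Inverse of [read_fastq()]: writes `@id/1` / `@id/2` headers, so
#' `write_fastq(read_fastq(x))` is byte-identical for files it produced.
#'
#' @param pairs `read_pairs` data frame.
#' @param path1 mate-1 output (or interleaved output).
#' @param path2 mate-2 output, or `NULL` to interleave into `path1`.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq <- function(pairs, path1, path2 = NULL) {
  rec <- function(id, mate, s, q) {
    as.vector(rbind(paste0("@", id, "/", mate), s, "+", q))
  }
  l1 <- rec(pairs$id, 1L, pairs$seq1, pairs$qual1)
  l2 <- rec(pairs$id, 2L, pairs$seq2, pairs$qual2)
  if (is.null(path2)) {
    inter <- character(length(l1) + length(l2))
    if (nrow(pairs)) {
      blk <- rep(seq_len(nrow(pairs)), each = 4L)
      inter <- as.vector(rbind(matrix(l1, nrow = 4L), matrix(l2, nrow = 4L)))
    }
    writeLines(inter, path1)
  } else {
    writeLines(l1, path1)
    writeLines(l2, path2)
  }
  invisible(c(path1, path2))
}

#' Decode Phred+33 quality strings
#'
#' @param qual character vector of quality strings.
#' @return list of integer vectors of Phred scores.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}
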