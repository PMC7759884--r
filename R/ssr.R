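# Perfect microsatellite detection with the classic survey thresholds:
# minimum 10/6/5/5/5/5 repeats for motif lengths 1-6. Only perfect simple
# SSRs are reported (no compound merging); partial trailing units are not
# counted and not covered by the reported coordinates. Output coordinates
# are 1-based inclusive.

#' SSR detection configuration
#'
#' @param min_repeats integer vector of length 6: minimum number of full
#'   repeats for motif lengths 1 through 6.
#' @return list of class `ssr_config`.
#' @export
ssr_config <- function(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  min_repeats <- as.integer(min_repeats)
  stopifnot(length(min_repeats) == 6, all(min_repeats >= 2))
  structure(list(min_repeats = min_repeats), class = "ssr_config")
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a whole-number repetition of a
#' shorter motif (`"AT"` is, `"ATAT"` is not).
#'
#' @param motif character vector of motifs.
#' @return logical vector.
#' @export
is_primitive <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n <= 1) return(TRUE)
    for (d in seq_len(n - 1)) {
      if (n %% d == 0 &&
          strrep(substr(m, 1, d), n / d) == m) return(FALSE)
    }
    TRUE
  }, TRUE, USE.NAMES = FALSE)
}

rotations <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n), function(i)
    paste0(substr(m, i, n), substr(m, 1, i - 1)), "")
}

#' Standardised motif class
#'
#' Collapses rotations and strands: `X` is the lexicographically smallest
#' rotation of the motif, `Y` the smallest rotation of its reverse
#' complement, and the class is `"min/max"` of the two (so `"TTA"` becomes
#' `"AAT/ATT"` and `"AT"` the self-complementary `"AT/AT"`).
#'
#' @param motif character vector of primitive motifs (length 1-6).
#' @return character vector of class labels.
#' @export
motif_class <- function(motif) {
  if (any(!is_primitive(motif)))
    stop("motif_class requires primitive motifs")
  vapply(motif, function(m) {
    x <- min(rotations(m))
    y <- min(rotations(revcomp(m)))
    paste(min(x, y), max(x, y), sep = "/")
  }, "", USE.NAMES = FALSE)
}

# candidate maximal runs for one sequence and one unit length, before
# cross-unit overlap resolution; chars/valid are precomputed vectors
runs_for_unit <- function(seq, chars, valid, u, min_rep) {
  n <- length(chars)
  if (n < u * min_rep) return(NULL)
  i <- seq_len(n - u)
  m <- chars[i] == chars[i + u] & valid[i] & valid[i + u]
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths + u >= u * min_rep)
  if (!length(sel)) return(NULL)
  out <- lapply(sel, function(j) {
    i0 <- starts[j]
    region_len <- r$lengths[j] + u
    reps <- region_len %/% u
    if (reps < min_rep) return(NULL)
    motif <- substr(seq, i0, i0 + u - 1L)
    if (!is_primitive(motif)) return(NULL)
    data.frame(start = i0, end = i0 + reps * u - 1L, unit_length = u,
               repeats = reps, motif = motif, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) NULL else do.call(rbind, out)
}

# greedy overlap resolution: records sorted by start then unit length;
# smaller units win ties, later overlapping records are suppressed
resolve_overlaps <- function(rec) {
  if (is.null(rec) || !nrow(rec)) return(rec)
  rec <- rec[order(rec$start, rec$unit_length), , drop = FALSE]
  keep <- logical(nrow(rec))
  last_end <- 0L
  for (i in seq_len(nrow(rec))) {
    if (rec$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- rec$end[i]
    }
  }
  rec[keep, , drop = FALSE]
}

#' Find perfect SSRs
#'
#' Reports every maximal perfect tandem run of a primitive motif of unit
#' length 1-6 meeting the per-unit minimum repeat count. Runs containing N
#' are excluded, only full units count toward `repeats` and coordinates,
#' the smallest primitive unit wins when an interval qualifies at several
#' unit lengths, and the output is non-overlapping and ordered by start.
#'
#' @param seqs named character vector of sequences (a single unnamed
#'   sequence is accepted) or a `contigs` data frame.
#' @param config an [ssr_config()].
#' @return data frame with `seqid`, `start`, `end` (1-based inclusive),
#'   `unit_length`, `repeats`, `motif`, `motif_class`.
#' @export
find_ssrs <- function(seqs, config = ssr_config()) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$id)
  if (is.null(names(seqs)))
    names(seqs) <- if (length(seqs) == 1) "seq1"
                   else sprintf("seq%d", seq_along(seqs))
  res <- lapply(names(seqs), function(id) {
    s <- toupper(seqs[[id]])
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    valid <- chars %in% c("A", "C", "G", "T")
    cand <- lapply(1:6, function(u)
      runs_for_unit(s, chars, valid, u, config$min_repeats[u]))
    cand <- cand[!vapply(cand, is.null, TRUE)]
    if (!length(cand)) return(NULL)
    rec <- resolve_overlaps(do.call(rbind, cand))
    if (!nrow(rec)) return(NULL)
    cbind(data.frame(seqid = id, stringsAsFactors = FALSE), rec)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), unit_length = integer(),
                      repeats = integer(), motif = character(),
                      motif_class = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$motif_class <- motif_class(out$motif)
  rownames(out) <- NULL
  out
}

#' Summarise an SSR record set
#'
#' Totals, counts and percentage shares by unit length, a repeat-number
#' distribution (top-coded), and motif-class counts with a top-20 ranking.
#' Shares are formatted to one decimal place (two below 1 percent).
#'
#' @param records output of [find_ssrs()].
#' @param repeat_cap repeat numbers at or above this value are pooled into
#'   one top-coded group (default 15).
#' @param top_n how many motif classes the `top_classes` table keeps.
#' @return list of class `ssr_summary` with `total`, `by_unit`,
#'   `by_repeat`, `by_class`, `top_classes`.
#' @export
summarize_ssrs <- function(records, repeat_cap = 15L, top_n = 20L) {
  total <- nrow(records)
  if (!total) {
    empty <- data.frame(count = integer(), share_pct = numeric(),
                        share = character())
    return(structure(list(total = 0L, by_unit = empty, by_repeat = empty,
                          by_class = empty, top_classes = empty),
                     class = "ssr_summary"))
  }
  share_cols <- function(count) {
    pct <- 100 * count / total
    list(share_pct = pct, share = format_percent(pct))
  }
  unit_tab <- table(factor(records$unit_length, levels = 1:6))
  by_unit <- data.frame(unit_length = 1:6,
                        count = as.integer(unit_tab))
  by_unit <- cbind(by_unit, share_cols(by_unit$count))

  reps <- pmin(records$repeats, repeat_cap)
  rep_lab <- ifelse(reps >= repeat_cap, paste0(repeat_cap, "+"),
                    as.character(reps))
  by_repeat <- as.data.frame(table(unit_length = records$unit_length,
                                   repeats = rep_lab),
                             stringsAsFactors = FALSE)
  names(by_repeat)[3] <- "count"
  by_repeat <- by_repeat[by_repeat$count > 0, ]
  by_repeat <- by_repeat[order(as.integer(by_repeat$unit_length),
                               suppressWarnings(
                                 as.integer(sub("\\+", "", by_repeat$repeats)))), ]
  rownames(by_repeat) <- NULL

  cls_tab <- sort(table(records$motif_class), decreasing = TRUE)
  by_class <- data.frame(motif_class = names(cls_tab),
                         count = as.integer(cls_tab),
                         stringsAsFactors = FALSE)
  by_class <- cbind(by_class, share_cols(by_class$count))

  structure(list(total = total, by_unit = by_unit, by_repeat = by_repeat,
                 by_class = by_class,
                 top_classes = head(by_class, top_n)),
            class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("%d SSRs\n", x$total))
  if (x$total) {
    cat("by unit length:\n")
    print(x$by_unit[, c("unit_length", "count", "share")],
          row.names = FALSE)
    cat("top motif classes:\n")
    print(head(x$top_classes[, c("motif_class", "count", "share")], 5),
          row.names = FALSE)
  }
  invisible(x)
}
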