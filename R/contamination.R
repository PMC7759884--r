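# Contaminant screening: contigs are placed in the (GC%, depth) plane,
# contigs falling in user-declared stray rectangles are pulled for
# taxonomic checking, contigs labelled microbial seed a contaminant k-mer
# database, and read pairs sharing enough k-mers with that database are
# filtered out. Labels decide database membership, not location: stray
# regions that turn out to hold low-depth host contigs contribute nothing.

#' Define a stray region of the GC-depth plane
#'
#' An axis-aligned rectangle (inclusive bounds) holding anomalous contigs
#' selected for taxonomic checking.
#'
#' @param gc_min,gc_max GC bounds in percent (0-100).
#' @param depth_min,depth_max depth bounds in fold coverage.
#' @param label region name.
#' @return list of class `stray_region`.
#' @export
stray_region <- function(gc_min, gc_max, depth_min, depth_max,
                         label = sprintf("gc%g-%g_depth%g-%g", gc_min,
                                         gc_max, depth_min, depth_max)) {
  stopifnot(gc_min >= 0, gc_min < gc_max, gc_max <= 100,
            depth_min >= 0, depth_min < depth_max)
  structure(list(gc_min = gc_min, gc_max = gc_max, depth_min = depth_min,
                 depth_max = depth_max, label = label),
            class = "stray_region")
}

#' GC-depth points and binned density grid
#'
#' Turns annotated contigs into points in the (GC percent, depth) plane
#' plus a binned density grid (1% GC by 1-fold depth bins by default, depth
#' clamped at `depth_cap`). Contigs shorter than `min_length` or without a
#' defined depth are excluded.
#'
#' @param contigs output of [annotate_gc_depth()].
#' @param min_length minimum contig length profiled (default 500).
#' @param gc_bin,depth_bin bin widths in GC percent and fold depth.
#' @param depth_cap maximum depth; larger depths are clamped for binning.
#' @return list with `points` (data frame `id`, `length`, `gc_pct`,
#'   `depth`) and `grid` (data frame `gc_bin`, `depth_bin`, `count`,
#'   lower bin edges).
#' @export
gc_depth_density <- function(contigs, min_length = 500L, gc_bin = 1,
                             depth_bin = 1, depth_cap = 250) {
  keep <- contigs$length >= min_length & !is.na(contigs$mean_depth)
  points <- data.frame(id = contigs$id[keep],
                       length = contigs$length[keep],
                       gc_pct = 100 * contigs$gc[keep],
                       depth = contigs$mean_depth[keep],
                       stringsAsFactors = FALSE)
  if (!nrow(points)) {
    grid <- data.frame(gc_bin = numeric(), depth_bin = numeric(),
                       count = integer())
    return(list(points = points, grid = grid))
  }
  gb <- floor(points$gc_pct / gc_bin) * gc_bin
  db <- floor(pmin(points$depth, depth_cap) / depth_bin) * depth_bin
  grid <- as.data.frame(table(gc_bin = gb, depth_bin = db),
                        stringsAsFactors = FALSE)
  grid <- grid[grid$Freq > 0, ]
  grid <- data.frame(gc_bin = as.numeric(grid$gc_bin),
                     depth_bin = as.numeric(grid$depth_bin),
                     count = grid$Freq)
  grid <- grid[order(grid$gc_bin, grid$depth_bin), ]
  rownames(grid) <- NULL
  list(points = points, grid = grid)
}

#' Extract contigs falling in stray regions
#'
#' A contig is assigned to every region containing it; bounds are
#' inclusive on all four sides.
#'
#' @param points `points` data frame from [gc_depth_density()].
#' @param regions list of [stray_region()]s.
#' @return data frame with `id`, `gc_pct`, `depth`, `region`; zero rows if
#'   nothing falls in any region.
#' @export
extract_stray <- function(points, regions) {
  out <- lapply(regions, function(r) {
    sel <- points$gc_pct >= r$gc_min & points$gc_pct <= r$gc_max &
      points$depth >= r$depth_min & points$depth <= r$depth_max
    if (!any(sel)) return(NULL)
    data.frame(id = points$id[sel], gc_pct = points$gc_pct[sel],
               depth = points$depth[sel], region = r$label,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(id = character(), gc_pct = numeric(),
                      depth = numeric(), region = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read a 12-column tabular hit file
#'
#' Standard tabular alignment format (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query/subject coordinates,
#' e-value, bit score), with an optional 13th taxon-label column.
#'
#' @param path tab-separated hit file without header.
#' @return data frame with named columns (including `taxon` when present).
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits()[, , drop = FALSE])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L & nf != 13L)
  if (length(bad))
    stop("malformed tabular hit row at line ", bad[1], " of ", path,
         " (", nf[bad[1]], " fields)")
  if (length(unique(nf)) > 1)
    stop("mixed 12/13-column rows in ", path)
  m <- do.call(rbind, fields)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric ", what, " at line ", bad[1], " of ", path)
    v
  }
  hits <- data.frame(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = num(3, "percent identity"), length = num(4, "length"),
    mismatch = num(5, "mismatches"), gapopen = num(6, "gap opens"),
    qstart = num(7, "qstart"), qend = num(8, "qend"),
    sstart = num(9, "sstart"), send = num(10, "send"),
    evalue = num(11, "e-value"), bitscore = num(12, "bit score"),
    stringsAsFactors = FALSE)
  if (any(hits$evalue < 0) || any(hits$bitscore < 0))
    stop("negative e-value or bit score in ", path)
  if (nf[1] == 13L) hits$taxon <- m[, 13]
  hits
}

#' Label contigs from taxonomy hits
#'
#' Hits are filtered at `max_evalue`, the best hit per contig is chosen by
#' maximal bit score (ties: minimal e-value, then first in file order), and
#' its taxon label (or subject id when no taxon column exists) is mapped to
#' a category. Contigs without a surviving hit, or whose taxon is not in
#' the map, are `unknown`.
#'
#' @param hits data frame from [read_blast_tab()] or [synthetic_hits()].
#' @param taxon_map named character vector mapping taxon labels to
#'   categories (typically `"host"` / `"microbe"`).
#' @param contig_ids optional full contig universe; ids without hits are
#'   reported as `unknown`.
#' @param max_evalue e-value cutoff (default `1e-5`).
#' @return data frame with `id`, `category`, `best_subject`, `best_taxon`.
#' @export
label_contigs <- function(hits, taxon_map, contig_ids = NULL,
                          max_evalue = 1e-5) {
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (is.null(hits$taxon)) hits$taxon <- hits$sseqid
  ids <- unique(c(hits$qseqid, contig_ids))
  if (!length(ids)) {
    return(data.frame(id = character(), category = character(),
                      best_subject = character(), best_taxon = character(),
                      stringsAsFactors = FALSE))
  }
  best <- lapply(split(seq_len(nrow(hits)), hits$qseqid), function(rows) {
    h <- hits[rows, , drop = FALSE]
    h <- h[order(-h$bitscore, h$evalue, rows), , drop = FALSE]
    h[1, c("sseqid", "taxon")]
  })
  cat_of <- function(tax) {
    v <- unname(taxon_map[tax])
    ifelse(is.na(v), "unknown", v)
  }
  res <- data.frame(id = ids, category = "unknown",
                    best_subject = NA_character_,
                    best_taxon = NA_character_, stringsAsFactors = FALSE)
  hit_ids <- names(best)
  m <- match(hit_ids, res$id)
  res$best_subject[m] <- vapply(best, function(b) b$sseqid, "")
  res$best_taxon[m] <- vapply(best, function(b) b$taxon, "")
  res$category[m] <- cat_of(res$best_taxon[m])
  res
}

#' Build a contaminant k-mer database
#'
#' Canonical k-mer set of all N-free windows of the contigs judged
#' contaminant.
#'
#' @param contigs `contigs` data frame or character vector of sequences.
#' @param k k-mer size (default 17).
#' @return list of class `contaminant_db` with `k`, `kmers` (sorted
#'   character vector) and `source_ids`.
#' @export
build_db <- function(contigs, k = 17L) {
  if (is.data.frame(contigs)) {
    seqs <- contigs$seq
    ids <- contigs$id
  } else {
    seqs <- as.character(contigs)
    ids <- names(contigs)
  }
  structure(list(k = as.integer(k),
                 kmers = if (length(seqs))
                   canonical_kmers_cpp(seqs, as.integer(k))
                 else character(0),
                 source_ids = ids),
            class = "contaminant_db")
}

#' Filter contaminant read pairs
#'
#' A pair is removed when either mate shares at least `share_threshold` of
#' its N-free k-mers with the contaminant database — a deterministic,
#' alignment-free stand-in for querying reads against a contaminant
#' sequence database. Whole pairs are removed, never single mates.
#'
#' @param pairs `read_pairs` data frame.
#' @param db a [build_db()] result.
#' @param share_threshold minimum shared-k-mer fraction (default 0.5).
#' @return list with `kept` and `removed` (`read_pairs` subsets) and
#'   `report`: total/removed pairs and bases, `removed_fraction` and the
#'   formatted percentage.
#' @export
filter_contaminant_reads <- function(pairs, db, share_threshold = 0.5) {
  stopifnot(inherits(db, "contaminant_db"),
            share_threshold > 0, share_threshold <= 1)
  if (length(db$kmers) == 0 || !nrow(pairs)) {
    removed <- rep(FALSE, nrow(pairs))
  } else {
    s1 <- kmer_share_cpp(pairs$seq1, db$kmers, db$k)
    s2 <- kmer_share_cpp(pairs$seq2, db$kmers, db$k)
    removed <- (!is.na(s1) & s1 >= share_threshold) |
      (!is.na(s2) & s2 >= share_threshold)
  }
  bases <- nchar(pairs$seq1) + nchar(pairs$seq2)
  total_bases <- sum(bases)
  removed_bases <- sum(bases[removed])
  pct <- if (total_bases > 0) 100 * removed_bases / total_bases else 0
  list(kept = pairs[!removed, , drop = FALSE],
       removed = pairs[removed, , drop = FALSE],
       report = list(total_pairs = nrow(pairs),
                     removed_pairs = sum(removed),
                     total_bases = total_bases,
                     removed_bases = removed_bases,
                     removed_fraction = if (total_bases > 0)
                       removed_bases / total_bases else 0,
                     removed_pct_label = format_percent(pct)))
}

#' Plot a GC-depth profile
#'
#' Contig points in the (GC percent, depth) plane with optional stray
#' rectangles.
#'
#' @param density output of [gc_depth_density()].
#' @param regions optional list of [stray_region()]s to draw.
#' @param depth_cap y-axis limit.
#' @return invisibly, the points data frame.
#' @export
plot_gc_depth <- function(density, regions = NULL, depth_cap = 250) {
  p <- density$points
  graphics::plot(p$gc_pct, pmin(p$depth, depth_cap),
                 pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlim = c(0, 100), ylim = c(0, depth_cap),
                 xlab = "GC content (%)", ylab = "average depth (x)")
  for (r in regions) {
    graphics::rect(r$gc_min, r$depth_min, r$gc_max,
                   pmin(r$depth_max, depth_cap),
                   border = "red", lty = 2)
  }
  invisible(p)
}
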