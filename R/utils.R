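# Shared small helpers: sequence utilities, formatting, plain-text IO.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement; characters outside `ACGTacgt` (e.g. `N`)
#' are kept as-is, so ambiguity codes survive a round trip.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  revcomp_cpp(x)
}

# count characters of `x` matching a regex character class
count_chars <- function(x, class) {
  nchar(x) - nchar(gsub(class, "", x, perl = TRUE))
}

#' GC content of DNA strings
#'
#' Fraction (G + C) / (A + C + G + T); `N` and other ambiguity characters
#' are excluded from the denominator.
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector of fractions in `[0, 1]`; `NaN` for sequences
#'   with no unambiguous base.
#' @export
gc_content <- function(x) {
  gc <- count_chars(x, "[GCgc]")
  acgt <- count_chars(x, "[ACGTacgt]")
  gc / acgt
}

# pooled GC over a whole vector of sequences (single fraction)
gc_content_pooled <- function(x) {
  gc <- sum(count_chars(x, "[GCgc]"))
  acgt <- sum(count_chars(x, "[ACGTacgt]"))
  if (acgt == 0) return(0)
  gc / acgt
}

#' Format a percentage the way survey reports print them
#'
#' One decimal place, two decimal places below 1 percent (so 8.742 prints
#' as `"8.7"` and 0.0648 as `"0.06"`).
#'
#' @param pct numeric vector of percentages (0-100 scale).
#' @return character vector.
#' @export
format_percent <- function(pct) {
  ifelse(abs(pct) < 1, sprintf("%.2f", pct), sprintf("%.1f", pct))
}

# run code with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# i.i.d. random DNA with P(G or C) = gc, returned as one string
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector (names become record ids) or a
#'   `contigs` data frame with `id` and `seq` columns.
#' @param path output file.
#' @param width line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$id)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("FASTA records need names")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path input file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) stop("not a FASTA file: ", path)
  grp <- cumsum(hdr)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 paste, collapse = "", FUN.VALUE = "")
  stats::setNames(toupper(seqs), ids)
}

# TSV helpers used across modules
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}
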