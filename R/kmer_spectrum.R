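# 17-mer spectrum analysis. The depth histogram of canonical k-mer species
# drives four estimates:
#   genome size      = total k-mer occurrences / main peak depth
#   error rate       = occurrences at depth 1 / total occurrences
#   revised size     = size * (1 - error rate)
#   heterozygosity   = a / (k * (2 - a)), a = half-depth species ratio
#   repetitive rate  = occurrences above 1.8 x main peak / occurrences
#                      above the error boundary

#' Count canonical k-mers of a read set
#'
#' Every length-`k` window free of non-ACGT characters contributes one
#' occurrence of its canonical form (the lexicographic minimum of the
#' k-mer and its reverse complement). Reads shorter than `k` contribute
#' nothing.
#'
#' @param reads character vector of sequences, or a `read_pairs` data frame
#'   (both mates are used).
#' @param k odd k-mer size between 3 and 31 (default 17).
#' @return object of class `kmer_histogram`: list with `k`, `depth`
#'   (integer, ascending) and `species` (numeric counts of distinct k-mers
#'   at each depth).
#' @export
count_kmers <- function(reads, k = 17L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 3L || k > 31L) stop("k must be between 3 and 31")
  if (is.data.frame(reads)) reads <- c(reads$seq1, reads$seq2)
  h <- kmer_hist_cpp(reads, k)
  kmer_histogram(h$depth, h$species, k = k)
}

#' Construct a k-mer depth histogram
#'
#' @param depth integer vector of depths (positive, unique).
#' @param species counts of distinct k-mer species at each depth.
#' @param k the k-mer size the histogram was computed at.
#' @return object of class `kmer_histogram`.
#' @export
kmer_histogram <- function(depth, species, k = 17L) {
  depth <- as.integer(depth)
  species <- as.numeric(species)
  stopifnot(length(depth) == length(species), !anyNA(depth),
            all(depth >= 1L), !any(duplicated(depth)), all(species >= 0))
  o <- order(depth)
  structure(list(k = as.integer(k), depth = depth[o], species = species[o]),
            class = "kmer_histogram")
}

#' Total distinct k-mer species in a histogram
#' @param hist a `kmer_histogram`.
#' @return numeric scalar.
#' @export
n_species <- function(hist) sum(hist$species)

#' Total k-mer occurrences in a histogram
#' @param hist a `kmer_histogram`.
#' @return numeric scalar (sum of depth x species).
#' @export
n_occurrences <- function(hist) sum(as.numeric(hist$depth) * hist$species)

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer histogram (k=%d): %d depth bins, %.4g species, %.4g occurrences\n",
              x$k, length(x$depth), n_species(x), n_occurrences(x)))
  invisible(x)
}

#' Write / read a k-mer histogram as two-column TSV
#'
#' The format (depth, species) matches standard k-mer counter histogram
#' dumps.
#'
#' @param hist a `kmer_histogram`.
#' @param path file path.
#' @param k k-mer size to attach on reading.
#' @return `path` / a `kmer_histogram`.
#' @export
write_kmer_histogram <- function(hist, path) {
  write_tsv(data.frame(depth = hist$depth, species = hist$species), path)
}

#' @rdname write_kmer_histogram
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  df <- read_tsv(path)
  kmer_histogram(df$depth, df$species, k = k)
}

# dense species vector over depths 1..max(depth)
dense_species <- function(hist) {
  sp <- numeric(max(hist$depth))
  sp[hist$depth] <- hist$species
  sp
}

#' Locate the error boundary and main peak of a k-mer spectrum
#'
#' The error boundary is the smallest depth `d >= 2` that is a local
#' minimum of the species counts (`species(d) <= species(d -1)` and
#' `species(d) <= species(d + 1)`, missing depths counting as zero). The
#' main peak is the smallest depth above the boundary with maximal species
#' count. Its half depth marks the heterozygous peak and 1.8 times the
#' peak marks the repeat threshold.
#'
#' @param hist a `kmer_histogram`.
#' @param smooth apply a window-3 moving average before peak-finding
#'   (off by default).
#' @return list of class `spectrum_peaks`: `error_boundary`, `main_peak`,
#'   `half_peak`, `repeat_threshold`.
#' @export
find_peaks <- function(hist, smooth = FALSE) {
  if (!length(hist$depth) || n_species(hist) == 0)
    stop("spectrum estimation error: empty histogram")
  sp <- dense_species(hist)
  if (length(sp) < 3)
    stop("spectrum estimation error: histogram has no structure beyond depth 2")
  if (smooth) {  # window-3 moving average, zero-padded at the ends
    sp <- as.numeric(stats::filter(c(0, sp, 0), rep(1 / 3, 3)))
    sp <- sp[2:(length(sp) - 1)]
  }
  spx <- c(sp, 0)
  eb <- NA_integer_
  for (d in 2:length(sp)) {
    if (spx[d] <= spx[d - 1] && spx[d] <= spx[d + 1]) { eb <- d; break }
  }
  if (is.na(eb) || eb >= length(sp))
    stop("spectrum estimation error: no local minimum after the error peak; ",
         "the histogram decreases monotonically (no genomic peak)")
  cand <- (eb + 1):length(sp)
  peak <- cand[which.max(sp[cand])]
  if (sp[peak] <= 0)
    stop("spectrum estimation error: no species mass above the error ",
         "boundary (depth ", eb, ")")
  structure(list(error_boundary = eb, main_peak = peak,
                 half_peak = peak / 2, repeat_threshold = 1.8 * peak),
            class = "spectrum_peaks")
}

#' Estimate genome size from a k-mer spectrum
#'
#' Total k-mer occurrences divided by the main peak depth.
#'
#' @param hist a `kmer_histogram`.
#' @param peaks a `spectrum_peaks` (default: computed from `hist`).
#' @return genome size in bases.
#' @export
estimate_genome_size <- function(hist, peaks = find_peaks(hist)) {
  stopifnot(peaks$main_peak > 0)
  n_occurrences(hist) / peaks$main_peak
}

#' Sequencing error rate from depth-1 k-mers
#'
#' The proportion of k-mer occurrences seen exactly once. A species-based
#' denominator is available as an alternative convention.
#'
#' @param hist a `kmer_histogram`.
#' @param denominator `"occurrences"` (default) or `"species"`.
#' @return error rate in `[0, 1]`.
#' @export
estimate_error_rate <- function(hist,
                                denominator = c("occurrences", "species")) {
  denominator <- match.arg(denominator)
  s1 <- if (any(hist$depth == 1L)) hist$species[hist$depth == 1L] else 0
  den <- if (denominator == "occurrences") n_occurrences(hist)
         else n_species(hist)
  if (den == 0) return(0)
  s1 / den
}

#' Revise a genome size estimate for sequencing error
#'
#' `revised = size * (1 - error_rate)` with the error rate taken from the
#' depth-1 k-mers of the histogram.
#'
#' @param size genome size in bases.
#' @param hist a `kmer_histogram`.
#' @param error_rate override the histogram-derived error rate.
#' @return revised genome size in bases.
#' @export
revise_genome_size <- function(size, hist,
                               error_rate = estimate_error_rate(hist)) {
  stopifnot(size > 0, error_rate >= 0, error_rate <= 1)
  size * (1 - error_rate)
}

#' Estimate heterozygosity from the half-depth peak
#'
#' `a` is the fraction of k-mer species (above the error boundary) whose
#' depth falls in the half-peak window, by default 0.4 to 0.6 times the
#' main peak. Per-base heterozygosity is then `a / (k * (2 - a))`.
#'
#' @param hist a `kmer_histogram`.
#' @param peaks a `spectrum_peaks`.
#' @param window half-peak attribution window as multiples of the main
#'   peak depth (inclusive bounds).
#' @return list with `a_half` and `heterozygosity` (fractions).
#' @export
estimate_heterozygosity <- function(hist, peaks = find_peaks(hist),
                                    window = c(0.4, 0.6)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  lo <- window[1] * peaks$main_peak
  hi <- window[2] * peaks$main_peak
  genomic <- hist$depth > peaks$error_boundary
  den <- sum(hist$species[genomic])
  a <- if (den == 0) 0 else
    sum(hist$species[genomic & hist$depth >= lo & hist$depth <= hi]) / den
  list(a_half = a, heterozygosity = a / (hist$k * (2 - a)))
}

#' Estimate the repetitive rate
#'
#' The fraction of k-mer occurrences (above the error boundary) at depths
#' strictly greater than `multiple` (default 1.8) times the main peak.
#'
#' @param hist a `kmer_histogram`.
#' @param peaks a `spectrum_peaks`.
#' @param multiple repeat depth threshold as a multiple of the main peak.
#' @return repetitive rate in `[0, 1]`.
#' @export
estimate_repetitive_rate <- function(hist, peaks = find_peaks(hist),
                                     multiple = 1.8) {
  occ <- as.numeric(hist$depth) * hist$species
  genomic <- hist$depth > peaks$error_boundary
  den <- sum(occ[genomic])
  if (den == 0) return(0)
  sum(occ[hist$depth > multiple * peaks$main_peak & genomic]) / den
}

#' Full genome estimate from a k-mer histogram
#'
#' Bundles peak depth, occurrence total, genome size, error-revised size,
#' half-peak species ratio, heterozygosity and repetitive rate — one row of
#' a survey's k-mer analysis table.
#'
#' @param hist a `kmer_histogram`.
#' @param peaks a `spectrum_peaks` (default: computed from `hist`).
#' @param het_window half-peak window passed to
#'   [estimate_heterozygosity()].
#' @param repeat_multiple threshold passed to
#'   [estimate_repetitive_rate()].
#' @return list of class `genome_estimate` with fields `main_peak_depth`,
#'   `n_kmer` (occurrences), `genome_size`, `error_rate`,
#'   `revised_genome_size` (bases), `a_half`, `heterozygosity`,
#'   `repetitive_rate` (fractions).
#' @export
genome_estimate <- function(hist, peaks = find_peaks(hist),
                            het_window = c(0.4, 0.6),
                            repeat_multiple = 1.8) {
  size <- estimate_genome_size(hist, peaks)
  err <- estimate_error_rate(hist)
  het <- estimate_heterozygosity(hist, peaks, het_window)
  structure(list(
    main_peak_depth = peaks$main_peak,
    n_kmer = n_occurrences(hist),
    genome_size = size,
    error_rate = err,
    revised_genome_size = revise_genome_size(size, hist, err),
    a_half = het$a_half,
    heterozygosity = het$heterozygosity,
    repetitive_rate = estimate_repetitive_rate(hist, peaks,
                                               repeat_multiple)),
    class = "genome_estimate")
}

#' @export
print.genome_estimate <- function(x, ...) {
  cat(sprintf(
    "depth %dx | %.0f k-mers | size %.2f Mb | revised %.2f Mb | het %s%% | repeats %s%%\n",
    x$main_peak_depth, x$n_kmer, x$genome_size / 1e6,
    x$revised_genome_size / 1e6,
    format_percent(100 * x$heterozygosity),
    format_percent(100 * x$repetitive_rate)))
  invisible(x)
}

#' Plot a k-mer spectrum
#'
#' Depth against species frequency, with the error boundary, half peak,
#' main peak and repeat threshold marked.
#'
#' @param hist a `kmer_histogram`.
#' @param peaks optional `spectrum_peaks` to annotate.
#' @param depth_cap maximum depth shown.
#' @return invisibly, the plotted data frame.
#' @export
plot_kmer_spectrum <- function(hist, peaks = NULL, depth_cap = 250) {
  keep <- hist$depth <= depth_cap
  freq <- hist$species / n_species(hist)
  graphics::plot(hist$depth[keep], freq[keep], type = "l",
                 xlab = "depth (x)", ylab = "fraction of k-mer species",
                 main = sprintf("%d-mer spectrum", hist$k))
  if (!is.null(peaks)) {
    graphics::abline(v = c(peaks$error_boundary, peaks$half_peak,
                           peaks$main_peak, peaks$repeat_threshold),
                     lty = c(3, 2, 1, 2),
                     col = c("grey50", "blue", "red", "darkgreen"))
  }
  invisible(data.frame(depth = hist$depth[keep], frequency = freq[keep]))
}
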