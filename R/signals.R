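#' GC content of a nucleotide window
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from numerator and
#' denominator. A window with no called base returns `NA`.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Numeric vector in `[0, 1]` (or `NA`).
#' @export
gc_content <- function(seq) {
  stopifnot(all(nchar(seq) > 0))
  counts <- base_counts(seq)
  called <- counts[, "A"] + counts[, "C"] + counts[, "G"] + counts[, "T"]
  out <- (counts[, "G"] + counts[, "C"]) / called
  out[called == 0] <- NA_real_
  unname(out)
}

#' GC skew of a nucleotide window
#'
#' `(G - C) / (G + C)`; a window with no G or C returns 0 by convention.
#' Discontinuities in GC skew along a replichore can mark horizontally
#' acquired DNA such as integrated prophages.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Numeric vector in `[-1, 1]`.
#' @export
gc_skew <- function(seq) {
  stopifnot(all(nchar(seq) > 0))
  counts <- base_counts(seq)
  gc <- counts[, "G"] + counts[, "C"]
  out <- (counts[, "G"] - counts[, "C"]) / gc
  out[gc == 0] <- 0
  unname(out)
}

base_counts <- function(seq) {
  x <- Biostrings::DNAStringSet(toupper(seq))
  Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character vector of nucleotide strings (A/C/G/T/N).
#' @return Reverse-complemented strings.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

genes_in_window <- function(genes, low, high) {
  mid <- (genes$low + genes$high) / 2
  genes[mid >= low & mid <= high, , drop = FALSE]
}

#' Median predicted-protein length in a window
#'
#' Median `aa_len` over genes whose midpoint lies in the window; phage
#' regions tend to carry markedly longer predicted proteins than host
#' background.
#'
#' @param ann A `genome_annotation`.
#' @param window `c(low, high)` in bp.
#' @return Median aa length, or `NA` when the window holds no gene.
#' @export
median_protein_length <- function(ann, window) {
  g <- genes_in_window(ann$genes, window[1], window[2])
  if (nrow(g) == 0) return(NA_real_)
  stats::median(g$aa_len)
}

#' Longest same-strand gene run, as a fraction of window genes
#'
#' Consecutive phage genes tend to be co-oriented; the statistic is the
#' length of the longest run of consecutive same-strand genes in the window
#' divided by the number of genes in the window.
#'
#' @param ann A `genome_annotation`.
#' @param window `c(low, high)` in bp.
#' @return Fraction in `(0, 1]`, or `NA` when the window holds no gene.
#' @export
strand_run_fraction <- function(ann, window) {
  g <- genes_in_window(ann$genes, window[1], window[2])
  if (nrow(g) == 0) return(NA_real_)
  runs <- rle(g$strand)
  max(runs$lengths) / nrow(g)
}

#' Fraction of phage-annotated genes in a window
#'
#' @param ann A `genome_annotation` (genes already categorized).
#' @param window `c(low, high)` in bp.
#' @param lexicon A `phage_lexicon`.
#' @return Fraction of window genes whose category is a phage category;
#'   0 when the window holds no gene.
#' @export
phage_density <- function(ann, window, lexicon = phage_lexicon()) {
  g <- genes_in_window(ann$genes, window[1], window[2])
  if (nrow(g) == 0) return(0)
  mean(is_phage_category(g$category, lexicon))
}

#' Window starts/ends tiling a genome
#'
#' Fixed-step tiling from position 1; when the genome length is not an exact
#' multiple of the step past the last full window, one final truncated
#' window is appended so the tiling reaches the genome end.
#'
#' @param genome_len Genome length in bp.
#' @param window_bp Window size.
#' @param step_bp Step size.
#' @return `data.frame` with `low` and `high`.
#' @export
tile_windows <- function(genome_len, window_bp, step_bp) {
  stopifnot(window_bp >= step_bp, step_bp >= 1)
  if (window_bp >= genome_len) {
    return(data.frame(low = 1L, high = as.integer(genome_len)))
  }
  starts <- seq.int(1L, genome_len - window_bp + 1L, by = step_bp)
  ends <- starts + window_bp - 1L
  if (ends[length(ends)] < genome_len) {
    starts <- c(starts, starts[length(starts)] + step_bp)
    ends <- c(ends, genome_len)
  }
  data.frame(low = as.integer(starts), high = as.integer(pmin(ends, genome_len)))
}

#' Compute all per-window signal tracks for a genome
#'
#' Nucleotide tracks (`gc_content`, `gc_skew`) are computed over
#' `window_bp`/`step_bp` windows and require a sequence; gene tracks
#' (`median_aa`, `strand_run_frac`, `phage_density`) are computed over
#' sliding windows of `genes_per_window` genes advanced by `gene_step`
#' genes, so that even a short prophage spans several gene windows.
#'
#' @param ann A `genome_annotation`.
#' @param window_bp,step_bp Nucleotide window and step (bp).
#' @param genes_per_window,gene_step Gene-window size and step (genes).
#' @param lexicon A `phage_lexicon`.
#' @return Named list of `signal_track` objects (each a `data.frame` with
#'   `low`, `high`, `value` and a `signal` attribute). GC tracks are absent
#'   when the annotation has no sequence.
#' @export
build_tracks <- function(ann, window_bp = 4000, step_bp = 1000,
                         genes_per_window = 20, gene_step = 5,
                         lexicon = phage_lexicon()) {
  stopifnot(inherits(ann, "genome_annotation"))
  tracks <- list()
  if (!is.null(ann$sequence)) {
    w <- tile_windows(ann$length, window_bp, step_bp)
    segs <- substring(ann$sequence, w$low, w$high)
    tracks$gc_content <- signal_track("gc_content", w$low, w$high,
                                      gc_content(segs))
    tracks$gc_skew <- signal_track("gc_skew", w$low, w$high, gc_skew(segs))
  }
  g <- ann$genes
  n <- nrow(g)
  if (n > 0) {
    k <- min(genes_per_window, n)
    starts <- seq.int(1L, max(1L, n - k + 1L), by = gene_step)
    if (starts[length(starts)] + k - 1L < n) starts <- c(starts, n - k + 1L)
    lo <- g$low[starts]
    hi <- g$high[pmin(starts + k - 1L, n)]
    mids <- (g$low + g$high) / 2
    med <- numeric(length(starts))
    run <- numeric(length(starts))
    dens <- numeric(length(starts))
    phage <- is_phage_category(g$category, lexicon)
    for (i in seq_along(starts)) {
      idx <- starts[i]:min(starts[i] + k - 1L, n)
      med[i] <- stats::median(g$aa_len[idx])
      run[i] <- max(rle(g$strand[idx])$lengths) / length(idx)
      dens[i] <- mean(phage[idx])
    }
    tracks$median_aa <- signal_track("median_aa", lo, hi, med)
    tracks$strand_run_frac <- signal_track("strand_run_frac", lo, hi, run)
    tracks$phage_density <- signal_track("phage_density", lo, hi, dens)
  }
  tracks
}

signal_track <- function(name, low, high, value) {
  structure(data.frame(low = as.integer(low), high = as.integer(high),
                       value = as.numeric(value)),
            signal = name, class = c("signal_track", "data.frame"))
}

#' Export signal tracks as a bedGraph-style TSV
#'
#' One row per window per track, 1-based inclusive coordinates.
#'
#' @param tracks Output of [build_tracks()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(names(tracks), function(nm) {
    data.frame(signal = nm, tracks[[nm]])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
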