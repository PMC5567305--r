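#' All maximal exact common substrings of two sequences
#'
#' Seed-and-extend search for every maximal exact match of length at least
#' `min_len` between `seq_a` and `seq_b`: a match is maximal when it cannot
#' be extended by one base on either side at its particular pair of
#' positions. Positions are 1-based.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param min_len Minimum match length (>= 8).
#' @return `data.frame` with `pos_a`, `pos_b`, `len`, sorted by decreasing
#'   length then position.
#' @export
find_direct_repeats <- function(seq_a, seq_b, min_len = 10) {
  if (min_len < 8) stop("min_len must be >= 8")
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) stop("empty sequence")
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  na <- length(a)
  nb <- length(b)
  empty <- data.frame(pos_a = integer(0), pos_b = integer(0), len = integer(0))
  if (na < min_len || nb < min_len) return(empty)
  k <- as.integer(min_len)
  ka <- substring(seq_a, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L)
  kb <- substring(seq_b, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L)
  pos_b_by_kmer <- split(seq_along(kb), kb)
  hits_a <- which(ka %in% names(pos_b_by_kmer))
  if (length(hits_a) == 0) return(empty)
  seen <- character(0)
  out_a <- integer(0); out_b <- integer(0); out_l <- integer(0)
  for (i in hits_a) {
    for (j in pos_b_by_kmer[[ka[i]]]) {
      # extend left
      s_a <- i; s_b <- j
      while (s_a > 1 && s_b > 1 && a[s_a - 1L] == b[s_b - 1L]) {
        s_a <- s_a - 1L; s_b <- s_b - 1L
      }
      # extend right
      e_a <- i + k - 1L; e_b <- j + k - 1L
      while (e_a < na && e_b < nb && a[e_a + 1L] == b[e_b + 1L]) {
        e_a <- e_a + 1L; e_b <- e_b + 1L
      }
      key <- paste(s_a, s_b, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      out_a <- c(out_a, s_a); out_b <- c(out_b, s_b)
      out_l <- c(out_l, e_a - s_a + 1L)
    }
  }
  res <- data.frame(pos_a = out_a, pos_b = out_b, len = out_l)
  res <- res[res$len >= min_len, , drop = FALSE]
  res <- res[order(-res$len, res$pos_a, res$pos_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find candidate attachment-site pairs flanking a prophage region
#'
#' Searches for exact direct repeats shared between the two flanks of a
#' called region — `end_window` bp to each side of the left and right
#' bounds — as attL/attR candidates (the recombination core of attP/attB is
#' an identical direct repeat, classically beside a tRNA gene). Candidates
#' are ranked by repeat length, ties broken by smaller distance to the
#' nearest tRNA.
#'
#' @param genome_seq Genome nucleotide string.
#' @param region A `candidate_region` (or list with `low`, `high`).
#' @param trnas tRNA `data.frame` (`low`, `high`); may be empty.
#' @param end_window Flank half-width around each bound (bp).
#' @param min_len Minimum repeat length.
#' @param max_candidates Maximum pairs returned.
#' @return `data.frame` with `repeat_seq`, `left_pos`, `right_pos`,
#'   `repeat_len`, `trna_distance`, `score`.
#' @export
find_att <- function(genome_seq, region, trnas = NULL, end_window = 2000,
                     min_len = 10, max_candidates = 5) {
  glen <- nchar(genome_seq)
  lo_a <- max(1L, region$low - end_window)
  hi_a <- min(glen, region$low + end_window)
  lo_b <- max(1L, region$high - end_window)
  hi_b <- min(glen, region$high + end_window)
  empty <- data.frame(repeat_seq = character(0), left_pos = integer(0),
                      right_pos = integer(0), repeat_len = integer(0),
                      trna_distance = numeric(0), score = integer(0))
  if (hi_a - lo_a + 1 < min_len || hi_b - lo_b + 1 < min_len) return(empty)
  flank_a <- substring(genome_seq, lo_a, hi_a)
  flank_b <- substring(genome_seq, lo_b, hi_b)
  rep_hits <- find_direct_repeats(flank_a, flank_b, min_len)
  if (nrow(rep_hits) == 0) return(empty)
  left_pos <- lo_a + rep_hits$pos_a - 1L
  right_pos <- lo_b + rep_hits$pos_b - 1L
  keep <- left_pos < right_pos
  rep_hits <- rep_hits[keep, , drop = FALSE]
  left_pos <- left_pos[keep]
  right_pos <- right_pos[keep]
  if (nrow(rep_hits) == 0) return(empty)
  tdist <- vapply(seq_len(nrow(rep_hits)), function(i) {
    if (is.null(trnas) || nrow(trnas) == 0) return(Inf)
    d1 <- interval_distance(left_pos[i], left_pos[i] + rep_hits$len[i] - 1L,
                            trnas)
    d2 <- interval_distance(right_pos[i], right_pos[i] + rep_hits$len[i] - 1L,
                            trnas)
    min(d1, d2)
  }, numeric(1))
  res <- data.frame(
    repeat_seq = substring(genome_seq, left_pos,
                           left_pos + rep_hits$len - 1L),
    left_pos = left_pos, right_pos = right_pos,
    repeat_len = rep_hits$len, trna_distance = tdist,
    score = rep_hits$len)
  res <- res[order(-res$repeat_len, res$trna_distance, res$left_pos), ,
             drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, max_candidates)
}

interval_distance <- function(low, high, intervals) {
  d <- pmax(0, pmax(intervals$low - high, low - intervals$high))
  min(d)
}
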