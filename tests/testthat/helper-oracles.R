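# Independent brute-force oracles, deliberately naive and separate from the
# production implementations they check.

# all maximal exact common substrings of length >= min_len, by checking
# every (i, j) start pair directly
bf_common_substrings <- function(seq_a, seq_b, min_len) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  na <- length(a)
  nb <- length(b)
  out <- list()
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (a[i] != b[j]) next
      # left-maximal only: previous characters must differ (or boundary)
      if (i > 1 && j > 1 && a[i - 1] == b[j - 1]) next
      l <- 0L
      while (i + l <= na && j + l <= nb && a[i + l] == b[j + l]) l <- l + 1L
      if (l >= min_len) {
        out[[length(out) + 1L]] <- c(i, j, l)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(pos_a = integer(0), pos_b = integer(0),
                      len = integer(0)))
  }
  m <- do.call(rbind, out)
  res <- data.frame(pos_a = m[, 1], pos_b = m[, 2], len = m[, 3])
  res[order(-res$len, res$pos_a, res$pos_b), ]
}

# exhaustive hairpin + U-tract enumeration over every (start, stem, loop)
bf_terminators <- function(seq_window, stem_range = c(4, 12),
                           loop_range = c(3, 8), min_u = 3,
                           min_stability = 6) {
  chars <- strsplit(toupper(seq_window), "")[[1]]
  n <- length(chars)
  pair <- function(x, y) {
    (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "G" & y == "C") | (x == "C" & y == "G")
  }
  out <- list()
  for (start in seq_len(n)) {
    for (stem in stem_range[1]:stem_range[2]) {
      for (loop in loop_range[1]:loop_range[2]) {
        hp_end <- start + 2 * stem + loop - 1
        if (hp_end > n) next
        ok <- TRUE
        gc <- 0
        at <- 0
        for (k in 1:stem) {
          x <- chars[start + k - 1]
          y <- chars[hp_end - k + 1]
          if (!pair(x, y)) { ok <- FALSE; break }
          if (x %in% c("G", "C")) gc <- gc + 1 else at <- at + 1
        }
        if (!ok) next
        stab <- gc + 0.5 * at
        if (stab < min_stability) next
        u <- 0
        for (k in 1:8) {
          if (hp_end + k > n) break
          if (chars[hp_end + k] == "T") u <- u + 1
        }
        if (u < min_u) next
        out[[length(out) + 1L]] <- data.frame(
          hairpin_start = start, stem_len = stem, loop_len = loop,
          u_count = u, stability = stab)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(hairpin_start = integer(0), stem_len = integer(0),
                      loop_len = integer(0), u_count = integer(0),
                      stability = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(-res$stability, res$hairpin_start, res$stem_len), ]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a small hand-built annotation for unit tests
toy_annotation <- function(strands = c("+", "+", "-", "+"),
                           annotations = rep("hypothetical protein", 4),
                           aa = rep(100L, length(strands)),
                           gene_len = 300L, gap = 100L,
                           sequence = NULL, length = NULL, trnas = NULL) {
  n <- length(strands)
  lows <- 1L + (seq_len(n) - 1L) * (gene_len + gap)
  highs <- lows + gene_len - 1L
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), strand = strands,
    start_raw = ifelse(strands == "+", lows, highs),
    stop_raw = ifelse(strands == "+", highs, lows),
    aa_len = aa, annotation = annotations, stringsAsFactors = FALSE)
  genome_annotation(genes, genome_id = "toy", sequence = sequence,
                    trnas = trnas, length = length)
}

sorted_key <- function(df) {
  df <- df[order(df$pos_a, df$pos_b, df$len), , drop = FALSE]
  paste(df$pos_a, df$pos_b, df$len, sep = ":", collapse = ";")
}
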