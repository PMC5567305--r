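#' Sigma-70 promoter model
#'
#' A consensus-derived position weight matrix for the housekeeping sigma-70
#' promoter: a -35 box (TTGACA) and a -10 box (TATAAT) separated by a
#' 15-19 bp spacer. Column base frequencies are built from the consensus
#' with a pseudocount of 0.1 against a uniform 0.25 background, and scores
#' are summed log2-odds over the twelve box positions.
#'
#' @param minus35,minus10 Consensus hexamers.
#' @param spacer_range Allowed spacer lengths (bp).
#' @param score_threshold Minimum summed log-odds for a hit. The default
#'   (12 bits) sits two consensus mismatches below the perfect-site score.
#' @param pseudocount Pseudocount per base.
#' @return An object of class `promoter_model`.
#' @export
promoter_model <- function(minus35 = "TTGACA", minus10 = "TATAAT",
                           spacer_range = c(15, 19), score_threshold = 12,
                           pseudocount = 0.1) {
  pwm <- function(consensus) {
    bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
    m <- matrix(pseudocount, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in seq_along(bases)) m[bases[i], i] <- m[bases[i], i] + 1
    m <- sweep(m, 2, colSums(m), "/")
    log2(m / 0.25)
  }
  structure(list(minus35 = pwm(minus35), minus10 = pwm(minus10),
                 spacer_range = as.integer(spacer_range),
                 score_threshold = score_threshold),
            class = "promoter_model")
}

#' Maximum achievable promoter model score
#'
#' @param model A `promoter_model`.
#' @return Sum of columnwise maxima of both boxes (bits).
#' @export
promoter_max_score <- function(model) {
  sum(apply(model$minus35, 2, max)) + sum(apply(model$minus10, 2, max))
}

pwm_scores <- function(chars, pwm, starts) {
  # summed log-odds of the pwm placed at each start (chars: genome letters)
  w <- ncol(pwm)
  s <- numeric(length(starts))
  for (k in seq_len(w)) {
    base <- chars[starts + k - 1L]
    col <- pwm[, k]
    v <- unname(col[base])
    v[is.na(v)] <- min(col)  # N scores as worst base
    s <- s + v
  }
  s
}

#' Scan a window for the best sigma-70 promoter hit
#'
#' Scans every placement of the -35 box, every spacer in the model's range
#' and the implied -10 box over the window (given on the gene's coding
#' strand) and returns the best summed log-odds placement, or `NULL` when no
#' placement reaches the model threshold.
#'
#' @param seq_window Nucleotide window on the coding strand.
#' @param model A `promoter_model`.
#' @return `NULL`, or a list with `pos` (1-based start of the -35 box within
#'   the window), `spacer` and `score`.
#' @export
score_promoter <- function(seq_window, model = promoter_model()) {
  n <- nchar(seq_window)
  min_span <- 12L + min(model$spacer_range)
  if (n < min_span) return(NULL)
  chars <- strsplit(toupper(seq_window), "", fixed = TRUE)[[1]]
  best <- NULL
  for (sp in seq.int(model$spacer_range[1], model$spacer_range[2])) {
    span <- 12L + sp
    if (n < span) next
    starts <- seq_len(n - span + 1L)
    sc <- pwm_scores(chars, model$minus35, starts) +
      pwm_scores(chars, model$minus10, starts + 6L + sp)
    i <- which.max(sc)
    if (is.null(best) || sc[i] > best$score) {
      best <- list(pos = starts[i], spacer = sp, score = sc[i])
    }
  }
  if (is.null(best) || best$score < model$score_threshold) return(NULL)
  best
}

#' Find rho-independent (intrinsic) terminators in a window
#'
#' Enumerates hairpins (stem length `stem_range`, loop length `loop_range`)
#' on the given strand and keeps those whose stem stability — counted as
#' GC pairs + 0.5 * AT/AU pairs — reaches `min_stability` and that are
#' followed by at least `min_u` T's within the 8 nt downstream of the
#' hairpin (the U-tract of the intrinsic termination signal). For each
#' hairpin start, only the innermost maximal-stem hairpin per (start, loop)
#' is enumerated by construction; hits are sorted by decreasing stability.
#'
#' @param seq_window Nucleotide window on the coding strand, downstream of a
#'   gene's stop.
#' @param stem_range,loop_range Stem and loop length bounds (bp).
#' @param min_u Minimum T count in the 8 nt after the hairpin.
#' @param min_stability Minimum stem stability.
#' @return `data.frame` with `hairpin_start`, `stem_len`, `loop_len`,
#'   `u_count`, `stability`.
#' @export
find_terminators <- function(seq_window, stem_range = c(4, 12),
                             loop_range = c(3, 8), min_u = 3,
                             min_stability = 6) {
  chars <- strsplit(toupper(seq_window), "", fixed = TRUE)[[1]]
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  out <- list()
  for (start in seq_len(n)) {
    for (loop in seq.int(loop_range[1], loop_range[2])) {
      for (stem in seq.int(stem_range[1], stem_range[2])) {
        hp_end <- start + 2L * stem + loop - 1L
        if (hp_end > n) break
        left <- chars[start:(start + stem - 1L)]
        right <- chars[(start + stem + loop):hp_end]
        if (!all(comp[left] == rev(right), na.rm = FALSE) ||
            anyNA(comp[left])) next
        pairs <- left
        stab <- sum(pairs %in% c("G", "C")) + 0.5 * sum(pairs %in% c("A", "T"))
        if (stab < min_stability) next
        u <- if (hp_end + 1L > n) 0L else
          sum(chars[seq.int(hp_end + 1L, min(n, hp_end + 8L))] == "T")
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
  res <- res[order(-res$stability, res$hairpin_start, res$stem_len), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' GC z-score of a gene against its flanking sequence
#'
#' `z = (gc(gene) - mean(gc of flank windows)) / sd(gc over sliding
#' sub-windows of the flanks)`, with an sd floor of 0.005 and the reported
#' z capped at +/-20. Flanks shorter than one sub-window are used whole.
#'
#' @param gene_seq Gene nucleotide string.
#' @param flank_seqs Character vector of flanking sequences (typically left
#'   and right flanks).
#' @param subwindow_bp Sliding sub-window width for the sd estimate.
#' @return A single z value.
#' @export
gc_zscore <- function(gene_seq, flank_seqs, subwindow_bp = 500) {
  flank_seqs <- flank_seqs[nchar(flank_seqs) > 0]
  if (length(flank_seqs) == 0) stop("no flanking sequence available")
  subs <- unlist(lapply(flank_seqs, function(f) {
    n <- nchar(f)
    if (n <= subwindow_bp) return(f)
    starts <- seq.int(1L, n - subwindow_bp + 1L, by = subwindow_bp %/% 2L)
    substring(f, starts, starts + subwindow_bp - 1L)
  }))
  gcf <- gc_content(subs)
  gcf <- gcf[!is.na(gcf)]
  if (length(gcf) == 0) stop("flanks contain no called bases")
  sdv <- max(stats::sd(gcf), 0.005)
  if (is.na(sdv)) sdv <- 0.005
  z <- (gc_content(gene_seq) - mean(gcf)) / sdv
  max(-20, min(20, z))
}

#' Screen a region's genes against the three moron criteria
#'
#' A moron is an autonomously transcribed extra gene: (1) not a phage core /
#' structural / lysogeny-control gene, (2) flanked by an upstream sigma-70
#' promoter and a downstream rho-independent terminator on its coding
#' strand, and (3) of anomalous GC content relative to neighbouring
#' sequence. Every eligible gene is reported with its evidence; the verdict
#' is the conjunction of the three criteria.
#'
#' @param region A `candidate_region` (or any list with `gene_ids`).
#' @param ann A `genome_annotation` with sequence.
#' @param z_min Minimum `|gc z-score|` for criterion 3.
#' @param upstream_bp,downstream_bp Search windows around the gene.
#' @param flank_bp Flank width for the GC z-score.
#' @param model A `promoter_model`.
#' @param terminator_params List of overrides for [find_terminators()].
#' @return `data.frame` (one row per screened gene): promoter/terminator
#'   evidence, `gc_z`, `is_core`, `verdict`; verdict-true rows sorted first.
#' @export
screen_region <- function(region, ann, z_min = 2, upstream_bp = 150,
                          downstream_bp = 150, flank_bp = 5000,
                          model = promoter_model(),
                          terminator_params = list()) {
  if (is.null(ann$sequence)) {
    stop("moron screening requires a genome sequence")
  }
  g <- ann$genes[ann$genes$gene_id %in% region$gene_ids, , drop = FALSE]
  if (nrow(g) == 0) {
    return(moron_empty())
  }
  rows <- lapply(seq_len(nrow(g)), function(i) {
    screen_gene(g[i, ], ann, z_min, upstream_bp, downstream_bp, flank_bp,
                model, terminator_params)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$verdict, -abs(res$gc_z)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

moron_empty <- function() {
  data.frame(gene_id = character(0), is_core = logical(0),
             promoter_pos = integer(0), promoter_score = numeric(0),
             terminator_pos = integer(0), terminator_stability = numeric(0),
             gc_z = numeric(0), verdict = logical(0), notes = character(0))
}

screen_gene <- function(gene, ann, z_min, upstream_bp, downstream_bp,
                        flank_bp, model, terminator_params) {
  seqs <- gene_context_seqs(gene, ann$sequence, upstream_bp, downstream_bp)
  is_core <- gene$category %in% MORON_EXCLUDED_CATEGORIES
  prom <- if (nchar(seqs$upstream) > 0) {
    score_promoter(seqs$upstream, model)
  } else NULL
  term <- if (nchar(seqs$downstream) > 0) {
    do.call(find_terminators, c(list(seqs$downstream), terminator_params))
  } else NULL
  has_term <- !is.null(term) && nrow(term) > 0
  glen <- nchar(ann$sequence)
  fl <- substring(ann$sequence, max(1L, gene$low - flank_bp), gene$low - 1L)
  fr <- substring(ann$sequence, gene$high + 1L,
                  min(glen, gene$high + flank_bp))
  gz <- gc_zscore(substring(ann$sequence, gene$low, gene$high), c(fl, fr))
  notes <- character(0)
  if (is_core) notes <- c(notes, "core/structural gene")
  if (is.null(prom)) notes <- c(notes, "no promoter")
  if (!has_term) notes <- c(notes, "no terminator")
  if (abs(gz) < z_min) notes <- c(notes, "GC not anomalous")
  data.frame(
    gene_id = gene$gene_id, is_core = is_core,
    promoter_pos = if (is.null(prom)) NA_integer_ else prom$pos,
    promoter_score = if (is.null(prom)) NA_real_ else prom$score,
    terminator_pos = if (has_term) term$hairpin_start[1] else NA_integer_,
    terminator_stability = if (has_term) term$stability[1] else NA_real_,
    gc_z = gz,
    verdict = !is_core && !is.null(prom) && has_term && abs(gz) >= z_min,
    notes = paste(notes, collapse = "; "),
    stringsAsFactors = FALSE)
}

gene_context_seqs <- function(gene, genome_seq, upstream_bp, downstream_bp) {
  glen <- nchar(genome_seq)
  if (gene$strand == "+") {
    up <- substring(genome_seq, max(1L, gene$low - upstream_bp),
                    gene$low - 1L)
    down <- substring(genome_seq, gene$high + 1L,
                      min(glen, gene$high + downstream_bp))
  } else {
    up <- reverse_complement(substring(genome_seq, gene$high + 1L,
                                       min(glen, gene$high + upstream_bp)))
    down <- reverse_complement(substring(genome_seq,
                                         max(1L, gene$low - downstream_bp),
                                         gene$low - 1L))
  }
  if (gene$low == 1L && gene$strand == "+") up <- ""
  list(upstream = up, downstream = down)
}
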