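#' Jaccard overlap of two genomic intervals
#'
#' @param a,b Intervals `c(low, high)`, 1-based inclusive.
#' @return `|intersection| / |union|` in bp.
#' @export
jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  union <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / union
}

new_region <- function(ann, caller, low, high, score, lexicon) {
  g <- ann$genes
  inside <- g$low >= low & g$high <= high
  inv <- intersect(core_categories(), unique(g$category[inside]))
  structure(list(region_id = NA_character_, caller = caller,
                 low = as.integer(low), high = as.integer(high),
                 score = score, gene_ids = g$gene_id[inside],
                 core_inventory = inv, completeness = NA_character_,
                 curated = FALSE, notes = ""),
            class = "candidate_region")
}

#' @export
print.candidate_region <- function(x, ...) {
  cat(sprintf("<candidate_region> %s [%d-%d] caller=%s score=%.2f genes=%d core={%s}%s\n",
              ifelse(is.na(x$region_id), "?", x$region_id), x$low, x$high,
              x$caller, x$score, length(x$gene_ids),
              paste(x$core_inventory, collapse = ","),
              if (isTRUE(x$curated)) " curated" else ""))
  invisible(x)
}

#' Call prophage regions from phage-gene clustering density
#'
#' Finds maximal runs of phage-category genes in gene order, allowing up to
#' `max_gap_genes` intervening non-phage genes inside a run. A run with at
#' least `min_phage_genes` phage genes becomes a candidate region spanning
#' from the first to the last phage gene of the run; the score is the phage
#' gene count.
#'
#' @param ann A `genome_annotation` with categorized genes.
#' @param lexicon A `phage_lexicon`.
#' @param min_phage_genes Minimum phage genes per region.
#' @param max_gap_genes Maximum consecutive non-phage genes bridged.
#' @return List of `candidate_region` (caller `"density"`).
#' @export
density_caller <- function(ann, lexicon = phage_lexicon(),
                           min_phage_genes = 6, max_gap_genes = 4) {
  g <- ann$genes
  phage <- which(is_phage_category(g$category, lexicon))
  if (length(phage) == 0) return(list())
  # split phage-gene indices wherever more than max_gap_genes non-phage
  # genes intervene
  brk <- which(diff(phage) > max_gap_genes + 1L)
  groups <- split(phage, cumsum(c(0L, seq_along(phage)[-1] %in% (brk + 1L))))
  out <- list()
  for (grp in groups) {
    if (length(grp) < min_phage_genes) next
    out[[length(out) + 1L]] <- new_region(
      ann, "density", g$low[min(grp)], g$high[max(grp)],
      score = length(grp), lexicon = lexicon)
  }
  number_regions(out, "density")
}

number_regions <- function(regions, prefix) {
  for (i in seq_along(regions)) {
    regions[[i]]$region_id <- sprintf("%s_%02d", prefix, i)
  }
  regions
}

#' Call prophage regions from composite windowed signals
#'
#' Each track is aligned onto a common window grid (the nucleotide grid when
#' GC tracks exist, else the gene grid) by taking the value of the track
#' window containing each grid window's midpoint. Per grid window, the
#' composite score is a weighted sum of genome-wide z-scores of: median
#' protein length, strand-run fraction, absolute GC-content deviation from
#' the genome mean, absolute GC-skew deviation, and phage-gene density.
#' Runs of at least `min_windows` consecutive windows with composite score
#' `>= z_threshold` become regions (overlapping windows merge).
#'
#' A track that is entirely undefined drops out and its weight is
#' redistributed proportionally over the remaining tracks.
#'
#' @param tracks Output of [build_tracks()].
#' @param ann The `genome_annotation` the tracks came from (used to attach
#'   gene inventories to the called regions).
#' @param z_threshold Composite-score threshold.
#' @param min_windows Minimum consecutive qualifying windows.
#' @param weights Named weights for
#'   `c(median_aa, strand_run_frac, gc_content, gc_skew, phage_density)`;
#'   normalized to sum to 1.
#' @param lexicon A `phage_lexicon`.
#' @return List of `candidate_region` (caller `"signal"`).
#' @export
signal_caller <- function(tracks, ann, z_threshold = 1.5, min_windows = 3,
                          weights = c(median_aa = 1, strand_run_frac = 1,
                                      gc_content = 1, gc_skew = 1,
                                      phage_density = 1),
                          lexicon = phage_lexicon()) {
  grid <- if (!is.null(tracks$gc_content)) tracks$gc_content else
    tracks$median_aa
  if (is.null(grid)) stop("no usable track for the signal caller")
  mid <- (grid$low + grid$high) / 2
  feature <- function(name) {
    tr <- tracks[[name]]
    if (is.null(tr)) return(rep(NA_real_, length(mid)))
    v <- step_lookup(tr, mid)
    if (name %in% c("gc_content", "gc_skew")) {
      v <- abs(v - mean(v, na.rm = TRUE))
    }
    v
  }
  znames <- c("median_aa", "strand_run_frac", "gc_content", "gc_skew",
              "phage_density")
  w <- weights[znames]
  w[is.na(w)] <- 0
  names(w) <- znames
  feats <- lapply(znames, feature)
  names(feats) <- znames
  usable <- vapply(feats, function(v) any(!is.na(v)) && stats::sd(v, na.rm = TRUE) > 0,
                   logical(1)) & w > 0
  if (!any(usable)) return(list())
  w <- w[usable] / sum(w[usable])
  comp <- rep(0, length(mid))
  for (nm in names(w)) {
    v <- feats[[nm]]
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    z[is.na(z)] <- 0
    comp <- comp + w[[nm]] * z
  }
  hot <- comp >= z_threshold
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  raw <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i] || runs$lengths[i] < min_windows) next
    raw[[length(raw) + 1L]] <- c(grid$low[starts[i]], grid$high[ends[i]],
                                 max(comp[starts[i]:ends[i]]))
  }
  if (length(raw) == 0) return(list())
  # windows are wider than the step, so qualifying runs separated by a
  # short sub-threshold gap can still overlap in bp; merge those
  m <- do.call(rbind, raw)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    j <- nrow(merged)
    if (m[i, 1] <= merged[j, 2]) {
      merged[j, 2] <- max(merged[j, 2], m[i, 2])
      merged[j, 3] <- max(merged[j, 3], m[i, 3])
    } else {
      merged <- rbind(merged, m[i, , drop = FALSE])
    }
  }
  out <- lapply(seq_len(nrow(merged)), function(i) {
    new_region(ann, "signal", merged[i, 1], merged[i, 2],
               score = merged[i, 3], lexicon = lexicon)
  })
  number_regions(out, "signal")
}

step_lookup <- function(track, positions) {
  # value of the track window containing each position (midpoint-nearest
  # window wins when several overlap due to the sliding step)
  wmid <- (track$low + track$high) / 2
  idx <- vapply(positions, function(p) {
    inside <- which(track$low <= p & track$high >= p)
    if (length(inside) == 0) inside <- which.min(abs(wmid - p))
    inside[which.min(abs(wmid[inside] - p))]
  }, integer(1))
  track$value[idx]
}

#' Consensus and curation of caller outputs
#'
#' Regions from different callers that overlap by at least 1 bp are grouped
#' by single linkage. Groups supported by at least `min_callers` distinct
#' callers survive; a surviving group takes the bounds of its
#' `primary_caller` member(s) when present, else the union of its members.
#' Finally any region shorter than `min_size_bp` is discarded and survivors
#' are flagged curated.
#'
#' @param regions_by_caller List of `candidate_region` lists (one element
#'   per caller), or a single flat list of tagged regions.
#' @param ann The `genome_annotation` (gene inventories are recomputed for
#'   the final bounds).
#' @param min_callers Minimum distinct callers supporting a group.
#' @param min_size_bp Minimum curated region size (regions below are
#'   discarded).
#' @param primary_caller Caller whose bounds are preferred.
#' @param lexicon A `phage_lexicon`.
#' @return List of curated `candidate_region` (caller `"consensus"`).
#' @export
consensus_and_curate <- function(regions_by_caller, ann, min_callers = 2,
                                 min_size_bp = 10000,
                                 primary_caller = "density",
                                 lexicon = phage_lexicon()) {
  regions <- if (length(regions_by_caller) > 0 &&
                 inherits(regions_by_caller[[1]], "candidate_region")) {
    regions_by_caller
  } else {
    do.call(c, regions_by_caller)
  }
  callers <- unique(vapply(regions, function(r) r$caller, character(1)))
  n_callers <- max(length(callers),
                   if (is.list(regions_by_caller) && length(regions_by_caller) > 0 &&
                       !inherits(regions_by_caller[[1]], "candidate_region"))
                     length(regions_by_caller) else 0L)
  if (min_callers > n_callers) {
    stop("min_callers (", min_callers, ") exceeds the number of callers (",
         n_callers, ")")
  }
  if (length(regions) == 0) return(list())
  lows <- vapply(regions, function(r) r$low, integer(1))
  highs <- vapply(regions, function(r) r$high, integer(1))
  ord <- order(lows, highs)
  group <- integer(length(regions))
  gid <- 0L
  gmax <- -Inf
  for (i in ord) {
    if (lows[i] > gmax) gid <- gid + 1L  # no 1 bp overlap with open group
    group[i] <- gid
    gmax <- max(gmax, highs[i])
  }
  out <- list()
  for (gi in unique(group)) {
    members <- regions[group == gi]
    mcallers <- vapply(members, function(r) r$caller, character(1))
    if (length(unique(mcallers)) < min_callers) next
    prim <- members[mcallers == primary_caller]
    src <- if (length(prim) > 0) prim else members
    lo <- min(vapply(src, function(r) r$low, integer(1)))
    hi <- max(vapply(src, function(r) r$high, integer(1)))
    if (hi - lo + 1 < min_size_bp) next
    reg <- new_region(ann, "consensus", lo, hi,
                      score = max(vapply(members, function(r) r$score,
                                         numeric(1))),
                      lexicon = lexicon)
    reg$curated <- TRUE
    reg$notes <- sprintf("callers=%s; bounds=%s",
                         paste(sort(unique(mcallers)), collapse = "+"),
                         if (length(prim) > 0) primary_caller else "union")
    out[[length(out) + 1L]] <- reg
  }
  number_regions(out, "pp")
}

#' Classify completeness of a candidate region
#'
#' A region is `complete` when its hallmark core inventory has at least
#' `min_core` of the seven core categories (and contains an integrase when
#' `require_integrase`); `remnant` when two or fewer; else `questionable`.
#'
#' @param region A `candidate_region` with `core_inventory` computed.
#' @param min_core Minimum hallmark categories for a complete call.
#' @param require_integrase Require integrase for completeness.
#' @return The region with `completeness` set.
#' @export
classify_completeness <- function(region, min_core = 5,
                                  require_integrase = TRUE) {
  inv <- region$core_inventory
  region$completeness <-
    if (length(inv) >= min_core &&
        (!require_integrase || "integrase" %in% inv)) {
      "complete"
    } else if (length(inv) <= 2) {
      "remnant"
    } else {
      "questionable"
    }
  region
}

#' Lysogeny (temperate-lifestyle) evidence for a region
#'
#' Flags the presence of an integrase, repressor and antirepressor among the
#' region's genes, and whether a tRNA interval lies inside the region or
#' within `trna_margin` bp of either bound (tRNA-adjacent insertion is a
#' classical integration signature). Verdict is `temperate-evidence` iff an
#' integrase plus a repressor or antirepressor is present.
#'
#' @param region A `candidate_region`.
#' @param ann The `genome_annotation` holding the region's genes.
#' @param trnas Optional tRNA `data.frame` (`low`, `high`); defaults to
#'   `ann$trnas`.
#' @param trna_margin Distance from a region bound still counted adjacent.
#' @return List of class `lifestyle_evidence` with flags and `verdict`.
#' @export
lifestyle_flags <- function(region, ann, trnas = NULL, trna_margin = 2000) {
  if (is.null(trnas)) trnas <- ann$trnas
  g <- ann$genes
  cats <- g$category[g$gene_id %in% region$gene_ids]
  has_int <- "integrase" %in% cats
  has_rep <- "repressor" %in% cats
  has_anti <- "antirepressor" %in% cats
  adj <- FALSE
  if (!is.null(trnas) && nrow(trnas) > 0) {
    adj <- any(trnas$high >= region$low - trna_margin &
               trnas$low <= region$high + trna_margin)
  }
  structure(list(has_integrase = has_int, has_repressor = has_rep,
                 has_antirepressor = has_anti, trna_adjacent = adj,
                 verdict = if (has_int && (has_rep || has_anti))
                   "temperate-evidence" else "insufficient"),
            class = "lifestyle_evidence")
}

#' Candidate regions as a data.frame
#'
#' @param regions List of `candidate_region`.
#' @return One row per region.
#' @export
regions_table <- function(regions) {
  if (length(regions) == 0) {
    return(data.frame(region_id = character(0), caller = character(0),
                      low = integer(0), high = integer(0),
                      size_bp = integer(0), score = numeric(0),
                      n_genes = integer(0), core_inventory = character(0),
                      completeness = character(0), curated = logical(0),
                      notes = character(0)))
  }
  do.call(rbind, lapply(regions, function(r) {
    data.frame(region_id = r$region_id, caller = r$caller, low = r$low,
               high = r$high, size_bp = r$high - r$low + 1L, score = r$score,
               n_genes = length(r$gene_ids),
               core_inventory = paste(r$core_inventory, collapse = ","),
               completeness = r$completeness, curated = r$curated,
               notes = r$notes, stringsAsFactors = FALSE)
  }))
}

#' Export regions as GFF3 (`prophage_region` features)
#'
#' @param regions List of `candidate_region`.
#' @param ann The `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_gff3 <- function(regions, ann, path) {
  if (length(regions) == 0) {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", ann$genome_id,
                         ann$length)), path)
    return(invisible(path))
  }
  tab <- regions_table(regions)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$genome_id,
    ranges = IRanges::IRanges(start = tab$low, end = tab$high))
  gr$type <- "prophage_region"
  gr$ID <- tab$region_id
  gr$score <- tab$score
  gr$completeness <- tab$completeness
  gr$source <- "prophagemine"
  sl <- ann$length
  names(sl) <- ann$genome_id
  GenomeInfoDb::seqlengths(gr) <- sl
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
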