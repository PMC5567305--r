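#' Configuration for the synthetic-genome generator
#'
#' Defaults encode the study conditions the detector is built for: a
#' high-GC host background (0.62), one integrated ~45 kb prophage whose GC
#' is shifted slightly down (-0.015, the typical phage-vs-host offset of a
#' resident temperate phage), longer phage proteins (mean 450 aa vs 300 aa),
#' a co-oriented phage gene block, a 15 bp att direct repeat at both
#' prophage bounds beside a tRNA gene, and one moron cassette (consensus
#' sigma-70 promoter, hairpin + U-tract terminator, GC shifted +0.08).
#'
#' @param genome_len Genome length (bp).
#' @param host_gc Host background GC fraction.
#' @param n_prophages Number of planted prophages.
#' @param prophage_len Length of each prophage (bp).
#' @param prophage_gc_delta GC shift inside prophages.
#' @param gene_len_host,gene_len_phage Mean protein length (aa).
#' @param phage_strand_block Co-orient ~90% of phage genes.
#' @param att_len Length of the planted att direct repeat (bp).
#' @param plant_trna Plant a tRNA adjacent to the left prophage bound.
#' @param n_morons Moron cassettes per prophage-bearing genome.
#' @param moron_gc_delta GC shift of moron gene bodies.
#' @param seed Integer seed; all randomness derives from it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(genome_len = 500000, host_gc = 0.62,
                             n_prophages = 1, prophage_len = 45000,
                             prophage_gc_delta = -0.015,
                             gene_len_host = 300, gene_len_phage = 450,
                             phage_strand_block = TRUE, att_len = 15,
                             plant_trna = TRUE, n_morons = 1,
                             moron_gc_delta = 0.08, seed = 1) {
  cfg <- list(genome_len = as.integer(genome_len), host_gc = host_gc,
              n_prophages = as.integer(n_prophages),
              prophage_len = as.integer(prophage_len),
              prophage_gc_delta = prophage_gc_delta,
              gene_len_host = gene_len_host, gene_len_phage = gene_len_phage,
              phage_strand_block = isTRUE(phage_strand_block),
              att_len = as.integer(att_len), plant_trna = isTRUE(plant_trna),
              n_morons = as.integer(n_morons),
              moron_gc_delta = moron_gc_delta, seed = as.integer(seed))
  levels <- c(host_gc, host_gc + prophage_gc_delta,
              host_gc + prophage_gc_delta + moron_gc_delta)
  if (any(levels <= 0 | levels >= 1)) {
    stop("GC levels must stay inside (0, 1)")
  }
  if (cfg$n_prophages > 0 &&
      cfg$prophage_len * cfg$n_prophages > 0.8 * cfg$genome_len) {
    stop("infeasible packing: prophages exceed 80% of the genome")
  }
  class(cfg) <- "generator_config"
  cfg
}

HOST_ANNOTATIONS <- c(
  "ABC transporter permease", "ribosomal protein L3",
  "DNA gyrase subunit A", "two-component sensor histidine kinase",
  "cytochrome c oxidase subunit II", "LysR family transcriptional regulator",
  "amino acid ABC transporter substrate-binding protein",
  "acyl-CoA dehydrogenase", "outer membrane porin", "hypothetical protein")

PHAGE_CORE_ANNOTATIONS <- c(
  integrase = "phage integrase family protein",
  terminase = "Phage terminase, large subunit",
  portal = "Phage portal protein",
  major_capsid = "Major capsid protein",
  tail_sheath = "Bacteriophage tail sheath protein",
  tape_measure = "Phage tail length tape-measure protein",
  lysin = "Endolysin")

PHAGE_EXTRA_ANNOTATIONS <- c(
  "Phage repressor", "Phage antirepressor protein",
  "Prophage tail protein", "Phage tail fiber protein",
  "Prophage baseplate assembly protein V", "Phage tail tube protein",
  "Phage protein", "Putative phage protein", "Minor tail protein",
  "Phage replication protein", "hypothetical protein")

sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

write_on_plus <- function(chars, pos, s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  chars[pos:(pos + length(v) - 1L)] <- v
  chars
}

# tile genes over [lo, hi]; returns data.frame of low/high
tile_genes <- function(lo, hi, mean_aa, gap_mean = 120) {
  lows <- integer(0); highs <- integer(0)
  pos <- lo + max(20L, round(stats::rexp(1, 1 / gap_mean)))
  repeat {
    aa <- max(50L, round(stats::rnorm(1, mean_aa, mean_aa / 3)))
    len <- 3L * (aa + 1L)
    if (pos + len - 1L > hi) break
    lows <- c(lows, pos); highs <- c(highs, pos + len - 1L)
    pos <- pos + len + max(20L, round(stats::rexp(1, 1 / gap_mean)))
  }
  data.frame(low = lows, high = highs)
}

#' Generate a synthetic bacterial genome with planted prophages
#'
#' Emulates the statistical structure the prophage signals rely on: an
#' i.i.d. host nucleotide background at `host_gc`, tiled host genes with
#' exponential-ish intergenic gaps, and for each planted prophage a block
#' with shifted GC, longer and largely co-oriented genes, phage-lexicon
#' annotations guaranteed to include all seven hallmark core categories
#' plus repressor/antirepressor, an exact `att_len` bp direct repeat at
#' both bounds, an adjacent tRNA, and optional moron cassettes (consensus
#' sigma-70 promoter upstream, GC-stem hairpin + U-tract downstream, gene
#' GC shifted by `moron_gc_delta`). Fully reproducible from `config$seed`.
#'
#' @param config A `generator_config`.
#' @return List with `ann` (a `genome_annotation` with sequence) and
#'   `truth` (planted prophage intervals, moron cassettes, att repeat,
#'   tRNA interval, config echo and seed).
#' @export
generate_genome <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  base_seed <- config$seed %% 1000000L
  # -- layout: one slot per prophage ---------------------------------------
  set.seed(base_seed + 1L)
  glen <- config$genome_len
  margin <- 2L * config$att_len + 200L + 5000L
  slots <- data.frame(low = integer(0), high = integer(0))
  if (config$n_prophages > 0) {
    slot <- glen %/% config$n_prophages
    for (i in seq_len(config$n_prophages)) {
      lo_min <- (i - 1L) * slot + margin
      lo_max <- i * slot - config$prophage_len - margin
      if (lo_max <= lo_min) stop("infeasible packing for prophage ", i)
      lo <- sample.int(lo_max - lo_min, 1L) + lo_min
      slots <- rbind(slots,
                     data.frame(low = lo, high = lo + config$prophage_len - 1L))
    }
  }
  # -- sequence -------------------------------------------------------------
  set.seed(base_seed + 2L)
  chars <- sample_bases(glen, config$host_gc)
  for (i in seq_len(nrow(slots))) {
    idx <- slots$low[i]:slots$high[i]
    chars[idx] <- sample_bases(length(idx),
                               config$host_gc + config$prophage_gc_delta)
  }
  # -- genes ----------------------------------------------------------------
  set.seed(base_seed + 3L)
  segs <- list()  # (low, high, is_phage) covering the genome
  prev <- 1L
  if (nrow(slots) > 0) {
    bounds <- slots[order(slots$low), ]
    for (i in seq_len(nrow(bounds))) {
      if (bounds$low[i] - 1L > prev) {
        segs[[length(segs) + 1L]] <- c(prev, bounds$low[i] - 1L, 0L)
      }
      segs[[length(segs) + 1L]] <- c(bounds$low[i], bounds$high[i], 1L)
      prev <- bounds$high[i] + 1L
    }
  }
  if (prev < glen) segs[[length(segs) + 1L]] <- c(prev, glen, 0L)
  genes <- list()
  pp <- data.frame(low = integer(0), high = integer(0))
  block_strand <- sample(c("+", "-"), 1L)
  for (sg in segs) {
    is_phage <- sg[3] == 1L
    mean_aa <- if (is_phage) config$gene_len_phage else config$gene_len_host
    # keep phage gene starts clear of the att repeats at the bounds
    lo <- if (is_phage) sg[1] + config$att_len else sg[1]
    hi <- if (is_phage) sg[2] - config$att_len else sg[2]
    tg <- tile_genes(lo, hi, mean_aa)
    if (nrow(tg) == 0) next
    if (is_phage) {
      # the prophage proper runs from just left of the first phage gene to
      # just right of the last one; att repeats sit at these bounds
      pp <- rbind(pp, data.frame(low = min(tg$low) - config$att_len - 5L,
                                 high = max(tg$high) + 5L))
      strand <- if (config$phage_strand_block) {
        ifelse(stats::runif(nrow(tg)) < 0.9, block_strand,
               setdiff(c("+", "-"), block_strand))
      } else {
        sample(c("+", "-"), nrow(tg), replace = TRUE)
      }
      annot <- sample(PHAGE_EXTRA_ANNOTATIONS, nrow(tg), replace = TRUE)
      # guarantee the hallmark inventory and the lysogeny pair; mirror the
      # canonical prophage layout: integrase beside attL/tRNA, terminase at
      # the far end
      guaranteed <- c(unname(PHAGE_CORE_ANNOTATIONS),
                      "Phage repressor", "Phage antirepressor protein")
      if (nrow(tg) >= length(guaranteed)) {
        annot[1L] <- PHAGE_CORE_ANNOTATIONS[["integrase"]]
        annot[nrow(tg)] <- PHAGE_CORE_ANNOTATIONS[["terminase"]]
        rest <- setdiff(guaranteed, annot[c(1L, nrow(tg))])
        mid <- 1L + sample.int(nrow(tg) - 2L, length(rest))
        annot[mid] <- rest
      }
    } else {
      strand <- sample(c("+", "-"), nrow(tg), replace = TRUE)
      annot <- sample(HOST_ANNOTATIONS, nrow(tg), replace = TRUE)
    }
    genes[[length(genes) + 1L]] <- data.frame(
      low = tg$low, high = tg$high, strand = strand, annotation = annot,
      phage = is_phage)
  }
  genes <- do.call(rbind, genes)
  genes <- genes[order(genes$low), ]
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes$aa_len <- as.integer((genes$high - genes$low + 1L) %/% 3L - 1L)
  # -- att repeat + tRNA ----------------------------------------------------
  set.seed(base_seed + 4L)
  att <- NULL
  trnas <- data.frame(low = integer(0), high = integer(0),
                      strand = character(0))
  if (nrow(pp) > 0 && config$att_len > 0) {
    att_seq <- paste(sample_bases(config$att_len, 0.5), collapse = "")
    left_pos <- pp$low[1]
    right_pos <- pp$high[1] + 1L
    chars <- write_on_plus(chars, left_pos, att_seq)
    chars <- write_on_plus(chars, right_pos, att_seq)
    att <- list(repeat_seq = att_seq, left_pos = left_pos,
                right_pos = right_pos, len = config$att_len)
  }
  if (nrow(pp) > 0 && config$plant_trna) {
    t_hi <- pp$low[1] - 10L
    trnas <- data.frame(low = t_hi - 75L, high = t_hi, strand = "+")
  }
  # -- moron cassettes ------------------------------------------------------
  set.seed(base_seed + 5L)
  morons <- data.frame(gene_id = character(0), low = integer(0),
                       high = integer(0), strand = character(0))
  if (nrow(pp) > 0 && config$n_morons > 0) {
    # candidate morons sit inside the block, clear of its ends, and are of
    # at least typical gene length so the GC anomaly is measurable over the
    # gene body
    inside <- which(genes$phage &
                    genes$low > pp$low[1] + 5000 &
                    genes$high < pp$high[1] - 5000 &
                    genes$high - genes$low + 1L >= 900L)
    # candidates need room for cassettes and must not sit at block ends
    pick <- inside[sample.int(length(inside),
                              min(config$n_morons, length(inside)))]
    for (gi in pick) {
      genes$annotation[gi] <- "hypothetical protein"
      g_lo <- genes$low[gi]; g_hi <- genes$high[gi]; st <- genes$strand[gi]
      body <- sample_bases(g_hi - g_lo + 1L,
                           config$host_gc + config$prophage_gc_delta +
                             config$moron_gc_delta)
      chars[g_lo:g_hi] <- body
      prom <- paste0("TTGACA", paste(sample_bases(17L, 0.5), collapse = ""),
                     "TATAAT")
      stem <- "GCGGCGGC"
      term <- paste0(stem, "TTCAA", reverse_complement(stem), "TTTTTTT")
      if (st == "+") {
        chars <- write_on_plus(chars, g_lo - 37L, prom)
        chars <- write_on_plus(chars, g_hi + 8L, term)
      } else {
        chars <- write_on_plus(chars, g_hi + 9L, reverse_complement(prom))
        chars <- write_on_plus(chars, g_lo - 7L - nchar(term),
                               reverse_complement(term))
      }
      morons <- rbind(morons, data.frame(gene_id = genes$gene_id[gi],
                                         low = g_lo, high = g_hi,
                                         strand = st))
    }
  }
  # -- assemble -------------------------------------------------------------
  tab <- data.frame(gene_id = genes$gene_id, strand = genes$strand,
                    start_raw = ifelse(genes$strand == "+", genes$low,
                                       genes$high),
                    stop_raw = ifelse(genes$strand == "+", genes$high,
                                      genes$low),
                    aa_len = genes$aa_len, annotation = genes$annotation,
                    stringsAsFactors = FALSE)
  ann <- genome_annotation(tab, genome_id = sprintf("synth_%d", config$seed),
                           sequence = paste(chars, collapse = ""),
                           trnas = trnas, length = glen)
  truth <- list(prophages = pp, morons = morons, att = att, trna = trnas,
                config = unclass(config), seed = config$seed)
  list(ann = ann, truth = truth)
}

#' Generate a homogeneous null genome (no prophage, no moron)
#'
#' @param config A `generator_config`; `n_prophages`/`n_morons` are forced
#'   to zero.
#' @return Same structure as [generate_genome()], with empty truth lists.
#' @export
null_genome <- function(config = generator_config()) {
  config$n_prophages <- 0L
  config$n_morons <- 0L
  generate_genome(config)
}

#' Write a synthetic genome to FASTA + GFF3 + truth JSON
#'
#' @param sim Output of [generate_genome()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_synthetic <- function(sim, dir, prefix = sim$ann$genome_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  js <- file.path(dir, paste0(prefix, ".truth.json"))
  write_fasta(sim$ann$genome_id, sim$ann$sequence, fa)
  write_gff3(sim$ann, gff)
  jsonlite::write_json(sim$truth, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(fasta = fa, gff3 = gff, truth = js))
}
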