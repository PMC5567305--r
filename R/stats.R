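#' Summary statistics of an annotated genome's ORFs
#'
#' @param ann A `genome_annotation`.
#' @return List of class `orf_stats`: `n_orfs`, `min_len_bp`, `max_len_bp`,
#'   `max_span_gene` (id and printed aa length of the gene with the largest
#'   coordinate span), `genome_span_bp` (largest coordinate), strand counts,
#'   and — only when a sequence is attached — `gc` and `start_codon_counts`.
#' @export
orf_stats <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes
  if (nrow(g) == 0) stop("empty gene list")
  len <- gene_length(ann)
  imax <- which.max(len)
  out <- list(
    n_orfs = nrow(g),
    min_len_bp = min(len),
    max_len_bp = max(len),
    max_span_gene = list(gene_id = g$gene_id[imax], aa_len = g$aa_len[imax]),
    genome_span_bp = max(g$high),
    n_minus = sum(g$strand == "-"),
    n_plus = sum(g$strand == "+"))
  if (!is.null(ann$sequence)) {
    out$gc <- gc_content(ann$sequence)
    starts <- ifelse(g$strand == "+",
                     substring(ann$sequence, g$low, g$low + 2L),
                     reverse_complement(substring(ann$sequence, g$high - 2L,
                                                  g$high)))
    codon <- ifelse(starts %in% c("ATG", "GTG", "TTG"), starts, "other")
    out$start_codon_counts <- table(factor(codon, levels = c("ATG", "GTG",
                                                             "TTG", "other")))
  }
  class(out) <- "orf_stats"
  out
}

#' @export
print.orf_stats <- function(x, ...) {
  cat(sprintf("ORFs: %d (%d +, %d -)\n", x$n_orfs, x$n_plus, x$n_minus))
  cat(sprintf("gene span: %d-%d bp; largest gene %s (%d aa)\n",
              x$min_len_bp, x$max_len_bp, x$max_span_gene$gene_id,
              x$max_span_gene$aa_len))
  cat(sprintf("genome span: %d bp (~%d Kb)\n", x$genome_span_bp,
              round_half_up(x$genome_span_bp / 1000, 0)))
  if (!is.null(x$gc)) cat(sprintf("GC: %.2f%%\n", 100 * x$gc))
  invisible(x)
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Span of a genomic interval in bp and Kb
#'
#' Kb is rounded half-up to one decimal.
#'
#' @param low,high 1-based inclusive bounds.
#' @return List with `bp` and `kb`.
#' @examples
#' region_span(6888478, 6932098)  # 43621 bp, 43.6 Kb
#' @export
region_span <- function(low, high) {
  if (low > high) stop("low must be <= high")
  bp <- high - low + 1
  list(bp = bp, kb = round_half_up(bp / 1000, 1))
}

#' Expand a printed ORF list with ranges
#'
#' Parses strings like `"orf3, 5, 70-77, 84-88"` (ranges inclusive; also
#' accepts en-dashes) into the full vector of ORF identifiers.
#'
#' @param text The printed list.
#' @param prefix Identifier prefix for bare numbers.
#' @return Character vector of identifiers, e.g. `c("orf3", "orf5", ...)`.
#' @export
expand_orf_list <- function(text, prefix = "orf") {
  parts <- strsplit(gsub("–|—", "-", text), ",")[[1]]
  parts <- trimws(parts)
  nums <- unlist(lapply(parts, function(p) {
    p <- gsub(prefix, "", p, fixed = TRUE)
    p <- gsub("[^0-9-]", "", p)
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      seq.int(ab[1], ab[2])
    } else {
      as.integer(p)
    }
  }))
  paste0(prefix, nums)
}

#' Functional ORF lists printed for the phi437 genome
#'
#' @return Named list of expanded ORF id vectors (morphogenesis, tail,
#'   baseplate, packaging-and-capsid).
#' @export
phi437_gene_lists <- function() {
  path <- system.file("extdata", "phi437_gene_lists.yaml",
                      package = "prophagemine", mustWork = TRUE)
  lapply(yaml::read_yaml(path), expand_orf_list)
}

#' Run the full prophage-mining pipeline
#'
#' Orchestrates signals -> density/signal callers -> consensus and curation
#' -> completeness and lifestyle classification -> att-site finding and
#' moron screening (the latter two only when a sequence is available) ->
#' ORF statistics. Controlled by a config list (or YAML file) with blocks
#' `io` / `signals` / `calling` / `att` / `moron`; every parameter defaults
#' to the package defaults.
#'
#' @param config A named list, or path to a YAML file. Recognized entries:
#'   `io$gene_table`, `io$gff3`, `io$fasta`, `io$fixture = TRUE` (use the
#'   packaged phi437 table), or `generate` (a [generator_config()] argument
#'   list); plus parameter blocks mirroring the function arguments.
#' @param out_dir Optional directory; when given, regions GFF3/TSV, att TSV,
#'   moron TSV, stats JSON and a run log are written there.
#' @return List of class `pipeline_report`: the annotation, tracks, caller
#'   regions, curated regions (with completeness and lifestyle), att and
#'   moron tables, `orf_stats`, and a log of the effective parameters.
#' @export
run_pipeline <- function(config = list(io = list(fixture = TRUE)),
                         out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  log <- list()
  lexicon <- phage_lexicon()
  # ---- input --------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$generate)) {
    gen_cfg <- do.call(generator_config, cfg$generate)
    sim <- generate_genome(gen_cfg)
    ann <- sim$ann
    truth <- sim$truth
    log$input <- sprintf("generated synthetic genome (seed %d)", gen_cfg$seed)
  } else if (isTRUE(cfg$io$fixture)) {
    ann <- phi437_annotation()
    log$input <- "packaged phi437 gene-table fixture"
  } else if (!is.null(cfg$io$gene_table)) {
    ann <- read_gene_table(cfg$io$gene_table, lexicon = lexicon)
    log$input <- cfg$io$gene_table
  } else if (!is.null(cfg$io$gff3)) {
    seq <- if (!is.null(cfg$io$fasta)) read_fasta(cfg$io$fasta)$sequence
    ann <- read_gff3(cfg$io$gff3, sequence = seq, lexicon = lexicon)
    log$input <- cfg$io$gff3
  } else {
    stop("config must name an input (io$fixture / io$gene_table / io$gff3) ",
         "or a generate block")
  }
  sig <- utils::modifyList(list(window_bp = 4000, step_bp = 1000,
                                genes_per_window = 20, gene_step = 5),
                           cfg$signals %||% list())
  call_p <- utils::modifyList(list(min_phage_genes = 6, max_gap_genes = 4,
                                   z_threshold = 1.5, min_windows = 3,
                                   min_callers = 2, min_size_bp = 10000,
                                   primary_caller = "density",
                                   min_core = 5, require_integrase = TRUE),
                              cfg$calling %||% list())
  att_p <- utils::modifyList(list(end_window = 2000, min_len = 10),
                             cfg$att %||% list())
  mor_p <- utils::modifyList(list(z_min = 2, upstream_bp = 150,
                                  downstream_bp = 150),
                             cfg$moron %||% list())
  log$params <- list(signals = sig, calling = call_p, att = att_p,
                     moron = mor_p)
  # ---- signals and callers ------------------------------------------------
  tracks <- build_tracks(ann, sig$window_bp, sig$step_bp,
                         sig$genes_per_window, sig$gene_step, lexicon)
  dens <- density_caller(ann, lexicon, call_p$min_phage_genes,
                         call_p$max_gap_genes)
  sigr <- signal_caller(tracks, ann, call_p$z_threshold, call_p$min_windows,
                        lexicon = lexicon)
  curated <- consensus_and_curate(list(dens, sigr), ann,
                                  call_p$min_callers, call_p$min_size_bp,
                                  call_p$primary_caller, lexicon)
  curated <- lapply(curated, classify_completeness,
                    min_core = call_p$min_core,
                    require_integrase = call_p$require_integrase)
  lifestyle <- lapply(curated, lifestyle_flags, ann = ann)
  # ---- sequence-dependent stages ------------------------------------------
  att_tab <- NULL
  moron_tab <- NULL
  if (!is.null(ann$sequence)) {
    att_rows <- lapply(curated, function(r) {
      hits <- find_att(ann$sequence, r, ann$trnas, att_p$end_window,
                       att_p$min_len)
      if (nrow(hits) > 0) cbind(region_id = r$region_id, hits)
    })
    att_rows <- att_rows[!vapply(att_rows, is.null, logical(1))]
    att_tab <- if (length(att_rows) > 0) do.call(rbind, att_rows) else
      data.frame(region_id = character(0), repeat_seq = character(0),
                 left_pos = integer(0), right_pos = integer(0),
                 repeat_len = integer(0), trna_distance = numeric(0),
                 score = integer(0))
    mor_rows <- lapply(curated, function(r) {
      tab <- screen_region(r, ann, mor_p$z_min, mor_p$upstream_bp,
                           mor_p$downstream_bp)
      if (nrow(tab) > 0) cbind(region_id = r$region_id, tab)
    })
    mor_rows <- mor_rows[!vapply(mor_rows, is.null, logical(1))]
    moron_tab <- if (length(mor_rows) > 0) do.call(rbind, mor_rows) else
      cbind(region_id = character(0), moron_empty())
  } else {
    log$skipped <- paste("att-site finding and moron screening skipped:",
                         "no genome sequence supplied")
  }
  stats <- orf_stats(ann)
  report <- structure(
    list(ann = ann, truth = truth, tracks = tracks,
         regions = list(density = dens, signal = sigr),
         curated = curated, lifestyle = lifestyle, att = att_tab,
         morons = moron_tab, orf_stats = stats, log = log),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s: %d curated region(s)\n",
              x$ann$genome_id, length(x$curated)))
  if (length(x$curated) > 0) print(regions_table(x$curated))
  if (!is.null(x$log$skipped)) cat(x$log$skipped, "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- regions_table(report$curated)
  utils::write.table(tab, file.path(out_dir, "regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_regions_gff3(report$curated, report$ann,
                     file.path(out_dir, "regions.gff3"))
  if (!is.null(report$att)) {
    utils::write.table(report$att, file.path(out_dir, "att_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$morons)) {
    utils::write.table(report$morons, file.path(out_dir, "morons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  st <- report$orf_stats
  st$start_codon_counts <- as.list(st$start_codon_counts)
  jsonlite::write_json(unclass(st), file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(paste("input:", report$log$input),
               paste("skipped:", report$log$skipped %||% "none"),
               utils::capture.output(utils::str(report$log$params))),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
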