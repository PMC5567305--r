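#' Construct a genome annotation object
#'
#' A light container for one bacterial genome (or phage genome): an optional
#' nucleotide sequence, an ordered gene table and tRNA intervals. All
#' coordinates are 1-based inclusive. Minus-strand genes printed with
#' start > stop keep their raw coordinates in `start_raw`/`stop_raw` and are
#' normalized to `low`/`high`.
#'
#' @param genes Gene `data.frame` with columns `gene_id`, `strand` (`+`/`-`),
#'   `start_raw`, `stop_raw`, `aa_len`, `annotation` (optionally `best_hit`).
#' @param genome_id Genome identifier.
#' @param sequence Optional nucleotide string over A/C/G/T/N.
#' @param trnas Optional `data.frame` with columns `low`, `high`, `strand`.
#' @param length Genome length in bp; defaults to `nchar(sequence)` when a
#'   sequence is given, else `max(high)` over the genes.
#' @param lexicon Lexicon used to assign the `category` column.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, genome_id = "genome", sequence = NULL,
                              trnas = NULL, length = NULL,
                              lexicon = phage_lexicon()) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "strand", "start_raw", "stop_raw", "aa_len", "annotation")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) stop("gene table missing columns: ",
                             paste(miss, collapse = ", "))
  genes$strand <- normalize_strand(genes$strand)
  genes$low <- pmin(genes$start_raw, genes$stop_raw)
  genes$high <- pmax(genes$start_raw, genes$stop_raw)
  if (any(genes$low < 1)) stop("gene coordinates must be >= 1")
  if (any(genes$aa_len < 0)) stop("aa_len must be >= 0")
  genes <- gene_categories(genes, lexicon)
  genes <- genes[order(genes$low, genes$high), , drop = FALSE]
  rownames(genes) <- NULL
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence)) {
      stop("sequence contains characters outside A/C/G/T/N")
    }
  }
  if (is.null(length)) {
    length <- if (!is.null(sequence)) nchar(sequence) else max(genes$high)
  }
  if (!is.null(sequence) && nchar(sequence) != length) {
    stop("sequence length (", nchar(sequence), ") != declared length (",
         length, ")")
  }
  if (any(genes$high > length)) stop("gene coordinates exceed genome length")
  if (is.null(trnas)) {
    trnas <- data.frame(low = integer(0), high = integer(0),
                        strand = character(0))
  }
  structure(list(genome_id = genome_id, length = as.integer(length),
                 sequence = sequence, genes = genes, trnas = trnas),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %s bp, %d genes, %d tRNAs, sequence %s\n",
              x$genome_id, format(x$length, big.mark = ","), nrow(x$genes),
              nrow(x$trnas), if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

normalize_strand <- function(strand) {
  s <- as.character(strand)
  s[s %in% c("−", "–")] <- "-"  # unicode minus / en-dash
  if (!all(s %in% c("+", "-"))) stop("strand must be '+' or '-'")
  s
}

#' Read a tab-separated gene table
#'
#' Expects at least six columns: gene id, strand, start, stop, amino-acid
#' length and annotation text; a seventh `best_hit` column is kept when
#' present. Raw printed coordinates are preserved and normalized to
#' `low`/`high`; rows come back sorted by `low`.
#'
#' @param path Path to the TSV file (first row is a header).
#' @param genome_id Genome identifier (defaults to the file name).
#' @param lexicon Lexicon for category assignment.
#' @return A `genome_annotation` (no sequence).
#' @export
read_gene_table <- function(path, genome_id = NULL, lexicon = phage_lexicon()) {
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           fill = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6) stop("gene table needs >= 6 columns, got ", ncol(tab))
  names(tab)[1:6] <- c("gene_id", "strand", "start_raw", "stop_raw",
                       "aa_len", "annotation")
  if (ncol(tab) >= 7) names(tab)[7] <- "best_hit"
  for (col in c("start_raw", "stop_raw", "aa_len")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad) > 0) {
      stop("malformed ", col, " at line ", bad[1] + 1L, " of ", path)
    }
    tab[[col]] <- v
  }
  zero <- which(tab$start_raw == tab$stop_raw)
  if (length(zero) > 0) {
    stop("zero-length gene (start == stop) at line ", zero[1] + 1L,
         " of ", path)
  }
  if (is.null(tab$best_hit)) tab$best_hit <- ""
  tab$best_hit[is.na(tab$best_hit)] <- ""
  genome_annotation(tab, genome_id = genome_id, lexicon = lexicon)
}

# md5 of the shipped phi437 gene-table fixture; guards accidental edits.
PHI437_FIXTURE_MD5 <- "022375bc6736114c5d51ef582a27f396"

#' The phi437 prophage gene-table fixture
#'
#' Returns the packaged 90-ORF gene table of phage phi437 (strand,
#' coordinates, amino-acid length, annotation and best-hit text) as a
#' `genome_annotation`. An md5 checksum guards against accidental edits of
#' the shipped TSV.
#'
#' @param check Verify the fixture checksum (default `TRUE`).
#' @return A `genome_annotation` with 90 genes and no sequence.
#' @export
phi437_annotation <- function(check = TRUE) {
  path <- system.file("extdata", "phi437_gene_table.tsv",
                      package = "prophagemine", mustWork = TRUE)
  if (check) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, PHI437_FIXTURE_MD5)) {
      stop("phi437 fixture checksum mismatch (", md5, "): the shipped gene ",
           "table has been modified")
    }
  }
  read_gene_table(path, genome_id = "phi437")
}

#' Coordinate-derived gene length
#'
#' @param ann A `genome_annotation`, or a gene `data.frame` with `low`/`high`.
#' @return Integer vector `high - low + 1` in bp.
#' @export
gene_length <- function(ann) {
  genes <- if (inherits(ann, "genome_annotation")) ann$genes else ann
  as.integer(genes$high - genes$low + 1L)
}

#' Consistency report between printed aa lengths and coordinates
#'
#' For each gene, estimates the protein length from the coordinate span as
#' `span/3 - 1` (the stop codon is not translated) and reports the difference
#' from the printed `aa_len`. Spans not divisible by 3 are flagged. The
#' report is diagnostic: discrepancies in a transcribed table are surfaced,
#' never corrected.
#'
#' @param ann A `genome_annotation`.
#' @return `data.frame` with `gene_id`, `aa_len`, `aa_estimated`, `delta`
#'   and `divisible_by_3`.
#' @export
aa_consistency_report <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  len <- gene_length(ann)
  div3 <- len %% 3L == 0L
  est <- ifelse(div3, len %/% 3L - 1L, NA_integer_)
  data.frame(gene_id = ann$genes$gene_id,
             aa_len = ann$genes$aa_len,
             aa_estimated = as.integer(est),
             delta = ann$genes$aa_len - as.integer(est),
             divisible_by_3 = div3)
}

#' Read a single-record nucleotide FASTA
#'
#' @param path FASTA file with exactly one nucleotide record.
#' @return List with `genome_id` and `sequence` (uppercase A/C/G/T/N).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA: ", path)
  if (length(set) > 1) {
    stop("multi-record FASTA not supported (", length(set), " records): ",
         path)
  }
  seq <- toupper(as.character(set[[1]]))
  if (grepl("[^ACGTN]", seq)) {
    stop("FASTA record contains characters outside A/C/G/T/N")
  }
  list(genome_id = sub("\\s.*$", "", names(set)[1]), sequence = seq)
}

#' Write a single-record nucleotide FASTA
#'
#' @param genome_id Record identifier.
#' @param sequence Nucleotide string.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome_id, sequence, path) {
  x <- Biostrings::DNAStringSet(toupper(sequence))
  names(x) <- genome_id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a GFF3 file into a genome annotation
#'
#' CDS features become gene records (annotation from the `product`
#' attribute, `hypothetical` default); tRNA features populate the tRNA
#' table. Coordinates are checked against the `##sequence-region` directive
#' when present.
#'
#' @param path GFF3 file.
#' @param sequence Optional genome sequence to attach.
#' @param lexicon Lexicon for category assignment.
#' @return A `genome_annotation`.
#' @export
read_gff3 <- function(path, sequence = NULL, lexicon = phage_lexicon()) {
  gr <- rtracklayer::import(path, format = "gff3")
  # rtracklayer does not carry ##sequence-region into seqinfo; parse it
  head_lines <- readLines(path, n = 100)
  sr <- grep("^##sequence-region", head_lines, value = TRUE)
  declared <- if (length(sr) >= 1) {
    as.integer(strsplit(trimws(sr[1]), "\\s+")[[1]][4])
  } else NULL
  if (!is.null(declared) && length(gr) > 0 &&
      max(GenomicRanges::end(gr)) > declared) {
    stop("GFF3 feature end ", max(GenomicRanges::end(gr)),
         " exceeds declared sequence-region length ", declared)
  }
  type <- as.character(gr$type)
  cds <- gr[type == "CDS"]
  trna <- gr[type == "tRNA"]
  product <- if (!is.null(cds$product)) {
    p <- cds$product
    # tolerate files where commas were left unescaped (multi-value lists)
    if (methods::is(p, "List")) p <- S4Vectors::unstrsplit(p, sep = ", ")
    as.character(p)
  } else rep(NA_character_, length(cds))
  product[is.na(product)] <- "hypothetical protein"
  ids <- if (!is.null(cds$ID)) as.character(cds$ID) else
    sprintf("gene_%04d", seq_along(cds))
  strand <- as.character(GenomicRanges::strand(cds))
  strand[!strand %in% c("+", "-")] <- "+"
  aa <- if (!is.null(cds$aa_len)) as.integer(cds$aa_len) else
    pmax(0L, as.integer(GenomicRanges::width(cds)) %/% 3L - 1L)
  genes <- data.frame(gene_id = ids, strand = strand,
                      start_raw = GenomicRanges::start(cds),
                      stop_raw = GenomicRanges::end(cds),
                      aa_len = aa, annotation = product,
                      stringsAsFactors = FALSE)
  # raw orientation mirrors the printed-table convention
  sw <- genes$strand == "-"
  tmp <- genes$start_raw[sw]
  genes$start_raw[sw] <- genes$stop_raw[sw]
  genes$stop_raw[sw] <- tmp
  trnas <- data.frame(low = GenomicRanges::start(trna),
                      high = GenomicRanges::end(trna),
                      strand = as.character(GenomicRanges::strand(trna)),
                      stringsAsFactors = FALSE)
  trnas$strand[!trnas$strand %in% c("+", "-")] <- "+"
  gid <- as.character(GenomeInfoDb::seqnames(gr)[1])
  genome_annotation(genes, genome_id = gid, sequence = sequence,
                    trnas = trnas, length = declared, lexicon = lexicon)
}

#' Write a genome annotation as GFF3
#'
#' Emits CDS features (with `ID`, `product` and `aa_len` attributes) and
#' tRNA features, plus a `##sequence-region` directive, in a form
#' [read_gff3()] round-trips.
#'
#' @param ann A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes
  # commas separate multi-valued GFF3 attributes, so escape them too
  esc <- function(x) {
    x <- gsub("%", "%25", x)
    x <- gsub(";", "%3B", x)
    x <- gsub("=", "%3D", x)
    gsub(",", "%2C", x)
  }
  cds <- sprintf("%s\tprophagemine\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s;aa_len=%d",
                 ann$genome_id, g$low, g$high, g$strand, esc(g$gene_id),
                 esc(g$annotation), g$aa_len)
  trna <- if (nrow(ann$trnas) > 0) {
    sprintf("%s\tprophagemine\ttRNA\t%d\t%d\t.\t%s\t.\tID=trna_%02d;product=tRNA",
            ann$genome_id, ann$trnas$low, ann$trnas$high, ann$trnas$strand,
            seq_len(nrow(ann$trnas)))
  } else character(0)
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", ann$genome_id,
                       ann$length),
               cds, trna), path)
  invisible(path)
}
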