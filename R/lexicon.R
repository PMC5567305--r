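#' Phage keyword lexicon
#'
#' Loads the keyword lexicon that maps gene annotation text to phage
#' functional categories. The lexicon is an editable YAML file: each category
#' lists case-insensitive keywords, every keyword belongs to exactly one
#' category, and matching is longest-match-wins with ties broken by category
#' order in the file. Categories marked `specific` name a concrete phage
#' function (integrase, terminase, portal, ...); the `other_phage` category
#' collects generic phage words.
#'
#' @param path Path to a lexicon YAML file. Defaults to the lexicon shipped
#'   with the package.
#' @return An object of class `phage_lexicon`: a list with `categories`
#'   (named list of keyword character vectors, in priority order) and
#'   `specific` (character vector of the specific category names).
#' @export
phage_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phage_lexicon.yaml",
                        package = "prophagemine", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)$categories
  kw <- lapply(raw, function(x) tolower(as.character(unlist(x$keywords))))
  specific <- names(raw)[vapply(raw, function(x) isTRUE(x$specific), logical(1))]
  dup <- unlist(kw)[duplicated(unlist(kw))]
  if (length(dup) > 0) {
    stop("lexicon keywords must be unique across categories: ",
         paste(unique(dup), collapse = ", "))
  }
  structure(list(categories = kw, specific = specific),
            class = "phage_lexicon")
}

#' Functional category names
#'
#' @param lexicon A `phage_lexicon`.
#' @return Category names in lexicon priority order, plus `"hypothetical"`.
#' @export
lexicon_categories <- function(lexicon = phage_lexicon()) {
  c(names(lexicon$categories), "hypothetical")
}

#' Classify a gene annotation into a phage functional category
#'
#' Deterministic keyword classification: the longest lexicon keyword found in
#' the (case-folded) annotation text wins; ties are broken by the category
#' order of the lexicon file. Text matching no keyword is classified
#' `hypothetical`.
#'
#' @param annotation_text Character vector of annotation strings.
#' @param lexicon A `phage_lexicon`.
#' @return Character vector of category names, one per input string.
#' @examples
#' classify_gene("phage integrase family protein")  # "integrase"
#' classify_gene("Hypothetical protein")            # "hypothetical"
#' @export
classify_gene <- function(annotation_text, lexicon = phage_lexicon()) {
  stopifnot(is.character(annotation_text))
  txt <- tolower(annotation_text)
  cats <- names(lexicon$categories)
  out <- rep("hypothetical", length(txt))
  best_len <- rep(0L, length(txt))
  for (ci in seq_along(cats)) {
    for (kw in lexicon$categories[[ci]]) {
      hit <- grepl(kw, txt, fixed = TRUE)
      # strictly-greater keeps the earlier category on equal-length ties
      upd <- hit & nchar(kw) > best_len
      if (any(upd)) {
        out[upd] <- cats[ci]
        best_len[upd] <- nchar(kw)
      }
    }
  }
  out
}

#' Assign categories to a gene table, optionally refining from best-hit text
#'
#' Primary categories come from [classify_gene()] on the annotation text.
#' When `use_best_hit` is `TRUE` and a `best_hit` column is present, genes
#' whose primary category is `hypothetical` or the generic `other_phage` are
#' upgraded using the best-hit text scanned against the *specific* lexicon
#' categories only (generic phage words in a database hit never upgrade a
#' gene). This recovers hallmark assignments for genes whose own annotation
#' is uninformative, e.g. a "Phage-related functions" gene whose best hit is
#' a major capsid protein.
#'
#' @param genes A gene `data.frame` with at least an `annotation` column.
#' @param lexicon A `phage_lexicon`.
#' @param use_best_hit Refine from `best_hit` text where available.
#' @return The gene table with a `category` column.
#' @export
gene_categories <- function(genes, lexicon = phage_lexicon(),
                            use_best_hit = TRUE) {
  stopifnot(is.data.frame(genes), "annotation" %in% names(genes))
  genes$category <- classify_gene(genes$annotation, lexicon)
  if (use_best_hit && "best_hit" %in% names(genes)) {
    spec_lex <- lexicon
    spec_lex$categories <- lexicon$categories[lexicon$specific]
    eligible <- genes$category %in% c("hypothetical", "other_phage") &
      !is.na(genes$best_hit) & nzchar(genes$best_hit)
    if (any(eligible)) {
      alt <- classify_gene(genes$best_hit[eligible], spec_lex)
      keep <- alt != "hypothetical"
      genes$category[eligible][keep] <- alt[keep]
    }
  }
  genes
}

#' Is a category a phage category?
#'
#' @param category Character vector of category names.
#' @param lexicon A `phage_lexicon`.
#' @return Logical: `TRUE` for every lexicon category, `FALSE` for
#'   `hypothetical`.
#' @export
is_phage_category <- function(category, lexicon = phage_lexicon()) {
  category %in% names(lexicon$categories)
}

# Hallmark structural/packaging categories used for completeness calls.
CORE_CATEGORIES <- c("integrase", "terminase", "portal", "major_capsid",
                     "tail_sheath", "tape_measure", "lysin")

# Categories excluded from moron candidacy (phage core machinery, structure,
# lysogeny control, replication).
MORON_EXCLUDED_CATEGORIES <- c(CORE_CATEGORIES, "tail", "baseplate",
                               "repressor", "antirepressor", "replication")

#' Hallmark phage core categories
#'
#' The seven hallmark structural/packaging/lysogeny-anchoring categories used
#' to score region completeness: integrase, large terminase, portal, major
#' capsid, tail sheath, tape measure and lysin.
#' @return Character vector of the seven category names.
#' @export
core_categories <- function() CORE_CATEGORIES
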