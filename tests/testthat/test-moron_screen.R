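test_that("promoter scan scores the consensus construct maximally", {
  model <- promoter_model()
  win <- paste0(strrep("C", 20), "TTGACA", strrep("G", 17),
                "TATAAT", strrep("C", 20))
  hit <- score_promoter(win, model)
  expect_false(is.null(hit))
  expect_equal(hit$pos, 21)
  expect_equal(hit$spacer, 17)
  expect_equal(hit$score, promoter_max_score(model))
})

test_that("promoter scan respects spacer bounds and thresholds", {
  model <- promoter_model()
  # spacer 14 is below range: consensus boxes must not register as a
  # perfect site
  win14 <- paste0(strrep("C", 20), "TTGACA", strrep("G", 14), "TATAAT",
                  strrep("C", 20))
  hit <- score_promoter(win14, model)
  if (!is.null(hit)) expect_lt(hit$score, promoter_max_score(model))
  # 60 nt of A scores far below threshold
  expect_null(score_promoter(strrep("A", 60), model))
  # window shorter than the minimal motif span
  expect_null(score_promoter("ACGTACGTAC", model))
})

test_that("the consensus construct is the global scan maximum", {
  model <- promoter_model()
  consensus_win <- paste0(strrep("C", 10), "TTGACA", strrep("A", 17),
                          "TATAAT", strrep("C", 10))
  ref <- score_promoter(consensus_win, model)$score
  expect_equal(ref, promoter_max_score(model))
  set.seed(404)
  n_hit <- 0
  for (i in 1:1000) {
    win <- random_dna(nchar(consensus_win))
    hit <- score_promoter(win, model)
    if (!is.null(hit)) {
      n_hit <- n_hit + 1
      expect_lte(hit$score, ref)
    }
  }
  # random windows rarely reach the default threshold at all
  expect_lte(n_hit / 1000, 0.1)
})

test_that("terminator finder detects the planted hairpin construct", {
  win <- paste0("GGCGGCGC", "TTCAA", reverse_complement("GGCGGCGC"),
                "TTTTTTT")
  hits <- find_terminators(win)
  expect_gt(nrow(hits), 0)
  # the planted 8-pair stem with its 5 nt loop and 7 T tract is reported
  planted <- hits[hits$stem_len == 8 & hits$loop_len == 5, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$hairpin_start, 1)
  expect_equal(planted$u_count, 7)
  expect_equal(planted$stability, 8)
  # exhaustive enumeration also admits the chance T/A closing pair that
  # extends the stem to 9; finder and oracle must agree on everything
  want <- bf_terminators(win)
  expect_equal(nrow(hits), nrow(want))
  expect_equal(hits$stability[1], want$stability[1])
  expect_equal(hits$stem_len[1], want$stem_len[1])
})

test_that("weak stems and missing U-tracts yield no terminator", {
  # 26 nt of AT cannot fit any stem whose stability reaches the floor
  expect_equal(nrow(find_terminators(strrep("AT", 13))), 0)
  # a longer AT run admits marginal all-AT stems that exactly reach the
  # floor; the finder must agree with enumeration rather than assume zero
  expect_equal(nrow(find_terminators(strrep("AT", 30))),
               nrow(bf_terminators(strrep("AT", 30))))
  no_tract <- paste0("GGCGGCGC", "TTCAA", reverse_complement("GGCGGCGC"),
                     "GCAGCAGC")
  expect_equal(nrow(find_terminators(no_tract)), 0)
})

test_that("terminator finder equals exhaustive enumeration", {
  set.seed(99)
  wins <- c(
    replicate(6, random_dna(sample(80:300, 1), gc = runif(1, 0.4, 0.7))),
    # seeded with planted terminators at random offsets
    replicate(4, {
      w <- random_dna(200, gc = 0.6)
      stem <- random_dna(sample(5:9, 1), gc = 0.9)
      cassette <- paste0(stem, random_dna(sample(3:8, 1)),
                         reverse_complement(stem), strrep("T", 6))
      p <- sample(1:(200 - nchar(cassette)), 1)
      substring(w, p, p + nchar(cassette) - 1) <- cassette
      w
    }))
  for (w in wins) {
    got <- find_terminators(w)
    want <- bf_terminators(w)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      key <- function(d) paste(d$hairpin_start, d$stem_len, d$loop_len,
                               d$u_count, d$stability, collapse = ";")
      got <- got[order(got$hairpin_start, got$stem_len, got$loop_len), ]
      want <- want[order(want$hairpin_start, want$stem_len, want$loop_len), ]
      expect_equal(key(got), key(want))
    }
  }
})

test_that("gc z-score follows its definition with floor and cap", {
  set.seed(5)
  flank <- random_dna(6000, gc = 0.6)
  # gene at flank GC: z near 0
  gene <- random_dna(2000, gc = 0.6)
  expect_lt(abs(gc_zscore(gene, flank)), 2)
  # uniform flanks force the sd floor; a +0.10 shift caps the report at 20
  uniform <- strrep("ACGGCGTGCC", 1000)  # GC exactly 0.7, every window
  hot <- strrep("G", 1000)
  expect_equal(gc_zscore(hot, uniform), 20)
  cold <- strrep("A", 1000)
  expect_equal(gc_zscore(cold, uniform), -20)
})

test_that("a planted GC shift of 0.08 is detectable at z >= 2", {
  set.seed(6)
  hits <- vapply(1:10, function(i) {
    flank <- random_dna(10000, gc = 0.6)
    gene <- random_dna(1200, gc = 0.68)
    abs(gc_zscore(gene, flank)) >= 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("screen_region applies the three moron criteria jointly", {
  sim <- generate_genome(generator_config(seed = 18))
  ann <- sim$ann
  cur <- consensus_and_curate(
    list(density_caller(ann), signal_caller(build_tracks(ann), ann)), ann)
  tab <- screen_region(cur[[1]], ann)
  planted <- sim$truth$morons$gene_id
  expect_true(planted %in% tab$gene_id[tab$verdict])
  # verdicts sort first and all verdicts satisfy the conjunction
  expect_true(all(which(tab$verdict) <= sum(tab$verdict)))
  v <- tab[tab$verdict, ]
  expect_true(all(!v$is_core & !is.na(v$promoter_pos) &
                    !is.na(v$terminator_pos) & abs(v$gc_z) >= 2))
  # core genes are excluded regardless of flanking elements
  expect_true(all(!tab$verdict[tab$is_core]))
})

test_that("a cassette without terminator fails with evidence recorded", {
  set.seed(19)
  glen <- 30000L
  seqs <- random_dna(glen, gc = 0.6)
  g_lo <- 15001L; g_hi <- 16200L
  substring(seqs, g_lo, g_hi) <- random_dna(1200, gc = 0.68)
  prom <- paste0("TTGACA", random_dna(17), "TATAAT")
  substring(seqs, g_lo - 37, g_lo - 9) <- prom
  # scrub the downstream window of any chance hairpin
  substring(seqs, g_hi + 1, g_hi + 150) <- strrep("A", 150)
  genes <- data.frame(gene_id = "m1", strand = "+", start_raw = g_lo,
                      stop_raw = g_hi, aa_len = 399L,
                      annotation = "hypothetical protein")
  ann <- genome_annotation(genes, sequence = seqs)
  region <- list(gene_ids = "m1", low = 1L, high = glen)
  tab <- screen_region(region, ann)
  expect_false(tab$verdict[1])
  expect_false(is.na(tab$promoter_pos[1]))
  expect_match(tab$notes[1], "no terminator")
  expect_gte(abs(tab$gc_z[1]), 2)
})

test_that("moron screening requires a sequence", {
  ann <- phi437_annotation()
  region <- list(gene_ids = ann$genes$gene_id, low = 1L, high = ann$length)
  expect_error(screen_region(region, ann), "sequence")
})
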