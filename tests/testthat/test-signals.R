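test_that("gc_content and gc_skew follow their definitions", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_true(is.na(gc_content("NNNN")))
  expect_equal(gc_content("GCNN"), 1.0)  # N excluded both sides
  expect_equal(gc_skew("GGGG"), 1.0)
  expect_equal(gc_skew("CCCC"), -1.0)
  expect_equal(gc_skew("GCGC"), 0.0)
  expect_equal(gc_skew("ATAT"), 0.0)  # no G/C convention
  expect_error(gc_content(""), "nchar")
})

test_that("GC statistics behave under reverse complement", {
  set.seed(7)
  for (i in 1:20) {
    w <- random_dna(sample(50:500, 1), gc = runif(1, 0.3, 0.7))
    rc <- reverse_complement(w)
    expect_equal(gc_content(rc), gc_content(w))
    expect_equal(gc_skew(rc), -gc_skew(w))
  }
})

test_that("gene-level window statistics match direct counts", {
  ann <- toy_annotation(strands = c("+", "+", "-", "+"),
                        aa = c(100L, 200L, 300L, 50L))
  span <- c(1, max(ann$genes$high))
  expect_equal(median_protein_length(ann, span), 150)
  expect_equal(median_protein_length(ann, c(1, 700)), 150)  # two genes
  expect_true(is.na(median_protein_length(ann, c(10000, 20000))))
  ann2 <- toy_annotation(strands = c("+", "-", "+", "-"))
  expect_equal(strand_run_fraction(ann2, span), 0.25)
  ann3 <- toy_annotation(strands = rep("+", 4))
  expect_equal(strand_run_fraction(ann3, span), 1.0)
  ann4 <- toy_annotation(strands = c("-", "-", "+", "+", "+", "+", "-", "-"))
  expect_equal(strand_run_fraction(ann4, c(1, max(ann4$genes$high))), 0.5)
})

test_that("classify_gene is deterministic, longest-match-wins", {
  expect_equal(classify_gene("phage integrase family protein"), "integrase")
  expect_equal(classify_gene("Phage tail length tape-measure protein"),
               "tape_measure")
  expect_equal(classify_gene("Hypothetical protein"), "hypothetical")
  expect_equal(classify_gene("Phage antirepressor protein"), "antirepressor")
  expect_equal(classify_gene("Phage repressor"), "repressor")
  expect_equal(classify_gene("Bacteriophage tail sheath protein"),
               "tail_sheath")
  expect_equal(classify_gene("Phage terminase, large subunit"), "terminase")
})

test_that("fixture categories match the phi437 hallmark assignments", {
  ann <- phi437_annotation()
  g <- ann$genes
  # annotation-text classification alone: exactly one integrase, at orf47
  cats <- classify_gene(g$annotation)
  expect_equal(g$gene_id[cats == "integrase"], "orf47")
  expect_equal(g$gene_id[g$annotation == "Phage terminase, large subunit"],
               "orf90")
  expect_true("terminase" %in% g$category[g$gene_id == "orf90"])
  # best-hit refinement recovers the capsid gene
  expect_equal(g$category[g$gene_id == "orf84"], "major_capsid")
  expect_equal(g$category[g$gene_id == "orf27"], "repressor")
  expect_equal(g$category[g$gene_id == "orf65"], "antirepressor")
  expect_equal(g$category[g$gene_id == "orf61"], "lysin")
})

test_that("phage_density counts phage-category genes", {
  ann <- toy_annotation(
    annotations = c("Phage protein", "Phage tail fiber protein",
                    "hypothetical protein", "ABC transporter"))
  span <- c(1, max(ann$genes$high))
  expect_equal(phage_density(ann, span), 0.5)
  expect_equal(phage_density(ann, c(10000, 20000)), 0)
  all_phage <- toy_annotation(annotations = rep("Phage protein", 4))
  expect_equal(phage_density(all_phage, span), 1.0)
})

test_that("windows tile the genome exactly", {
  w <- tile_windows(10000, 2000, 1000)
  expect_equal(nrow(w), 9)
  expect_equal(w$low[1], 1)
  expect_equal(w$high[9], 10000)
  # truncated final window when the tiling does not land on the end
  w2 <- tile_windows(10500, 2000, 1000)
  expect_equal(w2$high[nrow(w2)], 10500)
  expect_true(all(diff(w2$low) == 1000))
  # window larger than genome: single whole-genome window
  w3 <- tile_windows(500, 2000, 1000)
  expect_equal(w3, data.frame(low = 1L, high = 500L))
  # coverage: every base inside some window
  covered <- rep(FALSE, 10500)
  for (i in seq_len(nrow(w2))) covered[w2$low[i]:w2$high[i]] <- TRUE
  expect_true(all(covered))
})

test_that("build_tracks respects ranges and detects the planted GC shift", {
  sim <- generate_genome(generator_config(seed = 11))
  tracks <- build_tracks(sim$ann)
  expect_setequal(names(tracks), c("gc_content", "gc_skew", "median_aa",
                                   "strand_run_frac", "phage_density"))
  expect_true(all(tracks$gc_content$value >= 0 & tracks$gc_content$value <= 1,
                  na.rm = TRUE))
  expect_true(all(abs(tracks$gc_skew$value) <= 1, na.rm = TRUE))
  expect_true(all(tracks$strand_run_frac$value <= 1))
  expect_true(all(tracks$median_aa$value >= 0))
  pp <- sim$truth$prophages
  gct <- tracks$gc_content
  mid <- (gct$low + gct$high) / 2
  inside <- mid >= pp$low & mid <= pp$high
  delta <- mean(gct$value[inside]) - mean(gct$value[!inside])
  expect_lt(abs(delta - sim$truth$config$prophage_gc_delta), 0.02)
})

test_that("annotations without sequence yield gene tracks only", {
  ann <- phi437_annotation()
  tracks <- build_tracks(ann)
  expect_null(tracks$gc_content)
  expect_null(tracks$gc_skew)
  expect_false(is.null(tracks$median_aa))
  expect_false(is.null(tracks$phage_density))
})
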