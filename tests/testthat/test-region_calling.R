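test_that("density caller recovers a planted prophage", {
  sim <- generate_genome(generator_config(seed = 3))
  regions <- density_caller(sim$ann)
  expect_length(regions, 1)
  pp <- sim$truth$prophages
  expect_gte(jaccard(c(regions[[1]]$low, regions[[1]]$high),
                     c(pp$low, pp$high)), 0.9)
  # region bounds span first to last phage gene; gene_ids inside bounds
  g <- sim$ann$genes
  ids <- regions[[1]]$gene_ids
  expect_true(all(g$low[g$gene_id %in% ids] >= regions[[1]]$low))
  expect_true(all(g$high[g$gene_id %in% ids] <= regions[[1]]$high))
})

test_that("density caller returns nothing without phage genes", {
  ann <- toy_annotation(annotations = rep("ABC transporter", 4))
  expect_length(density_caller(ann), 0)
})

test_that("two well-separated prophages give two density regions", {
  sim <- generate_genome(generator_config(seed = 9, n_prophages = 2,
                                          genome_len = 400000,
                                          prophage_len = 40000,
                                          n_morons = 0))
  regions <- density_caller(sim$ann)
  expect_length(regions, 2)
  pp <- sim$truth$prophages
  for (i in 1:2) {
    best <- max(vapply(regions, function(r)
      jaccard(c(r$low, r$high), c(pp$low[i], pp$high[i])), numeric(1)))
    expect_gte(best, 0.9)
  }
})

test_that("signal caller finds a strongly contrasted planted prophage", {
  sim <- generate_genome(generator_config(seed = 21, prophage_gc_delta = 0.08,
                                          gene_len_phage = 600,
                                          n_morons = 0))
  tracks <- build_tracks(sim$ann)
  regions <- signal_caller(tracks, sim$ann)
  expect_gte(length(regions), 1)
  pp <- sim$truth$prophages
  best <- max(vapply(regions, function(r)
    jaccard(c(r$low, r$high), c(pp$low, pp$high)), numeric(1)))
  expect_gte(best, 0.75)
})

test_that("signal caller stays quiet on homogeneous genomes", {
  hits <- vapply(1:10, function(s) {
    sim <- null_genome(generator_config(seed = 300 + s,
                                        genome_len = 200000))
    length(signal_caller(build_tracks(sim$ann), sim$ann))
  }, integer(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("all weight on phage density reproduces the density caller", {
  sim <- generate_genome(generator_config(seed = 13, n_morons = 0))
  tracks <- build_tracks(sim$ann)
  sig <- signal_caller(tracks, sim$ann,
                       weights = c(phage_density = 1))
  dens <- density_caller(sim$ann)
  expect_length(sig, 1)
  expect_length(dens, 1)
  # agreement within one nucleotide window (4 kb) on each side
  expect_lte(abs(sig[[1]]$low - dens[[1]]$low), 4000)
  expect_lte(abs(sig[[1]]$high - dens[[1]]$high), 4000)
})

test_that("signal regions shrink monotonically as the threshold rises", {
  sim <- generate_genome(generator_config(seed = 17))
  tracks <- build_tracks(sim$ann)
  zs <- c(0.5, 1, 1.5, 2, 3, 5)
  calls <- lapply(zs, function(z)
    signal_caller(tracks, sim$ann, z_threshold = z))
  covered <- vapply(calls, function(rr)
    sum(vapply(rr, function(r) r$high - r$low + 1, numeric(1))), numeric(1))
  # covered bp never grows, and every higher-threshold region lies inside
  # some lower-threshold region (runs may split, so counts alone can rise)
  expect_true(all(diff(covered) <= 0))
  for (i in seq_along(zs)[-1]) {
    for (r in calls[[i]]) {
      contained <- any(vapply(calls[[i - 1]], function(q)
        q$low <= r$low && q$high >= r$high, logical(1)))
      expect_true(contained)
    }
  }
  # regions within one call never overlap one another
  for (rr in calls) {
    if (length(rr) < 2) next
    tab <- regions_table(rr)
    tab <- tab[order(tab$low), ]
    expect_true(all(tab$low[-1] > tab$high[-nrow(tab)]))
  }
})

test_that("consensus groups by overlap, prefers primary bounds, curates size", {
  ann <- toy_annotation()
  mk <- function(caller, low, high) {
    r <- prophagemine:::new_region(ann, caller, as.integer(low),
                                   as.integer(high), 1, phage_lexicon())
    r$region_id <- paste0(caller, "_", low)
    r
  }
  # both callers support a 9.5 kb region: grouped, then size-discarded
  out <- consensus_and_curate(list(list(mk("density", 100, 9599)),
                                   list(mk("signal", 200, 9400))), ann)
  expect_length(out, 0)
  # differing bounds: the primary caller's bounds win
  out <- consensus_and_curate(list(list(mk("density", 1000, 15000)),
                                   list(mk("signal", 500, 16000))), ann)
  expect_length(out, 1)
  expect_equal(out[[1]]$low, 1000)
  expect_equal(out[[1]]$high, 15000)
  expect_true(out[[1]]$curated)
  # union bounds when the primary caller is absent from the group
  out <- consensus_and_curate(list(list(mk("a", 1000, 15000)),
                                   list(mk("b", 500, 16000))), ann,
                              primary_caller = "density")
  expect_equal(c(out[[1]]$low, out[[1]]$high), c(500L, 16000L))
  # single-caller support is discarded at min_callers = 2
  out <- consensus_and_curate(list(list(mk("density", 1000, 20000)),
                                   list()), ann)
  expect_length(out, 0)
  # min_callers beyond the caller count is an error
  expect_error(consensus_and_curate(list(list(mk("density", 1, 20000))),
                                    ann, min_callers = 3), "min_callers")
})

test_that("curated regions satisfy the size floor and never overlap", {
  for (s in c(2, 4, 6)) {
    sim <- generate_genome(generator_config(seed = s, n_prophages = 2,
                                            genome_len = 400000,
                                            prophage_len = 40000))
    ann <- sim$ann
    cur <- consensus_and_curate(
      list(density_caller(ann), signal_caller(build_tracks(ann), ann)), ann)
    if (length(cur) < 2) next
    tab <- regions_table(cur)
    expect_true(all(tab$size_bp >= 10000))
    tab <- tab[order(tab$low), ]
    expect_true(all(tab$low[-1] > tab$high[-nrow(tab)]))
  }
})

test_that("completeness classification follows the core inventory", {
  ann <- phi437_annotation()
  full <- prophagemine:::new_region(ann, "manual", 1L, ann$length, 0,
                                    phage_lexicon())
  expect_setequal(full$core_inventory, core_categories())
  expect_equal(classify_completeness(full)$completeness, "complete")
  # without integrase requirement met, a rich inventory is not complete
  no_int <- full
  no_int$core_inventory <- setdiff(full$core_inventory, "integrase")
  expect_equal(classify_completeness(no_int)$completeness, "questionable")
  expect_equal(classify_completeness(no_int,
                                     require_integrase = FALSE)$completeness,
               "complete")
  remn <- full
  remn$core_inventory <- "tail_sheath"
  expect_equal(classify_completeness(remn)$completeness, "remnant")
  # planted synthetic prophage is complete
  sim <- generate_genome(generator_config(seed = 8))
  cur <- consensus_and_curate(
    list(density_caller(sim$ann),
         signal_caller(build_tracks(sim$ann), sim$ann)), sim$ann)
  expect_length(cur, 1)
  expect_equal(classify_completeness(cur[[1]])$completeness, "complete")
})

test_that("lifestyle evidence flags lysogeny genes and adjacent tRNAs", {
  ann <- phi437_annotation()
  full <- prophagemine:::new_region(ann, "manual", 1L, ann$length, 0,
                                    phage_lexicon())
  lf <- lifestyle_flags(full, ann)
  expect_true(lf$has_integrase)
  expect_true(lf$has_repressor)
  expect_true(lf$has_antirepressor)
  expect_equal(lf$verdict, "temperate-evidence")
  # tail genes only: insufficient
  tails <- toy_annotation(annotations = rep("Prophage tail protein", 4))
  r <- prophagemine:::new_region(tails, "manual", 1L, tails$length, 0,
                                 phage_lexicon())
  expect_equal(lifestyle_flags(r, tails)$verdict, "insufficient")
  # planted prophage: tRNA at the left bound
  sim <- generate_genome(generator_config(seed = 12))
  cur <- consensus_and_curate(
    list(density_caller(sim$ann),
         signal_caller(build_tracks(sim$ann), sim$ann)), sim$ann)
  lf2 <- lifestyle_flags(cur[[1]], sim$ann)
  expect_true(lf2$trna_adjacent)
  expect_equal(lf2$verdict, "temperate-evidence")
})
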