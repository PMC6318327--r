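test_that("TE placement is deterministic, in-bounds and non-overlapping", {
  spec <- syntheticGenomeSpec(
    c(chr1 = 1200000L, chr2 = 800000L),
    list(teTypeSpec("T1", "LTR", 60L, c(400L, 1500L), 80),
         teTypeSpec("T2", "LINE", 60L, c(800L, 4000L), 120),
         teTypeSpec("T3", "SINE", 60L, c(300L, 400L), 150)),
    seed = 7L)
  cat1 <- generateTEAnnotation(spec)
  gr <- teCopies(cat1)
  expect_length(gr, 180L)

  # brute-force O(n^2) pairwise overlap scan
  ch <- as.character(seqnames(gr)); st <- start(gr); en <- end(gr)
  overlaps <- 0L
  for (i in 1:(length(gr) - 1)) for (j in (i + 1):length(gr)) {
    if (ch[i] == ch[j] && st[i] <= en[j] && en[i] >= st[j])
      overlaps <- overlaps + 1L
  }
  expect_identical(overlaps, 0L)
  expect_true(all(st >= 1))
  expect_true(all(en <= seqlengths(gr)[ch]))
  expect_true(all(mcols(gr)$millidiv >= 0 & mcols(gr)$millidiv <= 1000))

  # byte-identical annotation files for a repeated run of the same seed
  f1 <- tempfile(); f2 <- tempfile()
  writeCatalogRmsk(cat1, f1)
  writeCatalogRmsk(generateTEAnnotation(spec), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("a zero-copy type yields an empty catalog and capacity errors are explicit", {
  spec0 <- syntheticGenomeSpec(c(chr1 = 100000L),
                               list(teTypeSpec("T0", "DNA", 0L)), seed = 1L)
  expect_length(teCopies(generateTEAnnotation(spec0)), 0L)

  # genome far too small for the requested copy load
  crowded <- syntheticGenomeSpec(
    c(chr1 = 5000L),
    list(teTypeSpec("TX", "LTR", 50L, c(1000L, 1000L), 50)), seed = 1L)
  expect_error(generateTEAnnotation(crowded, max_retries = 50L), "retries")
})

test_that("noise-free coverage tracks carry the planted magnitudes exactly", {
  spec <- tinySpec(seed = 3L)
  cat1 <- generateTEAnnotation(spec)
  # no effects, zero noise: constant 1.0 everywhere
  tr0 <- generateCoverageTrack(spec, cat1, list(), "flat", noise_sd = 0)
  v <- as.numeric(trackCoverage(tr0)$chr1)
  expect_true(all(v == 1))

  tr8 <- generateCoverageTrack(
    spec, cat1, list(plantedEffect("TEa", "mark_enrichment", 8)),
    "m8", noise_sd = 0)
  # brute-force per-base scan from the written bedGraph, independent of the
  # in-memory representation
  bg <- tempfile(fileext = ".bedGraph")
  writeTrackBedGraph(tr8, bg)
  rows <- read.table(bg, sep = "\t",
                     col.names = c("chrom", "start0", "end", "value"))
  vecs <- lapply(spec$chrom_sizes, numeric)
  for (i in seq_len(nrow(rows)))
    vecs[[rows$chrom[i]]][(rows$start0[i] + 1):rows$end[i]] <- rows$value[i]
  gr <- teCopies(cat1)
  a <- gr[mcols(gr)$type == "TEa"]
  vals_a <- unlist(lapply(seq_along(a), function(i)
    vecs[[as.character(seqnames(a))[i]]][start(a)[i]:end(a)[i]]))
  expect_equal(mean(vals_a), 8.0)
  expect_true(all(vals_a == 8.0))
  other <- gr[mcols(gr)$type != "TEa"]
  vals_o <- unlist(lapply(seq_along(other), function(i)
    vecs[[as.character(seqnames(other))[i]]][start(other)[i]:end(other)[i]]))
  expect_true(all(vals_o == 1.0))
})

test_that("a 5'-biased effect elevates only the first 500 bp, on both strands", {
  spec <- tinySpec(seed = 5L)
  cat1 <- generateTEAnnotation(spec)
  tr <- generateCoverageTrack(
    spec, cat1, list(plantedEffect("TEb", "mark_enrichment", 6,
                                   profile_bias = "fiveprime")),
    "bias", noise_sd = 0)
  gr <- teCopies(cat1)
  b <- gr[mcols(gr)$type == "TEb"]
  for (std in c("+", "-")) {
    cp <- b[as.character(strand(b)) == std]
    expect_gt(length(cp), 0L)
    for (i in seq_len(min(5L, length(cp)))) {
      v <- as.numeric(window(trackCoverage(tr)[[as.character(seqnames(cp))[i]]],
                             start(cp)[i], end(cp)[i]))
      if (std == "-") v <- rev(v)
      expect_equal(mean(v[1:500]), 6.0)
      expect_equal(mean(v[501:length(v)]), 1.0)
    }
  }
})

test_that("unknown planted targets are rejected by name", {
  spec <- tinySpec()
  expect_error(
    generateCoverageTrack(spec, NULL,
                          list(plantedEffect("nope", "mark_enrichment", 2)),
                          "m"),
    "nope")
})

test_that("count generation follows the requested NB/Poisson moments", {
  ids <- sprintf("g%04d", 1:200)
  # dispersion 0 degrades to Poisson(100): pooled mean within 3 SE
  se0 <- generateCountMatrix(ids, n_reps = 5L, nb_dispersion = 0,
                             seed = 11L, base_mean = 100)
  cnt <- SummarizedExperiment::assay(se0, "counts")
  n <- length(cnt)
  expect_gt(n, 999)
  expect_lt(abs(mean(cnt) - 100), 3 * sqrt(100 / n))

  # planted fold 1 everywhere: group means equal in expectation
  se1 <- generateCountMatrix(ids, n_reps = 10L, nb_dispersion = 0.05,
                             planted = lapply(ids, plantedEffect,
                                              kind = "expression_fold",
                                              magnitude = 1),
                             seed = 12L)
  g <- SummarizedExperiment::colData(se1)$group
  m1 <- rowMeans(SummarizedExperiment::assay(se1)[, g == "control"])
  m2 <- rowMeans(SummarizedExperiment::assay(se1)[, g == "knockdown"])
  expect_lt(abs(mean(m2) / mean(m1) - 1), 0.05)

  # planted 8-fold: empirical group-mean ratio within +/-15% at n_reps=10
  se8 <- generateCountMatrix(ids, n_reps = 10L, nb_dispersion = 0.1,
                             planted = lapply(ids, plantedEffect,
                                              kind = "expression_fold",
                                              magnitude = 8),
                             seed = 13L)
  m1 <- rowMeans(SummarizedExperiment::assay(se8)[, g == "control"])
  m2 <- rowMeans(SummarizedExperiment::assay(se8)[, g == "knockdown"])
  ratio <- mean(m2) / mean(m1)
  expect_gt(ratio, 8 * 0.85)
  expect_lt(ratio, 8 * 1.15)
  expect_error(generateCountMatrix(ids, base_mean = -5), "negative mean")
})

test_that("the signature dataset plants exactly the top set", {
  d0 <- generateSignatureDataset(n_top = 0L, n_genes = 50L, seed = 1L)
  expect_length(d0$truth, 0L)
  d <- generateSignatureDataset(n_genes = 500L, n_top = 200L,
                                fold_top = 10, seed = 2L)
  fold <- d$expr$C2 / d$expr$ESC
  top_by_sort <- d$expr$gene[order(-fold)][1:200]
  expect_setequal(top_by_sort, d$truth)
})

test_that("the fixture bundle is deterministic, complete and re-readable", {
  spec <- tinySpec(seed = 9L, n_copies = c(55L, 55L, 55L))
  effs <- list(mk1 = list(plantedEffect("TEa", "mark_enrichment", 4)))
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  b1 <- writeFixtureBundle(spec, effs, outdir = d1, noise_sd = 0.2)
  b2 <- writeFixtureBundle(spec, effs, outdir = d2, noise_sd = 0.2)
  expect_setequal(b1$manifest$file,
                  c("chrom.sizes", "te_rmsk.tsv", "te.bed", "genes.gtf",
                    "track_mk1.bedGraph", "counts.tsv", "expr_2c_esc.tsv",
                    "ground_truth.json"))
  expect_identical(b1$manifest$md5[order(b1$manifest$file)],
                   b2$manifest$md5[order(b2$manifest$file)])

  # round-trip through the annotation/coverage readers
  cat_rt <- readRepeatMasker(file.path(d1, "te_rmsk.tsv"), "ucsc_rmsk",
                             chrom_sizes = file.path(d1, "chrom.sizes"))
  truth <- jsonlite::read_json(file.path(d1, "ground_truth.json"))
  got <- table(mcols(teCopies(cat_rt))$type)
  for (tn in names(truth$n_copies_per_type))
    expect_identical(unname(got[tn]),
                     as.integer(truth$n_copies_per_type[[tn]]))
  tr <- readCoverage(file.path(d1, "track_mk1.bedGraph"),
                     chrom_sizes = file.path(d1, "chrom.sizes"))
  expect_s4_class(tr, "CoverageTrack")
  expect_identical(unname(trackSeqlengths(tr)),
                   unname(as.numeric(spec$chrom_sizes)))

  # annotation write -> read -> write round-trips losslessly
  f1 <- file.path(d1, "te_rmsk.tsv"); f3 <- tempfile()
  writeCatalogRmsk(cat_rt, f3)
  expect_identical(readLines(f1), readLines(f3))
})
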