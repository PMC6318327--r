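test_that("coverage reading normalizes bedGraph input and rejects ambiguity", {
  sizes <- c(chr1 = 1000L)
  f <- tempfile(fileext = ".bedGraph")

  writeLines(character(0), f)
  tr <- readCoverage(f, "bedGraph", sizes)
  expect_true(all(as.numeric(trackCoverage(tr)$chr1) == 0))
  expect_identical(length(trackCoverage(tr)$chr1), 1000L)

  writeLines("chr1\t0\t100\t2.5", f)
  tr <- readCoverage(f, "bedGraph", sizes)
  gr <- GRanges("chr1", IRanges(1, 100))
  expect_equal(trackMeans(tr, gr), 2.5)
  # 1-based [50,149]: 51 covered bases (50..100) at 2.5, 49 uncovered
  expect_equal(trackMeans(tr, GRanges("chr1", IRanges(50, 149))),
               51 * 2.5 / 100)

  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t2"), f)
  expect_error(readCoverage(f, "bedGraph", sizes), "ambiguous")

  writeLines("chr1\t900\t1100\t3", f)
  expect_warning(tr <- readCoverage(f, "bedGraph", sizes), "clipped")
  expect_identical(length(trackCoverage(tr)$chr1), 1000L)
  expect_equal(trackMeans(tr, GRanges("chr1", IRanges(901, 1000))), 3)
})

test_that("bedGraph round-trips through write and read to identical queries", {
  spec <- tinySpec(seed = 21L, n_copies = c(20L, 10L, 20L),
                   sizes = c(chr1 = 300000L))
  cat1 <- generateTEAnnotation(spec)
  tr <- generateCoverageTrack(spec, cat1,
                              list(plantedEffect("TEa", "mark_enrichment", 3)),
                              "m", noise_sd = 0.2)
  f <- tempfile(fileext = ".bedGraph")
  writeTrackBedGraph(tr, f)
  tr2 <- readCoverage(f, "bedGraph", spec$chrom_sizes)
  gr <- teCopies(cat1)
  expect_equal(trackMeans(tr2, gr), trackMeans(tr, gr), tolerance = 1e-8)
})

test_that("metagene binning is 5'-anchored, strand-aware and partial-bin exact", {
  sizes <- c(chr1 = 10000L)
  # constant track: every bin equals the constant
  v <- rep(4, 10000)
  trc <- trackFromVectors(list(chr1 = v))
  cp <- GRanges("chr1", IRanges(101, 1350), strand = "+",
                seqlengths = sizes)  # 1,250 bp -> bins 500/500/250
  bins <- binTEType(trc, cp)
  expect_length(bins, 3L)
  expect_equal(bins, c(4, 4, 4))

  # 5' 500 bp at 8 on a + and a - copy, else 1: bin 1 = 8, later bins = 1
  v <- rep(1, 10000)
  v[1001:1500] <- 8          # + copy [1001, 2200]: its 5' 500 bp
  v[5201:5700] <- 8          # - copy [4501, 5700]: its 5' 500 bp at the end
  tr <- trackFromVectors(list(chr1 = v))
  cps <- GRanges("chr1", IRanges(c(1001, 4501), c(2200, 5700)),
                 strand = c("+", "-"), seqlengths = sizes)
  bins <- binTEType(tr, cps)
  expect_equal(bins[1], 8)
  expect_true(all(bins[-1] == 1))

  # a copy shorter than one bin contributes a single bin
  short <- GRanges("chr1", IRanges(9001, 9200), strand = "+",
                   seqlengths = sizes)
  expect_length(binTEType(trc, short), 1L)
})

test_that("background regions are size-matched, deterministic and excludable", {
  sizes <- c(chr1 = 500000L, chr2 = 300000L)
  cp <- GRanges(c("chr1", "chr1", "chr2"),
                IRanges(c(1000, 5000, 2000), width = c(300, 900, 2100)),
                seqlengths = sizes)
  bg1 <- sampleBackgroundRegions(cp, sizes, seed = 5L)
  expect_identical(sort(width(bg1)), sort(width(cp)))
  expect_identical(length(bg1), length(cp))
  bg2 <- sampleBackgroundRegions(cp, sizes, seed = 5L)
  expect_identical(as.character(bg1), as.character(bg2))
  # exclusion honoured by rejection
  excl <- GRanges("chr1", IRanges(1, 499000), seqlengths = sizes)
  bg3 <- sampleBackgroundRegions(cp, sizes, seed = 5L, exclude = excl)
  expect_identical(sum(countOverlaps(bg3, excl)), 0L)
  # impossible placement errors out
  all_excl <- GRanges(c("chr1", "chr2"),
                      IRanges(1, c(500000, 300000)), seqlengths = sizes)
  expect_error(sampleBackgroundRegions(cp, sizes, seed = 1L,
                                       exclude = all_excl, max_retries = 20L),
               "retries")
})

test_that("enrichment equals the naive per-base oracle and recovers planted folds", {
  spec <- tinySpec(seed = 31L)
  cat1 <- generateTEAnnotation(spec)

  # constant track: log2 fold exactly 0 for every type
  sizes <- spec$chrom_sizes
  trc <- trackFromVectors(lapply(sizes, function(n) rep(2, n)), "const")
  em0 <- computeTEEnrichment(trc, cat1, seed = 4L)
  expect_true(all(log2Fold(em0) == 0))

  # planted 8-fold with noise: observed equals the naive per-base loop
  # exactly, and log2 fold is within the sampling band around 3
  tr <- generateCoverageTrack(spec, cat1,
                              list(plantedEffect("TEa", "mark_enrichment", 8)),
                              "m8", noise_sd = 0.25)
  em <- computeTEEnrichment(tr, cat1, seed = 4L)
  vecs <- lapply(trackCoverage(tr), as.numeric)
  gr <- teCopies(cat1)
  for (tn in teTypeNames(cat1)) {
    cp <- gr[mcols(gr)$type == tn]
    copies_df <- data.frame(chrom = as.character(seqnames(cp)),
                            start = start(cp), end = end(cp),
                            strand = as.character(strand(cp)))
    expect_equal(observedSignal(em)["m8", tn],
                 oracleMaxBin(vecs, copies_df), tolerance = 1e-12)
  }
  expect_lt(abs(log2Fold(em)["m8", "TEa"] - 3), 0.25)
  expect_lt(max(abs(log2Fold(em)["m8", c("TEb", "TEc")])), 0.5)
})

test_that("enrichment is stable across background seeds", {
  spec <- tinySpec(seed = 41L, sizes = c(chr1 = 800000L, chr2 = 400000L))
  cat1 <- generateTEAnnotation(spec)
  tr <- generateCoverageTrack(spec, cat1,
                              list(plantedEffect("TEb", "mark_enrichment", 4)),
                              "m", noise_sd = 0.25)
  lf <- vapply(1:10, function(s)
    log2Fold(computeTEEnrichment(tr, cat1, seed = s))["m", "TEb"],
    numeric(1))
  expect_lt(max(lf) - min(lf), 0.15)
})

test_that("mark calls use a strict threshold with correct tallies", {
  obs <- matrix(c(3.1, 1.7, 0.4, 2.0) - 0.01, nrow = 1,
                dimnames = list("mk", paste0("T", 1:4)))
  exp_ <- matrix(1 - 0.01, nrow = 1, ncol = 4,
                 dimnames = dimnames(obs))
  em <- EnrichmentMatrix(obs, exp_, pseudocount = 0.01)
  # folds are exactly {3.1, 1.7, 0.4, 2.0}
  expect_equal(unname(foldEnrichment(em)[1, ]), c(3.1, 1.7, 0.4, 2.0))
  strict <- callEnrichedMarks(em, 2.0)
  expect_identical(unname(strict$calls[1, ]), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(unname(strict$per_mark), 1)
  relaxed <- callEnrichedMarks(em, 1.5)
  expect_identical(sum(relaxed$calls), 3L)   # 3.1, 1.7 and 2.0 pass > 1.5
  expect_identical(sum(relaxed$calls[, c("T1", "T2", "T3")]), 2L)
  expect_identical(sum(callEnrichedMarks(em, 2.0, ">=")$calls), 2L)

  zero <- EnrichmentMatrix(exp_ * 0, exp_ * 0, pseudocount = 0.01)
  expect_identical(sum(callEnrichedMarks(zero)$calls), 0L)
})

test_that("High/Low partition matches the ranking rule", {
  folds <- c(5, 4, 3, 2.5, 2.1, 1.9, 1.5, 1.2, 0.9, 0.5)
  obs <- matrix(folds - 0.01, nrow = 1,
                dimnames = list("mk", paste0("T", 1:10)))
  exp_ <- matrix(1 - 0.01, nrow = 1, ncol = 10, dimnames = dimnames(obs))
  em <- EnrichmentMatrix(obs, exp_, pseudocount = 0.01)
  hl <- partitionHighLow(em, "mk", 2.0)
  expect_setequal(hl$high, paste0("T", 1:5))
  expect_setequal(hl$low, paste0("T", 6:10))
  expect_length(intersect(hl$high, hl$low), 0L)

  # nothing above threshold: both sets empty
  em_low <- EnrichmentMatrix(exp_ * 0.5, exp_, pseudocount = 0.01)
  hl0 <- partitionHighLow(em_low, "mk", 2.0)
  expect_length(hl0$high, 0L)
  expect_length(hl0$low, 0L)

  # High > half the types: no disjoint Low possible
  em_hi <- EnrichmentMatrix(exp_ * 10, exp_, pseudocount = 0.01)
  expect_error(partitionHighLow(em_hi, "mk", 2.0), "half")
})

test_that("clustering recovers planted blocks and ignores input order", {
  set.seed(99)
  base <- matrix(rnorm(8 * 12, sd = 0.1), nrow = 8,
                 dimnames = list(paste0("m", 1:8), paste0("T", 1:12)))
  base[1:4, 1:6] <- base[1:4, 1:6] + 3      # block A marks
  base[5:8, 7:12] <- base[5:8, 7:12] + 3    # block B marks
  cl <- clusterEnrichmentMatrix(base, axis = "marks")
  ct <- cutree(cl$hclust, k = 2)
  expect_length(unique(ct[paste0("m", 1:4)]), 1L)
  expect_length(unique(ct[paste0("m", 5:8)]), 1L)
  expect_false(ct[["m1"]] == ct[["m5"]])

  # permuting rows leaves memberships unchanged
  perm <- sample(8)
  ct2 <- cutree(clusterEnrichmentMatrix(base[perm, ], axis = "marks")$hclust,
                k = 2)
  agree <- outer(ct, ct, "==")
  agree2 <- outer(ct2[names(ct)], ct2[names(ct)], "==")
  expect_identical(agree, agree2)

  # identical columns merge at distance 0 first
  dup <- base; dup[, 2] <- dup[, 1]
  cld <- clusterEnrichmentMatrix(dup, axis = "te_types")
  expect_equal(min(cld$hclust$height), 0)
  first <- sort(cld$hclust$merge[1, ])
  expect_setequal(rownames(t(dup))[-first], c("T1", "T2"))
})

test_that("age-enrichment correlation handles perfect, null and degenerate cases", {
  ages <- setNames(seq(1e6, 12e6, length.out = 12), paste0("T", 1:12))
  lf <- matrix(rev(seq_len(12)), nrow = 1,
               dimnames = list("mk", paste0("T", 1:12)))
  em <- EnrichmentMatrix(2^lf, matrix(1, 1, 12, dimnames = dimnames(lf)),
                         pseudocount = 0)
  res <- correlateAgeEnrichment(em, ages)
  expect_equal(res$rho, -1)

  # independent vectors: small rho, p agreeing with a permutation oracle
  set.seed(7)
  y <- rnorm(200)
  ages2 <- setNames(runif(200, 1e6, 5e7), paste0("G", 1:200))
  em2 <- EnrichmentMatrix(
    matrix(2^y, 1, 200, dimnames = list("mk", names(ages2))),
    matrix(1, 1, 200, dimnames = list("mk", names(ages2))),
    pseudocount = 0)
  res2 <- correlateAgeEnrichment(em2, ages2)
  expect_lt(abs(res2$rho), 0.2)
  perm_rho <- replicate(1000, cor(sample(ages2), y, method = "spearman"))
  p_perm <- mean(abs(perm_rho) >= abs(res2$rho))
  expect_lt(abs(res2$p - p_perm), 0.1)

  # constant enrichment: undefined, flagged
  em3 <- EnrichmentMatrix(
    matrix(1, 1, 12, dimnames = list("mk", names(ages))),
    matrix(1, 1, 12, dimnames = list("mk", names(ages))), pseudocount = 0)
  expect_warning(res3 <- correlateAgeEnrichment(em3, ages), "undefined")
  expect_true(is.na(res3$rho))
})

test_that("scaled pileups put planted signal in the body and keep flanks at background", {
  sizes <- c(chr1 = 60000L)
  v <- rep(1, 60000)
  v[20001:24000] <- 5
  v[40001:42000] <- 5
  tr <- trackFromVectors(list(chr1 = v))
  cps <- GRanges("chr1", IRanges(c(20001, 40001), c(24000, 42000)),
                 strand = c("+", "-"), seqlengths = sizes)
  prof <- computeMetageneProfile(tr, cps, flank_bp = 5000L,
                                 n_body_bins = 20L, flank_bin_bp = 500L)
  body <- prof[grepl("^body_", names(prof))]
  up <- prof[grepl("^up_", names(prof))]
  dn <- prof[grepl("^down_", names(prof))]
  expect_length(body, 20L)
  expect_length(up, 10L)
  expect_equal(unname(body), rep(5, 20))
  expect_equal(unname(up), rep(1, 10))
  expect_equal(unname(dn), rep(1, 10))

  # constant track gives a flat profile
  flat <- computeMetageneProfile(trackFromVectors(list(chr1 = rep(2, 60000))),
                                 cps, n_body_bins = 10L)
  expect_true(all(flat == 2))
})

test_that("replicate QC keeps concordant tracks and merges by mean", {
  sizes <- c(chr1 = 50000L)
  cp_df <- data.frame(chrom = "chr1",
                      start = seq(1, 48001, by = 1000)[1:40],
                      end = seq(1, 48001, by = 1000)[1:40] + 499,
                      strand = "+", type = "TEq", class = "LTR",
                      family = "f", millidiv = 50)
  cat1 <- catalogFromDF(cp_df, sizes)
  mkTrack <- function(vals, label) {
    v <- rep(0.5, 50000)
    for (i in seq_len(nrow(cp_df))) v[cp_df$start[i]:cp_df$end[i]] <- vals[i]
    trackFromVectors(list(chr1 = v), label)
  }
  a_vals <- seq(1, 40)
  tA <- mkTrack(a_vals, "repA")
  tA2 <- mkTrack(a_vals, "repB")
  qc <- qcReplicates(list(tA, tA2), cat1)
  expect_setequal(qc$kept, c("repA", "repB"))
  expect_equal(qc$cor["repA", "repB"], 1)
  expect_equal(trackMeans(qc$merged, teCopies(cat1)),
               trackMeans(tA, teCopies(cat1)))

  # anti-correlated replicate is dropped; r checked against the direct
  # Pearson formula
  b_vals <- -a_vals + 50
  tB <- mkTrack(b_vals, "repC")
  qc2 <- qcReplicates(list(tA, tA2, tB), cat1)
  expect_identical(qc2$dropped, "repC")
  r_direct <- sum((a_vals - mean(a_vals)) * (b_vals - mean(b_vals))) /
    sqrt(sum((a_vals - mean(a_vals))^2) * sum((b_vals - mean(b_vals))^2))
  expect_equal(qc2$cor["repA", "repC"], r_direct)

  # an exactly r = 0.5 pair fails the > 0.6 rule: highest-coverage kept
  set.seed(123)
  za <- scale(a_vals)[, 1]
  resid <- scale(stats::residuals(lm(rnorm(40) ~ za)))[, 1]
  c_vals <- 20 + 5 * (0.5 * za + sqrt(0.75) * resid)
  tC <- mkTrack(c_vals, "repD")
  expect_equal(cor(a_vals, c_vals), 0.5, tolerance = 1e-12)
  expect_warning(qc3 <- qcReplicates(list(tA, tC), cat1), "discordant")
  expect_length(qc3$kept, 1L)
})
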