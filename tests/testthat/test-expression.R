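Sam <- function(lines, dir = tempdir()) {
  # minimal SAM -> sorted/indexed BAM for counting tests
  sam <- tempfile(tmpdir = dir, fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chr1\tLN:100000", "@SQ\tSN:chrM\tLN:16000")
  writeLines(c(hdr, lines), sam)
  bam <- Rsamtools::asBam(sam, tempfile(tmpdir = dir), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

read1 <- function(name, chrom, pos, len = 50L) {
  paste(name, 0L, chrom, pos, 255L, paste0(len, "M"), "*", 0L, 0L,
        paste(rep("A", len), collapse = ""), "*", sep = "\t")
}

countFixture <- function() {
  sizes <- c(chr1 = 100000L)
  te_df <- data.frame(chrom = "chr1", start = c(10001L, 30001L),
                      end = c(12000L, 31000L), strand = "+",
                      type = c("TEx", "TEy"), class = "LTR", family = "f",
                      millidiv = 50)
  genes <- GRanges("chr1", IRanges(c(11500L, 50001L), c(13000L, 52000L)),
                   strand = "+", seqlengths = sizes)
  mcols(genes)$gene_id <- c("geneA", "geneB")
  list(catalog = catalogFromDF(te_df, sizes), genes = genes)
}

test_that("reads are counted once with gene-over-TE precedence", {
  fx <- countFixture()
  bam <- Sam(c(
    read1("r1", "chr1", 10100),   # fully inside TEx -> TEx
    read1("r2", "chr1", 11600),   # overlaps geneA and TEx -> geneA
    read1("r3", "chr1", 50100),   # inside geneB
    read1("r4", "chr1", 80000),   # intergenic -> unassigned
    read1("r5", "chrM", 100),     # mitochondrial -> discarded
    read1("r6", "chr1", 30100)))  # inside TEy
  cnt <- countFeatures(bam, fx$genes, fx$catalog)
  got <- setNames(cnt$count, cnt$feature)
  expect_identical(got[["TEx"]], 1L)
  expect_identical(got[["TEy"]], 1L)
  expect_identical(got[["geneA"]], 1L)
  expect_identical(got[["geneB"]], 1L)
  expect_identical(attr(cnt, "n_discarded"), 1L)
  expect_identical(attr(cnt, "n_unassigned"), 1L)
  # conservation: assigned + unassigned + discarded = total
  expect_identical(attr(cnt, "n_assigned") + attr(cnt, "n_unassigned") +
                     attr(cnt, "n_discarded"), attr(cnt, "n_total"))

  # inverted precedence sends the ambiguous read to the TE
  cnt2 <- countFeatures(bam, fx$genes, fx$catalog, precedence = "te")
  got2 <- setNames(cnt2$count, cnt2$feature)
  expect_identical(got2[["TEx"]], 2L)
  expect_identical(got2[["geneA"]], 0L)

  # zero-read BAM gives an all-zero column
  bam0 <- Sam(character(0))
  cnt0 <- countFeatures(bam0, fx$genes, fx$catalog)
  expect_true(all(cnt0$count == 0L))
})

test_that("TE read fraction is the TE share of assigned counts", {
  df <- data.frame(feature = c("g1", "g2", "t1"),
                   kind = c("gene", "gene", "te"),
                   count = c(500L, 484L, 16L))
  expect_equal(unname(computeTEReadFraction(df)), 0.016)
  df$count <- c(0L, 0L, 7L)
  expect_equal(unname(computeTEReadFraction(df)), 1.0)
  m <- matrix(c(0L, 0L), ncol = 1, dimnames = list(c("g", "t"), "s1"))
  expect_warning(fr <- computeTEReadFraction(m, kind = c("gene", "te")),
                 "zero")
  expect_true(is.na(fr))
})

test_that("full-quantile normalization equalizes distributions and is idempotent", {
  set.seed(42)
  m <- matrix(rnbinom(400, mu = 100, size = 10), ncol = 4,
              dimnames = list(sprintf("f%03d", 1:100), paste0("s", 1:4)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m))
  # a sample at exactly 2x another: post-normalization sorted
  # distributions identical
  m2 <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m2))
  n2 <- SummarizedExperiment::assay(normalizeCounts(se2), "normalized")
  expect_equal(sort(n2[, 1]), sort(n2[, 2]), ignore_attr = TRUE)
  # rank orders preserved within each sample
  expect_identical(order(n2[, 2]), order(m2[, 2]))

  # identical samples pass through unchanged
  m3 <- cbind(s1 = m[, 1], s2 = m[, 1])
  n3 <- SummarizedExperiment::assay(normalizeCounts(
    SummarizedExperiment::SummarizedExperiment(assays = list(counts = m3))),
    "normalized")
  expect_equal(unname(n3), unname(m3) * 1.0)

  # idempotence: applying full-quantile twice equals once, exactly
  n1 <- SummarizedExperiment::assay(normalizeCounts(se), "normalized")
  se_again <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = n1))
  n_again <- SummarizedExperiment::assay(normalizeCounts(se_again),
                                         "normalized")
  expect_equal(n_again, n1, tolerance = 1e-14)

  # near-agreement with the established quantile engine (tie handling
  # differs slightly by design)
  ref <- limma::normalizeQuantiles(1.0 * m)
  expect_equal(unname(n1), unname(ref), tolerance = 0.02)

  expect_error(normalizeCounts(se, method = "median"), "unknown")
})

test_that("BH adjustment matches the brute-force step-up exactly", {
  for (s in 1:5) {
    set.seed(s)
    p <- runif(sample(c(10L, 100L, 1000L), 1L))
    expect_equal(p.adjust(p, "BH"), oracleBH(p), tolerance = 1e-15)
  }
})

test_that("the NB Wald test is calibrated under the null", {
  feats <- data.frame(feature = sprintf("f%03d", 1:200),
                      kind = rep(c("te", "gene"), c(20, 180)))
  rates <- c(); calls <- 0L
  for (s in 1:10) {
    se <- generateCountMatrix(feats, n_reps = 3L, nb_dispersion = 0.1,
                              seed = 5000L + s)
    de <- testDifferential(se)
    rates <- c(rates, mean(de$p < 0.05, na.rm = TRUE))
    calls <- calls + sum(de$call != "ns")
  }
  # nominal p < 0.05 near alpha (moment estimator + normal reference make
  # it mildly liberal at n = 3), and essentially no calls survive
  # BH + fold filter
  expect_lt(mean(rates), 0.12)
  expect_gt(mean(rates), 0.01)
  expect_lt(calls / (200 * 10), 0.01)
})

test_that("a planted 8-fold TE at n=2, dispersion 0.05 is reliably called up", {
  feats <- data.frame(feature = c("TEkd", sprintf("g%03d", 1:99)),
                      kind = c("te", rep("gene", 99)))
  hit <- vapply(1:100, function(s) {
    se <- generateCountMatrix(feats, n_reps = 2L,
                              planted = list(plantedEffect(
                                "TEkd", "expression_fold", 8)),
                              nb_dispersion = 0.05, seed = 9000L + s)
    de <- testDifferential(se)
    de$call[de$feature == "TEkd"] == "up"
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("degenerate features and single replicates are handled explicitly", {
  m <- matrix(c(0L, 0L, 0L, 0L, 100L, 105L, 210L, 190L), nrow = 2,
              byrow = TRUE, dimnames = list(c("dead", "live"),
                                            c("c1", "c2", "k1", "k2")))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(
      group = factor(rep(c("control", "knockdown"), each = 2L),
                     levels = c("control", "knockdown"))))
  de <- testDifferential(se)
  expect_false(de$tested[de$feature == "dead"])
  expect_true(is.na(de$p[de$feature == "dead"]))
  expect_true(de$tested[de$feature == "live"])

  se1 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m[, c(1, 3), drop = FALSE]),
    colData = S4Vectors::DataFrame(
      group = factor(c("control", "knockdown"))))
  expect_warning(testDifferential(se1), "fewer than 2 replicates")
})

test_that("TE deregulation summaries follow the set arithmetic and >4-fold rule", {
  mkDE <- function(feat, kind, lfc, call) {
    data.frame(feature = feat, kind = kind, base_mean = 100,
               log2fc = lfc, p = 0.001, padj = 0.001, call = call,
               tested = TRUE)
  }
  # knockdown A: TEs t1 (up 8x), t2 (up 3x), t3 (down); B: t2 up again
  deA <- mkDE(c("t1", "t2", "t3", "g1"), c("te", "te", "te", "gene"),
              log2(c(8, 3, 1 / 4, 5)), c("up", "up", "down", "up"))
  deB <- mkDE(c("t1", "t2", "t3", "g1"), c("te", "te", "te", "gene"),
              c(0, log2(6), 0, 0), c("ns", "up", "ns", "ns"))
  s_ <- summarizeDeregulatedTEs(list(A = deA, B = deB))
  expect_identical(s_$per_knockdown$n_up, c(2L, 1L))
  expect_identical(s_$per_knockdown$n_down, c(1L, 0L))
  expect_setequal(s_$unique_tes, c("t1", "t3"))
  expect_setequal(s_$shared_tes, "t2")
  # > 4-fold strictly: t1 (8x) and B's t2 (6x) qualify, A's t2 (3x) not
  expect_setequal(paste(s_$high_fold$knockdown, s_$high_fold$feature),
                  c("A t1", "B t2"))

  none <- summarizeDeregulatedTEs(list(
    A = mkDE("t1", "te", 0, "ns")))
  expect_identical(none$per_knockdown$n_up, 0L)
  expect_length(none$unique_tes, 0L)
})

test_that("the stand-in DE engine agrees with an established NB engine on calls", {
  skip_if_not_installed("DESeq2")
  feats <- data.frame(feature = sprintf("f%03d", 1:150),
                      kind = rep("gene", 150))
  planted <- lapply(sprintf("f%03d", 1:10), plantedEffect,
                    kind = "expression_fold", magnitude = 6)
  se <- generateCountMatrix(feats, n_reps = 3L, planted = planted,
                            nb_dispersion = 0.1, seed = 77L)
  de <- testDifferential(se)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    SummarizedExperiment::assay(se, "counts"),
    S4Vectors::DataFrame(group = SummarizedExperiment::colData(se)$group),
    ~group)
  res <- as.data.frame(DESeq2::results(suppressMessages(DESeq2::DESeq(dds,
                                                                      quiet = TRUE))))
  ref_up <- rownames(res)[!is.na(res$padj) & res$padj < 0.05 &
                            res$log2FoldChange > 1]
  own_up <- de$feature[de$call == "up"]
  # both engines recover essentially the planted set
  expect_gte(length(intersect(own_up, ref_up)) /
               length(union(own_up, ref_up)), 0.8)
})
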