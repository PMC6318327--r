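# Stage orchestration: a single config object carries every path and every
# standing parameter of the analysis; stages declare their prerequisites
# and write their outputs under outdir/<stage>/. runDemo() exercises the
# whole DAG on a synthetic bundle with planted ground truth and reports
# planted-vs-recovered for every effect.

#' Pipeline configuration
#'
#' Collects the paths and parameters of a full run. Every parameter
#' default is the standing value used throughout the package: 500-bp bins,
#' the 300 bp / 50 copies catalog filters, 2-fold enrichment (1.5 relaxed),
#' BH 0.05 with |fold| > 2 for differential expression, the 1.2/0.8
#' accessibility rule, 10-kb proximity windows, 200-gene signatures, and a
#' Jukes-Cantor substitution rate of 4.5e-9 per base per year.
#'
#' @param catalog Path to the TE annotation (UCSC-rmsk-style TSV).
#' @param chrom_sizes Path to chrom.sizes.
#' @param tracks Named character vector of mark bedGraph paths.
#' @param atac_tracks Named character vector of ATAC bedGraph paths.
#' @param atac_control Name of the ATAC control sample.
#' @param counts Named character vector of per-knockdown count TSVs
#'   (columns: feature, kind, then samples `control_*`/`knockdown_*`).
#' @param gtf Path to the gene GTF.
#' @param expr_2c Path to the 2C-vs-ESC expression TSV.
#' @param expr_knockdowns Path to a gene x sample expression TSV for
#'   signature scoring (must contain `control_col`).
#' @param control_col Control column of `expr_knockdowns`.
#' @param outdir Output directory.
#' @param bin_bp,min_len,min_copies,enrich_threshold,relaxed,pseudocount
#'   Enrichment-side parameters.
#' @param de_alpha,de_fc Differential-expression thresholds.
#' @param atac_up,atac_down Accessibility fold bounds.
#' @param fisher_alpha Fisher significance level.
#' @param window Proximity window (bp) for peak-gene and MERVL-gene links.
#' @param sig_n Signature size.
#' @param age_rate Substitution rate (per base per year).
#' @param seed Master seed for every stochastic step.
#' @return A `pipelineConfig` list.
#' @export
pipelineConfig <- function(catalog = NULL, chrom_sizes = NULL,
                           tracks = character(0),
                           atac_tracks = character(0),
                           atac_control = "control",
                           counts = character(0), gtf = NULL,
                           expr_2c = NULL, expr_knockdowns = NULL,
                           control_col = "control",
                           outdir = "temetagene_out",
                           bin_bp = 500L, min_len = 300L, min_copies = 50L,
                           enrich_threshold = 2.0, relaxed = 1.5,
                           pseudocount = 0.01,
                           de_alpha = 0.05, de_fc = 2.0,
                           atac_up = 1.2, atac_down = 0.8,
                           fisher_alpha = 0.01,
                           window = 10000L, sig_n = 200L,
                           age_rate = 4.5e-9, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipelineConfig")
}

#' Read / write a pipeline configuration (YAML)
#'
#' Round-trips exactly: `readPipelineConfig(writePipelineConfig(cfg, p))`
#' reproduces `cfg`.
#'
#' @param cfg A [pipelineConfig()].
#' @param path YAML file.
#' @export
writePipelineConfig <- function(cfg, path) {
  raw <- unclass(cfg)
  # named atomic vectors lose their names in YAML scalars; write as maps
  for (f in c("tracks", "atac_tracks", "counts"))
    raw[[f]] <- if (length(raw[[f]])) as.list(raw[[f]]) else NULL
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipelineConfig, lapply(raw, function(x) {
    if (is.list(x)) unlist(x) else x
  }))
  for (f in c("tracks", "atac_tracks", "counts"))
    if (!length(cfg[[f]])) cfg[[f]] <- character(0)
  cfg
}

stageDeps <- list(annotate = character(0),
                  enrich = "annotate",
                  network = "enrich",
                  express = character(0),
                  atac = c("annotate", "enrich"),
                  signature = "express")

#' Run one pipeline stage
#'
#' Stages: `annotate` (read + filter the catalog, age estimates), `enrich`
#' (enrichment matrix + calls), `network`, `express` (per-knockdown DE +
#' TE summaries), `atac` (accessibility + Fisher), `signature`. Stage
#' prerequisites are declared; running a stage before its prerequisite is
#' an error naming the missing stage. Outputs land under
#' `outdir/<stage>/` and intermediate objects accumulate in `state`.
#'
#' @param name Stage name.
#' @param config A [pipelineConfig()].
#' @param state Environment carrying earlier stage results (created if
#'   missing).
#' @return `state`, invisibly.
#' @export
runStage <- function(name, config, state = new.env(parent = emptyenv())) {
  name <- match.arg(name, names(stageDeps))
  for (dep in stageDeps[[name]])
    if (!isTRUE(state$done[[dep]]))
      stop("stage '", name, "' requires stage '", dep, "' to run first")
  dir <- file.path(config$outdir, name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(state$done)) state$done <- list()

  if (name == "annotate") {
    cat0 <- readRepeatMasker(config$catalog, dialect = "ucsc_rmsk",
                             chrom_sizes = config$chrom_sizes)
    state$catalog <- filterTECatalog(cat0, config$min_len, config$min_copies)
    writeCatalogBED(state$catalog, file.path(dir, "catalog_filtered.bed"))
    state$age <- estimateTEAge(state$catalog, rate = config$age_rate)
    write.table(state$age, file.path(dir, "te_age.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else if (name == "enrich") {
    trks <- lapply(names(config$tracks), function(mk)
      readCoverage(config$tracks[[mk]], chrom_sizes = config$chrom_sizes,
                   label = mk))
    names(trks) <- names(config$tracks)
    state$em <- computeTEEnrichment(trks, state$catalog,
                                    bin_bp = config$bin_bp,
                                    pseudocount = config$pseudocount,
                                    seed = config$seed)
    state$calls <- callEnrichedMarks(state$em, config$enrich_threshold)
    lf <- log2Fold(state$em)
    write.table(data.frame(mark = rownames(lf), signif(lf, 6)),
                file.path(dir, "enrichment_log2fold.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(mark = rownames(lf), state$calls$calls),
                file.path(dir, "enrichment_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else if (name == "network") {
    state$net <- buildRelationalNetwork(state$em,
                                        threshold = config$enrich_threshold)
    exportNetwork(state$net, file.path(dir, "network_edges.tsv"),
                  "tsv_edgelist")
    state$net_summary <- networkSummary(state$net)
  } else if (name == "express") {
    state$de <- lapply(names(config$counts), function(kd) {
      se <- readCountTable(config$counts[[kd]])
      testDifferential(se, alpha = config$de_alpha, fc_min = config$de_fc)
    })
    names(state$de) <- names(config$counts)
    for (kd in names(state$de))
      write.table(state$de[[kd]],
                  file.path(dir, paste0("de_", kd, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    state$te_summary <- summarizeDeregulatedTEs(state$de)
    write.table(state$te_summary$per_knockdown,
                file.path(dir, "te_deregulation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else if (name == "atac") {
    trks <- lapply(names(config$atac_tracks), function(s)
      readCoverage(config$atac_tracks[[s]],
                   chrom_sizes = config$chrom_sizes, label = s))
    names(trks) <- names(config$atac_tracks)
    state$atac <- quantifyTEAccessibility(trks, state$catalog)
    state$atac_states <- callAccessibilityChanges(
      state$atac, config$atac_control, config$atac_up, config$atac_down)
    state$opened <- summarizeOpenedTEs(state$atac_states$state)
    state$fisher <- testMarkEnrichmentOfOpened(
      state$atac_states$state, state$calls$calls, config$fisher_alpha)
    write.table(data.frame(type = rownames(state$atac),
                           signif(state$atac, 6)),
                file.path(dir, "accessibility.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(state$fisher, file.path(dir, "fisher.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else if (name == "signature") {
    expr <- read.table(config$expr_2c, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
    state$signature <- buildSignature(expr, n = config$sig_n)
    write.table(state$signature, file.path(dir, "signature.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(config$expr_knockdowns)) {
      kexpr <- read.table(config$expr_knockdowns, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
      kds <- setdiff(colnames(kexpr), c("gene", config$control_col))
      state$sig_scores <- lapply(kds, function(kd)
        scoreSignature(state$signature, kexpr, kd, config$control_col))
      names(state$sig_scores) <- kds
    }
  }
  state$done[[name]] <- TRUE
  invisible(state)
}

#' Read a count table written by the fixture bundle
#'
#' Columns `feature`, `kind`, then one column per sample named
#' `<group>_<rep>`.
#'
#' @param path Count TSV.
#' @return A `SummarizedExperiment` with `counts` and `colData$group`.
#' @export
readCountTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$feature
  grp <- sub("_[0-9]+$", "", colnames(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    rowData = DataFrame(kind = df$kind, row.names = df$feature),
    colData = DataFrame(group = factor(grp, levels = unique(grp)),
                        row.names = colnames(m)))
}

# The demo's fixed study conditions: a 3-Mb two-chromosome genome, five TE
# types spanning the realistic copy-number (60-120) and length (0.3-7 kb)
# ranges, four marks with planted 4-8x enrichments (one 5'-biased LINE
# signal), ATAC opening/closing effects and expression folds per
# knockdown, and a 500-gene 2C table with a planted 200-gene top set.
demoSpec <- function(seed) {
  syntheticGenomeSpec(
    c(chr1 = 2000000L, chr2 = 1000000L),
    list(
      teTypeSpec("L1Md_T", "LINE", 70L, c(1000L, 7000L), 120),
      teTypeSpec("IAPEz-int", "LTR", 80L, c(1000L, 4000L), 60),
      teTypeSpec("MERVL-int", "LTR", 60L, c(500L, 5000L), 80),
      teTypeSpec("MT2_Mm", "LTR", 80L, c(300L, 500L), 80),
      teTypeSpec("B1_Mus1", "SINE", 120L, c(300L, 400L), 150)),
    seed = seed)
}

demoMarkEffects <- function() list(
  H3K9me3 = list(plantedEffect("IAPEz-int", "mark_enrichment", 8),
                 plantedEffect("MERVL-int", "mark_enrichment", 4)),
  H3K27ac = list(plantedEffect("MT2_Mm", "mark_enrichment", 4)),
  H4R3me2 = list(plantedEffect("L1Md_T", "mark_enrichment", 6,
                               profile_bias = "fiveprime")),
  input = list())

demoAtacEffects <- function() list(
  control = list(),
  shRnf2 = list(plantedEffect("MT2_Mm", "accessibility_fold", 2),
                plantedEffect("MERVL-int", "accessibility_fold", 1.8)),
  shSetdb1 = list(plantedEffect("IAPEz-int", "accessibility_fold", 1.6),
                  plantedEffect("B1_Mus1", "accessibility_fold", 0.5)))

# strong-knockdown regime: 6-8x deregulation at dispersion 0.05, the level
# of the robust TE responses the pipeline is meant to showcase
demoExpressionEffects <- function() list(
  shRnf2 = list(plantedEffect("MERVL-int", "expression_fold", 8),
                plantedEffect("MT2_Mm", "expression_fold", 6)),
  shSetdb1 = list(plantedEffect("IAPEz-int", "expression_fold", 8),
                  plantedEffect("B1_Mus1", "expression_fold", 0.125)))

#' One-shot end-to-end demo on a synthetic bundle
#'
#' Generates the full fixture bundle (genome, TE catalog, mark and ATAC
#' coverage with planted folds, per-knockdown count tables, 2C table),
#' runs every stage through the file-based readers, and compares recovered
#' effects against the planted truth: mark enrichments within +/- 0.25
#' log2 units, DE calls of the planted TE folds, ATAC opened/closed sets,
#' Fisher concordance, and exact recovery of the planted signature set.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param noise_sd Coverage noise SD (default 0.25).
#' @return A list: `checks` (named logicals, all `TRUE` when every planted
#'   effect is recovered), `recovery` (`data.frame` of planted vs
#'   recovered mark folds), `state` (stage results). A JSON report is
#'   written to `outdir/demo_report.json`.
#' @export
runDemo <- function(outdir, seed = 1L, noise_sd = 0.25) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bundle_dir <- file.path(outdir, "bundle")
  spec <- demoSpec(seed)
  mark_eff <- demoMarkEffects()
  atac_eff <- demoAtacEffects()
  expr_eff <- demoExpressionEffects()

  bundle <- writeFixtureBundle(spec, mark_eff, list(), bundle_dir,
                               noise_sd = noise_sd)

  # ATAC tracks and per-knockdown count tables
  catalog0 <- bundle$catalog
  atac_paths <- character(0)
  for (s in names(atac_eff)) {
    tr <- generateCoverageTrack(spec, catalog0, atac_eff[[s]],
                                mark = paste0("ATAC_", s),
                                noise_sd = noise_sd)
    p <- file.path(bundle_dir, paste0("atac_", s, ".bedGraph"))
    writeTrackBedGraph(tr, p)
    atac_paths[s] <- p
  }
  feats <- data.frame(
    feature = c(mcols(bundle$genes)$gene_id, teTypeNames(catalog0)),
    kind = c(rep("gene", length(bundle$genes)),
             rep("te", length(teTypeNames(catalog0)))))
  count_paths <- character(0)
  for (k in seq_along(expr_eff)) {
    kd <- names(expr_eff)[k]
    se <- generateCountMatrix(feats, n_reps = 3L, planted = expr_eff[[kd]],
                              nb_dispersion = 0.05, seed = seed + 1000L * k)
    p <- file.path(bundle_dir, paste0("counts_", kd, ".tsv"))
    cnt <- data.frame(feature = rownames(se),
                      kind = SummarizedExperiment::rowData(se)$kind,
                      as.data.frame(SummarizedExperiment::assay(se)),
                      check.names = FALSE)
    write.table(cnt, p, sep = "\t", quote = FALSE, row.names = FALSE)
    count_paths[kd] <- p
  }
  # knockdown gene-expression table for signature scoring: signature genes
  # planted 4x up in shRnf2, shSetdb1 null
  sig_tab <- read.table(file.path(bundle_dir, "expr_2c_esc.tsv"),
                        sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  truth_top <- unlist(bundle$truth$signature_top)
  kexpr <- withSeed(seed + 77L, {
    base <- sig_tab$ESC
    noise <- function() rlnorm(length(base), 0, 0.1)
    data.frame(gene = sig_tab$gene,
               control = base * noise(),
               shRnf2 = base * ifelse(sig_tab$gene %in% truth_top, 4, 1) *
                 noise(),
               shSetdb1 = base * noise(), stringsAsFactors = FALSE)
  })
  kexpr_path <- file.path(bundle_dir, "expr_knockdowns.tsv")
  write.table(kexpr, kexpr_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  cfg <- pipelineConfig(
    catalog = file.path(bundle_dir, "te_rmsk.tsv"),
    chrom_sizes = file.path(bundle_dir, "chrom.sizes"),
    tracks = setNames(file.path(bundle_dir, paste0(
      "track_", gsub("[^A-Za-z0-9._-]", "_", names(mark_eff)),
      ".bedGraph")), names(mark_eff)),
    atac_tracks = atac_paths, atac_control = "control",
    counts = count_paths, gtf = file.path(bundle_dir, "genes.gtf"),
    expr_2c = file.path(bundle_dir, "expr_2c_esc.tsv"),
    expr_knockdowns = kexpr_path,
    control_col = "control", outdir = outdir, seed = seed)

  state <- new.env(parent = emptyenv())
  for (st in c("annotate", "enrich", "network", "express", "atac",
               "signature"))
    runStage(st, cfg, state)

  # planted-vs-recovered comparison
  lf <- log2Fold(state$em)
  rec <- do.call(rbind, lapply(names(mark_eff), function(mk) {
    do.call(rbind, lapply(mark_eff[[mk]], function(ef) {
      if (!ef$target %in% colnames(lf)) return(NULL)
      # the max bin sees the full magnitude for both uniform and 5'-biased
      # profiles (the 5' window spans at least one whole bin)
      data.frame(mark = mk, te_type = ef$target,
                 planted_log2 = log2(ef$magnitude),
                 recovered_log2 = lf[mk, ef$target],
                 stringsAsFactors = FALSE)
    }))
  }))
  rec$within_0.25 <- abs(rec$recovered_log2 - rec$planted_log2) <= 0.25

  de_ok <- vapply(names(expr_eff), function(kd) {
    de <- state$de[[kd]]
    all(vapply(expr_eff[[kd]], function(ef) {
      row <- de[de$feature == ef$target, ]
      if (ef$magnitude > 1) row$call == "up" else row$call == "down"
    }, logical(1)))
  }, logical(1))

  atac_ok <- vapply(setdiff(names(atac_eff), "control"), function(s) {
    st_ <- state$atac_states$state
    all(vapply(atac_eff[[s]], function(ef) {
      want <- if (ef$magnitude >= 1.2) "opened"
              else if (ef$magnitude <= 0.8) "closed" else "unchanged"
      st_[ef$target, s] == want
    }, logical(1)))
  }, logical(1))

  sig_rec <- setequal(state$signature$gene, truth_top)
  sig_p_ok <- state$sig_scores$shRnf2$p < 0.05 &&
    state$sig_scores$shSetdb1$p > 0.05

  # the called cells must be exactly the planted > 2-fold (mark, type) pairs
  expected_calls <- matrix(FALSE, nrow = nrow(lf), ncol = ncol(lf),
                           dimnames = dimnames(lf))
  for (i in seq_len(nrow(rec)))
    if (2^rec$planted_log2[i] > 2)
      expected_calls[rec$mark[i], rec$te_type[i]] <- TRUE
  checks <- c(mark_recovery = all(rec$within_0.25),
              calls_match_planted =
                identical(unname(state$calls$calls),
                          unname(expected_calls)),
              de_recovery = all(de_ok),
              atac_recovery = all(atac_ok),
              signature_recovery = sig_rec,
              signature_score = sig_p_ok)
  report <- list(seed = seed, checks = as.list(checks),
                 mark_recovery = rec,
                 de = state$te_summary$per_knockdown,
                 opened = state$opened[c("n_unique", "n_shared")],
                 signature_scores = lapply(state$sig_scores, function(s)
                   s[c("median_log2fc", "p")]))
  jsonlite::write_json(report, file.path(outdir, "demo_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  list(checks = checks, recovery = rec, state = state, config = cfg)
}
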