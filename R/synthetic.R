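#' Specify a synthetic TE type
#'
#' Describes one transposable-element type for the synthetic genome:
#' copy-number, length distribution, mean milliDiv and strand balance.
#' Defaults are in the range typical of mouse RepeatMasker types (tens to
#' hundreds of copies, 0.3-7 kb).
#'
#' @param name Type name (repName), e.g. `"MERVL-int"`.
#' @param te_class One of `"LINE"`, `"SINE"`, `"LTR"`, `"DNA"`.
#' @param n_copies Number of genomic copies (>= 0).
#' @param length_range Length range in bp, `c(min, max)`.
#' @param millidiv_mean Mean per-mille divergence from consensus, in
#'   \[0, 1000\]. Copies sample `Normal(millidiv_mean, 30)` clipped to
#'   \[0, 1000\].
#' @param strand_balance Fraction of copies on the + strand.
#' @param family Repeat family label (defaults to the class).
#' @return A `teTypeSpec` list.
#' @export
teTypeSpec <- function(name, te_class = c("LTR", "LINE", "SINE", "DNA"),
                       n_copies = 100L, length_range = c(300L, 7000L),
                       millidiv_mean = 100, strand_balance = 0.5,
                       family = NULL) {
  te_class <- match.arg(te_class)
  stopifnot(n_copies >= 0, length(length_range) == 2L,
            length_range[1] > 0, length_range[2] >= length_range[1],
            millidiv_mean >= 0, millidiv_mean <= 1000,
            strand_balance >= 0, strand_balance <= 1)
  structure(list(name = name, te_class = te_class,
                 n_copies = as.integer(n_copies),
                 length_range = as.integer(length_range),
                 millidiv_mean = millidiv_mean,
                 strand_balance = strand_balance,
                 family = if (is.null(family)) te_class else family),
            class = "teTypeSpec")
}

#' Specify a synthetic genome
#'
#' A coordinates-only toy genome (no sequence): chromosome sizes plus the TE
#' types to place on it. Copies are placed without overlap by rejection
#' sampling; placement is deterministic for a fixed seed.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param te_types List of [teTypeSpec()] objects.
#' @param seed Integer RNG seed.
#' @return A `syntheticGenomeSpec` list.
#' @export
syntheticGenomeSpec <- function(chrom_sizes, te_types, seed = 1L) {
  stopifnot(length(chrom_sizes) >= 1, all(chrom_sizes > 0),
            !is.null(names(chrom_sizes)), all(nzchar(names(chrom_sizes))))
  if (!is.list(te_types) || inherits(te_types, "teTypeSpec"))
    te_types <- list(te_types)
  stopifnot(all(vapply(te_types, inherits, logical(1), "teTypeSpec")))
  nm <- vapply(te_types, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate TE type names in spec")
  structure(list(chrom_sizes = setNames(as.integer(chrom_sizes),
                                        names(chrom_sizes)),
                 te_types = te_types, seed = as.integer(seed)),
            class = "syntheticGenomeSpec")
}

#' Describe a planted effect for the synthetic data
#'
#' Ground truth for parameter-recovery tests: a fold-enrichment of a
#' chromatin mark at a TE type, an expression fold on a feature, or an
#' accessibility fold.
#'
#' @param target TE-type name or gene/feature id.
#' @param kind One of `"mark_enrichment"`, `"expression_fold"`,
#'   `"accessibility_fold"`.
#' @param magnitude Linear fold versus background/control (> 0).
#' @param profile_bias `"uniform"` (whole element) or `"fiveprime"`
#'   (signal restricted to the 5' 500 bp of each copy, strand-aware).
#' @return A `plantedEffect` list.
#' @export
plantedEffect <- function(target,
                          kind = c("mark_enrichment", "expression_fold",
                                   "accessibility_fold"),
                          magnitude, profile_bias = c("uniform", "fiveprime")) {
  kind <- match.arg(kind)
  profile_bias <- match.arg(profile_bias)
  stopifnot(is.numeric(magnitude), magnitude > 0)
  structure(list(target = target, kind = kind, magnitude = magnitude,
                 profile_bias = profile_bias),
            class = "plantedEffect")
}

#' Generate a synthetic TE annotation
#'
#' Places every copy of every type on the toy genome by rejection sampling
#' (uniform over the genome, chromosomes weighted by length), so that no two
#' copies overlap and no copy crosses a chromosome boundary. milliDiv per
#' copy is sampled `Normal(millidiv_mean, 30)` clipped to \[0, 1000\].
#'
#' @param spec A [syntheticGenomeSpec()].
#' @param max_retries Placement attempts per copy before giving up with a
#'   capacity error.
#' @return A [TECatalog-class]; deterministic for a fixed `spec$seed`.
#' @export
generateTEAnnotation <- function(spec, max_retries = 1000L) {
  stopifnot(inherits(spec, "syntheticGenomeSpec"))
  withSeed(spec$seed, {
    sizes <- spec$chrom_sizes
    placed_start <- integer(0); placed_end <- integer(0)
    placed_chr <- character(0)
    rows <- list()
    for (ts in spec$te_types) {
      if (ts$n_copies == 0L) next
      for (k in seq_len(ts$n_copies)) {
        len <- if (ts$length_range[1] == ts$length_range[2]) ts$length_range[1]
               else sample(ts$length_range[1]:ts$length_range[2], 1L)
        ok_chr <- names(sizes)[sizes >= len]
        if (!length(ok_chr))
          stop("no chromosome long enough for a ", len, " bp copy of ", ts$name)
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          ch <- if (length(ok_chr) == 1L) ok_chr else
            sample(ok_chr, 1L, prob = sizes[ok_chr])
          st <- sample.int(sizes[[ch]] - len + 1L, 1L)  # 1-based start
          en <- st + len - 1L
          same <- placed_chr == ch
          if (!any(same & placed_start <= en & placed_end >= st)) {
            placed_chr <- c(placed_chr, ch)
            placed_start <- c(placed_start, st)
            placed_end <- c(placed_end, en)
            md <- min(1000, max(0, rnorm(1, ts$millidiv_mean, 30)))
            std <- if (runif(1) < ts$strand_balance) "+" else "-"
            rows[[length(rows) + 1L]] <-
              list(ch, st, en, std, ts$name, ts$te_class, ts$family, md)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place copy ", k, " of ", ts$name, " after ",
               max_retries, " retries: genome too small for the requested ",
               "copy load")
      }
    }
    if (!length(rows)) {
      gr <- GRanges(seqlengths = sizes)
      mcols(gr) <- DataFrame(type = character(0), te_class = character(0),
                             family = character(0), millidiv = numeric(0))
      return(TECatalog(gr))
    }
    gr <- GRanges(vapply(rows, function(r) r[[1]], character(1)),
                  IRanges(vapply(rows, function(r) r[[2]], numeric(1)),
                          vapply(rows, function(r) r[[3]], numeric(1))),
                  strand = vapply(rows, function(r) r[[4]], character(1)),
                  seqlengths = sizes)
    mcols(gr) <- DataFrame(
      type = vapply(rows, function(r) r[[5]], character(1)),
      te_class = vapply(rows, function(r) r[[6]], character(1)),
      family = vapply(rows, function(r) r[[7]], character(1)),
      millidiv = vapply(rows, function(r) r[[8]], numeric(1)))
    TECatalog(sort(gr, ignore.strand = TRUE))
  })
}

#' Generate a synthetic coverage track with planted enrichments
#'
#' Background signal is 1.0 RPKM-equivalent everywhere plus Gaussian noise
#' truncated at 0 (coverage cannot be negative). Each `mark_enrichment`
#' effect multiplies the signal over its target type's copies by the planted
#' magnitude — over the whole copy for `profile_bias = "uniform"`, or only
#' over the 5'-most 500 bp (strand-aware) for `"fiveprime"`.
#'
#' With `noise_sd = 0` the planted magnitude is exactly the per-base mean
#' over the target copies, which makes fold-recovery oracles exact.
#'
#' @param spec A [syntheticGenomeSpec()].
#' @param catalog The [TECatalog-class] generated from `spec` (so effects
#'   land on the same coordinates). If `NULL`, regenerated from `spec`.
#' @param effects List of [plantedEffect()] of kind `mark_enrichment` or
#'   `accessibility_fold`.
#' @param mark Track label; also offsets the noise seed so different marks
#'   get independent noise under one spec seed.
#' @param noise_sd Standard deviation of the background noise (RPKM).
#' @param seed Noise seed; default derives from `spec$seed` and `mark`.
#' @param fiveprime_bp Width of the 5' window used by `"fiveprime"` bias.
#' @return A [CoverageTrack-class].
#' @export
generateCoverageTrack <- function(spec, catalog = NULL, effects = list(),
                                  mark = "mark", noise_sd = 0.25,
                                  seed = NULL, fiveprime_bp = 500L) {
  stopifnot(inherits(spec, "syntheticGenomeSpec"))
  if (is.null(catalog)) catalog <- generateTEAnnotation(spec)
  if (inherits(effects, "plantedEffect")) effects <- list(effects)
  gr <- teCopies(catalog)
  known <- unique(mcols(gr)$type)
  for (ef in effects) {
    stopifnot(inherits(ef, "plantedEffect"))
    if (!ef$target %in% known)
      stop("planted effect targets unknown TE type: ", ef$target)
  }
  if (is.null(seed)) seed <- spec$seed + stringSeedOffset(mark)
  withSeed(seed, {
    sizes <- spec$chrom_sizes
    vecs <- lapply(names(sizes), function(ch) {
      n <- sizes[[ch]]
      if (noise_sd > 0) pmax(0, 1 + rnorm(n, 0, noise_sd)) else rep(1, n)
    })
    names(vecs) <- names(sizes)
    for (ef in effects) {
      hit <- gr[mcols(gr)$type == ef$target]
      for (j in seq_along(hit)) {
        ch <- as.character(seqnames(hit))[j]
        st <- start(hit)[j]; en <- end(hit)[j]
        if (ef$profile_bias == "fiveprime") {
          w <- min(fiveprime_bp, en - st + 1L)
          if (as.character(strand(hit))[j] == "-") st <- en - w + 1L
          else en <- st + w - 1L
        }
        vecs[[ch]][st:en] <- vecs[[ch]][st:en] * ef$magnitude
      }
    }
    CoverageTrack(methods::as(lapply(vecs, Rle), "RleList"), label = mark)
  })
}

#' Generate a negative-binomial count matrix with planted fold-changes
#'
#' Emulates RNA-seq / ATAC count input for differential testing: a
#' control-vs-knockdown design with counts drawn negative-binomial around a
#' baseline mean; `expression_fold` effects multiply the knockdown-group
#' mean of their target feature. Dispersion 0 degrades to Poisson.
#'
#' @param features Character vector of feature ids, or a `data.frame` with
#'   columns `feature` and `kind` (`"gene"` or `"te"`).
#' @param n_reps Replicates per group (>= 1).
#' @param planted List of [plantedEffect()] of kind `expression_fold`.
#' @param nb_dispersion NB dispersion (var = mu + dispersion * mu^2); >= 0.
#' @param seed RNG seed.
#' @param base_mean Baseline group mean count; either a single value or one
#'   per feature. Must be >= 0.
#' @param groups Group labels, control first.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `rowData(x)$kind` and `colData(x)$group`.
#' @export
generateCountMatrix <- function(features, n_reps = 3L, planted = list(),
                                nb_dispersion = 0.1, seed = 1L,
                                base_mean = 100,
                                groups = c("control", "knockdown")) {
  if (is.data.frame(features)) {
    ids <- as.character(features$feature)
    kind <- as.character(features$kind)
  } else {
    ids <- as.character(features)
    kind <- rep("gene", length(ids))
  }
  stopifnot(n_reps >= 1, nb_dispersion >= 0, length(groups) == 2L,
            !anyDuplicated(ids))
  if (any(base_mean < 0)) stop("negative mean is not allowed")
  if (inherits(planted, "plantedEffect")) planted <- list(planted)
  mu <- matrix(rep(base_mean, length.out = length(ids)),
               nrow = length(ids), ncol = 2L,
               dimnames = list(ids, groups))
  for (ef in planted) {
    stopifnot(inherits(ef, "plantedEffect"))
    if (!ef$target %in% ids)
      stop("planted effect targets unknown feature: ", ef$target)
    mu[ef$target, 2L] <- mu[ef$target, 2L] * ef$magnitude
  }
  withSeed(seed, {
    cols <- paste(rep(groups, each = n_reps), rep(seq_len(n_reps), 2L),
                  sep = "_")
    counts <- matrix(0L, nrow = length(ids), ncol = 2L * n_reps,
                     dimnames = list(ids, cols))
    for (g in 1:2) for (r in seq_len(n_reps)) {
      j <- (g - 1L) * n_reps + r
      counts[, j] <- if (nb_dispersion == 0) rpois(length(ids), mu[, g])
                     else rnbinom(length(ids), mu = mu[, g],
                                  size = 1 / nb_dispersion)
    }
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      rowData = DataFrame(kind = kind, row.names = ids),
      colData = DataFrame(group = factor(rep(groups, each = n_reps),
                                         levels = groups),
                          row.names = cols),
      metadata = list(normalization = "raw",
                      planted = planted, nb_dispersion = nb_dispersion))
  })
}

#' Generate a 2C-vs-ESC expression table with a planted top set
#'
#' Emulates the reference two-condition expression table from which the
#' 2C-like signature is built. Exactly `n_top` genes carry the highest
#' fold-changes (around `fold_top`), all other genes' folds stay below 2, so
#' sorting fold-changes recovers the planted set exactly. Ties at the
#' top-set boundary are broken deterministically by gene id.
#'
#' @param n_genes Total genes.
#' @param n_top Planted top-upregulated genes (<= `n_genes`).
#' @param fold_top Planted linear fold of the top set (> 2).
#' @param seed RNG seed.
#' @return A list with `expr` (`data.frame`: gene, ESC, C2) and `truth`
#'   (character vector of the planted gene ids).
#' @export
generateSignatureDataset <- function(n_genes = 500L, n_top = 200L,
                                     fold_top = 10, seed = 1L) {
  stopifnot(n_top <= n_genes, n_top >= 0, fold_top > 2)
  withSeed(seed, {
    gene <- sprintf("gene_%04d", seq_len(n_genes))
    esc <- rlnorm(n_genes, meanlog = 4, sdlog = 1)
    fold <- runif(n_genes, 0.5, 1.9)
    top <- sort(sample(gene, n_top))
    i <- match(top, gene)
    fold[i] <- fold_top * runif(n_top, 0.9, 1.1)
    expr <- data.frame(gene = gene, ESC = esc, C2 = esc * fold,
                       stringsAsFactors = FALSE)
    list(expr = expr, truth = top)
  })
}

#' Generate a toy gene annotation anchored to TE copies
#'
#' Fixed-length genes on both strands: for each copy of the anchor TE types
#' a gene is placed within `window` bp (alternately upstream/downstream,
#' alternately same/opposite strand), plus unanchored background genes far
#' from any anchor. Exercises MERVL-proximity annotation with known truth.
#'
#' @param catalog A [TECatalog-class].
#' @param anchor_types TE types to place genes next to.
#' @param window Max gap (bp) between gene body and anchor copy.
#' @param gene_length Gene body length (bp).
#' @param n_background Unanchored genes to add.
#' @param seed RNG seed.
#' @return A `GRanges` of genes with `gene_id` and a `truth_orientation`
#'   metadata column (`same_ori`/`opposite_ori`/`none`).
#' @export
generateGeneAnnotation <- function(catalog,
                                   anchor_types = c("MERVL-int", "MT2_Mm"),
                                   window = 10000L, gene_length = 2000L,
                                   n_background = 20L, seed = 1L) {
  gr <- teCopies(catalog)
  sizes <- seqlengths(gr)
  anchors <- gr[mcols(gr)$type %in% anchor_types]
  withSeed(seed, {
    rows <- list()
    for (j in seq_along(anchors)) {
      ch <- as.character(seqnames(anchors))[j]
      up <- j %% 2L == 0L
      same <- (j %% 4L) < 2L
      gap <- sample.int(window - gene_length - 1L, 1L)
      if (up) {
        en <- start(anchors)[j] - gap; st <- en - gene_length + 1L
      } else {
        st <- end(anchors)[j] + gap; en <- st + gene_length - 1L
      }
      if (st < 1L || en > sizes[[ch]]) next
      a_std <- as.character(strand(anchors))[j]
      g_std <- if (same) a_std else setdiff(c("+", "-"), a_std)
      rows[[length(rows) + 1L]] <- list(ch, st, en, g_std,
                                        if (same) "same_ori" else "opposite_ori")
    }
    # background genes: rejection-sample far (> window) from every anchor
    for (k in seq_len(n_background)) {
      for (try in 1:200) {
        ch <- sample(names(sizes), 1L, prob = sizes)
        st <- sample.int(sizes[[ch]] - gene_length, 1L)
        cand <- GRanges(ch, IRanges(st, st + gene_length - 1L))
        d <- suppressWarnings(distance(rep(cand, length(anchors)), anchors))
        if (!length(anchors) || all(is.na(d) | d > window)) {
          rows[[length(rows) + 1L]] <-
            list(ch, st, st + gene_length - 1L,
                 sample(c("+", "-"), 1L), "none")
          break
        }
      }
    }
    genes <- GRanges(vapply(rows, `[[`, character(1), 1),
                     IRanges(vapply(rows, `[[`, numeric(1), 2),
                             vapply(rows, `[[`, numeric(1), 3)),
                     strand = vapply(rows, `[[`, character(1), 4),
                     seqlengths = sizes)
    mcols(genes)$gene_id <- sprintf("toygene_%03d", seq_along(genes))
    mcols(genes)$truth_orientation <- vapply(rows, `[[`, character(1), 5)
    genes
  })
}

#' Write a self-contained synthetic fixture bundle
#'
#' Emits everything the pipeline readers consume: `chrom.sizes`, a UCSC
#' rmsk-style TE table, BED, a toy gene GTF, one bedGraph per mark, count
#' tables, the 2C expression table, a ground-truth JSON and a manifest with
#' md5 checksums. Identical `(spec, effects, seed)` give byte-identical
#' files.
#'
#' @param spec A [syntheticGenomeSpec()].
#' @param mark_effects Named list: one entry per mark, each a list of
#'   [plantedEffect()]s planted on that mark's coverage track.
#' @param expression_effects List of [plantedEffect()]s of kind
#'   `expression_fold` (targets may be TE types or toy gene ids).
#' @param outdir Output directory (created if missing).
#' @param noise_sd Coverage noise SD.
#' @param n_reps,nb_dispersion Count-matrix design.
#' @param signature Arguments for [generateSignatureDataset()] as a list,
#'   or `NULL` to skip.
#' @return Invisibly, a list with the catalog, genes, track file paths and
#'   the manifest `data.frame`.
#' @export
writeFixtureBundle <- function(spec, mark_effects = list(),
                               expression_effects = list(),
                               outdir, noise_sd = 0.25, n_reps = 3L,
                               nb_dispersion = 0.1,
                               signature = list(n_genes = 500L, n_top = 200L,
                                                fold_top = 10)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  catalog <- generateTEAnnotation(spec)
  paths <- character(0)

  p <- file.path(outdir, "chrom.sizes")
  writeChromSizes(spec$chrom_sizes, p); paths <- c(paths, p)

  p <- file.path(outdir, "te_rmsk.tsv")
  writeCatalogRmsk(catalog, p); paths <- c(paths, p)
  p <- file.path(outdir, "te.bed")
  writeCatalogBED(catalog, p); paths <- c(paths, p)

  genes <- generateGeneAnnotation(catalog, seed = spec$seed)
  p <- file.path(outdir, "genes.gtf")
  writeToyGTF(genes, p); paths <- c(paths, p)

  for (mk in names(mark_effects)) {
    tr <- generateCoverageTrack(spec, catalog, mark_effects[[mk]],
                                mark = mk, noise_sd = noise_sd)
    p <- file.path(outdir, paste0("track_", gsub("[^A-Za-z0-9._-]", "_", mk),
                                  ".bedGraph"))
    writeTrackBedGraph(tr, p); paths <- c(paths, p)
  }

  feats <- data.frame(
    feature = c(mcols(genes)$gene_id, teTypeNames(catalog)),
    kind = c(rep("gene", length(genes)),
             rep("te", length(teTypeNames(catalog)))),
    stringsAsFactors = FALSE)
  se <- generateCountMatrix(feats, n_reps = n_reps,
                            planted = expression_effects,
                            nb_dispersion = nb_dispersion, seed = spec$seed)
  p <- file.path(outdir, "counts.tsv")
  cnt <- data.frame(feature = rownames(se),
                    kind = SummarizedExperiment::rowData(se)$kind,
                    as.data.frame(SummarizedExperiment::assay(se, "counts")),
                    check.names = FALSE)
  write.table(cnt, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  sig_truth <- NULL
  if (!is.null(signature)) {
    sig <- do.call(generateSignatureDataset,
                   c(signature, list(seed = spec$seed)))
    p <- file.path(outdir, "expr_2c_esc.tsv")
    write.table(sig$expr, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    sig_truth <- sig$truth
  }

  truth <- list(
    seed = spec$seed,
    n_copies_per_type = as.list(table(mcols(teCopies(catalog))$type)),
    mark_effects = lapply(mark_effects, function(efs)
      lapply(efs, function(e) e[c("target", "kind", "magnitude",
                                  "profile_bias")])),
    expression_effects = lapply(expression_effects, function(e)
      e[c("target", "kind", "magnitude")]),
    signature_top = sig_truth,
    gene_orientation = setNames(as.list(mcols(genes)$truth_orientation),
                                mcols(genes)$gene_id))
  p <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(truth, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, p)

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(outdir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(catalog = catalog, genes = genes, paths = paths,
                 manifest = manifest, truth = truth))
}
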