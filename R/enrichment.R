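# The core statistic: each TE type is treated as a metagene. Copies are cut
# into consecutive 500-bp bins anchored at their 5' end (strand-aware), the
# per-bin mean over copies gives the metagene profile, and the maximum bin
# is the observed signal. The expected signal is the same statistic on one
# size-matched random region per copy. Enrichment is
# log2((obs + pc) / (exp + pc)).

# internal: oriented per-base numeric vector for one range
orientedBases <- function(covchr, st, en, neg) {
  v <- as.numeric(window(covchr, st, en))
  if (neg) rev(v) else v
}

# internal: bin one oriented per-base vector into consecutive bins of
# bin_bp; the final partial bin keeps its per-base mean. A vector shorter
# than one bin contributes a single bin.
binBases <- function(v, bin_bp) {
  n <- length(v)
  nb <- max(1L, ceiling(n / bin_bp))
  idx <- rep(seq_len(nb), each = bin_bp, length.out = n)
  as.numeric(tapply(v, idx, mean))
}

#' Metagene bin profile of one TE type
#'
#' Each copy of the type is partitioned into consecutive `bin_bp` bins
#' anchored at its 5' end (bin 1 is the 5'-most bin; minus-strand copies
#' are read right-to-left), the last partial bin keeping its per-base mean.
#' The metagene value of bin *k* is the mean over all copies that have a
#' bin *k*; copies shorter than one bin contribute a single bin.
#'
#' @param track A [CoverageTrack-class].
#' @param copies `GRanges` of the type's copies (or a [TECatalog-class]
#'   plus `type`).
#' @param type TE type name when `copies` is a catalog.
#' @param bin_bp Bin width in bp (default 500).
#' @return Numeric vector of metagene bin values (length = max bin count
#'   over copies).
#' @export
binTEType <- function(track, copies, type = NULL, bin_bp = 500L) {
  if (is(copies, "TECatalog")) {
    stopifnot(!is.null(type))
    gr <- teCopies(copies)
    copies <- gr[mcols(gr)$type == type]
  }
  if (!length(copies)) stop("no copies to bin")
  cov <- trackCoverage(track)
  chroms <- as.character(seqnames(copies))
  neg <- as.character(strand(copies)) == "-"
  per_copy <- lapply(seq_along(copies), function(i)
    binBases(orientedBases(cov[[chroms[i]]], start(copies)[i],
                           end(copies)[i], neg[i]), bin_bp))
  nb <- max(lengths(per_copy))
  vapply(seq_len(nb), function(k) {
    vals <- unlist(lapply(per_copy, function(b) if (length(b) >= k) b[k]))
    mean(vals)
  }, numeric(1))
}

#' Draw size-matched random background regions
#'
#' One random region per copy, with exactly the copy's length, placed
#' uniformly over the genome (chromosome chosen proportional to its length
#' among chromosomes long enough); deterministic for a fixed seed. An
#' optional exclusion set (e.g. assembly gaps) is honoured by rejection.
#'
#' @param copies `GRanges` of the copies to match.
#' @param chrom_sizes Named chromosome lengths (or chrom.sizes path).
#' @param seed RNG seed.
#' @param exclude Optional `GRanges` the background must not overlap.
#' @param max_retries Rejection-sampling attempts per region.
#' @return Unstranded `GRanges`, same multiset of widths as `copies`.
#' @export
sampleBackgroundRegions <- function(copies, chrom_sizes, seed = 1L,
                                    exclude = NULL, max_retries = 1000L) {
  sizes <- readChromSizes(chrom_sizes)
  if (length(copies) && max(width(copies)) > max(sizes))
    stop("no chromosome is long enough for the longest copy")
  withSeed(seed, {
    chs <- character(length(copies)); sts <- integer(length(copies))
    for (i in seq_along(copies)) {
      len <- width(copies)[i]
      ok <- names(sizes)[sizes >= len]
      done <- FALSE
      for (try in seq_len(max_retries)) {
        ch <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = sizes[ok])
        st <- sample.int(sizes[[ch]] - len + 1L, 1L)
        if (!is.null(exclude)) {
          cand <- GRanges(ch, IRanges(st, st + len - 1L))
          if (any(countOverlaps(cand, exclude) > 0L)) next
        }
        chs[i] <- ch; sts[i] <- st; done <- TRUE
        break
      }
      if (!done) stop("could not place background region ", i,
                      " after ", max_retries, " retries")
    }
    GRanges(chs, IRanges(sts, width = width(copies)), seqlengths = sizes)
  })
}

#' Compute the mark x TE-type enrichment matrix
#'
#' For every track and every TE type: observed = maximum bin of the type's
#' metagene profile ([binTEType()]); expected = the same statistic over one
#' size-matched random region per copy ([sampleBackgroundRegions()]).
#' Background regions are drawn once per (type, seed) and shared across all
#' tracks of the run, so marks are compared against the same null.
#'
#' A cell with zero observed and zero expected signal is defined as fold 1
#' (log2 fold 0) by the pseudocount and flagged low-information in the
#' result's `lowinfo` attribute.
#'
#' @param tracks A [CoverageTrack-class] or list of them (named by label).
#' @param catalog A filtered [TECatalog-class].
#' @param bin_bp Bin width (default 500 bp).
#' @param pseudocount RPKM pseudocount on both components (default 0.01).
#' @param seed Background-sampling seed.
#' @param exclude Exclusion set for the background: `"self"` (default)
#'   rejects background regions overlapping any catalog copy — on a small
#'   genome, where TEs occupy a visible fraction, an unconstrained
#'   background would re-sample the TE signal itself; pass a `GRanges`
#'   (e.g. assembly gaps) for a custom set or `NULL` for the fully
#'   unconstrained uniform background.
#' @return An [EnrichmentMatrix-class] (rows = tracks, cols = TE types).
#' @export
computeTEEnrichment <- function(tracks, catalog, bin_bp = 500L,
                                pseudocount = 0.01, seed = 1L,
                                exclude = "self") {
  if (is(tracks, "CoverageTrack")) tracks <- list(tracks)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- vapply(tracks, trackLabel, character(1))
  gr <- teCopies(catalog)
  sizes <- seqlengths(gr)
  types <- teTypeNames(catalog)
  if (!length(types)) stop("catalog has no TE types")
  if (identical(exclude, "self")) {
    exclude <- gr
    strand(exclude) <- "*"
  }
  bg <- lapply(seq_along(types), function(k) {
    cp <- gr[mcols(gr)$type == types[k]]
    sampleBackgroundRegions(cp, sizes, seed = seed + k, exclude = exclude)
  })
  names(bg) <- types
  obs <- exp_ <- matrix(NA_real_, nrow = length(tracks), ncol = length(types),
                        dimnames = list(names(tracks), types))
  for (m in seq_along(tracks)) {
    tr <- tracks[[m]]
    for (k in seq_along(types)) {
      cp <- gr[mcols(gr)$type == types[k]]
      obs[m, k] <- max(binTEType(tr, cp, bin_bp = bin_bp))
      exp_[m, k] <- max(binTEType(tr, bg[[k]], bin_bp = bin_bp))
    }
  }
  em <- EnrichmentMatrix(obs, exp_, pseudocount = pseudocount,
                         seed = as.integer(seed), bin_bp = bin_bp)
  low <- which(obs == 0 & exp_ == 0, arr.ind = TRUE)
  attr(em, "lowinfo") <- low
  em
}

#' Call enriched marks from an enrichment matrix
#'
#' A mark is called enriched at a TE type when its linear fold-enrichment
#' is strictly greater than the threshold (default 2; a fold of exactly 2
#' is not enriched). Tallies report, per TE type, how many marks are
#' enriched, and per mark, how many TE types — the quantities behind
#' "marked by 2 or more chromatin marks" style summaries.
#'
#' @param em An [EnrichmentMatrix-class].
#' @param threshold Linear fold threshold (default 2; use 1.5 for the
#'   relaxed call).
#' @param comparator `">"` (strict, default) or `">="`.
#' @return List: `calls` (logical marks x types matrix), `per_mark`
#'   (enriched types per mark), `per_type` (enriched marks per type),
#'   `threshold`.
#' @export
callEnrichedMarks <- function(em, threshold = 2.0, comparator = c(">", ">=")) {
  comparator <- match.arg(comparator)
  f <- foldEnrichment(em)
  calls <- if (comparator == ">") f > threshold else f >= threshold
  list(calls = calls,
       per_mark = rowSums(calls),
       per_type = colSums(calls),
       threshold = threshold, comparator = comparator)
}

#' Partition TE types into High and Low sets for one mark
#'
#' High = TE types with fold-enrichment strictly above `threshold` for the
#' mark. Low = ranking all TE types by fold-enrichment and taking types
#' from the bottom of the list until it has the same length as High. The
#' two sets are disjoint by construction; if High holds more than half of
#' the types the bottom-of-list rule cannot produce a disjoint Low set and
#' an error is raised.
#'
#' @param em An [EnrichmentMatrix-class].
#' @param mark Row name of the mark.
#' @param threshold Fold threshold (default 2, strict `>`).
#' @return List with character vectors `high` and `low`.
#' @export
partitionHighLow <- function(em, mark, threshold = 2.0) {
  f <- foldEnrichment(em)
  if (!mark %in% rownames(f)) stop("unknown mark: ", mark)
  v <- f[mark, ]
  high <- names(v)[v > threshold]
  if (length(high) > length(v) / 2)
    stop("High set holds more than half of the TE types; ",
         "a disjoint size-matched Low set cannot be formed")
  ord <- names(v)[order(v, names(v))]      # ascending; ties by name
  low <- head(ord, length(high))
  list(high = sort(high), low = sort(low))
}

#' Hierarchically cluster an enrichment matrix
#'
#' Average-linkage clustering under a 1 - Pearson-correlation distance on
#' the log2 fold matrix, over marks or TE types. A constant row has no
#' defined correlation; its distance to everything is defined as 1.
#'
#' @param em An [EnrichmentMatrix-class] (or a plain numeric matrix).
#' @param axis `"marks"` (rows) or `"te_types"` (columns).
#' @param linkage `hclust` method (default `"average"`).
#' @return List: `hclust`, `order` (leaf labels in dendrogram order), and
#'   `dist` (the distance matrix used).
#' @export
clusterEnrichmentMatrix <- function(em, axis = c("marks", "te_types"),
                                    linkage = "average") {
  axis <- match.arg(axis)
  m <- if (is(em, "EnrichmentMatrix")) log2Fold(em) else em
  if (axis == "te_types") m <- t(m)
  if (nrow(m) < 2L) stop("need at least 2 items on the chosen axis")
  cc <- suppressWarnings(cor(t(m)))
  d <- 1 - cc
  d[is.na(d)] <- 1          # constant rows: correlation undefined
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = linkage)
  list(hclust = hc, order = rownames(m)[hc$order], dist = as.dist(d))
}

#' Correlate TE age with enrichment, per mark
#'
#' Spearman rank correlation (ties mid-ranked) between per-type age and
#' per-type log2 fold-enrichment, for each mark. Types without a defined
#' age are dropped; a mark with constant enrichment or fewer than 3 usable
#' types is flagged with `NA`.
#'
#' @param em An [EnrichmentMatrix-class].
#' @param ages Named per-type ages (years), e.g. from [estimateTEAge()]
#'   (a `data.frame` with `type` and `age_years` is accepted).
#' @return `data.frame`: `mark`, `n`, `rho`, `p`.
#' @export
correlateAgeEnrichment <- function(em, ages) {
  if (is.data.frame(ages)) ages <- setNames(ages$age_years, ages$type)
  lf <- log2Fold(em)
  common <- intersect(colnames(lf), names(ages)[!is.na(ages)])
  out <- do.call(rbind, lapply(rownames(lf), function(mk) {
    x <- ages[common]; y <- lf[mk, common]
    if (length(common) < 3L || sd(y) == 0 || sd(x) == 0) {
      if (length(common) >= 3L)
        warning("constant vector for mark ", mk, "; rho undefined")
      return(data.frame(mark = mk, n = length(common),
                        rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    data.frame(mark = mk, n = length(common),
               rho = unname(ct$estimate), p = ct$p.value)
  }))
  rownames(out) <- NULL
  out
}

#' Scaled metagene pileup with flanks
#'
#' For figure-style pileups: every copy's body is rescaled to `n_body_bins`
#' equal fractions and the flanking `flank_bp` regions are binned at fixed
#' width, all strand-aware (upstream flank first), then averaged across
#' copies. Used for inspection only — the enrichment statistic uses the
#' fixed-width body bins of [binTEType()], never the flanks.
#'
#' @param track A [CoverageTrack-class].
#' @param copies `GRanges` of copies (or catalog + `type`).
#' @param type TE type name when `copies` is a catalog.
#' @param flank_bp Flank width (default 5000 bp, the figure convention).
#' @param n_body_bins Scaled body bins (default 100).
#' @param flank_bin_bp Fixed flank bin width (default 250).
#' @return Numeric vector: upstream flank bins, body bins, downstream
#'   flank bins; names mark the segments.
#' @export
computeMetageneProfile <- function(track, copies, type = NULL,
                                   flank_bp = 5000L, n_body_bins = 100L,
                                   flank_bin_bp = 250L) {
  stopifnot(n_body_bins >= 1)
  if (is(copies, "TECatalog")) {
    stopifnot(!is.null(type))
    gr <- teCopies(copies)
    copies <- gr[mcols(gr)$type == type]
  }
  if (!length(copies)) stop("no copies")
  cov <- trackCoverage(track)
  sizes <- setNames(vapply(cov, length, numeric(1)), names(cov))
  nfb <- as.integer(ceiling(flank_bp / flank_bin_bp))
  scale_body <- function(v) {
    L <- length(v)
    br <- floor(seq_len(n_body_bins) * L / n_body_bins)
    st <- c(0L, head(br, -1L)) + 1L
    vapply(seq_len(n_body_bins), function(j)
      if (st[j] > br[j]) NA_real_ else mean(v[st[j]:br[j]]), numeric(1))
  }
  bin_flank <- function(v) {
    if (!length(v)) return(rep(NA_real_, nfb))
    out <- binBases(v, flank_bin_bp)
    # right-align partial flanks (clipped at a chromosome edge)
    c(rep(NA_real_, nfb - length(out)), out)
  }
  prof <- matrix(NA_real_, nrow = length(copies),
                 ncol = nfb + n_body_bins + nfb)
  for (i in seq_along(copies)) {
    ch <- as.character(seqnames(copies))[i]
    st <- start(copies)[i]; en <- end(copies)[i]
    neg <- as.character(strand(copies))[i] == "-"
    body <- orientedBases(cov[[ch]], st, en, neg)
    upL <- max(1L, st - flank_bp); upR <- st - 1L
    dnL <- en + 1L; dnR <- min(sizes[[ch]], en + flank_bp)
    up <- if (upR >= upL) as.numeric(window(cov[[ch]], upL, upR)) else numeric(0)
    dn <- if (dnR >= dnL) as.numeric(window(cov[[ch]], dnL, dnR)) else numeric(0)
    if (neg) { tmp <- rev(dn); dn <- rev(up); up <- tmp }
    prof[i, ] <- c(bin_flank(up), scale_body(body), rev(bin_flank(rev(dn))))
  }
  out <- colMeans(prof, na.rm = TRUE)
  names(out) <- c(paste0("up_", seq_len(nfb)),
                  paste0("body_", seq_len(n_body_bins)),
                  paste0("down_", seq_len(nfb)))
  out
}

#' Replicate quality control by per-TE correlation
#'
#' Replicate tracks are compared as per-copy RPKM vectors over all TEs of
#' the catalog; pairs with Pearson r strictly above `min_r` are considered
#' concordant. Tracks concordant with at least one other track are kept and
#' merged by the per-base mean (preserving the RPKM scale); discordant
#' tracks are dropped. If every track is mutually discordant the track with
#' the highest mean coverage is kept alone, with a warning. A single input
#' track is kept as-is.
#'
#' @param tracks List of [CoverageTrack-class] replicates.
#' @param catalog A [TECatalog-class].
#' @param min_r Pearson threshold (default 0.6, strict `>`).
#' @return List: `kept`, `dropped` (labels), `merged`
#'   ([CoverageTrack-class]), `cor` (correlation matrix).
#' @export
qcReplicates <- function(tracks, catalog, min_r = 0.6) {
  stopifnot(length(tracks) >= 1L)
  labs <- vapply(tracks, trackLabel, character(1))
  if (anyDuplicated(labs)) labs <- make.unique(labs)
  gr <- teCopies(catalog)
  vecs <- lapply(tracks, trackMeans, gr = gr)
  n <- length(tracks)
  cc <- diag(1, n); dimnames(cc) <- list(labs, labs)
  if (n > 1L) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- suppressWarnings(cor(vecs[[i]], vecs[[j]]))
    cc[i, j] <- cc[j, i] <- r
  }
  keep <- if (n == 1L) TRUE else
    vapply(seq_len(n), function(i)
      any(cc[i, -i] > min_r, na.rm = TRUE), logical(1))
  if (!any(keep)) {
    mu <- vapply(tracks, function(t)
      mean(vapply(trackCoverage(t), mean, numeric(1))), numeric(1))
    keep <- seq_len(n) == which.max(mu)
    warning("all replicates mutually discordant (r <= ", min_r,
            "); keeping highest-coverage track '", labs[keep], "'")
  }
  kept_tracks <- tracks[keep]
  merged_cov <- trackCoverage(kept_tracks[[1L]])
  if (length(kept_tracks) > 1L) {
    for (t in kept_tracks[-1L]) {
      add <- trackCoverage(t)
      merged_cov <- methods::as(
        lapply(names(merged_cov), function(ch) merged_cov[[ch]] + add[[ch]]),
        "RleList")
      names(merged_cov) <- names(trackCoverage(kept_tracks[[1L]]))
    }
    merged_cov <- merged_cov / length(kept_tracks)
  }
  list(kept = labs[keep], dropped = labs[!keep],
       merged = CoverageTrack(merged_cov,
                              label = paste0(labs[which(keep)[1L]], "_merged")),
       cor = cc)
}
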