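# ATAC-seq stage: aggregate TE-type accessibility per sample, the 20%
# opened/closed rule against the control, peak-to-gene linkage within
# 10 kb, and the Fisher test for chromatin-mark enrichment among opened
# TE types.

#' Quantify TE-type accessibility per sample
#'
#' Per TE type and sample, the length-weighted mean per-base RPKM over all
#' copies of the type (total signal over total length, i.e. the aggregate
#' accessibility of the type, not the max-bin peak statistic).
#'
#' @param tracks Named list of [CoverageTrack-class], one per sample
#'   (RPKM-normalised, QC'd).
#' @param catalog A [TECatalog-class].
#' @return Numeric matrix, TE types x samples. Zero-coverage samples are
#'   flagged with a warning.
#' @export
quantifyTEAccessibility <- function(tracks, catalog) {
  if (is(tracks, "CoverageTrack")) tracks <- list(tracks)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- vapply(tracks, trackLabel, character(1))
  gr <- teCopies(catalog)
  types <- teTypeNames(catalog)
  out <- matrix(NA_real_, nrow = length(types), ncol = length(tracks),
                dimnames = list(types, names(tracks)))
  for (s in seq_along(tracks)) {
    mu <- trackMeans(tracks[[s]], gr)
    w <- width(gr)
    tot <- tapply(mu * w, mcols(gr)$type, sum)
    len <- tapply(w, mcols(gr)$type, sum)
    out[, s] <- (tot / len)[types]
  }
  zero <- colSums(out) == 0
  if (any(zero))
    warning("zero-coverage sample(s): ",
            paste(colnames(out)[zero], collapse = ", "))
  out
}

#' Call accessibility changes against a control sample
#'
#' The 20% rule: a TE type is `opened` in a knockdown when its aggregate
#' accessibility is at least 20% higher than in the control (fold >= `up`,
#' default 1.2), `closed` when at least 20% lower (fold <= `down`, default
#' 0.8), else `unchanged`. A pseudocount is applied to both sides before
#' the ratio so folds stay finite and positive.
#'
#' @param table TE types x samples matrix from [quantifyTEAccessibility()].
#' @param control Name of the control column.
#' @param up,down Fold bounds of the rule (defaults 1.2 / 0.8, inclusive).
#' @param pseudocount Added to both sides before the ratio (default 0.01).
#' @return List: `fold` (types x non-control samples), `state` (character
#'   matrix, same shape, in `opened`/`closed`/`unchanged`).
#' @export
callAccessibilityChanges <- function(table, control, up = 1.2, down = 0.8,
                                     pseudocount = 0.01) {
  stopifnot(control %in% colnames(table), up > down)
  samples <- setdiff(colnames(table), control)
  ctrl <- table[, control] + pseudocount
  fold <- sweep(table[, samples, drop = FALSE] + pseudocount, 1L, ctrl, "/")
  state <- matrix("unchanged", nrow = nrow(fold), ncol = ncol(fold),
                  dimnames = dimnames(fold))
  state[fold >= up] <- "opened"
  state[fold <= down] <- "closed"
  list(fold = fold, state = state)
}

#' Unique vs shared opened TE types across knockdowns
#'
#' @param state State matrix from [callAccessibilityChanges()] (TE types x
#'   knockdowns), or a named list of per-knockdown opened-type character
#'   vectors.
#' @return List: `opened_by` (named list), `unique_tes`, `shared_tes`,
#'   `n_unique`, `n_shared`. With a single knockdown the shared count is 0
#'   by definition.
#' @export
summarizeOpenedTEs <- function(state) {
  opened_by <- if (is.list(state)) state else
    apply(state == "opened", 2L, function(z) rownames(state)[z],
          simplify = FALSE)
  all_opened <- unlist(opened_by)
  mult <- table(all_opened)
  uniq <- sort(names(mult)[mult == 1L])
  shared <- sort(names(mult)[mult >= 2L])
  list(opened_by = opened_by, unique_tes = uniq, shared_tes = shared,
       n_unique = length(uniq), n_shared = length(shared))
}

#' Link ATAC peaks to nearby genes
#'
#' A peak links to every gene whose gene body lies within `window` bp of
#' it (gap distance; overlap counts as distance 0; the boundary is
#' inclusive).
#'
#' @param peaks `GRanges` of peaks (BED/narrowPeak import).
#' @param genes `GRanges` of gene bodies with a `gene_id` column.
#' @param window Max gap in bp (default 10000).
#' @return `data.frame`: `peak` (index or name), `gene_id`, `distance`.
#' @export
linkPeaksToGenes <- function(peaks, genes, window = 10000L) {
  hits <- findOverlaps(peaks, genes, maxgap = window, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(peak = character(0), gene_id = character(0),
                      distance = integer(0)))
  d <- distance(peaks[S4Vectors::queryHits(hits)],
                genes[S4Vectors::subjectHits(hits)], ignore.strand = TRUE)
  keep <- !is.na(d) & d <= window
  pk <- if (!is.null(names(peaks))) names(peaks) else
    paste0("peak_", seq_along(peaks))
  out <- data.frame(peak = pk[S4Vectors::queryHits(hits)[keep]],
                    gene_id = mcols(genes)$gene_id[
                      S4Vectors::subjectHits(hits)[keep]],
                    distance = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$peak, out$distance, out$gene_id), , drop = FALSE]
}

#' Chromatin-mark enrichment among opened TE types (Fisher exact)
#'
#' For each knockdown and each chromatin mark, a 2x2 table over the shared
#' TE universe — opened vs not, mark-enriched vs not — is tested with a
#' two-sided Fisher exact test (point-probability method). Significant iff
#' P < `alpha` (default 0.01). A table with an empty margin has no defined
#' P; it is reported as `NA`.
#'
#' @param state State matrix from [callAccessibilityChanges()].
#' @param calls Logical marks x TE-types matrix from
#'   [callEnrichedMarks()]`$calls`.
#' @param alpha Significance level (default 0.01).
#' @return `data.frame`: `knockdown`, `mark`, `n_opened`, `n_enriched`,
#'   `odds_ratio`, `p`, `significant`.
#' @export
testMarkEnrichmentOfOpened <- function(state, calls, alpha = 0.01) {
  universe <- intersect(rownames(state), colnames(calls))
  if (!length(universe)) stop("no shared TE types between inputs")
  out <- list()
  for (kd in colnames(state)) {
    opened <- state[universe, kd] == "opened"
    for (mk in rownames(calls)) {
      enr <- calls[mk, universe]
      tab <- table(factor(opened, levels = c(TRUE, FALSE)),
                   factor(enr, levels = c(TRUE, FALSE)))
      if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
        p <- NA_real_; or <- NA_real_
      } else {
        ft <- fisher.test(tab, alternative = "two.sided")
        p <- ft$p.value; or <- unname(ft$estimate)
      }
      out[[length(out) + 1L]] <- data.frame(
        knockdown = kd, mark = mk,
        n_opened = sum(opened), n_enriched = sum(enr),
        odds_ratio = or, p = p,
        significant = !is.na(p) & p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
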