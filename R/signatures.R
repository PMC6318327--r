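# 2C-like program analysis. Mouse embryonic stem cell cultures harbour a
# rare 2C-like subpopulation resembling the totipotent two-cell embryo,
# marked by MERVL/MT2_Mm expression and 2C genes such as Zscan4. The
# signature is the top-200 genes by 2C-vs-ESC fold-change; knockdowns are
# scored by how that gene set shifts relative to control.

#' Build a gene signature from a two-condition reference table
#'
#' Fold-changes (with pseudocount) of the test condition over the
#' reference; the signature is the top `n` genes by descending fold among
#' upregulated genes (fold > 1), ties broken deterministically by gene id.
#' If fewer than `n` genes are upregulated, all of them are returned with
#' a warning.
#'
#' @param expr `data.frame` with a gene-id column and two condition
#'   columns.
#' @param test,reference Column names of the contrast (e.g. 2C vs ESC).
#' @param gene_col Gene-id column name (default `"gene"`).
#' @param n Signature size (default 200).
#' @param pseudocount Added to both conditions (default 1).
#' @return `data.frame` (`gene`, `fold`) sorted by descending fold, class
#'   `geneSignature`.
#' @export
buildSignature <- function(expr, test = "C2", reference = "ESC",
                           gene_col = "gene", n = 200L, pseudocount = 1) {
  stopifnot(all(c(gene_col, test, reference) %in% colnames(expr)))
  fold <- (expr[[test]] + pseudocount) / (expr[[reference]] + pseudocount)
  df <- data.frame(gene = as.character(expr[[gene_col]]), fold = fold,
                   stringsAsFactors = FALSE)
  df <- df[df$fold > 1, , drop = FALSE]
  df <- df[order(-df$fold, df$gene), , drop = FALSE]
  if (nrow(df) < n)
    warning("only ", nrow(df), " upregulated gene(s) available for a ",
            n, "-gene signature")
  out <- head(df, n)
  rownames(out) <- NULL
  class(out) <- c("geneSignature", "data.frame")
  out
}

#' Score a knockdown against a gene signature
#'
#' Per-gene log2 fold-changes of knockdown over control (pseudocount 1)
#' are split into signature genes and background genes; the score is the
#' median (and mean) log2 fold of the signature genes, with a one-sided
#' Mann-Whitney U test of signature > background. Warns when the
#' expression table covers less than half of the signature. For the fully
#' degenerate null (knockdown identical to control, every fold tied at 0)
#' the exact one-sided p is 1: every permutation yields the same U.
#'
#' @param sig A signature from [buildSignature()] (or a character vector
#'   of gene ids).
#' @param expr `data.frame` with gene ids and the two sample columns.
#' @param knockdown,control Column names to contrast.
#' @param gene_col Gene-id column (default `"gene"`).
#' @param pseudocount Added to both samples (default 1).
#' @return List: `median_log2fc`, `mean_log2fc`, `p` (one-sided
#'   Mann-Whitney), `n_signature`, `n_background`, `coverage`.
#' @export
scoreSignature <- function(sig, expr, knockdown, control,
                           gene_col = "gene", pseudocount = 1) {
  genes <- if (is.character(sig)) sig else sig$gene
  stopifnot(all(c(gene_col, knockdown, control) %in% colnames(expr)))
  ids <- as.character(expr[[gene_col]])
  in_sig <- ids %in% genes
  coverage <- sum(genes %in% ids) / length(genes)
  if (coverage == 0) stop("no signature gene present in the table")
  if (coverage < 0.5)
    warning("expression table covers only ", round(100 * coverage),
            "% of the signature")
  lfc <- log2((expr[[knockdown]] + pseudocount) /
                (expr[[control]] + pseudocount))
  p <- suppressWarnings(
    wilcox.test(lfc[in_sig], lfc[!in_sig], alternative = "greater",
                exact = FALSE)$p.value)
  list(median_log2fc = median(lfc[in_sig]),
       mean_log2fc = mean(lfc[in_sig]),
       p = p, n_signature = sum(in_sig), n_background = sum(!in_sig),
       coverage = coverage)
}

#' Measure knockdown-upregulated genes across reference stages
#'
#' The reverse direction of the signature analysis: take the top `n`
#' upregulated genes of a knockdown DE result, then ask in which reference
#' stage (e.g. embryonic stages including 2C) that gene set is highly
#' expressed — per stage, the set's expression distribution against all
#' other genes, with a one-sided Mann-Whitney U test.
#'
#' @param de DE `data.frame` from [testDifferential()] (or a character
#'   vector of upregulated gene ids used as-is).
#' @param reference_expr `data.frame`: gene-id column plus one column per
#'   reference stage.
#' @param gene_col Gene-id column (default `"gene"`).
#' @param n Top upregulated genes to use (default 200).
#' @return `data.frame`: `stage`, `n_set`, `median_set`,
#'   `median_background`, `p`. An empty up-set yields an all-`NA` row per
#'   stage with a warning.
#' @export
reverseSignature <- function(de, reference_expr, gene_col = "gene",
                             n = 200L) {
  stages <- setdiff(colnames(reference_expr), gene_col)
  if (is.character(de)) {
    up <- de
  } else {
    cand <- de[de$call == "up" & de$kind %in% "gene", , drop = FALSE]
    cand <- cand[order(-cand$log2fc, cand$feature), , drop = FALSE]
    up <- head(cand$feature, n)
  }
  ids <- as.character(reference_expr[[gene_col]])
  in_set <- ids %in% up
  if (!length(up) || !any(in_set)) {
    warning("empty (or uncovered) upregulated gene set")
    return(data.frame(stage = stages, n_set = 0L, median_set = NA_real_,
                      median_background = NA_real_, p = NA_real_))
  }
  out <- do.call(rbind, lapply(stages, function(st) {
    v <- reference_expr[[st]]
    p <- suppressWarnings(
      wilcox.test(v[in_set], v[!in_set], alternative = "greater",
                  exact = FALSE)$p.value)
    data.frame(stage = st, n_set = sum(in_set),
               median_set = median(v[in_set]),
               median_background = median(v[!in_set]), p = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Annotate genes by proximity and orientation of MERVL elements
#'
#' A gene is MERVL-associated when a MERVL element (by default the
#' internal `MERVL-int` or the solo-LTR `MT2_Mm`) lies within `window` bp
#' up- or downstream of the gene body (gap distance; overlap counts as 0).
#' The gene is labelled `same_ori` if any qualifying copy is on the gene's
#' strand — same-strand precedence when both orientations qualify, since
#' same-strand MERVLs are the ones that can splice into the gene —
#' `opposite_ori` if only opposite-strand copies qualify, else `none`.
#'
#' @param genes `GRanges` of gene bodies with `gene_id`; strandless genes
#'   are an error.
#' @param catalog A [TECatalog-class].
#' @param te_names MERVL type names (default `MERVL-int`, `MT2_Mm`).
#' @param window Max gap in bp (default 10000).
#' @return `data.frame`: `gene_id`, `orientation` in
#'   `none`/`same_ori`/`opposite_ori`, `n_same`, `n_opposite`.
#' @export
annotateMervlProximalGenes <- function(genes, catalog,
                                       te_names = c("MERVL-int", "MT2_Mm"),
                                       window = 10000L) {
  g_std <- as.character(strand(genes))
  if (any(g_std == "*"))
    stop("strandless gene record(s): ",
         paste(head(mcols(genes)$gene_id[g_std == "*"]), collapse = ", "))
  gr <- teCopies(catalog)
  mervl <- gr[mcols(gr)$type %in% te_names]
  t_std <- as.character(strand(mervl))
  if (any(t_std == "*"))
    stop("strandless MERVL copy records in the catalog")
  n_same <- integer(length(genes)); n_opp <- integer(length(genes))
  if (length(mervl)) {
    hits <- findOverlaps(genes, mervl, maxgap = window, ignore.strand = TRUE)
    if (length(hits)) {
      d <- distance(genes[S4Vectors::queryHits(hits)],
                    mervl[S4Vectors::subjectHits(hits)], ignore.strand = TRUE)
      keep <- !is.na(d) & d <= window
      q <- S4Vectors::queryHits(hits)[keep]
      s <- S4Vectors::subjectHits(hits)[keep]
      same <- g_std[q] == t_std[s]
      n_same <- as.integer(table(factor(q[same], levels = seq_along(genes))))
      n_opp <- as.integer(table(factor(q[!same], levels = seq_along(genes))))
    }
  }
  orientation <- ifelse(n_same > 0L, "same_ori",
                        ifelse(n_opp > 0L, "opposite_ori", "none"))
  data.frame(gene_id = mcols(genes)$gene_id, orientation = orientation,
             n_same = n_same, n_opposite = n_opp,
             stringsAsFactors = FALSE)
}
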