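# Bipartite relational network: chromatin marks and chromatin modifiers on
# one side, TE types on the other; an edge records that the mark/modifier
# passed the fold-enrichment threshold at that TE type.

#' Build the mark/modifier vs TE-type relational network
#'
#' Edges are drawn between a chromatin mark and a TE type, or a chromatin
#' modifier (CM) and a TE type, when the fold-enrichment passes the
#' threshold (default 2-fold, strict `>` to match the enrichment calls; set
#' `comparator = ">="` for an inclusive "at least 2-fold" reading). Marks
#' and modifiers are distinct node types in one graph. TE types with no
#' passing edge are dropped unless `keep_isolates`.
#'
#' @param mark_em [EnrichmentMatrix-class] of chromatin marks.
#' @param cm_em Optional [EnrichmentMatrix-class] of chromatin modifiers;
#'   the TE-type column spaces are intersected (an empty intersection is an
#'   error).
#' @param threshold Linear fold threshold (default 2).
#' @param comparator `">"` (default) or `">="`.
#' @param keep_isolates Keep unconnected TE-type nodes (default drop).
#' @return An `igraph` graph with vertex attributes `name` and `node_type`
#'   (`mark`/`modifier`/`te_type`) and edge attribute `log2fold`.
#' @export
buildRelationalNetwork <- function(mark_em, cm_em = NULL, threshold = 2.0,
                                   comparator = c(">", ">="),
                                   keep_isolates = FALSE) {
  comparator <- match.arg(comparator)
  mats <- list(mark = mark_em)
  if (!is.null(cm_em)) mats$modifier <- cm_em
  te_space <- Reduce(intersect, lapply(mats, function(m)
    colnames(observedSignal(m))))
  if (!length(te_space))
    stop("the enrichment matrices share no TE types")
  if (!is.null(cm_em) &&
      length(te_space) < length(union(colnames(observedSignal(mark_em)),
                                      colnames(observedSignal(cm_em)))))
    message("using the intersection of TE-type spaces: ",
            length(te_space), " type(s)")
  edges <- do.call(rbind, lapply(names(mats), function(side) {
    f <- foldEnrichment(mats[[side]])[, te_space, drop = FALSE]
    lf <- log2Fold(mats[[side]])[, te_space, drop = FALSE]
    pass <- if (comparator == ">") f > threshold else f >= threshold
    idx <- which(pass, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(from = rownames(f)[idx[, 1L]],
               to = te_space[idx[, 2L]],
               source_type = side,
               log2fold = lf[idx], stringsAsFactors = FALSE)
  }))
  left <- unlist(lapply(names(mats), function(side)
    setNames(rep(side, nrow(observedSignal(mats[[side]]))),
             rownames(observedSignal(mats[[side]])))))
  verts <- data.frame(name = c(names(left), te_space),
                      node_type = c(unname(left),
                                    rep("te_type", length(te_space))),
                      stringsAsFactors = FALSE)
  if (is.null(edges)) edges <- data.frame(from = character(0),
                                          to = character(0),
                                          source_type = character(0),
                                          log2fold = numeric(0))
  if (!keep_isolates) {
    used <- unique(c(edges$from, edges$to))
    verts <- verts[verts$name %in% used, , drop = FALSE]
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Summarise a relational network
#'
#' Degrees (incident edge count, the quantity node sizes are drawn
#' proportional to), connected components, and the top-`k` hubs with a
#' deterministic lexicographic tie-break.
#'
#' @param net Graph from [buildRelationalNetwork()].
#' @param n_hubs Hubs to report (default 5).
#' @return List: `degrees` (`data.frame` node/node_type/degree),
#'   `n_components`, `hubs` (character).
#' @export
networkSummary <- function(net, n_hubs = 5L) {
  if (igraph::vcount(net) == 0L)
    return(list(degrees = data.frame(node = character(0),
                                     node_type = character(0),
                                     degree = integer(0)),
                n_components = 0L, hubs = character(0)))
  deg <- igraph::degree(net)
  df <- data.frame(node = names(deg),
                   node_type = igraph::V(net)$node_type,
                   degree = as.integer(deg), stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$node), , drop = FALSE]
  rownames(df) <- NULL
  list(degrees = df,
       n_components = as.integer(igraph::components(net)$no),
       hubs = head(df$node, n_hubs))
}

#' Export / re-import a relational network
#'
#' `tsv_edgelist` writes `source, target, source_type, log2fold` plus a
#' side-car `<path>.nodes.tsv` with node types (so isolates survive);
#' [readNetworkEdgelist()] rebuilds the identical graph. `graphml` writes
#' GraphML via igraph with node type and degree as attributes.
#'
#' @param net Graph from [buildRelationalNetwork()].
#' @param path Output file.
#' @param format `"tsv_edgelist"` or `"graphml"`.
#' @export
exportNetwork <- function(net, path, format = c("tsv_edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::V(net)$degree <- igraph::degree(net)
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  ed <- igraph::as_data_frame(net, what = "edges")
  out <- data.frame(source = ed$from, target = ed$to,
                    source_type = if (nrow(ed)) ed$source_type else character(0),
                    log2fold = if (nrow(ed)) ed$log2fold else numeric(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nv <- igraph::as_data_frame(net, what = "vertices")
  write.table(nv, paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname exportNetwork
#' @return `readNetworkEdgelist` returns the rebuilt `igraph` graph.
#' @export
readNetworkEdgelist <- function(path) {
  ed <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "character",
                                  "numeric"))
  nv <- read.table(paste0(path, ".nodes.tsv"), sep = "\t", header = TRUE,
                   colClasses = "character")
  names(ed)[1:2] <- c("from", "to")
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nv)
}
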