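#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame Rle runValue runLength
#'   window
#' @importFrom IRanges IRanges Views viewMeans ranges coverage pintersect
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   countOverlaps findOverlaps granges strand<- distance end<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
#' @importFrom stats rnorm runif rnbinom rpois median sd cor var
#'   p.adjust pnorm pt wilcox.test fisher.test cor.test hclust as.dist
#'   cutree rlnorm quantile setNames weighted.mean loess fitted na.exclude
#' @importFrom utils read.table write.table head tail
NULL

#' TECatalog: genomic copies of transposable-element types
#'
#' Container for a RepeatMasker-style annotation of transposable elements
#' (TEs). Each copy is a genomic interval carrying its type (repName, e.g.
#' \code{L1Md_Gf}), class (LINE/SINE/LTR/DNA), family and milliDiv (the
#' per-mille divergence of the copy from its family consensus as reported by
#' RepeatMasker). All copies of one type are treated downstream as a single
#' metagene.
#'
#' @slot copies A [GenomicRanges::GRanges] with metadata columns
#'   \code{type} (character), \code{te_class} (character), \code{family}
#'   (character) and \code{millidiv} (numeric, per-mille, in \[0, 1000\] or
#'   NA). Seqlengths must be set.
#'
#' @seealso [readRepeatMasker()], [filterTECatalog()], [estimateTEAge()]
#' @export
setClass("TECatalog", representation(copies = "GRanges"))

setValidity("TECatalog", function(object) {
  gr <- object@copies
  msg <- character()
  need <- c("type", "te_class", "family", "millidiv")
  miss <- setdiff(need, colnames(mcols(gr)))
  if (length(miss))
    msg <- c(msg, paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(gr)) {
    if (!length(miss)) {
      md <- mcols(gr)$millidiv
      bad <- !is.na(md) & (md < 0 | md > 1000)
      if (any(bad)) msg <- c(msg, "millidiv must be in [0, 1000] or NA")
    }
    if (any(is.na(seqlengths(gr))))
      msg <- c(msg, "seqlengths must be set for all chromosomes")
    else if (any(end(gr) > seqlengths(gr)[as.character(seqnames(gr))]))
      msg <- c(msg, "copies extend past chromosome ends")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TECatalog
#'
#' @param copies A `GRanges` with metadata columns `type`, `te_class`,
#'   `family`, `millidiv` and seqlengths set.
#' @return A [TECatalog-class] object.
#' @export
TECatalog <- function(copies) {
  new("TECatalog", copies = copies)
}

#' @describeIn TECatalog-class the underlying `GRanges` of copies
#' @param x,object A `TECatalog`.
#' @export
teCopies <- function(x) x@copies

#' @describeIn TECatalog-class the distinct TE type names
#' @export
teTypeNames <- function(x) sort(unique(mcols(x@copies)$type))

#' Per-type summary of a TECatalog
#'
#' @param x A `TECatalog`.
#' @return A `data.frame` with one row per TE type: `type`, `te_class`,
#'   `family`, `n_copies`, `median_length`, `mean_millidiv`.
#' @export
teTypeSummary <- function(x) {
  gr <- x@copies
  if (!length(gr)) {
    return(data.frame(type = character(), te_class = character(),
                      family = character(), n_copies = integer(),
                      median_length = numeric(), mean_millidiv = numeric(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_along(gr), mcols(gr)$type)
  out <- do.call(rbind, lapply(names(sp), function(tn) {
    i <- sp[[tn]]
    data.frame(type = tn,
               te_class = mcols(gr)$te_class[i[1L]],
               family = mcols(gr)$family[i[1L]],
               n_copies = length(i),
               median_length = median(width(gr)[i]),
               mean_millidiv = mean(mcols(gr)$millidiv[i], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$type), , drop = FALSE]
}

setMethod("show", "TECatalog", function(object) {
  gr <- object@copies
  cat("TECatalog with", length(gr), "copies of",
      length(unique(mcols(gr)$type)), "TE types on",
      length(seqlevels(gr)), "sequence(s)\n")
  if (length(gr)) {
    tab <- sort(table(mcols(gr)$te_class), decreasing = TRUE)
    cat("  classes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

#' CoverageTrack: per-base genome coverage for one assay
#'
#' A per-base signal over a genome (ChIP-seq, ATAC-seq or similar), in
#' RPKM-normalised units, stored as a run-length-encoded list with one
#' element per chromosome.
#'
#' @slot cov An `RleList`, one numeric `Rle` per chromosome, length equal to
#'   the chromosome length; all values >= 0.
#' @slot label Assay / mark / modifier name.
#' @export
setClass("CoverageTrack",
         representation(cov = "RleList", label = "character"))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@label) != 1L) msg <- c(msg, "label must be length 1")
  if (length(object@cov)) {
    mins <- vapply(object@cov, function(r) min(runValue(r), 0), numeric(1))
    if (any(mins < 0)) msg <- c(msg, "coverage values must be >= 0")
    if (is.null(names(object@cov)) || any(!nzchar(names(object@cov))))
      msg <- c(msg, "cov must be named by chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' @param cov A named `RleList` (one numeric `Rle` per chromosome).
#' @param label Assay name.
#' @return A [CoverageTrack-class].
#' @export
CoverageTrack <- function(cov, label = "track") {
  new("CoverageTrack", cov = methods::as(cov, "RleList"), label = label)
}

#' @describeIn CoverageTrack-class the per-chromosome `RleList`
#' @param x,object A `CoverageTrack`.
#' @export
trackCoverage <- function(x) x@cov

#' @describeIn CoverageTrack-class the assay label
#' @export
trackLabel <- function(x) x@label

#' @describeIn CoverageTrack-class chromosome lengths covered by the track
#' @export
trackSeqlengths <- function(x) {
  setNames(vapply(x@cov, length, numeric(1)), names(x@cov))
}

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack '", object@label, "' over ",
      length(object@cov), " sequence(s), ",
      format(sum(vapply(object@cov, length, numeric(1))), big.mark = ","),
      " bp\n", sep = "")
})

#' Mean per-base signal of a track over a set of ranges
#'
#' @param x A `CoverageTrack`.
#' @param gr A `GRanges` on the track's chromosomes.
#' @return Numeric vector, one length-weighted per-base mean per range.
#' @export
trackMeans <- function(x, gr) {
  stopifnot(is(x, "CoverageTrack"), is(gr, "GRanges"))
  chroms <- as.character(seqnames(gr))
  bad <- setdiff(unique(chroms), names(x@cov))
  if (length(bad))
    stop("chromosome(s) absent from track: ", paste(bad, collapse = ", "))
  out <- numeric(length(gr))
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    v <- Views(x@cov[[ch]], start = start(gr)[i], end = end(gr)[i])
    out[i] <- viewMeans(v)
  }
  out
}

#' EnrichmentMatrix: observed/expected max-bin enrichment per mark and TE type
#'
#' Rows are chromatin marks / chromatin modifiers / assays; columns are TE
#' types. Each cell stores the observed max-bin metagene RPKM and the
#' expected max-bin RPKM from size-matched random background regions; the
#' log2 fold-enrichment is derived as
#' `log2((observed + pseudocount) / (expected + pseudocount))`.
#'
#' @slot observed,expected Numeric matrices (marks x TE types), values >= 0,
#'   identical dimnames.
#' @slot pseudocount Pseudocount applied to both components.
#' @slot seed Integer seed used to draw the background regions.
#' @slot bin_bp Bin width (bp) of the metagene binning.
#' @export
setClass("EnrichmentMatrix",
         representation(observed = "matrix", expected = "matrix",
                        pseudocount = "numeric", seed = "integer",
                        bin_bp = "integer"))

setValidity("EnrichmentMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@observed), dim(object@expected)))
    msg <- c(msg, "observed and expected dimensions differ")
  if (!identical(dimnames(object@observed), dimnames(object@expected)))
    msg <- c(msg, "observed and expected dimnames differ")
  if (any(object@observed < 0, na.rm = TRUE) ||
      any(object@expected < 0, na.rm = TRUE))
    msg <- c(msg, "observed/expected must be >= 0")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msg <- c(msg, "pseudocount must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an EnrichmentMatrix
#'
#' @param observed,expected Marks x TE-types matrices of max-bin RPKM.
#' @param pseudocount Pseudocount (RPKM) added to both components.
#' @param seed Background-sampling seed.
#' @param bin_bp Bin width in bp.
#' @return An [EnrichmentMatrix-class].
#' @export
EnrichmentMatrix <- function(observed, expected, pseudocount = 0.01,
                             seed = NA_integer_, bin_bp = 500L) {
  new("EnrichmentMatrix", observed = observed, expected = expected,
      pseudocount = pseudocount, seed = as.integer(seed),
      bin_bp = as.integer(bin_bp))
}

#' @describeIn EnrichmentMatrix-class linear fold-enrichment
#'   `(obs + pc) / (exp + pc)`
#' @param x,object An `EnrichmentMatrix`.
#' @export
foldEnrichment <- function(x) {
  (x@observed + x@pseudocount) / (x@expected + x@pseudocount)
}

#' @describeIn EnrichmentMatrix-class log2 fold-enrichment
#' @export
log2Fold <- function(x) log2(foldEnrichment(x))

#' @describeIn EnrichmentMatrix-class observed max-bin values
#' @export
observedSignal <- function(x) x@observed

#' @describeIn EnrichmentMatrix-class expected (background) max-bin values
#' @export
expectedSignal <- function(x) x@expected

setMethod("show", "EnrichmentMatrix", function(object) {
  cat("EnrichmentMatrix:", nrow(object@observed), "mark(s) x",
      ncol(object@observed), "TE type(s); pseudocount",
      object@pseudocount, "RPKM; bin", object@bin_bp, "bp\n")
  lf <- log2Fold(object)
  if (length(lf))
    cat("  log2 fold range:", round(min(lf), 3), "..", round(max(lf), 3), "\n")
})

# internal: run code under a temporary RNG state, restoring afterwards
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# internal: small deterministic string hash (for per-mark seed offsets)
stringSeedOffset <- function(s) {
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 100000L
}
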