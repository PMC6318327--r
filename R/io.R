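# Readers and writers for the plain-text formats the pipeline consumes:
# chrom.sizes, UCSC-rmsk-style TSV, RepeatMasker .out, BED6(+2), bedGraph /
# bigWig (via rtracklayer) and GTF. All coordinates are converted on entry
# to the 1-based closed convention GRanges uses; rmsk/BED starts are 0-based
# half-open on disk.

#' Read a chrom.sizes file
#'
#' @param path Two-column TSV (`name`, `length`), UCSC chrom.sizes style, or
#'   a named numeric vector (returned as integer unchanged).
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  if (is.numeric(path)) return(setNames(as.integer(path), names(path)))
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "integer"))
  setNames(df$size, df$chrom)
}

#' @rdname readChromSizes
#' @param sizes Named integer vector.
#' @export
writeChromSizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), unname(sizes)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a RepeatMasker-style TE annotation
#'
#' Supports three dialects: `"ucsc_rmsk"` — the UCSC rmsk table export with
#' header columns `genoName, genoStart, genoEnd, strand, repName, repClass,
#' repFamily, milliDiv` (0-based half-open starts); `"rmsk_out"` — native
#' RepeatMasker `.out` (3 header lines, whitespace-separated, 1-based
#' inclusive coordinates, divergence in percent); `"bed"` — BED6 with the
#' TE type in the name column, optionally extended with `repClass`,
#' `repFamily` and `milliDiv` columns (BED6+2/+3).
#'
#' @param path Annotation file.
#' @param dialect One of `"ucsc_rmsk"`, `"rmsk_out"`, `"bed"`.
#' @param chrom_sizes Named lengths or a chrom.sizes path; required to set
#'   seqlengths (inferred from the data maxima, with a warning, if absent).
#' @param skip_malformed If `TRUE`, malformed lines are skipped with a
#'   warning naming their line numbers; default is to fail fast.
#' @return A [TECatalog-class].
#' @export
readRepeatMasker <- function(path, dialect = c("ucsc_rmsk", "rmsk_out", "bed"),
                             chrom_sizes = NULL, skip_malformed = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "rmsk_out" && length(lines) >= 3L) lines <- lines[-(1:3)]
  header <- NULL
  if (dialect == "ucsc_rmsk" && length(lines)) {
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    header <- sub("^#", "", header)
    lines <- lines[-1L]
  }
  lines_no <- seq_along(lines) +
    switch(dialect, ucsc_rmsk = 1L, rmsk_out = 3L, bed = 0L)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lines_no <- lines_no[keep]

  parse_one <- function(line) {
    f <- if (dialect == "rmsk_out") strsplit(trimws(line), "[ \t]+")[[1L]]
         else strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (dialect == "ucsc_rmsk") {
      v <- setNames(f, header)
      need <- c("genoName", "genoStart", "genoEnd", "strand", "repName",
                "repClass", "repFamily", "milliDiv")
      if (any(!need %in% names(v))) return(NULL)
      st0 <- suppressWarnings(as.numeric(v["genoStart"]))
      en <- suppressWarnings(as.numeric(v["genoEnd"]))
      md <- suppressWarnings(as.numeric(v["milliDiv"]))
      if (is.na(st0) || is.na(en) || en <= st0) return(NULL)
      list(chrom = unname(v["genoName"]), start = st0 + 1, end = en,
           strand = unname(v["strand"]), type = unname(v["repName"]),
           te_class = unname(v["repClass"]), family = unname(v["repFamily"]),
           millidiv = md)
    } else if (dialect == "rmsk_out") {
      if (length(f) < 11L) return(NULL)
      st <- suppressWarnings(as.numeric(f[6L]))
      en <- suppressWarnings(as.numeric(f[7L]))
      div <- suppressWarnings(as.numeric(f[2L]))
      if (is.na(st) || is.na(en) || en < st) return(NULL)
      cf <- strsplit(f[11L], "/", fixed = TRUE)[[1L]]
      list(chrom = f[5L], start = st, end = en,
           strand = if (f[9L] == "C") "-" else f[9L],
           type = f[10L], te_class = cf[1L],
           family = if (length(cf) > 1L) cf[2L] else cf[1L],
           millidiv = div * 10)
    } else {  # bed: BED6(+2 class/family)(+1 millidiv)
      if (length(f) < 6L) return(NULL)
      st0 <- suppressWarnings(as.numeric(f[2L]))
      en <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(st0) || is.na(en) || en <= st0) return(NULL)
      list(chrom = f[1L], start = st0 + 1, end = en, strand = f[6L],
           type = f[4L],
           te_class = if (length(f) >= 7L) f[7L] else "other",
           family = if (length(f) >= 8L) f[8L] else "other",
           millidiv = if (length(f) >= 9L)
             suppressWarnings(as.numeric(f[9L])) else NA_real_)
    }
  }

  parsed <- lapply(lines, parse_one)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    where <- paste(lines_no[bad], collapse = ", ")
    if (!skip_malformed)
      stop("malformed ", dialect, " record(s) at line(s): ", where)
    warning("skipped malformed line(s): ", where)
    parsed <- parsed[!bad]
  }
  sizes <- if (!is.null(chrom_sizes)) readChromSizes(chrom_sizes) else NULL
  if (!length(parsed)) {
    gr <- GRanges(seqlengths = if (is.null(sizes)) integer(0) else sizes)
    mcols(gr) <- DataFrame(type = character(0), te_class = character(0),
                           family = character(0), millidiv = numeric(0))
    return(TECatalog(gr))
  }
  chrom <- vapply(parsed, `[[`, character(1), "chrom")
  if (is.null(sizes)) {
    warning("no chrom_sizes supplied; inferring seqlengths from data maxima")
    en <- vapply(parsed, `[[`, numeric(1), "end")
    sizes <- vapply(split(en, chrom), max, numeric(1))
  }
  gr <- GRanges(chrom,
                IRanges(vapply(parsed, `[[`, numeric(1), "start"),
                        vapply(parsed, `[[`, numeric(1), "end")),
                strand = vapply(parsed, `[[`, character(1), "strand"),
                seqlengths = sizes)
  mcols(gr) <- DataFrame(
    type = vapply(parsed, `[[`, character(1), "type"),
    te_class = vapply(parsed, `[[`, character(1), "te_class"),
    family = vapply(parsed, `[[`, character(1), "family"),
    millidiv = vapply(parsed, `[[`, numeric(1), "millidiv"))
  TECatalog(gr)
}

#' Write a TECatalog as a UCSC rmsk-style table
#'
#' Columns `genoName genoStart genoEnd strand repName repClass repFamily
#' milliDiv`, 0-based half-open starts; round-trips losslessly through
#' [readRepeatMasker()] (`dialect = "ucsc_rmsk"`).
#'
#' @param catalog A [TECatalog-class].
#' @param path Output file.
#' @export
writeCatalogRmsk <- function(catalog, path) {
  gr <- teCopies(catalog)
  df <- data.frame(genoName = as.character(seqnames(gr)),
                   genoStart = start(gr) - 1L, genoEnd = end(gr),
                   strand = as.character(strand(gr)),
                   repName = mcols(gr)$type, repClass = mcols(gr)$te_class,
                   repFamily = mcols(gr)$family,
                   milliDiv = mcols(gr)$millidiv)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCatalogRmsk
#' @details `writeCatalogBED` writes BED6+3 (name = TE type; extra columns
#'   repClass, repFamily, milliDiv), readable with `dialect = "bed"`.
#' @export
writeCatalogBED <- function(catalog, path) {
  gr <- teCopies(catalog)
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   mcols(gr)$type, 0L, as.character(strand(gr)),
                   mcols(gr)$te_class, mcols(gr)$family, mcols(gr)$millidiv)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a per-type catalog summary (type, class, family, copy number,
#' divergence, age)
#'
#' @param catalog A [TECatalog-class].
#' @param path Output TSV.
#' @param rate Substitution rate passed to [estimateTEAge()].
#' @export
writeCatalogSummary <- function(catalog, path, rate = 4.5e-9) {
  age <- estimateTEAge(catalog, rate = rate)
  write.table(age, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# GTF writer for the toy gene annotation (gene features only, GTF2.2
# attribute syntax); 1-based inclusive like all GTF.
writeToyGTF <- function(genes, path) {
  attr_s <- sprintf('gene_id "%s"; gene_name "%s";',
                    mcols(genes)$gene_id, mcols(genes)$gene_id)
  df <- data.frame(as.character(seqnames(genes)), "TEmetagene", "gene",
                   start(genes), end(genes), ".",
                   as.character(strand(genes)), ".", attr_s)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation (GTF)
#'
#' @param path GTF file.
#' @param feature Feature type to keep (default `"gene"`; falls back to all
#'   records reduced per gene_id when absent).
#' @param chrom_sizes Optional named lengths to set seqlengths.
#' @return A `GRanges` with a `gene_id` metadata column.
#' @export
readGeneGTF <- function(path, feature = "gene", chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% colnames(mcols(gr)) && any(mcols(gr)$type == feature))
    gr <- gr[mcols(gr)$type == feature]
  mcols(gr) <- mcols(gr)["gene_id"]
  if (!is.null(chrom_sizes)) {
    sizes <- readChromSizes(chrom_sizes)
    seqlengths(gr) <- sizes[seqlevels(gr)]
  }
  gr
}

#' Read a coverage track (bedGraph or bigWig)
#'
#' Normalises either format to the same internal per-base representation so
#' downstream queries are format-independent. Overlapping input intervals
#' are an error (the signal would be ambiguous); intervals past a chromosome
#' end are clipped with a warning. Bases not covered by any interval are 0.
#'
#' @param path Track file.
#' @param format `"bedGraph"` or `"bigWig"` (default: from the extension).
#' @param chrom_sizes Named lengths or chrom.sizes path.
#' @param label Track label (defaults to the file name).
#' @return A [CoverageTrack-class].
#' @export
readCoverage <- function(path, format = NULL, chrom_sizes, label = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
      "bigWig" else "bedGraph"
  }
  format <- match.arg(format, c("bedGraph", "bigWig"))
  sizes <- readChromSizes(chrom_sizes)
  gr <- rtracklayer::import(path, format = format)
  strand(gr) <- "*"
  if (length(gr) && any(countOverlaps(gr, gr) > 1L))
    stop("overlapping intervals in ", path, ": signal is ambiguous")
  known <- as.character(seqnames(gr)) %in% names(sizes)
  if (!all(known)) stop("track chromosome(s) absent from chrom_sizes: ",
                        paste(unique(as.character(seqnames(gr))[!known]),
                              collapse = ", "))
  over <- end(gr) > sizes[as.character(seqnames(gr))]
  if (any(over)) {
    warning(sum(over), " interval(s) extend past chromosome ends; clipped")
    end(gr)[over] <- sizes[as.character(seqnames(gr))[over]]
    gr <- gr[width(gr) > 0L]
  }
  sl <- Seqinfo(names(sizes), unname(sizes))
  gr2 <- GRanges(as.character(seqnames(gr)), ranges(gr), seqinfo = sl)
  cov <- if (length(gr2)) coverage(gr2, weight = gr$score)
         else coverage(gr2)
  CoverageTrack(cov, label = if (is.null(label)) basename(path) else label)
}

#' Write a CoverageTrack as bedGraph
#'
#' Runs of equal value become one interval; zero-valued runs are written too
#' so the file round-trips to the identical track.
#'
#' @param track A [CoverageTrack-class].
#' @param path Output bedGraph.
#' @export
writeTrackBedGraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(trackCoverage(track))) {
    r <- trackCoverage(track)[[ch]]
    en <- cumsum(runLength(r))
    st0 <- en - runLength(r)   # 0-based starts
    df <- data.frame(ch, st0, en, format(runValue(r), trim = TRUE,
                                         scientific = FALSE, digits = 10))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
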