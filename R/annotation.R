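#' Filter a TE catalog by copy length and type copy number
#'
#' Applies the two standing filters of the enrichment analysis, in a fixed,
#' documented order: first, copies shorter than `min_len` bp are removed;
#' second, TE types whose *remaining* copy number is below `min_copies` are
#' removed entirely. The order matters (a type can drop below the copy
#' threshold only because of the length filter) and is fixed length-first.
#' The operation is idempotent.
#'
#' @param catalog A [TECatalog-class].
#' @param min_len Minimum copy length in bp (default 300; copies with
#'   length < 300 are deleted).
#' @param min_copies Minimum copies per type (default 50; types with fewer
#'   than 50 remaining copies are deleted).
#' @return The filtered [TECatalog-class].
#' @export
filterTECatalog <- function(catalog, min_len = 300L, min_copies = 50L) {
  stopifnot(min_len >= 0, min_copies >= 0)
  gr <- teCopies(catalog)
  gr <- gr[width(gr) >= min_len]
  if (length(gr)) {
    n <- table(mcols(gr)$type)
    keep <- names(n)[n >= min_copies]
    gr <- gr[mcols(gr)$type %in% keep]
  }
  TECatalog(gr)
}

#' Split LINE types into long and short pseudo-types
#'
#' LINE elements divide into near-intact long copies and truncated short
#' ones with distinct chromatin behaviour. Copies of each LINE-class type
#' are reassigned to `<type>__long` when strictly longer than `cutoff` bp
#' and to `<type>__short` otherwise (a copy of exactly `cutoff` bp is
#' "short": long is strict `> cutoff`). Non-LINE types are untouched.
#'
#' @param catalog A [TECatalog-class].
#' @param cutoff Length cutoff in bp (default 5000).
#' @return A [TECatalog-class] with LINE copies renamed.
#' @seealso [mergeSplitTypes()] to undo the split.
#' @export
splitLinesByLength <- function(catalog, cutoff = 5000L) {
  stopifnot(cutoff > 0)
  gr <- teCopies(catalog)
  is_line <- mcols(gr)$te_class == "LINE"
  suffix <- ifelse(width(gr) > cutoff, "__long", "__short")
  mcols(gr)$type <- ifelse(is_line,
                           paste0(mcols(gr)$type, suffix),
                           mcols(gr)$type)
  TECatalog(gr)
}

#' @rdname splitLinesByLength
#' @details `mergeSplitTypes` strips the `__long`/`__short` suffixes,
#'   reconstructing the original copy set exactly.
#' @export
mergeSplitTypes <- function(catalog) {
  gr <- teCopies(catalog)
  mcols(gr)$type <- sub("__(long|short)$", "", mcols(gr)$type)
  TECatalog(gr)
}

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`; undefined (NA) for `p >= 0.75`.
#'
#' @param p Proportion of substituted sites, in \[0, 0.75).
#' @return Expected substitutions per site.
#' @export
jukesCantorDistance <- function(p) {
  stopifnot(all(p >= 0, na.rm = TRUE))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}

#' Estimate TE-type age from RepeatMasker divergence
#'
#' The mean milliDiv of a type's copies, divided by 1000, is taken as the
#' proportion of substituted sites `p` between the copies and the family
#' consensus; the Jukes-Cantor correction gives the per-site distance `d`,
#' and dividing by a neutral substitution rate gives the age in years.
#' Because divergence is measured against the consensus (which approximates
#' the ancestral sequence) the default is the single-lineage convention
#' `T = d / rate`; set `doubled = TRUE` for the pairwise convention
#' `T = d / (2 * rate)` — both are in published use.
#'
#' Types whose mean `p >= 0.75` are outside the Jukes-Cantor domain: they
#' are flagged (`jc_domain_ok = FALSE`) with `NA` age, not dropped.
#'
#' @param catalog A [TECatalog-class], or a numeric vector of per-type mean
#'   milliDiv values (optionally named).
#' @param rate Substitution rate per base per year (default 4.5e-9).
#' @param doubled Use `d / (2 * rate)` instead of `d / rate`.
#' @param length_weighted Weight each copy's milliDiv by its length when
#'   averaging per type (default unweighted).
#' @return `data.frame`: `type`, `mean_millidiv`, `p`, `jc_distance`,
#'   `age_years`, `jc_domain_ok`.
#' @export
estimateTEAge <- function(catalog, rate = 4.5e-9, doubled = FALSE,
                          length_weighted = FALSE) {
  stopifnot(rate > 0)
  if (is(catalog, "TECatalog")) {
    gr <- teCopies(catalog)
    sp <- split(seq_along(gr), mcols(gr)$type)
    md <- vapply(sp, function(i) {
      if (length_weighted)
        stats::weighted.mean(mcols(gr)$millidiv[i], width(gr)[i],
                             na.rm = TRUE)
      else mean(mcols(gr)$millidiv[i], na.rm = TRUE)
    }, numeric(1))
  } else {
    md <- catalog
    if (is.null(names(md))) names(md) <- paste0("type_", seq_along(md))
  }
  p <- md / 1000
  d <- jukesCantorDistance(p)
  age <- d / (rate * if (doubled) 2 else 1)
  ok <- !is.na(p) & p < 0.75
  if (any(!ok))
    warning("TE type(s) outside the Jukes-Cantor domain (p >= 0.75): ",
            paste(names(md)[!ok], collapse = ", "))
  data.frame(type = names(md), mean_millidiv = unname(md), p = unname(p),
             jc_distance = unname(d), age_years = unname(age),
             jc_domain_ok = unname(ok),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean GC content per TE type
#'
#' Per-copy GC fraction over `[start, end)`, averaged per type; `N` bases
#' are excluded from the denominator.
#'
#' @param catalog A [TECatalog-class].
#' @param genome_fasta Path to the genome FASTA (or a
#'   [Biostrings::DNAStringSet]).
#' @return Named numeric vector of per-type mean GC fractions.
#' @export
computeGCContent <- function(catalog, genome_fasta) {
  genome <- if (is(genome_fasta, "DNAStringSet")) genome_fasta
            else Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- teCopies(catalog)
  missing <- setdiff(unique(as.character(seqnames(gr))), names(genome))
  if (length(missing))
    stop("chromosome(s) missing from FASTA: ", paste(missing, collapse = ", "))
  gc <- vapply(seq_along(gr), function(i) {
    s <- Biostrings::subseq(genome[[as.character(seqnames(gr))[i]]],
                            start(gr)[i], end(gr)[i])
    f <- Biostrings::letterFrequency(s, c("G", "C", "A", "T"))
    denom <- sum(f)
    if (denom == 0) NA_real_ else (f[["G"]] + f[["C"]]) / denom
  }, numeric(1))
  vapply(split(gc, mcols(gr)$type), mean, numeric(1), na.rm = TRUE)
}
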