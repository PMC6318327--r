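# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's internal representations: they work on plain numeric
# per-base vectors and data.frames, with naive loops.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

tinySpec <- function(seed = 7L, n_copies = c(60L, 60L, 60L),
                     sizes = c(chr1 = 1000000L, chr2 = 500000L)) {
  syntheticGenomeSpec(
    sizes,
    list(teTypeSpec("TEa", "LTR", n_copies[1], c(500L, 2000L), 80),
         teTypeSpec("TEb", "LINE", n_copies[2], c(1000L, 6000L), 120),
         teTypeSpec("TEc", "SINE", n_copies[3], c(300L, 400L), 150)),
    seed = seed)
}

# build a CoverageTrack straight from plain per-base vectors, so tests can
# hold the same vectors for oracle arithmetic
trackFromVectors <- function(vecs, label = "test") {
  CoverageTrack(as(lapply(vecs, S4Vectors::Rle), "RleList"), label = label)
}

# catalog from a plain data.frame (chrom, start(1-based), end, strand,
# type, class, family, millidiv)
catalogFromDF <- function(df, sizes) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                seqlengths = sizes)
  mcols(gr) <- DataFrame(type = df$type, te_class = df$class,
                         family = df$family, millidiv = df$millidiv)
  TECatalog(gr)
}

# ---- oracles -------------------------------------------------------------

# naive per-base metagene binning + max, from plain vectors and a copies
# data.frame (chrom, start, end, strand); independent loop implementation
oracleMaxBin <- function(vecs, copies, bin_bp = 500L) {
  per_copy <- list()
  for (i in seq_len(nrow(copies))) {
    v <- vecs[[copies$chrom[i]]][copies$start[i]:copies$end[i]]
    if (copies$strand[i] == "-") v <- rev(v)
    nb <- max(1, ceiling(length(v) / bin_bp))
    bins <- numeric(nb)
    for (b in seq_len(nb)) {
      lo <- (b - 1L) * bin_bp + 1L
      hi <- min(b * bin_bp, length(v))
      bins[b] <- mean(v[lo:hi])
    }
    per_copy[[i]] <- bins
  }
  nb <- max(lengths(per_copy))
  prof <- numeric(nb)
  for (b in seq_len(nb)) {
    vals <- c()
    for (pc in per_copy) if (length(pc) >= b) vals <- c(vals, pc[b])
    prof[b] <- mean(vals)
  }
  max(prof)
}

# brute-force Benjamini-Hochberg step-up
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# two-sided Fisher exact p by full hypergeometric enumeration
# (point-probability method: sum of table probabilities <= observed)
oracleFisher2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# connected components of an undirected edge list by BFS
oracleComponents <- function(edges, nodes) {
  if (!length(nodes)) return(0L)
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  ncomp <- 0L
  for (nd in nodes) {
    if (seen[[nd]]) next
    ncomp <- ncomp + 1L
    queue <- nd
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      if (seen[[cur]]) next
      seen[[cur]] <- TRUE
      queue <- c(queue, adj[[cur]])
    }
  }
  ncomp
}

# exact one-sided Mann-Whitney p by enumeration of all group assignments
oracleMannWhitney <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2L, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  mean(us >= u_obs - 1e-9)
}
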