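# Independent oracles, each deliberately built on a different route than
# the implementation it checks.

# Consequence oracle: rebuild the whole mutated contig, shift the
# transcript coordinates past the edit, re-extract the CDS and translate
# both with Biostrings::translate. Category rules applied to the two
# proteins only.
oracle_consequence <- function(pos, ref, alt, tx, genome,
                               splice_window = 2L) {
  contig <- genome[[tx$chrom]]
  v0 <- pos - 1L
  v1 <- v0 + nchar(ref)
  cds_iv <- cbind(pmax(tx$exon_starts, tx$cds_start),
                  pmin(tx$exon_ends, tx$cds_end))
  cds_iv <- cds_iv[cds_iv[, 1L] < cds_iv[, 2L], , drop = FALSE]
  in_cds <- any(v0 < cds_iv[, 2L] & v1 > cds_iv[, 1L])
  if (!in_cds) {
    n <- length(tx$exon_starts)
    spl <- FALSE
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        is <- tx$exon_ends[i]; ie <- tx$exon_starts[i + 1L]
        w <- min(splice_window, ie - is)
        don <- c(is, is + w); acc <- c(ie - w, ie)
        if ((v0 < don[2L] && v1 > don[1L]) ||
            (v0 < acc[2L] && v1 > acc[1L])) spl <- TRUE
      }
    }
    return(if (spl) "splice_site" else "noncoding")
  }
  mut <- paste0(substr(contig, 1L, v0), alt,
                substr(contig, v1 + 1L, nchar(contig)))
  ld <- nchar(alt) - nchar(ref)
  shift <- function(x) ifelse(x >= v1, x + ld, x)
  extract <- function(ctg, es, ee, cs, ce) {
    s <- pmax(es, cs); e <- pmin(ee, ce)
    keep <- s < e
    paste(substring(ctg, s[keep] + 1L, e[keep]), collapse = "")
  }
  cds_ref <- extract(contig, tx$exon_starts, tx$exon_ends,
                     tx$cds_start, tx$cds_end)
  cds_alt <- extract(mut, shift(tx$exon_starts), shift(tx$exon_ends),
                     shift(tx$cds_start), shift(tx$cds_end))
  if (tx$strand == "-") {
    rcb <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(x)))
    cds_ref <- rcb(cds_ref); cds_alt <- rcb(cds_alt)
  }
  tr <- function(x) {
    x <- substr(x, 1L, 3L * (nchar(x) %/% 3L))
    suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(x),
                            if.fuzzy.codon = "X",
                            no.init.codon = TRUE)))
  }
  p_ref <- tr(cds_ref); p_alt <- tr(cds_alt)
  if (ld %% 3L != 0L) return("frameshift")
  stop_at <- function(p) {
    s <- regexpr("*", p, fixed = TRUE)
    if (s < 0L) Inf else as.integer(s)
  }
  s_ref <- stop_at(p_ref); s_alt <- stop_at(p_alt)
  if (s_alt < s_ref + ld %/% 3L) return("nonsense")
  if (ld != 0L) return("inframe_indel")
  trim <- function(p, s) if (is.finite(s)) substr(p, 1L, s) else p
  if (trim(p_ref, s_ref) == trim(p_alt, s_ref)) "synonymous" else
    "missense"
}

# Coding-length oracle: enumerate every genomic position marked
# translated by any transcript.
oracle_coding_length <- function(g) {
  pos <- integer(0)
  for (tx in g$transcripts) {
    for (i in seq_along(tx$exon_starts)) {
      s <- max(tx$exon_starts[i], tx$cds_start)
      e <- min(tx$exon_ends[i], tx$cds_end)
      if (s < e) pos <- c(pos, seq.int(s, e - 1L))
    }
  }
  length(unique(pos))
}

# Exhaustive fixed-margins enumeration of an R x 2 table; returns the
# exact two-sided Fisher p (sum of table probabilities <= observed).
oracle_fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(ncol(tab) == 2L)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  lp <- function(x) sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
    lgamma(n + 1) - sum(lgamma(x + 1)) - sum(lgamma(rs - x + 1))
  # enumerate first-column counts per row
  grids <- lapply(seq_along(rs), function(i)
    0:min(rs[i], cs[1L]))
  combos <- expand.grid(grids)
  ok <- rowSums(combos) == cs[1L]
  combos <- combos[ok, , drop = FALSE]
  lps <- apply(combos, 1L, function(x) {
    if (any(x > rs) || any(rs - x < 0)) return(NA_real_)
    lp(as.numeric(x))
  })
  obs <- lp(tab[, 1L])
  sum(exp(lps[lps <= obs + 1e-7]))
}

# Single-subject two-population admixture log-likelihood grid search.
oracle_admixture_2pop <- function(x, f1, f2, grid = seq(0, 1, 0.01)) {
  eps <- 1e-6
  f1 <- pmin(pmax(f1, eps), 1 - eps)
  f2 <- pmin(pmax(f2, eps), 1 - eps)
  ll <- vapply(grid, function(q) {
    p <- q * f1 + (1 - q) * f2
    sum(x * log(p) + (2 - x) * log(1 - p))
  }, 0)
  grid[which.max(ll)]
}

# Closed-form least squares via the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1L]
}
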