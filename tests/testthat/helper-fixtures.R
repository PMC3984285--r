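# Shared fixtures: handcrafted genes/genomes and small genotype sets.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                              collapse = "")

rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                     "")[[1L]]), collapse = "")

# A protein-coding sequence: ATG + random non-stop codons + stop.
rand_cds <- function(n_codon) {
  gc <- Biostrings::GENETIC_CODE
  nonstop <- names(gc)[gc != "*"]
  paste0("ATG", paste(sample(nonstop, n_codon - 2L, replace = TRUE),
                      collapse = ""), sample(c("TAA", "TAG", "TGA"), 1L))
}

# Plus-strand toy gene: CDS split over n_exons exons with random introns
# and 20 bp flanks. Returns the transcript, contig and chunk map.
make_test_gene <- function(n_codon = 60L, n_exons = 3L, chrom = "chrT",
                           id = "TXT") {
  cds <- rand_cds(n_codon)
  len <- nchar(cds)
  repeat {
    cuts <- sort(sample(seq(10L, len - 10L), n_exons - 1L))
    if (all(diff(c(0L, cuts, len)) >= 10L)) break
  }
  cs <- c(0L, cuts); ce <- c(cuts, len)
  flank <- 20L
  gpos <- flank
  exon_starts <- exon_ends <- integer(n_exons)
  pieces <- rand_dna(flank)
  for (i in seq_len(n_exons)) {
    exon_starts[i] <- gpos
    pieces <- c(pieces, substr(cds, cs[i] + 1L, ce[i]))
    gpos <- gpos + ce[i] - cs[i]
    exon_ends[i] <- gpos
    if (i < n_exons) {
      ilen <- sample(20:60, 1L)
      pieces <- c(pieces, rand_dna(ilen))
      gpos <- gpos + ilen
    }
  }
  pieces <- c(pieces, rand_dna(flank))
  contig <- paste(pieces, collapse = "")
  tx <- transcript(id, "GENE", chrom, "+", exon_starts, exon_ends,
                   exon_starts[1L], exon_ends[n_exons])
  genome <- setNames(list(contig), chrom)
  list(tx = tx, genome = genome, contig = contig, cds = cds,
       chunk_start = cs, chunk_end = ce)
}

# Mirror a plus-strand gene onto the minus strand of the reverse
# complemented contig; returns the mirrored transcript/genome and a
# function mapping a (pos, ref, alt) variant to its mirrored form.
mirror_gene <- function(g) {
  L <- nchar(g$contig)
  contig2 <- rc(g$contig)
  tx <- g$tx
  es2 <- rev(L - tx$exon_ends)
  ee2 <- rev(L - tx$exon_starts)
  tx2 <- transcript(paste0(tx$transcript_id, "m"), tx$gene_symbol,
                    tx$chrom, "-", es2, ee2, L - tx$cds_end,
                    L - tx$cds_start)
  map <- function(pos, ref, alt) {
    list(pos = L - (pos - 1L + nchar(ref)) + 1L, ref = rc(ref),
         alt = rc(alt))
  }
  list(tx = tx2, genome = setNames(list(contig2), tx$chrom), map = map)
}

# Small genotype set from explicit matrices, with sensible depths.
small_genotype_set <- function(dosage, chrom = "ctg1", sex = NULL,
                               dp_value = 40L) {
  n <- nrow(dosage); m <- ncol(dosage)
  variants <- data.frame(chrom = rep(chrom, length.out = n),
                         pos = seq_len(n) * 10L,
                         ref = "A", alt = "G", gene = "G1",
                         stringsAsFactors = FALSE)
  subjects <- data.frame(subject_id = sprintf("s%02d", seq_len(m)),
                         stringsAsFactors = FALSE)
  if (!is.null(sex)) subjects$sex <- sex
  dp <- matrix(dp_value, n, m)
  ad_alt <- round(dp * ifelse(is.na(dosage), 0, dosage) / 2)
  genotype_set(variants, subjects, dosage, dp - ad_alt, ad_alt, dp)
}
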