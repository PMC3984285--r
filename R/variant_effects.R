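# Consequence annotation by translation of reference and alternate coding
# sequences, plus the nonexclusive variant classes used for profiling.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter", X = "Xaa")

CONSEQUENCE_SEVERITY <- c("frameshift", "nonsense", "splice_site",
                          "missense", "inframe_indel", "synonymous",
                          "noncoding")

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

# Translate a nucleotide string with the standard genetic code; stops are
# "*", incomplete trailing codons are dropped, unknown codons become "X".
translate_dna <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

aa_at <- function(protein, i) {
  a <- substr(protein, i, i)
  if (a == "") "Xaa" else unname(AA3[a])
}

first_stop <- function(protein) {
  s <- regexpr("*", protein, fixed = TRUE)
  if (s < 0L) Inf else as.integer(s)
}

# Genomic sequence of a transcript's coding region (exonic bases within
# the CDS bounds, concatenated in genomic order, plus strand).
coding_genomic_seq <- function(tx, genome) {
  seq <- genome_seq(genome, tx$chrom)
  s <- pmax(tx$exon_starts, tx$cds_start)
  e <- pmin(tx$exon_ends, tx$cds_end)
  keep <- s < e
  paste(substring(seq, s[keep] + 1L, e[keep]), collapse = "")
}

genome_seq <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    as.character(genome[[chrom]])
  } else {
    s <- genome[[chrom]]
    if (is.null(s)) stop("contig ", chrom, " absent from genome")
    s
  }
}

#' Classify the predicted protein effect of a variant on one transcript
#'
#' Builds the reference and alternate coding sequences, translates both
#' with the standard genetic code and assigns a consequence category: a
#' length change that is not a multiple of 3 is a frameshift; a new stop
#' codon upstream of the reference stop is nonsense; an amino-acid
#' substitution is missense; an identical protein is synonymous; an
#' in-frame length change is an in-frame indel. Variants outside the CDS
#' that hit the first or last `splice_window` bases of an intron are
#' splice-site; everything else is noncoding.
#'
#' @param chrom,pos,ref,alt variant in VCF convention (1-based `pos`,
#'   alleles over ACGT). The variant should be normalized
#'   ([normalize_variant()]).
#' @param tx a [transcript()].
#' @param genome named list/character vector of contig sequences or a
#'   `Biostrings::DNAStringSet`.
#' @param splice_window intronic bases counted as splice region.
#' @return list with `transcript_id`, `category` and `protein_change`
#'   (HGVS-like, empty for splice-site and noncoding categories).
#' @export
classify_consequence <- function(chrom, pos, ref, alt, tx, genome,
                                 splice_window = 2L) {
  ann <- function(category, protein_change = "")
    list(transcript_id = tx$transcript_id, category = category,
         protein_change = protein_change)
  if (chrom != tx$chrom) return(ann("noncoding"))
  ctx <- locate_variant(chrom, pos, ref, tx, splice_window = splice_window)
  if (ctx == "splice_region") return(ann("splice_site"))
  if (ctx != "coding") return(ann("noncoding"))

  s <- pmax(tx$exon_starts, tx$cds_start)
  e <- pmin(tx$exon_ends, tx$cds_end)
  keep <- s < e
  s <- s[keep]; e <- e[keep]
  off0 <- cumsum(c(0L, (e - s)[-length(s)]))
  v0 <- as.integer(pos) - 1L
  v1 <- v0 + nchar(ref)
  i <- which(s <= v0 & v1 <= e)
  if (length(i) != 1L) {
    # Straddles a CDS/intron or exon/exon boundary: effect on the coding
    # sequence is not a simple substring edit; report by length change.
    ld <- nchar(alt) - nchar(ref)
    if (ld %% 3L != 0L) return(ann("frameshift", "p.?"))
    return(ann(if (ld == 0L) "missense" else "inframe_indel", "p.?"))
  }
  cds_ref <- coding_genomic_seq(tx, genome)
  off <- off0[i] + (v0 - s[i])
  obs <- substr(cds_ref, off + 1L, off + nchar(ref))
  if (obs != ref)
    warning("reference allele mismatch at ", chrom, ":", pos,
            " (genome has '", obs, "', variant says '", ref, "')")
  cds_alt <- paste0(substr(cds_ref, 1L, off), alt,
                    substr(cds_ref, off + nchar(ref) + 1L, nchar(cds_ref)))
  if (tx$strand == "-") {
    # translate 3'->5' with reverse complement; re-express the edit
    # offset in coding coordinates
    off_cd <- nchar(cds_ref) - (off + nchar(ref))
    cds_ref <- revcomp(cds_ref)
    cds_alt <- revcomp(cds_alt)
  } else {
    off_cd <- off
  }
  ref_p <- translate_dna(cds_ref)
  if (substr(cds_ref, 1L, 3L) != "ATG")
    warning("transcript ", tx$transcript_id, ": CDS does not start with ATG")
  if (first_stop(ref_p) == Inf)
    warning("transcript ", tx$transcript_id, ": CDS lacks a stop codon")
  alt_p <- translate_dna(cds_alt)
  codon1 <- off_cd %/% 3L + 1L               # first affected codon
  ld <- nchar(alt) - nchar(ref)

  if (ld %% 3L != 0L)
    return(ann("frameshift", sprintf("p.%s%dfs", aa_at(ref_p, codon1),
                                     codon1)))
  s_ref <- first_stop(ref_p)
  s_alt <- first_stop(alt_p)
  # an in-frame indel shifts the reference stop by ld/3 codons; only a
  # stop upstream of that expected position is a new (nonsense) stop
  if (s_alt < s_ref + ld %/% 3L)
    return(ann("nonsense", sprintf("p.%s%dTer", aa_at(ref_p, s_alt), s_alt)))
  if (ld != 0L) {
    verb <- if (ld < 0L) "del" else "ins"
    return(ann("inframe_indel", sprintf("p.%s%d%s", aa_at(ref_p, codon1),
                                        codon1, verb)))
  }
  trim <- function(p, s) if (is.finite(s)) substr(p, 1L, s) else p
  rp <- trim(ref_p, s_ref); ap <- trim(alt_p, s_ref)
  if (rp == ap)
    return(ann("synonymous", sprintf("p.%s%d=", aa_at(ref_p, codon1),
                                     codon1)))
  d <- which(strsplit(rp, "")[[1L]] != strsplit(ap, "")[[1L]])[1L]
  ann("missense", sprintf("p.%s%d%s", aa_at(rp, d), d, aa_at(ap, d)))
}

#' Aggregate per-transcript consequences to a gene-level category
#'
#' A variant receives the most severe category it has on any annotated
#' transcript, with severity order frameshift > nonsense > splice_site >
#' missense > inframe_indel > synonymous > noncoding.
#'
#' @param categories character vector of per-transcript categories.
#' @return single gene-level category.
#' @export
aggregate_gene_category <- function(categories) {
  if (length(categories) == 0L) stop("no per-transcript annotations")
  bad <- setdiff(categories, CONSEQUENCE_SEVERITY)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  CONSEQUENCE_SEVERITY[min(match(categories, CONSEQUENCE_SEVERITY))]
}

#' Bin a PolyPhen-style score
#'
#' Scores above 0.85 are probably damaging, scores from 0.15 to 0.85
#' (inclusive at both bounds) possibly damaging, scores below 0.15 benign;
#' missing scores map to `"none"`.
#'
#' @param score numeric vector in `[0, 1]`, `NA` allowed.
#' @return character vector of bins.
#' @export
bin_polyphen <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 1)))
    stop("PolyPhen score outside [0, 1]")
  out <- rep("none", length(score))
  out[!is.na(score) & score > 0.85] <- "probably_damaging"
  out[!is.na(score) & score >= 0.15 & score <= 0.85] <- "possibly_damaging"
  out[!is.na(score) & score < 0.15] <- "benign"
  out
}

#' Assign the nonexclusive reporting classes of a variant
#'
#' Three nonexclusive classes over nonsynonymous variants: deleterious
#' (gene-level frameshift, nonsense or splice-site), HGMD-listed, and VUS
#' (nonsynonymous variants in neither other class); plus a novel flag for
#' variants absent from the known-variant table. Synonymous and noncoding
#' variants carry no class flags and are excluded from the nonsynonymous
#' set entirely.
#'
#' @param gene_category vector of gene-level categories
#'   ([aggregate_gene_category()]).
#' @param in_hgmd logical vector: listed in the HGMD-like table.
#' @param known logical vector: present in the known-variant (dbSNP-like)
#'   table.
#' @return data.frame with logical columns `nonsynonymous`, `deleterious`,
#'   `hgmd`, `vus`, `novel`.
#' @export
assign_classes <- function(gene_category, in_hgmd, known) {
  nonsyn <- gene_category %in% c("missense", "nonsense", "frameshift",
                                 "splice_site", "inframe_indel")
  del <- nonsyn & gene_category %in% c("frameshift", "nonsense",
                                       "splice_site")
  hg <- nonsyn & in_hgmd
  data.frame(nonsynonymous = nonsyn,
             deleterious = del,
             hgmd = hg,
             vus = nonsyn & !del & !hg,
             novel = nonsyn & !known)
}

#' Normalize a variant to its left-aligned minimal representation
#'
#' Trims shared trailing then leading bases (keeping a VCF-style anchor
#' base for indels) and left-aligns indels against the reference contig.
#'
#' @param chrom,pos,ref,alt variant in VCF convention.
#' @param genome contig sequences (see [classify_consequence()]).
#' @return list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, genome) {
  seq <- genome_seq(genome, chrom)
  pos <- as.integer(pos)
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        !(nr == 1L && na == 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
    } else if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos == 1L) stop("cannot left-align at contig start")
      pos <- pos - 1L
      b <- substr(seq, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Infer the variant type from its alleles
#'
#' @param ref,alt allele strings.
#' @return `"SNV"`, `"insertion"`, `"deletion"` or `"MNV"`.
#' @export
variant_type <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV",
         ifelse(na > nr, "insertion",
                ifelse(nr > na, "deletion", "MNV")))
}
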