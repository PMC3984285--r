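# Transcript and gene-model geometry. Internal coordinates are 0-based
# half-open; VCF positions are converted from 1-based on ingest.

#' Construct a transcript
#'
#' @param transcript_id character scalar.
#' @param gene_symbol character scalar.
#' @param chrom chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of 0-based half-open exon
#'   bounds, in genomic order.
#' @param cds_start,cds_end 0-based half-open bounds of the translated
#'   region (genomic coordinates, independent of strand).
#' @return object of class `transcript`.
#' @export
transcript <- function(transcript_id, gene_symbol, chrom, strand,
                       exon_starts, exon_ends, cds_start, cds_end) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L,
            strand %in% c("+", "-"),
            nzchar(chrom))
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o])
  exon_ends <- as.integer(exon_ends[o])
  if (any(exon_starts >= exon_ends))
    stop("transcript ", transcript_id, ": exon with start >= end")
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)]))
    stop("transcript ", transcript_id, ": overlapping exons")
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (cds_start < exon_starts[1L] || cds_end > exon_ends[length(exon_ends)])
    stop("transcript ", transcript_id, ": CDS outside exon span")
  structure(list(transcript_id = transcript_id,
                 gene_symbol = gene_symbol,
                 chrom = chrom, strand = strand,
                 exon_starts = exon_starts, exon_ends = exon_ends,
                 cds_start = cds_start, cds_end = cds_end),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%d-%d [%s], %d exon(s), CDS %d-%d>\n",
              x$transcript_id, x$gene_symbol, x$chrom,
              x$exon_starts[1L], x$exon_ends[length(x$exon_ends)],
              x$strand, length(x$exon_starts), x$cds_start, x$cds_end))
  invisible(x)
}

# Exonic intervals clipped to the CDS bounds, as an IRanges (1-based
# closed, the IRanges convention).
cds_ranges <- function(tx) {
  s <- pmax(tx$exon_starts, tx$cds_start)
  e <- pmin(tx$exon_ends, tx$cds_end)
  keep <- s < e
  IRanges::IRanges(start = s[keep] + 1L, end = e[keep])
}

#' Coding length of a gene model
#'
#' Number of distinct genomic bases predicted to be translated in any of
#' the gene's transcripts: the size of the union, across transcripts, of
#' exonic positions within each transcript's CDS bounds.
#'
#' @param g a `gene_model`.
#' @return integer, bases.
#' @export
coding_length <- function(g) {
  stopifnot(inherits(g, "gene_model"))
  rl <- lapply(g$transcripts, cds_ranges)
  sum(IRanges::width(IRanges::reduce(do.call(c, rl))))
}

#' Construct a gene model
#'
#' @param gene_symbol character scalar.
#' @param transcripts list of [transcript()] objects sharing `gene_symbol`.
#' @param gene_type one of `"oncogene"`, `"tumor_suppressor"`,
#'   `"predisposition"`, `"unknown"`.
#' @param census_reason free-text annotation for why the gene is on the
#'   cancer-gene list.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_symbol, transcripts,
                       gene_type = c("unknown", "oncogene",
                                     "tumor_suppressor", "predisposition"),
                       census_reason = "") {
  gene_type <- match.arg(gene_type)
  stopifnot(length(transcripts) >= 1L)
  syms <- vapply(transcripts, `[[`, "", "gene_symbol")
  if (!all(syms == gene_symbol))
    stop("gene model ", gene_symbol, ": transcript with mismatching symbol")
  structure(list(gene_symbol = gene_symbol, transcripts = transcripts,
                 gene_type = gene_type, census_reason = census_reason),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s (%s): %d transcript(s), coding length %d bp>\n",
              x$gene_symbol, x$gene_type, length(x$transcripts),
              coding_length(x)))
  invisible(x)
}

parse_ucsc_ints <- function(x, line, field) {
  v <- suppressWarnings(as.integer(strsplit(sub(",+$", "", x), ",")[[1L]]))
  if (length(v) == 0L || anyNA(v))
    stop("transcript table line ", line, ": malformed ", field, " '", x, "'")
  v
}

#' Read a knownGene-style transcript table
#'
#' Expects a TSV with columns `name`, `geneSymbol`, `chrom`, `strand`,
#' `txStart`, `txEnd`, `cdsStart`, `cdsEnd`, `exonCount`, `exonStarts`,
#' `exonEnds` (exon columns comma-separated, UCSC style). Coordinates are
#' 0-based half-open.
#'
#' @param path TSV file path.
#' @return list of [transcript()] objects.
#' @export
read_transcripts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "geneSymbol", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("transcript table missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    es <- parse_ucsc_ints(row$exonStarts, i + 1L, "exonStarts")
    ee <- parse_ucsc_ints(row$exonEnds, i + 1L, "exonEnds")
    if (length(es) != row$exonCount || length(ee) != row$exonCount)
      stop("transcript table line ", i + 1L, ": exonCount disagrees with ",
           "exon coordinate lists")
    transcript(row$name, row$geneSymbol, row$chrom, row$strand,
               es, ee, row$cdsStart, row$cdsEnd)
  })
}

#' Load gene models from a transcript table and a gene list
#'
#' Joins a knownGene-style transcript table with a cancer-gene list
#' (columns `symbol`, `gene_type`, and optionally `census_reason`). Genes
#' on the list with no transcript in the table are reported via a warning
#' and returned in the `"missing_genes"` attribute rather than silently
#' dropped.
#'
#' @param transcript_table path to transcript TSV (see
#'   [read_transcripts()]).
#' @param gene_list path to gene-list TSV.
#' @return named list of [gene_model()] objects with attribute
#'   `missing_genes`.
#' @export
load_gene_models <- function(transcript_table, gene_list) {
  txs <- read_transcripts(transcript_table)
  genes <- read.delim(gene_list, stringsAsFactors = FALSE)
  if (!all(c("symbol", "gene_type") %in% names(genes)))
    stop("gene list must have columns 'symbol' and 'gene_type'")
  if (is.null(genes$census_reason)) genes$census_reason <- ""
  tx_sym <- vapply(txs, `[[`, "", "gene_symbol")
  models <- list()
  missing <- character()
  for (i in seq_len(nrow(genes))) {
    sym <- genes$symbol[i]
    sel <- txs[tx_sym == sym]
    if (length(sel) == 0L) {
      missing <- c(missing, sym)
      next
    }
    models[[sym]] <- gene_model(sym, sel, gene_type = genes$gene_type[i],
                                census_reason = genes$census_reason[i])
  }
  if (length(missing))
    warning("gene(s) absent from transcript table: ",
            paste(missing, collapse = ", "))
  attr(models, "missing_genes") <- missing
  models
}

#' Locate a variant relative to a transcript
#'
#' Classifies the site context of a variant's reference-allele span:
#' `"coding"` if it intersects CDS exonic bases, `"splice_region"` if it
#' intersects the first or last `splice_window` intronic bases of any
#' intron, `"intronic"` if it falls elsewhere within an intron, otherwise
#' `"noncoding"` (UTR exonic or outside the transcript).
#'
#' @param chrom,pos,ref variant site: chromosome, 1-based VCF position,
#'   reference allele string.
#' @param tx a [transcript()].
#' @param splice_window intronic bases at each end of an intron counted as
#'   splice region (canonical donor/acceptor default of 2).
#' @return one of `"coding"`, `"splice_region"`, `"intronic"`,
#'   `"noncoding"`.
#' @export
locate_variant <- function(chrom, pos, ref, tx, splice_window = 2L) {
  if (chrom != tx$chrom)
    stop("variant on ", chrom, " but transcript on ", tx$chrom)
  v0 <- as.integer(pos) - 1L                 # 0-based start
  v1 <- v0 + nchar(ref)                      # 0-based exclusive end
  span <- IRanges::IRanges(v0 + 1L, v1)
  if (length(IRanges::findOverlaps(span, cds_ranges(tx))) > 0L)
    return("coding")
  n <- length(tx$exon_starts)
  if (n > 1L) {
    is <- tx$exon_ends[-n]                   # intron starts (0-based)
    ie <- tx$exon_starts[-1L]                # intron ends (0-based excl)
    w <- pmin(splice_window, ie - is)
    donor <- IRanges::IRanges(is + 1L, is + w)
    accept <- IRanges::IRanges(ie - w + 1L, ie)
    if (length(IRanges::findOverlaps(span, c(donor, accept))) > 0L)
      return("splice_region")
    introns <- IRanges::IRanges(is + 1L, ie)
    if (length(IRanges::findOverlaps(span, introns)) > 0L)
      return("intronic")
  }
  "noncoding"
}
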