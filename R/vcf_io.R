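# VCF v4.1 interchange for genotype sets (GT:AD:DP), via vcfR.

#' Write a genotype set as VCF v4.1
#'
#' Emits one biallelic record per variant with GT, AD and DP per sample.
#' Masked/no-call genotypes are written as `./.` (depths retained).
#'
#' @param gs a [genotype_set()].
#' @param path output path; a `.gz` suffix writes bgzip-style gzip output
#'   (vcfR convention), anything else plain text.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gs, path) {
  stopifnot(inherits(gs, "genotype_set"))
  n <- nrow(gs$variants)
  meta <- c("##fileformat=VCFv4.1",
            "##source=germvar",
            paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                   "Description=\"Genotype\">"),
            paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                   "Description=\"Allelic depths\">"),
            paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                   "Description=\"Total depth\">"))
  gt_str <- matrix("./.", n, ncol(gs$dosage))
  d <- gs$dosage
  gt_str[!is.na(d) & d == 0L] <- "0/0"
  gt_str[!is.na(d) & d == 1L] <- "0/1"
  gt_str[!is.na(d) & d >= 2L] <- "1/1"
  cells <- paste(gt_str,
                 paste(gs$ad_ref, gs$ad_alt, sep = ","),
                 gs$dp, sep = ":")
  body <- matrix(cells, n, ncol(gs$dosage),
                 dimnames = list(NULL, gs$subjects$subject_id))
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", gs$subjects$subject_id),
                  collapse = "\t")
  fixed <- cbind(gs$variants$chrom, gs$variants$pos, gs$variants$id,
                 gs$variants$ref, gs$variants$alt, ".", ".", ".",
                 "GT:AD:DP")
  lines <- c(meta, header,
             apply(cbind(fixed, body), 1L, paste, collapse = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype set
#'
#' Parses GT (biallelic, diploid or hemizygous), AD and DP fields with
#' vcfR. Multi-allelic records must be decomposed upstream.
#'
#' @param path VCF path (plain or gzipped).
#' @param subjects optional data.frame with `subject_id` (+ `sex`,
#'   `group`) to attach; defaults to the VCF sample columns.
#' @return a [genotype_set()].
#' @export
read_vcf_genotypes <- function(path, subjects = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic records present; decompose before reading")
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         id = fix[, "ID"], stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  alt_count <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) {
      if (anyNA(x) || any(x == ".")) NA_integer_
      else sum(as.integer(x) > 0L)
    }, 0L)
  }
  dosage <- matrix(alt_count(as.vector(gt)), nrow(gt), ncol(gt))
  sp <- strsplit(as.vector(ad), ",", fixed = TRUE)
  ad_ref <- matrix(vapply(sp, function(x)
    suppressWarnings(as.integer(x[1L])), 0L), nrow(gt), ncol(gt))
  ad_alt <- matrix(vapply(sp, function(x)
    suppressWarnings(as.integer(x[2L])), 0L), nrow(gt), ncol(gt))
  if (is.null(subjects))
    subjects <- data.frame(subject_id = colnames(gt),
                           stringsAsFactors = FALSE)
  genotype_set(variants, subjects, dosage, ad_ref, ad_alt,
               matrix(as.integer(dp), nrow(gt), ncol(gt)))
}

#' Write a synthetic cohort's file bundle
#'
#' Serialises the cohort to its on-disk interchange formats: a VCF v4.1
#' (GT:AD:DP), a knownGene-style transcript TSV, a gene-list TSV, an
#' ancestral-panel TSV, an annotation TSV, a subjects TSV and a truth
#' JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             transcripts = file.path(dir, "transcripts.tsv"),
             genes = file.path(dir, "genes.tsv"),
             panel = file.path(dir, "panel.tsv"),
             panel_dosage = file.path(dir, "panel_dosage.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             subjects = file.path(dir, "subjects.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(cohort$genotypes, paths[["vcf"]])
  tsv <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  tsv(cohort$transcript_table, paths[["transcripts"]])
  tsv(cohort$gene_table, paths[["genes"]])
  pan <- cbind(cohort$panel$markers,
               setNames(as.data.frame(cohort$panel$freqs),
                        paste0("f_", colnames(cohort$panel$freqs))))
  tsv(pan, paths[["panel"]])
  tsv(as.data.frame(cohort$panel_dosage), paths[["panel_dosage"]])
  tsv(cohort$annotations, paths[["annotations"]])
  tsv(cohort$genotypes$subjects, paths[["subjects"]])
  tr <- cohort$truth
  tr$planted_lowdepth <- as.data.frame(tr$planted_lowdepth)
  jsonlite::write_json(tr, paths[["truth"]], digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", matrix = "rowmajor")
  paths
}
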