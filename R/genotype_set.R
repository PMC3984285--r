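# In-memory container for multi-sample genotypes with per-allele depths.
# Sites are rows, subjects columns; dosage is the alt-allele count per
# genotype (0/1/2 autosomal, 0/1 hemizygous; NA = no-call).

#' Construct a genotype set
#'
#' @param variants data.frame with at least `chrom`, `pos`, `ref`, `alt`
#'   (VCF convention, biallelic records; multi-allelic sites must be
#'   decomposed upstream) and optionally `id` and `gene`.
#' @param subjects data.frame with `subject_id` and optionally `sex`
#'   (`"F"`/`"M"`, needed for chromosome-X allele counting) and `group`.
#' @param dosage integer matrix (sites x subjects) of alt-allele dosages,
#'   `NA` for no-calls.
#' @param ad_ref,ad_alt,dp integer matrices of per-allele read depths and
#'   total depth, same shape as `dosage`.
#' @return object of class `genotype_set`.
#' @export
genotype_set <- function(variants, subjects, dosage, ad_ref, ad_alt, dp) {
  stopifnot(is.data.frame(variants), is.data.frame(subjects),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            "subject_id" %in% names(subjects),
            nrow(dosage) == nrow(variants),
            ncol(dosage) == nrow(subjects),
            identical(dim(dosage), dim(ad_ref)),
            identical(dim(dosage), dim(ad_alt)),
            identical(dim(dosage), dim(dp)))
  if (is.null(variants$id))
    variants$id <- paste0(variants$chrom, ":", variants$pos, "_",
                          variants$ref, ">", variants$alt)
  if (is.null(subjects$sex)) subjects$sex <- "F"
  rownames(dosage) <- rownames(ad_ref) <- rownames(ad_alt) <-
    rownames(dp) <- variants$id
  colnames(dosage) <- colnames(ad_ref) <- colnames(ad_alt) <-
    colnames(dp) <- subjects$subject_id
  structure(list(variants = variants, subjects = subjects,
                 dosage = dosage, ad_ref = ad_ref, ad_alt = ad_alt,
                 dp = dp),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set: %d site(s) x %d subject(s), %.1f%% called>\n",
              nrow(x$variants), nrow(x$subjects),
              100 * mean(!is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_set <- function(x) c(nrow(x$variants), nrow(x$subjects))

# Subset a genotype set by site index (logical or integer).
subset_sites <- function(gs, keep) {
  genotype_set(gs$variants[keep, , drop = FALSE], gs$subjects,
               gs$dosage[keep, , drop = FALSE],
               gs$ad_ref[keep, , drop = FALSE],
               gs$ad_alt[keep, , drop = FALSE],
               gs$dp[keep, , drop = FALSE])
}

# Depth of the least-supported allele actually carried in each genotype:
# both alleles for a het, the single carried allele for a hom.
min_carried_depth <- function(gs) {
  d <- gs$dosage
  out <- matrix(NA_integer_, nrow(d), ncol(d), dimnames = dimnames(d))
  het <- !is.na(d) & d == 1L
  homr <- !is.na(d) & d == 0L
  homa <- !is.na(d) & d >= 2L
  out[het] <- pmin(gs$ad_ref[het], gs$ad_alt[het])
  out[homr] <- gs$ad_ref[homr]
  out[homa] <- gs$ad_alt[homa]
  out
}
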