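# Two-stage genotype reliability filter: a position filter on cohort call
# rate and average fractional allele depth, then a genotype filter on the
# minimum carried-allele depth. Thresholds are published constants from
# the decision-tree model trained on orthogonally validated genotypes;
# no re-training happens here.

#' Default filter thresholds
#'
#' Position filter: exclude sites with cohort call rate < 0.80 or average
#' fractional allele depth <= 0.295. Genotype filter: mask calls whose
#' minimum carried-allele depth is <= 11.
#' @return named list of thresholds.
#' @export
filter_thresholds <- function() {
  list(min_call_rate = 0.80, min_frac_depth = 0.295, min_allele_depth = 11L)
}

#' Per-site quality summary
#'
#' Computes, for every site, the cohort call rate (called genotypes over
#' subjects) and the average fractional allele depth: the mean over called
#' genotypes with positive total depth of the depth of the least-supported
#' carried allele divided by the total depth (for homozygous calls, the
#' carried allele's fraction).
#'
#' @param gs a [genotype_set()].
#' @return data.frame with `id`, `call_rate`,
#'   `avg_fractional_allele_depth` (NaN when no called genotype has
#'   positive depth).
#' @export
site_quality <- function(gs) {
  stopifnot(inherits(gs, "genotype_set"))
  n_sub <- nrow(gs$subjects)
  called <- !is.na(gs$dosage)
  call_rate <- rowSums(called) / n_sub
  md <- min_carried_depth(gs)
  frac <- md / gs$dp
  frac[!called | !is.finite(frac)] <- NA
  avg_frac <- rowMeans(frac, na.rm = TRUE)
  data.frame(id = gs$variants$id, call_rate = call_rate,
             avg_fractional_allele_depth = avg_frac,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Position filter
#'
#' @param sq data.frame from [site_quality()].
#' @param min_call_rate sites with call rate strictly below this are
#'   excluded (default 0.80).
#' @param min_frac_depth sites with average fractional allele depth at or
#'   below this are excluded (default 0.295; note the inclusive bound).
#' @return logical vector, `TRUE` = keep.
#' @export
apply_position_filter <- function(sq, min_call_rate = 0.80,
                                  min_frac_depth = 0.295) {
  keep <- sq$call_rate >= min_call_rate &
    !is.na(sq$avg_fractional_allele_depth) &
    sq$avg_fractional_allele_depth > min_frac_depth
  keep & !is.na(keep)
}

#' Genotype filter
#'
#' Masks called genotypes whose minimum carried-allele depth is at or
#' below `min_allele_depth` (both alleles for a het, the single carried
#' allele for a hom). Masked genotypes are treated as no-calls downstream.
#'
#' @param gs a [genotype_set()].
#' @param min_allele_depth inclusive masking bound (default 11: a depth
#'   of 12 passes).
#' @return logical matrix, `TRUE` = masked.
#' @export
apply_genotype_filter <- function(gs, min_allele_depth = 11L) {
  md <- min_carried_depth(gs)
  masked <- !is.na(gs$dosage) & (is.na(md) | md <= min_allele_depth)
  masked
}

#' Apply the full two-stage filter
#'
#' The position filter is evaluated first on raw calls; the genotype
#' filter then masks individual calls at the retained sites.
#'
#' @param gs a [genotype_set()].
#' @param thresholds named list as from [filter_thresholds()].
#' @return list of class `filter_result`: `genotypes` (the filtered
#'   [genotype_set()], masked calls set to `NA`), `site_quality`,
#'   `sites_kept` (logical over input sites), `mask_report` (data.frame
#'   subject/site/reason for every masked genotype and excluded site).
#' @export
filter_genotypes <- function(gs, thresholds = filter_thresholds()) {
  sq <- site_quality(gs)
  keep <- apply_position_filter(sq, thresholds$min_call_rate,
                                thresholds$min_frac_depth)
  n_exc <- sum(!keep)
  excluded <- data.frame(subject_id = rep(NA_character_, n_exc),
                         id = sq$id[!keep],
                         reason = rep("position_filter", n_exc))
  kept <- subset_sites(gs, keep)
  masked <- apply_genotype_filter(kept, thresholds$min_allele_depth)
  idx <- which(masked, arr.ind = TRUE)
  mask_rep <- data.frame(
    subject_id = kept$subjects$subject_id[idx[, 2L]],
    id = kept$variants$id[idx[, 1L]],
    reason = rep("genotype_filter", nrow(idx)))
  kept$dosage[masked] <- NA_integer_
  structure(list(genotypes = kept, site_quality = sq, sites_kept = keep,
                 mask_report = rbind(excluded, mask_rep)),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf(paste0("<filter_result: %d/%d site(s) kept, ",
                     "%d genotype(s) masked>\n"),
              sum(x$sites_kept), length(x$sites_kept),
              sum(x$mask_report$reason == "genotype_filter")))
  invisible(x)
}

#' Estimate post-filter genotype error rates by cross-validation
#'
#' Stratified k-fold cross-validation of the fixed genotype filter against
#' a validated call set. In each held-out fold, the false-negative rate is
#' the fraction of truth-positive (validated variant) calls that are
#' masked by the filter or called homozygous reference, and the
#' false-positive rate is the fraction of truth-negative calls that pass
#' the filter with a variant genotype. Rates are pooled over held-out
#' folds (each call is held out exactly once) with Clopper-Pearson 95%
#' intervals.
#'
#' @param calls data.frame with columns `truth` (`"variant"` /
#'   `"non_variant"`), `dosage`, `ad_ref`, `ad_alt`, `dp`.
#' @param k number of folds (default 10).
#' @param seed integer RNG seed for fold assignment.
#' @param min_allele_depth genotype-filter threshold.
#' @return list with `false_negative_rate`, `false_positive_rate`, their
#'   95% confidence intervals, counts, and the per-call fold assignment.
#' @export
estimate_error_rates <- function(calls, k = 10L, seed,
                                 min_allele_depth = 11L) {
  stopifnot(k >= 2L, all(c("truth", "dosage", "ad_ref", "ad_alt",
                           "dp") %in% names(calls)))
  if (missing(seed)) stop("seed is required")
  classes <- c("variant", "non_variant")
  if (!all(classes %in% calls$truth))
    stop("both truth classes must be present")
  if (any(table(calls$truth) < k))
    stop("need at least k entries per truth class")
  set.seed(seed)
  fold <- integer(nrow(calls))
  for (cl in classes) {
    i <- which(calls$truth == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  md <- ifelse(calls$dosage == 1L, pmin(calls$ad_ref, calls$ad_alt),
               ifelse(calls$dosage == 0L, calls$ad_ref, calls$ad_alt))
  passes <- !is.na(calls$dosage) & md > min_allele_depth
  fn <- fp <- 0L; n_pos <- n_neg <- 0L
  for (f in seq_len(k)) {
    held <- fold == f
    pos <- held & calls$truth == "variant"
    neg <- held & calls$truth == "non_variant"
    fn <- fn + sum(pos & (!passes | calls$dosage == 0L), na.rm = TRUE)
    fp <- fp + sum(neg & passes & calls$dosage > 0L, na.rm = TRUE)
    n_pos <- n_pos + sum(pos)
    n_neg <- n_neg + sum(neg)
  }
  ci <- function(x, n) as.numeric(binom.test(x, n)$conf.int)
  list(false_negative_rate = fn / n_pos,
       false_positive_rate = fp / n_neg,
       fn_ci = ci(fn, n_pos), fp_ci = ci(fp, n_neg),
       n_positive = n_pos, n_negative = n_neg, fold = fold)
}
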