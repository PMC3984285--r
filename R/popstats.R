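# Ancestry-stratified allele counts and the frequency statistics built on
# them: test selection (chi-squared vs simulated Fisher), between-group
# difference tests, major/minor allele flips, group-specific common
# variants, and reference-minor-allele positions.

#' Ancestry-stratified allele counts and frequencies
#'
#' Counts alt alleles and total called alleles per variant in each
#' subpopulation, excluding masked/no-call genotypes from the denominator
#' and excluding the `"Other"` group (it is not an ancestry-based
#' population). Autosomal sites contribute 2 alleles per called subject;
#' on chromosome X outside the pseudo-autosomal regions males contribute
#' a single allele (dosage > 0 counts as one alt allele) and females two.
#'
#' @param gs a filtered [genotype_set()]; `gs$subjects$sex` is used for
#'   chromosome-X sites.
#' @param groups factor of subpopulation labels per subject (levels as
#'   [cluster_subjects()]).
#' @param x_chrom chromosome names treated as X.
#' @param par list of pseudo-autosomal regions as `cbind(start, end)`
#'   1-based inclusive (treated as diploid), or `NULL`.
#' @return list of class `group_freq_table`: `alt` and `total` (variants x
#'   groups count matrices), `freq`, `overall_maf` (cohort minor-allele
#'   frequency over the counted groups), `variants`.
#' @export
group_allele_counts <- function(gs, groups, x_chrom = c("chrX", "X"),
                                par = NULL) {
  stopifnot(inherits(gs, "genotype_set"),
            length(groups) == nrow(gs$subjects))
  groups <- factor(groups, levels = SUBPOP_LABELS)
  use_groups <- setdiff(SUBPOP_LABELS, "Other")
  d <- gs$dosage
  is_x <- gs$variants$chrom %in% x_chrom
  if (!is.null(par) && any(is_x)) {
    inpar <- rep(FALSE, nrow(d))
    for (r in seq_len(nrow(par)))
      inpar <- inpar | (gs$variants$pos >= par[r, 1L] &
                        gs$variants$pos <= par[r, 2L])
    is_x <- is_x & !inpar
  }
  male <- gs$subjects$sex == "M"
  ploidy <- matrix(2L, nrow(d), ncol(d))
  ploidy[is_x, male] <- 1L
  dd <- d
  dd[is_x, male] <- pmin(dd[is_x, male], 1L)    # hemizygous: 0/1 alleles
  called <- !is.na(dd)
  dd[!called] <- 0L
  pl <- ploidy * called
  alt <- matrix(0, nrow(d), length(use_groups),
                dimnames = list(gs$variants$id, use_groups))
  total <- alt
  for (g in use_groups) {
    sel <- which(!is.na(groups) & groups == g)
    if (length(sel)) {
      alt[, g] <- rowSums(dd[, sel, drop = FALSE])
      total[, g] <- rowSums(pl[, sel, drop = FALSE])
    }
  }
  freq <- alt / total
  af <- rowSums(alt) / rowSums(total)
  structure(list(alt = alt, total = total, freq = freq,
                 overall_maf = pmin(af, 1 - af),
                 variants = gs$variants),
            class = "group_freq_table")
}

#' @export
print.group_freq_table <- function(x, ...) {
  cat(sprintf("<group_freq_table: %d variant(s) x %d group(s)>\n",
              nrow(x$alt), ncol(x$alt)))
  invisible(x)
}

#' Classify a minor allele frequency as rare/intermediate/common
#'
#' Rare: MAF < 1%. Common: MAF > 5%. Anything between is intermediate.
#'
#' @param maf numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @return character vector.
#' @export
classify_rarity <- function(maf) {
  if (any(maf > 0.5 + 1e-12, na.rm = TRUE))
    stop("MAF > 0.5 supplied; pass the minor-allele frequency")
  out <- rep("intermediate", length(maf))
  out[maf < 0.01] <- "rare"
  out[maf > 0.05] <- "common"
  out[is.na(maf)] <- NA_character_
  out
}

#' Choose the between-group frequency test for a contingency table
#'
#' The chi-squared test is used when every expected cell count under
#' independence is strictly greater than 1; otherwise Fisher's exact test
#' with simulated p-values. Degenerate tables (an all-zero allele column)
#' fall to the simulated Fisher with a warning.
#'
#' @param tab groups x 2 matrix of (alt, ref) allele counts.
#' @return `"chi_squared"` or `"fisher_simulated"`.
#' @export
select_test <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(cs == 0)) {
    warning("degenerate table (empty allele column); using simulated Fisher")
    return("fisher_simulated")
  }
  expected <- outer(rs, cs) / sum(tab)
  if (all(expected[rs > 0, ] > 1)) "chi_squared" else "fisher_simulated"
}

# Log probability of an R x C table under the fixed-margins
# (multivariate hypergeometric) null.
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Monte-Carlo Fisher test on a contingency table
#'
#' Samples `n_sim` tables with the observed margins fixed and reports
#' `p = (1 + #\{simulated table probability <= observed\}) / (n_sim + 1)`,
#' the add-one-corrected two-sided exact test estimate.
#'
#' @param tab R x C count matrix (zero-margin rows/columns are dropped).
#' @param n_sim Monte-Carlo replicates.
#' @param seed integer RNG seed.
#' @return list with `p_value` and `n_simulations`.
#' @export
simulated_fisher <- function(tab, n_sim = 10000L, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_sim < 1000L) warning("fewer than 1000 Fisher simulations")
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (any(dim(tab) < 2L)) return(list(p_value = 1, n_simulations = 0L))
  set.seed(seed)
  lp_obs <- log_table_prob(tab)
  sims <- r2dtable(n_sim, rowSums(tab), colSums(tab))
  lp <- vapply(sims, log_table_prob, 0)
  hits <- sum(lp <= lp_obs + 1e-7)
  list(p_value = (1 + hits) / (n_sim + 1), n_simulations = n_sim)
}

#' Test a between-group allele-frequency difference
#'
#' Applies [select_test()] and runs either the Pearson chi-squared test
#' (no continuity correction, df = groups - 1) or the Monte-Carlo Fisher
#' test with fixed margins.
#'
#' @param tab groups x 2 matrix of (alt, ref) allele counts; groups with
#'   zero total are dropped.
#' @param n_sim simulated-Fisher replicates.
#' @param seed integer RNG seed (used only on the simulated path).
#' @return list of class `freq_test_result`: `test_used`, `p_value`,
#'   `n_simulations`, `statistic` (chi-squared only).
#' @export
test_freq_difference <- function(tab, n_sim = 10000L, seed = 1L) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L) stop("need at least 2 groups with nonzero totals")
  choice <- select_test(tab)
  if (choice == "chi_squared") {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    res <- list(test_used = "chi_squared",
                p_value = min(1, max(ct$p.value, .Machine$double.xmin)),
                n_simulations = NA_integer_,
                statistic = unname(ct$statistic))
  } else {
    sf <- simulated_fisher(tab, n_sim = n_sim, seed = seed)
    res <- list(test_used = "fisher_simulated", p_value = sf$p_value,
                n_simulations = sf$n_simulations, statistic = NA_real_)
  }
  structure(res, class = "freq_test_result")
}

# One-sided exact binomial test of an allele count against frequency 0.5,
# directed at the observed side.
binom_vs_half <- function(x, n) {
  if (n == 0L) return(1)
  alt <- if (x / n >= 0.5) "greater" else "less"
  binom.test(x, n, p = 0.5, alternative = alt)$p.value
}

#' Detect a major/minor allele flip between subpopulations
#'
#' A variant is a flip when the minimum group frequency is below 0.5, the
#' maximum is above 0.5, the two extreme groups differ by a one-sided
#' Fisher's exact test on their 2x2 allele table, and each extreme
#' frequency differs from 0.5 by a one-sided exact binomial test, all at
#' level `alpha`. Groups with zero total alleles are excluded from the
#' min/max search.
#'
#' @param alt,total named numeric vectors of per-group alt and total
#'   allele counts for one variant.
#' @param alpha significance level (default 0.05).
#' @param frequency_only if `TRUE`, only the frequency component
#'   (min < 0.5 < max) is applied.
#' @return list of class `flip_result`: `is_flip`, `min_group`,
#'   `max_group`, `p_pairwise`, `p_min_vs_half`, `p_max_vs_half`.
#' @export
detect_flip <- function(alt, total, alpha = 0.05, frequency_only = FALSE) {
  use <- total > 0
  if (sum(use) < 2L)
    return(structure(list(is_flip = FALSE, min_group = NA_character_,
                          max_group = NA_character_, p_pairwise = NA_real_,
                          p_min_vs_half = NA_real_,
                          p_max_vs_half = NA_real_),
                     class = "flip_result"))
  f <- alt[use] / total[use]
  gmin <- names(f)[which.min(f)]
  gmax <- names(f)[which.max(f)]
  freq_ok <- f[gmin] < 0.5 && f[gmax] > 0.5
  p_pair <- p_min <- p_max <- NA_real_
  if (!frequency_only && freq_ok) {
    t22 <- rbind(c(alt[gmin], total[gmin] - alt[gmin]),
                 c(alt[gmax], total[gmax] - alt[gmax]))
    p_pair <- fisher.test(t22, alternative = "less")$p.value
    p_min <- binom_vs_half(alt[gmin], total[gmin])
    p_max <- binom_vs_half(alt[gmax], total[gmax])
  }
  is_flip <- if (frequency_only) isTRUE(freq_ok) else
    isTRUE(freq_ok) && p_pair < alpha && p_min < alpha && p_max < alpha
  structure(list(is_flip = is_flip, min_group = gmin, max_group = gmax,
                 p_pairwise = p_pair, p_min_vs_half = p_min,
                 p_max_vs_half = p_max),
            class = "flip_result")
}

#' Screen a table of per-group frequencies for allele flips
#'
#' Reconstructs per-group allele counts from reported frequencies and
#' subpopulation sizes (`count = round(freq x total alleles)`) and applies
#' [detect_flip()] to every row. Chromosome-X rows use the hemizygote
#' ploidy rule with an assumed male fraction.
#'
#' @param freq_df data.frame with a `position` column (`"chrN:pos"`) and
#'   per-group frequency columns named `freq_<group>`.
#' @param sizes data.frame with `subpopulation` and `n_individuals`
#'   (see [load_subpopulation_sizes()]).
#' @param male_fraction assumed male fraction for chromosome-X rows.
#' @param alpha significance level.
#' @param frequency_only apply only the min < 0.5 < max component.
#' @return data.frame with one row per input row: `is_flip`, `min_group`,
#'   `max_group` and the three p-values.
#' @export
flip_frequency_screen <- function(freq_df, sizes, male_fraction = 0.5,
                                  alpha = 0.05, frequency_only = FALSE) {
  fcols <- grep("^freq_", names(freq_df), value = TRUE)
  gnames <- sub("^freq_", "", fcols)
  sz <- setNames(sizes$n_individuals, sizes$subpopulation)[gnames]
  if (anyNA(sz)) stop("frequency column without a matching group size")
  out <- vector("list", nrow(freq_df))
  for (i in seq_len(nrow(freq_df))) {
    chrom <- sub(":.*$", "", freq_df$position[i])
    if (chrom %in% c("chrX", "X")) {
      males <- round(sz * male_fraction)
      total <- 2 * (sz - males) + males
    } else {
      total <- 2 * sz
    }
    total <- setNames(as.numeric(total), gnames)
    freq <- as.numeric(freq_df[i, fcols])
    altc <- setNames(round(freq * total), gnames)
    fl <- detect_flip(altc, total, alpha = alpha,
                      frequency_only = frequency_only)
    out[[i]] <- data.frame(is_flip = fl$is_flip, min_group = fl$min_group,
                           max_group = fl$max_group,
                           p_pairwise = fl$p_pairwise,
                           p_min_vs_half = fl$p_min_vs_half,
                           p_max_vs_half = fl$p_max_vs_half)
  }
  do.call(rbind, out)
}

#' Variants common in, and specific to, a single ancestry group
#'
#' Among variants with frequency above `common_threshold` in at least one
#' group, returns those whose alt allele is observed in exactly one of
#' the six groups, annotated by whether that group is one of the four
#' low-admixture ancestry groups (African, Central Asian, East Asian,
#' European).
#'
#' @param gft a [group_allele_counts()] result.
#' @param common_threshold group frequency above which a variant counts
#'   as common in that group (default 0.05).
#' @return data.frame with `id`, `group`, `max_freq`, `low_admixture`.
#' @export
group_specific_common <- function(gft, common_threshold = 0.05) {
  freq <- gft$freq
  freq[!is.finite(freq)] <- 0
  common_any <- apply(freq, 1L, max) > common_threshold
  n_groups_with_alt <- rowSums(gft$alt > 0)
  sel <- which(common_any & n_groups_with_alt == 1L)
  grp <- colnames(gft$alt)[max.col(gft$alt[sel, , drop = FALSE],
                                   ties.method = "first")]
  data.frame(id = rownames(gft$alt)[sel],
             group = grp,
             max_freq = apply(freq[sel, , drop = FALSE], 1L, max),
             low_admixture = grp %in% c("African", "CentralAsian",
                                        "EastAsian", "European"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Positions where the reference carries a minor allele
#'
#' Returns variants whose nonreference-allele frequency exceeds 0.5 in
#' every group with observed alleles (and in all six groups when all are
#' observed), the signature of a reference sequence carrying the minor
#' allele.
#'
#' @param gft a [group_allele_counts()] result.
#' @return character vector of variant ids.
#' @export
reference_minor_positions <- function(gft) {
  freq <- gft$freq
  ok <- apply(freq, 1L, function(f) all(is.finite(f)) && all(f > 0.5))
  rownames(gft$alt)[ok]
}
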