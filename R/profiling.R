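# Per-individual and per-gene variant-load summaries plus the regression
# and ANOVA/ANCOVA analyses built on them.

#' Per-individual variant-load profile
#'
#' For each subject, counts carried variant sites (het or hom-alt,
#' unmasked; a hom-alt genotype counts as one site) in total and within
#' the nonexclusive classes, the number of rare carried sites, and the
#' number of distinct genes with at least one carried site.
#'
#' @param gs a filtered [genotype_set()] whose `variants` data.frame
#'   carries a `gene` column.
#' @param classes data.frame as from [assign_classes()], one row per
#'   variant, aligned with `gs$variants`.
#' @param rarity character vector per variant (`"rare"`, `"intermediate"`,
#'   `"common"`), e.g. from [classify_rarity()].
#' @return data.frame with one row per subject: `subject_id`, `n_total`,
#'   `n_hgmd`, `n_deleterious`, `n_vus`, `n_novel`, `n_rare`,
#'   `n_genes_with_variant`.
#' @export
individual_profile <- function(gs, classes, rarity) {
  stopifnot(inherits(gs, "genotype_set"),
            nrow(classes) == nrow(gs$variants),
            length(rarity) == nrow(gs$variants))
  carried <- !is.na(gs$dosage) & gs$dosage > 0L
  count_for <- function(flag) as.integer(colSums(carried & flag))
  n_total <- count_for(classes$nonsynonymous)
  genes <- gs$variants$gene
  gene_counts <- vapply(seq_len(ncol(carried)), function(j) {
    length(unique(genes[carried[, j] & classes$nonsynonymous]))
  }, 0L)
  data.frame(subject_id = gs$subjects$subject_id,
             n_total = n_total,
             n_hgmd = count_for(classes$hgmd),
             n_deleterious = count_for(classes$deleterious),
             n_vus = count_for(classes$vus),
             n_novel = count_for(classes$novel),
             n_rare = count_for(classes$nonsynonymous &
                                  !is.na(rarity) & rarity == "rare"),
             n_genes_with_variant = gene_counts,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene variant-load profile
#'
#' @param gs a filtered [genotype_set()] with a `gene` column; only
#'   nonsynonymous variants should be supplied (or pass `classes` to
#'   subset).
#' @param models named list of [gene_model()]s (genes with zero observed
#'   variants still appear, with `n_variants = 0`).
#' @param classes optional data.frame from [assign_classes()]; when given,
#'   only nonsynonymous variants are tallied.
#' @param rarity optional rarity vector for the rare-variant carrier
#'   count.
#' @return data.frame per gene: `gene_symbol`, `gene_type`, `n_variants`,
#'   `n_individuals`, `n_individuals_rare`, `coding_length`,
#'   `variants_per_kb`, `prevalence` (carriers / cohort size).
#' @export
gene_profiles <- function(gs, models, classes = NULL, rarity = NULL) {
  stopifnot(inherits(gs, "genotype_set"))
  keep <- rep(TRUE, nrow(gs$variants))
  if (!is.null(classes)) keep <- classes$nonsynonymous
  genes <- gs$variants$gene
  unassigned <- keep & (is.na(genes) | !genes %in% names(models))
  if (any(unassigned))
    warning(sum(unassigned), " variant(s) map to no supplied gene model; ",
            "tallied under 'unassigned'")
  carried <- !is.na(gs$dosage) & gs$dosage > 0L
  n_sub <- nrow(gs$subjects)
  rare <- if (is.null(rarity)) rep(FALSE, nrow(gs$variants)) else
    !is.na(rarity) & rarity == "rare"
  symbols <- c(names(models), if (any(unassigned)) "unassigned")
  rows <- lapply(symbols, function(sym) {
    if (sym == "unassigned") {
      vsel <- which(unassigned)
      clen <- NA_integer_
      gtype <- NA_character_
    } else {
      vsel <- which(keep & !is.na(genes) & genes == sym)
      clen <- coding_length(models[[sym]])
      gtype <- models[[sym]]$gene_type
    }
    carrier <- if (length(vsel))
      colSums(carried[vsel, , drop = FALSE]) > 0L else logical(n_sub)
    carrier_rare <- if (any(rare[vsel]))
      colSums(carried[vsel[rare[vsel]], , drop = FALSE]) > 0L else
        logical(n_sub)
    data.frame(gene_symbol = sym, gene_type = gtype,
               n_variants = length(vsel),
               n_individuals = sum(carrier),
               n_individuals_rare = sum(carrier_rare),
               coding_length = clen,
               variants_per_kb = length(vsel) / (clen / 1000),
               prevalence = sum(carrier) / n_sub,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Variants-per-kilobase rate from regression on coding length
#'
#' Ordinary least squares of the per-gene variant count on coding length
#' (intercept included); the slope is reported per kilobase.
#'
#' @param gp data.frame from [gene_profiles()] (the `"unassigned"` row,
#'   if present, is dropped).
#' @return list of class `variability_rate`: `slope_per_kb`, `intercept`,
#'   `r_squared`, `fit` (the `lm` object).
#' @export
variability_rate <- function(gp) {
  gp <- gp[!is.na(gp$coding_length), , drop = FALSE]
  if (nrow(gp) < 3L) stop("need at least 3 genes")
  if (var(gp$coding_length) == 0) stop("zero variance in coding length")
  fit <- lm(n_variants ~ coding_length, data = gp)
  structure(list(slope_per_kb = unname(coef(fit)[2L]) * 1000,
                 intercept = unname(coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 fit = fit),
            class = "variability_rate")
}

#' @export
print.variability_rate <- function(x, ...) {
  cat(sprintf("<variability_rate: %.2f variants/kb, r^2 = %.2f>\n",
              x$slope_per_kb, x$r_squared))
  invisible(x)
}

#' One-way ANOVA of a per-individual count across ancestry groups
#'
#' Fixed-effects one-way ANOVA of the chosen per-individual count across
#' the six ancestry-based subpopulations; `"Other"` is excluded.
#'
#' @param profiles data.frame from [individual_profile()].
#' @param groups factor of subpopulation labels per subject.
#' @param response profile column to analyse (e.g. `"n_total"`).
#' @return list with `F`, `p_value`, `df`, `group_means`.
#' @export
anova_by_group <- function(profiles, groups, response = "n_total") {
  stopifnot(response %in% names(profiles),
            length(groups) == nrow(profiles))
  use <- !is.na(groups) & groups != "Other"
  g <- droplevels(factor(groups[use]))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 subjects")
  y <- profiles[[response]][use]
  fit <- aov(y ~ g)
  s <- summary(fit)[[1L]]
  Fv <- s[1L, "F value"]; pv <- s[1L, "Pr(>F)"]
  if (s[1L, "Sum Sq"] < .Machine$double.eps * max(1, sum(y^2))) {
    Fv <- 0; pv <- 1                # no between-group variation at all
  }
  list(F = Fv, p_value = pv, df = s[, "Df"],
       group_means = tapply(y, g, mean))
}

#' ANCOVA of per-gene variant counts on coding length and gene type
#'
#' Linear model `n_variants ~ coding_length + gene_type`; reports the
#' partial F-test p-value for the gene-type term.
#'
#' @param gp data.frame from [gene_profiles()] with a `gene_type` column.
#' @return list with `p_value`, `F`, `fit`.
#' @export
ancova_gene_type <- function(gp) {
  gp <- gp[!is.na(gp$coding_length) & !is.na(gp$gene_type), , drop = FALSE]
  types <- table(gp$gene_type)
  if (length(types) < 2L) stop("need at least 2 gene types")
  if (any(types < 3L)) stop("need at least 3 genes per type")
  fit1 <- lm(n_variants ~ coding_length + gene_type, data = gp)
  fit0 <- lm(n_variants ~ coding_length, data = gp)
  a <- anova(fit0, fit1)
  list(p_value = a[2L, "Pr(>F)"], F = a[2L, "F"], fit = fit1)
}
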