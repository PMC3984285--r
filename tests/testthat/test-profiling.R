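profile_fixture <- function() {
  # 4 sites x 3 subjects across two genes
  variants <- data.frame(chrom = "c1", pos = c(10L, 20L, 30L, 40L),
                         ref = "A", alt = "G",
                         gene = c("GA", "GA", "GB", "GB"))
  subjects <- data.frame(subject_id = c("s1", "s2", "s3"))
  dosage <- rbind(c(1L, 0L, 0L),
                  c(1L, 1L, NA),
                  c(2L, 0L, 0L),
                  c(0L, 1L, 0L))
  dp <- matrix(40L, 4, 3)
  ad_alt <- round(dp * ifelse(is.na(dosage), 0, dosage) / 2)
  gs <- genotype_set(variants, subjects, dosage, dp - ad_alt, ad_alt, dp)
  classes <- assign_classes(c("missense", "nonsense", "missense",
                              "missense"),
                            in_hgmd = c(TRUE, FALSE, FALSE, FALSE),
                            known = c(TRUE, TRUE, FALSE, TRUE))
  list(gs = gs, classes = classes,
       rarity = c("common", "rare", "rare", "intermediate"))
}

test_that("individual profiles count carried sites once and tally the
           nonexclusive classes", {
  fx <- profile_fixture()
  ip <- individual_profile(fx$gs, fx$classes, fx$rarity)
  # s1 carries sites 1, 2 and 3 (hom-alt counts once) -> 3
  expect_equal(ip$n_total, c(3L, 2L, 0L))
  expect_equal(ip$n_hgmd, c(1L, 0L, 0L))
  expect_equal(ip$n_deleterious, c(1L, 1L, 0L))
  expect_equal(ip$n_rare, c(2L, 1L, 0L))
  # sites in genes {GA, GA, GB} -> 2 distinct genes
  expect_equal(ip$n_genes_with_variant, c(2L, 2L, 0L))
  # class identity: vus + (deleterious union hgmd) = total, per subject
  carried <- !is.na(fx$gs$dosage) & fx$gs$dosage > 0
  du <- fx$classes$deleterious | fx$classes$hgmd
  expect_equal(ip$n_vus + unname(colSums(carried & du)), ip$n_total)
})

test_that("gene profiles include zero-variant genes and report carrier
           prevalence", {
  fx <- profile_fixture()
  mk <- function(sym) gene_model(sym, list(
    transcript(paste0("t", sym), sym, "c1", "+", 0, 300, 0, 300)))
  models <- list(GA = mk("GA"), GB = mk("GB"), GZ = mk("GZ"))
  gp <- gene_profiles(fx$gs, models, classes = fx$classes,
                      rarity = fx$rarity)
  expect_equal(gp$n_variants[gp$gene_symbol == "GZ"], 0)
  expect_equal(gp$prevalence[gp$gene_symbol == "GZ"], 0)
  expect_equal(gp$n_variants[gp$gene_symbol == "GA"], 2)
  expect_equal(gp$n_individuals[gp$gene_symbol == "GA"], 2)
  expect_equal(gp$n_individuals_rare[gp$gene_symbol == "GB"], 1)
  expect_equal(gp$variants_per_kb[gp$gene_symbol == "GA"], 2 / 0.3)
  # unmapped variants go to an 'unassigned' row with a warning
  fx2 <- profile_fixture()
  fx2$gs$variants$gene[4] <- "GHOST"
  expect_warning(gp2 <- gene_profiles(fx2$gs, models,
                                      classes = fx2$classes),
                 "unassigned")
  expect_true("unassigned" %in% gp2$gene_symbol)
})

test_that("the variants-per-kb slope equals the closed-form least
           squares solution", {
  gp <- data.frame(gene_symbol = c("a", "b", "c"),
                   n_variants = c(6, 12, 18),
                   coding_length = c(1000, 2000, 3000))
  vr <- suppressWarnings(variability_rate(gp))  # exact fit warns in lm
  expect_equal(vr$slope_per_kb, 6)
  expect_equal(vr$r_squared, 1)
  # flat response -> slope 0
  gp$n_variants <- c(7, 7, 7)
  expect_equal(suppressWarnings(variability_rate(gp))$slope_per_kb, 0)
  # random data against the normal equations
  set.seed(19)
  gp3 <- data.frame(gene_symbol = letters[1:20],
                    coding_length = runif(20, 500, 9000))
  gp3$n_variants <- rpois(20, gp3$coding_length / 200)
  vr3 <- variability_rate(gp3)
  beta <- oracle_ols(gp3$coding_length, gp3$n_variants)
  expect_equal(vr3$slope_per_kb, unname(beta[2]) * 1000, tolerance = 1e-8)
  expect_equal(vr3$intercept, unname(beta[1]), tolerance = 1e-8)
  expect_error(variability_rate(gp3[1:2, ]), "at least 3")
})

test_that("one-way ANOVA matches the closed-form two-group F and keeps
           its type-I calibration", {
  # two groups with the cohort's reported total-load contrast
  set.seed(23)
  n1 <- 331; n2 <- 43
  y <- c(rnorm(n1, 64.5, 8), rnorm(n2, 84, 8))
  grp <- factor(c(rep("European", n1), rep("African", n2)),
                levels = germvar:::SUBPOP_LABELS)
  prof <- data.frame(subject_id = seq_along(y), n_total = y)
  res <- anova_by_group(prof, grp, "n_total")
  # closed form: two-group one-way ANOVA
  m1 <- mean(y[1:n1]); m2 <- mean(y[-(1:n1)]); mg <- mean(y)
  ssb <- n1 * (m1 - mg)^2 + n2 * (m2 - mg)^2
  ssw <- sum((y[1:n1] - m1)^2) + sum((y[-(1:n1)] - m2)^2)
  Fc <- ssb / (ssw / (n1 + n2 - 2))
  expect_equal(res$F, Fc, tolerance = 1e-8)
  expect_lt(res$p_value, 1e-10)
  # identical constant values -> F = 0
  prof0 <- data.frame(subject_id = 1:20, n_total = rep(5, 20))
  grp0 <- factor(rep(c("European", "African"), 10),
                 levels = germvar:::SUBPOP_LABELS)
  expect_equal(anova_by_group(prof0, grp0, "n_total")$F, 0)
  # null calibration: uniform p under repetition
  set.seed(29)
  ps <- replicate(200, {
    yy <- rnorm(60)
    gg <- factor(rep(c("European", "African", "EastAsian"), each = 20),
                 levels = germvar:::SUBPOP_LABELS)
    anova_by_group(data.frame(subject_id = 1:60, n_total = yy), gg,
                   "n_total")$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_error(anova_by_group(prof0[1:2, ],
                              factor(c("European", "European"),
                                     levels = germvar:::SUBPOP_LABELS)),
               "at least 2 groups")
})

test_that("gene-type ANCOVA detects a planted rate difference and
           rejects degenerate designs", {
  set.seed(31)
  detected <- replicate(10, {
    len <- runif(100, 1000, 10000)
    type <- rep(c("predisposition", "tumor_suppressor"), each = 50)
    rate <- ifelse(type == "predisposition", 8, 5) / 1000
    gp <- data.frame(gene_symbol = seq_along(len),
                     n_variants = rpois(100, len * rate),
                     coding_length = len, gene_type = type)
    ancova_gene_type(gp)$p_value < 0.05
  })
  expect_gte(mean(detected), 0.8)
  gp1 <- data.frame(gene_symbol = 1:10, n_variants = rpois(10, 5),
                    coding_length = runif(10, 1000, 5000),
                    gene_type = "oncogene")
  expect_error(ancova_gene_type(gp1), "at least 2 gene types")
})
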