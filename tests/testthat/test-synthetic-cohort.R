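# A reduced configuration keeps the per-test cohorts fast; the default
# full-scale conditions are exercised by the acceptance tests.
small_config <- function(seed, ...) {
  cohort_config(seed = seed, n_variants = 400L, n_genes = 40L,
                n_nonsense = 4L, n_frameshift = 6L, n_splice = 3L,
                n_inframe = 4L, n_hgmd = 50L, n_novel = 170L,
                n_flips = 6L, n_reference_minor = 4L,
                n_group_specific = 8L, n_low_callrate_sites = 5L,
                n_low_fracdepth_sites = 4L, n_panel_markers = 300L, ...)
}

test_that("regeneration with the same seed is fully deterministic", {
  a <- generate_cohort(small_config(101))
  b <- generate_cohort(small_config(101))
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$genotypes$dp, b$genotypes$dp)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_identical(a$panel_dosage, b$panel_dosage)
  d <- generate_cohort(small_config(102))
  expect_false(identical(a$genotypes$dosage, d$genotypes$dosage))
})

test_that("truth tables cover every emitted variant and subject", {
  co <- generate_cohort(small_config(103))
  n_sites <- nrow(co$genotypes$variants)
  expect_length(co$truth$stratum, n_sites)
  expect_length(co$truth$category, n_sites)
  expect_equal(nrow(co$truth$Q), nrow(co$genotypes$subjects))
  expect_equal(unname(rowSums(co$truth$Q)), rep(1, nrow(co$truth$Q)),
               tolerance = 1e-9)
  expect_equal(sum(co$genotypes$subjects$group == "European"), 331)
  expect_equal(nrow(co$genotypes$subjects), 681)
  # planted singletons and doubletons have exactly 1 and 2 carriers
  # before missingness; allow the no-call loss
  carr <- rowSums(!is.na(co$genotypes$dosage) & co$genotypes$dosage > 0)
  expect_true(all(carr[co$truth$stratum == "singleton"] <= 1))
  expect_true(all(carr[co$truth$stratum == "doubleton"] <= 2))
})

test_that("the generated consequence truth is confirmed by the
           classifier", {
  co <- generate_cohort(small_config(104))
  v <- co$genotypes$variants
  idx <- sample(nrow(v), 120)
  got <- vapply(idx, function(i) {
    tx <- co$models[[v$gene[i]]]$transcripts[[1]]
    suppressWarnings(
      classify_consequence(v$chrom[i], v$pos[i], v$ref[i], v$alt[i],
                           tx, co$genome))$category
  }, "")
  expect_equal(got, co$truth$category[idx])
})

test_that("planted features are recovered downstream", {
  co <- generate_cohort(small_config(105))
  fr <- filter_genotypes(co$genotypes)
  grp <- factor(co$truth$group, levels = germvar:::SUBPOP_LABELS)
  gft <- group_allele_counts(fr$genotypes, grp)
  # position filter removes the planted bad sites
  expect_true(all(co$truth$planted_bad_site_ids %in%
                    fr$site_quality$id[!fr$sites_kept]))
  # reference-minor sites are recovered exactly
  found_rm <- reference_minor_positions(gft)
  expect_setequal(intersect(found_rm, co$genotypes$variants$id),
                  co$truth$reference_minor_ids)
  # planted flips are recovered at >= 90%
  hits <- vapply(co$truth$flip_ids, function(id) {
    i <- match(id, rownames(gft$alt))
    !is.na(i) && detect_flip(gft$alt[i, ], gft$total[i, ])$is_flip
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # group-specific sites only ever show alleles in their target group
  gsp <- co$truth$group_specific
  for (r in seq_len(nrow(gsp))) {
    i <- match(gsp$id[r], rownames(gft$alt))
    nz <- names(which(gft$alt[i, ] > 0))
    expect_true(all(nz == gsp$group[r]))
  }
  # planted low-depth genotypes are masked or already no-calls
  pl <- co$truth$planted_lowdepth
  masked <- apply_genotype_filter(co$genotypes)
  gone <- masked[pl] | is.na(co$genotypes$dosage[pl])
  expect_gte(mean(gone), 0.99)
})

test_that("with no planted flips none are reported at planted sites", {
  co <- generate_cohort(small_config(106, n_flips = 0L))
  expect_length(co$truth$flip_ids, 0)
})

test_that("within-group genotypes are Hardy-Weinberg consistent at
           common non-planted sites", {
  co <- generate_cohort(small_config(107))
  d <- co$genotypes$dosage
  grp <- co$truth$group
  eur <- which(grp == "European")
  bg <- which(co$truth$stratum == "background")
  ps <- c()
  for (i in bg) {
    x <- d[i, eur]; x <- x[!is.na(x)]
    f <- mean(x) / 2
    if (f < 0.05 || f > 0.95) next
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    exp <- length(x) * c((1 - f)^2, 2 * f * (1 - f), f^2)
    stat <- sum((obs - exp)^2 / exp)
    ps <- c(ps, pchisq(stat, df = 1, lower.tail = FALSE))
  }
  expect_gt(length(ps), 5)
  expect_gte(mean(ps > 0.01), 0.9)
})

test_that("the VCF bundle round-trips losslessly", {
  co <- generate_cohort(small_config(108))
  td <- withr::local_tempdir()
  paths <- write_cohort(co, td)
  expect_true(all(file.exists(paths)))
  gs2 <- read_vcf_genotypes(paths[["vcf"]],
                            subjects = co$genotypes$subjects)
  expect_equal(unname(gs2$dosage), unname(co$genotypes$dosage))
  expect_equal(unname(gs2$ad_ref), unname(co$genotypes$ad_ref))
  expect_equal(unname(gs2$ad_alt), unname(co$genotypes$ad_alt))
  expect_equal(unname(gs2$dp), unname(co$genotypes$dp))
  expect_equal(gs2$variants[, c("chrom", "pos", "ref", "alt")],
               co$genotypes$variants[, c("chrom", "pos", "ref", "alt")])
  # gene models rebuilt from the emitted TSVs match the in-memory ones
  models <- load_gene_models(paths[["transcripts"]], paths[["genes"]])
  expect_named(models, names(co$models))
  expect_equal(vapply(models, coding_length, 0L),
               vapply(co$models, coding_length, 0L))
})

test_that("validation sets plant the requested error structure
           deterministically", {
  co <- generate_cohort(small_config(109))
  v1 <- emit_validation_set(co, n = 341, fp_rate = 0.05, fn_rate = 0.05,
                            seed = 11)
  v2 <- emit_validation_set(co, n = 341, fp_rate = 0.05, fn_rate = 0.05,
                            seed = 11)
  expect_identical(v1, v2)
  expect_equal(nrow(v1), 341)
  n_neg <- sum(v1$truth == "non_variant" & !v1$planted_error) +
    sum(v1$truth == "non_variant" & v1$planted_error)
  expect_equal(sum(v1$planted_error & v1$truth == "non_variant"),
               round(0.05 * n_neg))
  v0 <- emit_validation_set(co, n = 341, fp_rate = 0, fn_rate = 0,
                            seed = 12)
  expect_false(any(v0$planted_error))
  expect_error(emit_validation_set(co, n = 341, fp_rate = 2, seed = 1))
  # planted errors sit at low depth, so the published filter removes them
  er <- estimate_error_rates(v1, k = 10, seed = 13)
  expect_lt(er$false_positive_rate, 0.023)
})
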