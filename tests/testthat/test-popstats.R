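subpop_levels <- germvar:::SUBPOP_LABELS

test_that("group allele counts follow the diploid and X-hemizygote
           ploidy rules", {
  # 10 het + 1 hom-alt among 50 diploid subjects -> 12/100
  dosage <- matrix(0L, 1, 50)
  dosage[1, 1:10] <- 1L; dosage[1, 11] <- 2L
  gs <- small_genotype_set(dosage)
  grp <- factor(rep("European", 50), levels = subpop_levels)
  gft <- group_allele_counts(gs, grp)
  expect_equal(unname(gft$alt[1, "European"]), 12)
  expect_equal(unname(gft$total[1, "European"]), 100)
  expect_equal(unname(gft$freq[1, "European"]), 0.12)

  # all hom-ref -> frequency 0
  gs0 <- small_genotype_set(matrix(0L, 1, 43))
  gft0 <- group_allele_counts(gs0, factor(rep("African", 43),
                                          levels = subpop_levels))
  expect_equal(unname(gft0$freq[1, "African"]), 0)

  # X-linked site: 20 females (2 het) + 20 males (3 hemizygous alt)
  dosX <- matrix(0L, 1, 40)
  dosX[1, 1:2] <- 1L          # two female hets
  dosX[1, 21:23] <- 1L        # three male carriers
  gsX <- small_genotype_set(dosX, chrom = "chrX",
                            sex = rep(c("F", "M"), each = 20))
  gftX <- group_allele_counts(gsX, factor(rep("African", 40),
                                          levels = subpop_levels))
  expect_equal(unname(gftX$alt[1, "African"]), 5)
  expect_equal(unname(gftX$total[1, "African"]), 60)

  # masked genotypes and the Other group leave the denominator
  dosage2 <- matrix(1L, 1, 6)
  dosage2[1, 6] <- NA
  gs2 <- small_genotype_set(dosage2)
  grp2 <- factor(c(rep("European", 4), "Other", "European"),
                 levels = subpop_levels)
  gft2 <- group_allele_counts(gs2, grp2)
  expect_equal(unname(gft2$total[1, "European"]), 8)
  expect_false("Other" %in% colnames(gft2$alt))
})

test_that("allele-count conservation holds for every variant", {
  set.seed(12)
  dosage <- matrix(sample(c(0L, 1L, 2L, NA), 400, TRUE,
                          prob = c(0.6, 0.2, 0.1, 0.1)), 20, 20)
  gs <- small_genotype_set(dosage)
  grp <- factor(sample(subpop_levels, 20, TRUE), levels = subpop_levels)
  gft <- group_allele_counts(gs, grp)
  not_other <- !is.na(grp) & grp != "Other"
  called <- !is.na(dosage[, not_other, drop = FALSE])
  expect_equal(unname(rowSums(gft$total)), 2 * rowSums(called))
  expect_equal(unname(rowSums(gft$alt)),
               rowSums(dosage[, not_other, drop = FALSE], na.rm = TRUE))
})

test_that("rarity classification uses the 1% and 5% MAF cutoffs", {
  expect_equal(classify_rarity(c(3 / 1362, 0.06, 0.03, 0.01, 0.05)),
               c("rare", "common", "intermediate", "intermediate",
                 "intermediate"))
  expect_error(classify_rarity(0.6), "minor")
})

test_that("test selection requires all expected counts > 1 for the
           chi-squared path", {
  big <- cbind(alt = c(40, 35, 30, 45, 50, 38),
               ref = c(60, 65, 70, 55, 50, 62))
  expect_equal(select_test(big), "chi_squared")
  singleton <- cbind(alt = c(1, 0, 0, 0, 0, 0),
                     ref = c(85, 91, 99, 123, 661, 235))
  expect_equal(select_test(singleton), "fisher_simulated")
  # expected count exactly 1.0 falls to the simulated Fisher (>1 strict)
  tab <- cbind(alt = c(1, 1), ref = c(99, 99))
  expect_true(all(outer(rowSums(tab), colSums(tab)) / sum(tab) >= 1))
  expect_equal(select_test(tab), "fisher_simulated")
  expect_warning(select_test(cbind(alt = c(0, 0), ref = c(10, 10))),
                 "degenerate")
})

test_that("simulated Fisher p-values match exact enumeration within
           Monte-Carlo error", {
  # 2x2 diagonal table: exact two-sided p = 2/C(20,10)
  tab <- rbind(c(10, 0), c(0, 10))
  exact <- sum(dhyper(c(0, 10), 10, 10, 10))
  sf <- simulated_fisher(tab, n_sim = 40000, seed = 2)
  se <- sqrt(exact * (1 - exact) / 40000)
  expect_lt(abs(sf$p_value - exact), max(3 * se, 2 / 40000))
  expect_equal(sf$p_value, fisher.test(tab)$p.value, tolerance = 0.05)

  # small 3x2 tables against full enumeration
  set.seed(77)
  for (rep in 1:5) {
    tab3 <- matrix(sample(0:6, 6, TRUE), 3, 2)
    tab3 <- tab3[rowSums(tab3) > 0, , drop = FALSE]
    if (nrow(tab3) < 2 || any(colSums(tab3) == 0)) next
    exact3 <- min(oracle_fisher_exact(tab3), 1)
    sf3 <- simulated_fisher(tab3, n_sim = 20000, seed = rep)
    se3 <- sqrt(exact3 * max(1 - exact3, 0) / 20000)
    expect_lt(abs(sf3$p_value - exact3), 3 * se3 + 2 / 20000)
  }
})

test_that("chi-squared path returns the Pearson statistic with
           groups - 1 df and sane p", {
  tab <- cbind(alt = c(40, 60, 35), ref = c(60, 40, 65))
  res <- test_freq_difference(tab)
  expect_equal(res$test_used, "chi_squared")
  ct <- chisq.test(tab, correct = FALSE)
  expect_equal(res$p_value, ct$p.value)
  expect_equal(unname(ct$parameter), 2)
  # identical frequencies, large counts -> p ~ 1
  same <- cbind(alt = rep(50, 6), ref = rep(150, 6))
  expect_gt(test_freq_difference(same)$p_value, 0.99)
})

test_that("flip detection applies the frequency and significance
           components", {
  sizes <- load_subpopulation_sizes()
  flips <- load_flip_candidates()
  # PTCH1 row: reconstructed counts give a flip
  r1 <- flip_frequency_screen(flips[1, ], sizes)
  expect_true(r1$is_flip)
  expect_equal(r1$min_group, "African")
  expect_equal(r1$max_group, "EastAsian")

  # all frequencies below 0.5 -> never a flip
  alt <- c(African = 10, AfricanEuropean = 12, CentralAsian = 15,
           EastAsian = 20, European = 30, Hispanic = 18)
  tot <- c(African = 86, AfricanEuropean = 92, CentralAsian = 100,
           EastAsian = 124, European = 662, Hispanic = 236)
  expect_false(detect_flip(alt, tot)$is_flip)

  # near-0.5 frequencies with 10 alleles per group fail significance
  weak2 <- detect_flip(c(A = 4, B = 6), c(A = 10, B = 10))
  expect_false(weak2$is_flip)
  expect_gt(weak2$p_pairwise, 0.05)
})

test_that("all 21 published flip rows pass the frequency component and
           at least 19 the full criterion", {
  sizes <- load_subpopulation_sizes()
  flips <- load_flip_candidates()
  freq_part <- flip_frequency_screen(flips, sizes, frequency_only = TRUE)
  expect_equal(sum(freq_part$is_flip), 21)
  full <- flip_frequency_screen(flips, sizes)
  expect_gte(sum(full$is_flip), 19)
})

test_that("flip detection keeps its type-I rate under a simulated null", {
  set.seed(55)
  sizes <- load_subpopulation_sizes()
  tot <- 2 * sizes$n_individuals[sizes$subpopulation != "Other"]
  names(tot) <- sizes$subpopulation[sizes$subpopulation != "Other"]
  reps <- 400
  hits <- 0
  for (r in seq_len(reps)) {
    alt <- rbinom(length(tot), tot, 0.5)
    names(alt) <- names(tot)
    hits <- hits + detect_flip(alt, tot)$is_flip
  }
  alpha <- 0.05
  se <- sqrt(alpha * (1 - alpha) / reps)
  expect_lte(hits / reps, alpha + 3 * se)
})

test_that("group-specific and reference-minor screens follow their
           definitions", {
  alt <- rbind(c(6, 0, 0, 0, 0, 0),      # African-specific, freq 0.07
               c(6, 5, 0, 0, 0, 0),      # two groups -> excluded
               c(60, 70, 80, 95, 500, 180),  # common everywhere
               c(3, 0, 0, 0, 0, 0))      # specific but rare -> excluded
  tot <- matrix(rep(c(86, 92, 100, 124, 662, 236), each = 4), 4, 6)
  colnames(alt) <- colnames(tot) <- setdiff(subpop_levels, "Other")
  rownames(alt) <- rownames(tot) <- paste0("v", 1:4)
  gft <- structure(list(alt = alt, total = tot, freq = alt / tot,
                        overall_maf = rep(0.1, 4),
                        variants = data.frame(id = rownames(alt))),
                   class = "group_freq_table")
  gsc <- group_specific_common(gft)
  expect_equal(gsc$id, "v1")
  expect_equal(gsc$group, "African")
  expect_true(gsc$low_admixture)
  rmp <- reference_minor_positions(gft)
  expect_equal(rmp, "v3")
})
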