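# Synthetic admixed cohort generator. Emits toy genes and transcripts,
# subject admixture vectors, genotypes with per-allele depths, an
# ancestral marker panel, annotation tables and complete truth tables,
# with the statistical structure the downstream analysis assumes: a
# rare-variant-heavy site-frequency spectrum (singletons/doubletons
# planted by direct allele-count assignment), a group-divergent common
# stratum, and planted allele flips, group-specific sites,
# reference-minor sites and low-quality positions/genotypes.

STOP_CODONS <- c("TAA", "TAG", "TGA")

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Deterministic per-stage seeds derived from the master seed, kept within
# 32-bit range so every module can be regenerated in isolation.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483629)
}

#' Generator configuration
#'
#' Defaults encode the study conditions of the profiled cohort: the seven
#' ancestry-based subpopulation sizes (681 subjects), 158 genes, 2,688
#' variant sites with 65% singletons and 10% doubletons, 21 planted
#' allele flips, 14 reference-minor sites, 58 group-specific sites
#' (weighted 49/2/6/1 toward African/Central Asian/East Asian/European),
#' mean per-gene coverage 58x (range ~21-84x), and a 2,000-marker
#' ancestral panel. The background-stratum frequency scale is calibrated
#' so the expected post-filter variant load is ~68 carried sites per
#' person.
#'
#' @param seed integer seed (mandatory; all randomness derives from it).
#' @param ... overrides for any default listed above (see the source for
#'   the full set of keys).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    group_sizes = c(African = 43L, AfricanEuropean = 46L,
                    CentralAsian = 50L, EastAsian = 62L, European = 331L,
                    Hispanic = 118L, Other = 31L),
    n_genes = 158L,
    n_variants = 2688L,
    prop_singleton = 0.65,
    prop_doubleton = 0.10,
    n_flips = 21L,
    n_reference_minor = 14L,
    n_group_specific = 58L,
    group_specific_weights = c(African = 49, CentralAsian = 2,
                               EastAsian = 6, European = 1),
    flip_freq_min = c(0.13, 0.28),
    flip_freq_max = c(0.62, 0.80),
    flip_freq_mid = c(0.28, 0.50),
    refminor_freq = c(0.70, 0.95),
    group_specific_freq = c(0.06, 0.20),
    bg_freq_min = 0.01, bg_freq_max = 0.50,
    bg_shape1 = 0.8, bg_shape2 = 17.5,
    bg_divergence_sd = 0.4,
    # consequence-category counts (all sites are nonsynonymous)
    n_nonsense = 22L, n_frameshift = 42L, n_splice = 16L, n_inframe = 30L,
    n_deleterious_common = 6L,
    n_hgmd = 326L, n_hgmd_common = 12L, n_novel = 1166L,
    coverage_mean = 58, coverage_sd = 12, coverage_range = c(21, 84),
    missing_rate = 0.005,
    n_low_callrate_sites = 25L, low_callrate = 0.70,
    n_low_fracdepth_sites = 15L,
    lowdepth_genotype_rate = 0.002, lowdepth_mean = 5,
    n_panel_markers = 2000L,
    male_fraction = 0.5,
    # Dirichlet concentrations per truth group over
    # (African, European, NativeAmerican, EastAsian, CentralAsian, Oceanic)
    dirichlet = rbind(
      African         = c(50, 3.5, 0.3, 0.3, 0.6, 0.3),
      AfricanEuropean = c(18, 22, 0.1, 0.1, 0.15, 0.05),
      CentralAsian    = c(0.3, 3.5, 0.3, 0.6, 50, 0.3),
      EastAsian       = c(0.3, 1.5, 0.3, 50, 2.5, 0.4),
      European        = c(0.4, 60, 0.3, 0.4, 2.5, 0.3),
      Hispanic        = c(1.2, 9, 5.5, 0.25, 0.25, 0.3),
      Other           = c(0.4, 6, 0.3, 5, 6, 0.3)))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  n_planted <- round(cfg$prop_singleton * cfg$n_variants) +
    round(cfg$prop_doubleton * cfg$n_variants) +
    cfg$n_flips + cfg$n_reference_minor + cfg$n_group_specific
  if (n_planted > cfg$n_variants)
    stop("infeasible config: planted sites exceed n_variants")
  structure(cfg, class = "cohort_config")
}

# ---- toy genes, transcripts and genome ------------------------------------

make_toy_gene <- function(idx, cds_len) {
  n_codon <- cds_len %/% 3L
  codons <- names(Biostrings::GENETIC_CODE)
  nonstop <- codons[Biostrings::GENETIC_CODE != "*"]
  cds <- paste0("ATG",
                paste(sample(nonstop, n_codon - 2L, replace = TRUE),
                      collapse = ""),
                sample(STOP_CODONS, 1L))
  n_exons <- sample(2:5, 1L)
  # contiguous CDS chunks of >= 30 bases each
  repeat {
    cuts <- sort(sample(seq(30L, cds_len - 30L), n_exons - 1L))
    if (all(diff(c(0L, cuts, cds_len)) >= 30L)) break
  }
  chunk_start <- c(0L, cuts)                  # coding offsets, 0-based
  chunk_end <- c(cuts, cds_len)
  introns <- sample(200:800, n_exons - 1L, replace = TRUE)
  flank <- 50L
  exon_starts <- integer(n_exons)
  exon_ends <- integer(n_exons)
  gpos <- flank
  pieces <- character(0)
  pieces <- c(pieces, random_dna(flank))
  for (i in seq_len(n_exons)) {
    exon_starts[i] <- gpos
    piece <- substr(cds, chunk_start[i] + 1L, chunk_end[i])
    pieces <- c(pieces, piece)
    gpos <- gpos + nchar(piece)
    exon_ends[i] <- gpos
    if (i < n_exons) {
      pieces <- c(pieces, random_dna(introns[i]))
      gpos <- gpos + introns[i]
    }
  }
  pieces <- c(pieces, random_dna(flank))
  contig <- paste(pieces, collapse = "")
  sym <- sprintf("G%03d", idx)
  tx <- transcript(sprintf("TX%03d", idx), sym, sprintf("ctg%03d", idx),
                   "+", exon_starts, exon_ends,
                   cds_start = exon_starts[1L],
                   cds_end = exon_ends[n_exons])
  list(symbol = sym, transcript = tx, contig = contig, cds = cds,
       cds_len = cds_len, chunk_start = chunk_start, chunk_end = chunk_end)
}

# All 9 single-base substitutions of a codon, with old/new amino acids.
# Memoised: the map is tiny (64 codons) and hit constantly by the
# variant designer.
codon_sub_cache <- new.env(parent = emptyenv())
codon_substitutions <- function(cod) {
  hit <- codon_sub_cache[[cod]]
  if (!is.null(hit)) return(hit)
  p <- rep(1:3, each = 4L)
  b <- rep(c("A", "C", "G", "T"), 3L)
  newcod <- vapply(seq_along(p), function(r) {
    x <- cod; substr(x, p[r], p[r]) <- b[r]; x
  }, "")
  keep <- newcod != cod
  out <- list(p = p[keep], b = b[keep],
              aa_old = Biostrings::GENETIC_CODE[[cod]],
              aa_new = unname(Biostrings::GENETIC_CODE[newcod[keep]]))
  codon_sub_cache[[cod]] <- out
  out
}

# genomic 0-based position of a coding offset
coding_to_genomic <- function(gene, off) {
  i <- findInterval(off, gene$chunk_start)
  gene$transcript$exon_starts[i] + (off - gene$chunk_start[i])
}

# TRUE when coding offsets off..off+len-1 lie in one exon chunk
same_chunk <- function(gene, off, len) {
  i <- findInterval(off, gene$chunk_start)
  (off + len) <= gene$chunk_end[i]
}

# Design the (pos, ref, alt) of one variant realising a consequence
# category on a plus-strand toy gene. Offsets are coding-coordinate.
design_variant <- function(gene, category, used) {
  cds <- gene$cds
  n_codon <- nchar(cds) %/% 3L
  base_at <- function(o) substr(cds, o + 1L, o + 1L)
  for (attempt in 1:200) {
    if (category == "splice_site") {
      tx <- gene$transcript
      n_ex <- length(tx$exon_starts)
      i <- sample(n_ex - 1L, 1L)
      g0 <- tx$exon_ends[i] + sample(0:1, 1L)   # 0-based intron base
      pos <- g0 + 1L
      ref <- substr(gene$contig, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    } else if (category %in% c("missense", "nonsense")) {
      j <- sample(2:(n_codon - 1L), 1L)
      cod <- substr(cds, 3L * j - 2L, 3L * j)
      tab <- codon_substitutions(cod)
      ok <- if (category == "nonsense") tab$aa_new == "*"
            else tab$aa_new != tab$aa_old & tab$aa_new != "*"
      if (!any(ok)) next
      r <- which(ok)[sample(sum(ok), 1L)]
      off <- 3L * (j - 1L) + (tab$p[r] - 1L)
      pos <- coding_to_genomic(gene, off) + 1L
      ref <- base_at(off)
      alt <- tab$b[r]
    } else {                                    # frameshift / inframe del
      del <- if (category == "frameshift") 1L else 3L
      if (category == "inframe_indel") {
        # delete one whole codon so no novel (possibly stop) codon forms
        j <- sample(3:(n_codon - 1L), 1L)
        off <- 3L * (j - 1L)
      } else {
        off <- sample(seq(3L, nchar(cds) - del - 4L), 1L)
      }
      if (!same_chunk(gene, off - 1L, del + 1L)) next
      a0 <- coding_to_genomic(gene, off - 1L)
      pos <- a0 + 1L
      ref <- substr(gene$contig, pos, pos + del)
      alt <- substr(gene$contig, pos, pos)
    }
    span <- pos:(pos + nchar(ref) - 1L)
    if (!any(span %in% used)) {
      return(list(pos = pos, ref = ref, alt = alt, span = span))
    }
  }
  stop("could not place a ", category, " variant in gene ", gene$symbol)
}

# ---- main generator -------------------------------------------------------

#' Generate a synthetic admixed cohort with truth tables
#'
#' See [cohort_config()] for the generative model and its defaults. All
#' randomness flows from `config$seed` through fixed per-stage seeds, so
#' regeneration with the same config is fully deterministic.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort`: `genotypes` (a
#'   [genotype_set()] including the planted low-quality extra sites),
#'   `genome` (named contig sequences), `models` (gene models),
#'   `transcript_table` / `gene_table` (data.frames mirroring the TSV
#'   interfaces), `panel` (+ `panel_dosage`), `annotations` (per-variant
#'   HGMD-like / known-variant / PolyPhen-like table), `truth` (admixture
#'   vectors, per-variant stratum and class truth, planted low-quality
#'   flags), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config

  # --- stage 1: genes, transcripts, genome ---------------------------------
  set.seed(stage_seed(cfg$seed, 1L))
  cds_len <- 3L * pmin(pmax(round(rlnorm(cfg$n_genes, log(2400), 0.55) / 3),
                            100L), 5000L)
  genes <- lapply(seq_len(cfg$n_genes), function(i)
    make_toy_gene(i, cds_len[i]))
  names(genes) <- vapply(genes, `[[`, "", "symbol")
  genome <- setNames(lapply(genes, `[[`, "contig"),
                     vapply(genes, function(g) g$transcript$chrom, ""))
  gene_type <- sample(c("oncogene", "tumor_suppressor", "predisposition"),
                      cfg$n_genes, replace = TRUE,
                      prob = c(0.4, 0.4, 0.2))
  models <- lapply(seq_along(genes), function(i)
    gene_model(genes[[i]]$symbol, list(genes[[i]]$transcript),
               gene_type = gene_type[i], census_reason = "synthetic"))
  names(models) <- names(genes)

  # --- stage 2: subjects and admixture truth -------------------------------
  set.seed(stage_seed(cfg$seed, 2L))
  groups <- factor(rep(names(cfg$group_sizes), cfg$group_sizes),
                   levels = SUBPOP_LABELS)
  n_sub <- length(groups)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_sub)),
    sex = sample(c("F", "M"), n_sub, replace = TRUE,
                 prob = c(1 - cfg$male_fraction, cfg$male_fraction)),
    group = as.character(groups),
    stringsAsFactors = FALSE)
  Q <- matrix(NA_real_, n_sub, 6L,
              dimnames = list(subjects$subject_id, ANCESTRAL_POPS))
  for (g in rownames(cfg$dirichlet)) {
    sel <- which(groups == g)
    if (length(sel))
      Q[sel, ] <- rdirichlet(length(sel), cfg$dirichlet[g, ])
  }

  # --- stage 3: variant site plan ------------------------------------------
  set.seed(stage_seed(cfg$seed, 3L))
  n_single <- round(cfg$prop_singleton * cfg$n_variants)
  n_double <- round(cfg$prop_doubleton * cfg$n_variants)
  n_bg <- cfg$n_variants - n_single - n_double - cfg$n_flips -
    cfg$n_reference_minor - cfg$n_group_specific
  stratum <- c(rep("singleton", n_single), rep("doubleton", n_double),
               rep("flip", cfg$n_flips),
               rep("reference_minor", cfg$n_reference_minor),
               rep("group_specific", cfg$n_group_specific),
               rep("background", n_bg),
               rep("low_callrate", cfg$n_low_callrate_sites),
               rep("low_fracdepth", cfg$n_low_fracdepth_sites))
  n_sites <- length(stratum)
  calibrated <- stratum %in% c("singleton", "doubleton", "flip",
                               "reference_minor", "group_specific",
                               "background")
  # consequence categories: deleterious and in-frame indels planted among
  # the rare strata, everything else missense -- except for a handful of
  # common deleterious sites (the reported ~2 deleterious variants per
  # person require some non-rare loss-of-function alleles)
  category <- rep("missense", n_sites)
  rare_idx <- which(stratum %in% c("singleton", "doubleton"))
  n_delc <- min(cfg$n_deleterious_common,
                sum(stratum == "background"),
                cfg$n_nonsense + cfg$n_splice)
  delc_nonsense <- min(n_delc %/% 2L + n_delc %% 2L, cfg$n_nonsense)
  delc_splice <- min(n_delc - delc_nonsense, cfg$n_splice)
  n_delc <- delc_nonsense + delc_splice
  delc_idx <- sample(which(stratum == "background"), n_delc)
  category[delc_idx] <- rep(c("nonsense", "splice_site"),
                            c(delc_nonsense, delc_splice))
  special <- sample(rare_idx,
                    cfg$n_nonsense - delc_nonsense + cfg$n_frameshift +
                      (cfg$n_splice - delc_splice) + cfg$n_inframe)
  category[special] <- rep(c("nonsense", "frameshift", "splice_site",
                             "inframe_indel"),
                           c(cfg$n_nonsense - delc_nonsense,
                             cfg$n_frameshift,
                             cfg$n_splice - delc_splice, cfg$n_inframe))
  gene_of <- sample(names(genes), n_sites, replace = TRUE,
                    prob = cds_len)
  # realise (pos, ref, alt) per site
  used <- lapply(genes, function(g) integer(0))
  pos <- integer(n_sites); ref <- alt <- character(n_sites)
  for (i in seq_len(n_sites)) {
    g <- gene_of[i]
    d <- design_variant(genes[[g]], category[i], used[[g]])
    pos[i] <- d$pos; ref[i] <- d$ref; alt[i] <- d$alt
    used[[g]] <- c(used[[g]], d$span)
  }
  variants <- data.frame(
    chrom = vapply(genes[gene_of], function(g) g$transcript$chrom, ""),
    pos = pos, ref = ref, alt = alt, gene = gene_of,
    stringsAsFactors = FALSE)

  # --- stage 4: frequencies and genotypes ----------------------------------
  set.seed(stage_seed(cfg$seed, 4L))
  use_groups <- setdiff(SUBPOP_LABELS, "Other")
  gidx <- match(as.character(groups), SUBPOP_LABELS)
  # subpopulation-level frequencies for planted strata (+ extra bad sites)
  subpop_freq <- matrix(0, n_sites, length(SUBPOP_LABELS),
                        dimnames = list(NULL, SUBPOP_LABELS))
  flip_idx <- which(stratum == "flip")
  flip_truth <- data.frame(idx = flip_idx,
                           min_group = rep(NA_character_,
                                           length(flip_idx)),
                           max_group = rep(NA_character_,
                                           length(flip_idx)))
  for (r in seq_len(nrow(flip_truth))) {
    i <- flip_truth$idx[r]
    gm <- sample(use_groups, 2L)
    f <- runif(6L, cfg$flip_freq_mid[1L], cfg$flip_freq_mid[2L])
    names(f) <- use_groups
    f[gm[1L]] <- runif(1L, cfg$flip_freq_min[1L], cfg$flip_freq_min[2L])
    f[gm[2L]] <- runif(1L, cfg$flip_freq_max[1L], cfg$flip_freq_max[2L])
    subpop_freq[i, use_groups] <- f
    subpop_freq[i, "Other"] <- mean(f)
    flip_truth$min_group[r] <- gm[1L]
    flip_truth$max_group[r] <- gm[2L]
  }
  rm_idx <- which(stratum == "reference_minor")
  subpop_freq[rm_idx, ] <-
    runif(length(rm_idx) * ncol(subpop_freq),
          cfg$refminor_freq[1L], cfg$refminor_freq[2L])
  gs_idx <- which(stratum == "group_specific")
  gs_target <- sample(names(cfg$group_specific_weights), length(gs_idx),
                      replace = TRUE, prob = cfg$group_specific_weights)
  subpop_freq[cbind(gs_idx, match(gs_target, SUBPOP_LABELS))] <-
    runif(length(gs_idx), cfg$group_specific_freq[1L],
          cfg$group_specific_freq[2L])
  if (length(lc_plan <- which(stratum == "low_callrate")))
    subpop_freq[lc_plan, ] <- runif(length(lc_plan), 0.02, 0.10)
  # het-rich so the skewed-depth signature dominates the site average
  if (length(lf_plan <- which(stratum == "low_fracdepth")))
    subpop_freq[lf_plan, ] <- runif(length(lf_plan), 0.25, 0.45)
  bad_idx <- which(!calibrated)
  # ancestral-frequency model for the background stratum
  bg_idx <- which(stratum == "background")
  m_bg <- cfg$bg_freq_min +
    rbeta(length(bg_idx), cfg$bg_shape1, cfg$bg_shape2) *
    (cfg$bg_freq_max - cfg$bg_freq_min)
  if (length(delc_idx)) {
    # hand the largest background frequencies to the planted common
    # deleterious sites so each is carried by roughly half the cohort
    pos_in_bg <- match(delc_idx, bg_idx)
    top_idx <- order(m_bg, decreasing = TRUE)[seq_along(pos_in_bg)]
    top_vals <- m_bg[top_idx]
    rest_vals <- m_bg[-top_idx]
    m_bg[pos_in_bg] <- top_vals
    m_bg[setdiff(seq_along(m_bg), pos_in_bg)] <- rest_vals
  }
  F_bg <- m_bg * exp(matrix(rnorm(length(bg_idx) * 6L, 0,
                                  cfg$bg_divergence_sd),
                            length(bg_idx), 6L))
  F_bg <- pmin(pmax(F_bg, 1e-4), 0.95)
  colnames(F_bg) <- ANCESTRAL_POPS

  p <- subpop_freq[, as.character(groups), drop = FALSE]
  p[bg_idx, ] <- F_bg %*% t(Q)
  dosage <- matrix(rbinom(n_sites * n_sub, 2L, p), n_sites, n_sub)
  # direct allele-count assignment for the rare stratum
  s_idx <- which(stratum == "singleton")
  dosage[s_idx, ] <- 0L
  dosage[cbind(s_idx, sample.int(n_sub, length(s_idx), replace = TRUE))] <- 1L
  d_idx <- which(stratum == "doubleton")
  dosage[d_idx, ] <- 0L
  for (i in d_idx) dosage[i, sample.int(n_sub, 2L)] <- 1L
  # group-specific sites carry alt alleles only in the target group
  for (r in seq_along(gs_idx)) {
    i <- gs_idx[r]
    out_grp <- which(as.character(groups) != gs_target[r])
    dosage[i, out_grp] <- 0L
    in_grp <- which(as.character(groups) == gs_target[r])
    if (all(dosage[i, in_grp] == 0L))
      dosage[i, sample(in_grp, 1L)] <- 1L
  }

  # --- stage 5: depths, missingness, planted low quality -------------------
  set.seed(stage_seed(cfg$seed, 5L))
  coverage <- pmin(pmax(rnorm(cfg$n_genes, cfg$coverage_mean,
                              cfg$coverage_sd),
                        cfg$coverage_range[1L]), cfg$coverage_range[2L])
  names(coverage) <- names(genes)
  lam <- matrix(coverage[gene_of], n_sites, n_sub)
  lowdepth <- matrix(FALSE, n_sites, n_sub)
  homref <- dosage == 0L
  cand <- which(homref & calibrated)
  n_ld <- round(cfg$lowdepth_genotype_rate * length(cand))
  lowdepth[sample(cand, n_ld)] <- TRUE
  lam[lowdepth] <- cfg$lowdepth_mean
  dp <- matrix(rpois(n_sites * n_sub, lam), n_sites, n_sub)
  err <- 0.005
  alt_frac <- matrix(NA_real_, n_sites, n_sub)
  alt_frac[dosage == 0L] <- err
  alt_frac[dosage == 1L] <- 0.5
  alt_frac[dosage == 2L] <- 1 - err
  lf_idx <- which(stratum == "low_fracdepth")
  if (length(lf_idx)) {                     # systematically skewed site
    alt_frac[lf_idx, ][dosage[lf_idx, ] == 1L] <- 0.10
    alt_frac[lf_idx, ][dosage[lf_idx, ] == 0L] <- 0.70
    alt_frac[lf_idx, ][dosage[lf_idx, ] == 2L] <- 0.30
  }
  ad_alt <- matrix(rbinom(n_sites * n_sub, dp, alt_frac), n_sites, n_sub)
  ad_ref <- dp - ad_alt
  miss <- matrix(runif(n_sites * n_sub) < cfg$missing_rate, n_sites, n_sub)
  lc_idx <- which(stratum == "low_callrate")
  if (length(lc_idx))
    miss[lc_idx, ] <- matrix(runif(length(lc_idx) * n_sub) >
                               cfg$low_callrate,
                             length(lc_idx), n_sub)
  dosage[miss] <- NA_integer_

  variants$id <- paste0(variants$chrom, ":", variants$pos, "_",
                        variants$ref, ">", variants$alt)
  gs <- genotype_set(variants, subjects, dosage, ad_ref, ad_alt, dp)

  # --- stage 6: annotation tables ------------------------------------------
  set.seed(stage_seed(cfg$seed, 6L))
  carriers <- rowSums(!is.na(dosage) & dosage > 0L)
  # HGMD-like flags: a fixed slice of the very common planted sites (the
  # disease-annotation databases contain well-known common polymorphisms)
  # plus a uniform draw over everything else; the split reproduces the
  # reported ~14 HGMD variants per person
  hgmd <- rep(FALSE, n_sites)
  common_pool <- which(stratum %in% c("flip", "reference_minor"))
  n_hc <- min(cfg$n_hgmd_common, length(common_pool), cfg$n_hgmd)
  rest_pool <- setdiff(which(calibrated), common_pool)
  hgmd[sample(common_pool, n_hc)] <- TRUE
  hgmd[sample(rest_pool, min(cfg$n_hgmd - n_hc, length(rest_pool)))] <- TRUE
  novel <- rep(FALSE, n_sites)
  rare_enough <- calibrated & carriers <= 19L
  n_novel <- min(cfg$n_novel, sum(rare_enough))
  novel[sample(which(rare_enough), n_novel)] <- TRUE
  polyphen <- rep(NA_real_, n_sites)
  mis <- category == "missense"
  bimodal <- ifelse(runif(sum(mis)) < 0.55, rbeta(sum(mis), 0.5, 4),
                    rbeta(sum(mis), 5, 0.8))
  polyphen[mis] <- pmin(pmax(bimodal, 0), 1)
  annotations <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt, id = variants$id,
    known = !novel, hgmd = hgmd, polyphen = polyphen,
    stringsAsFactors = FALSE)

  # --- stage 7: ancestral marker panel -------------------------------------
  set.seed(stage_seed(cfg$seed, 7L))
  L <- cfg$n_panel_markers
  panel_freqs <- matrix(rbeta(L * 6L, 0.5, 0.5), L, 6L,
                        dimnames = list(NULL, ANCESTRAL_POPS))
  panel_markers <- data.frame(
    chrom = "panel", pos = seq_len(L),
    ref = sample(c("A", "C", "G", "T"), L, replace = TRUE),
    alt = NA_character_, stringsAsFactors = FALSE)
  panel_markers$alt <- vapply(panel_markers$ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  panel_p <- panel_freqs %*% t(Q)
  panel_dosage <- matrix(rbinom(L * n_sub, 2L, panel_p), L, n_sub,
                         dimnames = list(NULL, subjects$subject_id))

  transcript_table <- do.call(rbind, lapply(genes, function(g) {
    tx <- g$transcript
    data.frame(name = tx$transcript_id, geneSymbol = tx$gene_symbol,
               chrom = tx$chrom, strand = tx$strand,
               txStart = tx$exon_starts[1L],
               txEnd = tx$exon_ends[length(tx$exon_ends)],
               cdsStart = tx$cds_start, cdsEnd = tx$cds_end,
               exonCount = length(tx$exon_starts),
               exonStarts = paste0(paste(tx$exon_starts, collapse = ","),
                                   ","),
               exonEnds = paste0(paste(tx$exon_ends, collapse = ","), ","),
               stringsAsFactors = FALSE)
  }))
  rownames(transcript_table) <- NULL
  gene_table <- data.frame(symbol = names(genes), gene_type = gene_type,
                           census_reason = "synthetic",
                           stringsAsFactors = FALSE)

  truth <- list(
    Q = Q,
    group = as.character(groups),
    stratum = stratum,
    calibrated = calibrated,
    category = category,
    subpop_freq = subpop_freq,
    background_freq = F_bg,
    flip = flip_truth,
    reference_minor_ids = variants$id[rm_idx],
    flip_ids = variants$id[flip_truth$idx],
    group_specific = data.frame(id = variants$id[gs_idx],
                                group = gs_target,
                                stringsAsFactors = FALSE),
    planted_bad_site_ids = variants$id[bad_idx],
    planted_lowdepth = which(lowdepth, arr.ind = TRUE),
    hgmd = hgmd, novel = novel, coverage = coverage)

  structure(list(genotypes = gs, genome = genome, models = models,
                 transcript_table = transcript_table,
                 gene_table = gene_table,
                 panel = list(markers = panel_markers, freqs = panel_freqs),
                 panel_dosage = panel_dosage,
                 annotations = annotations,
                 truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort: %d subject(s), %d site(s) ",
                     "(%d calibrated), %d gene(s), seed %d>\n"),
              nrow(x$genotypes$subjects), nrow(x$genotypes$variants),
              sum(x$truth$calibrated), length(x$models), x$config$seed))
  invisible(x)
}

#' Variant classes of a synthetic cohort
#'
#' Runs [assign_classes()] over the generator's per-variant consequence
#' truth and annotation tables.
#'
#' @param cohort a [generate_cohort()] result.
#' @param ids optional variant ids to subset/reorder to.
#' @return data.frame from [assign_classes()].
#' @export
cohort_classes <- function(cohort, ids = NULL) {
  i <- if (is.null(ids)) seq_along(cohort$truth$category) else
    match(ids, cohort$genotypes$variants$id)
  assign_classes(cohort$truth$category[i],
                 cohort$annotations$hgmd[i],
                 cohort$annotations$known[i])
}

#' Emit a labeled validation call set for filter cross-validation
#'
#' Samples `n` genotype calls from the cohort, labels them with the
#' generator's truth (variant / non-variant), and plants false-positive
#' and false-negative calls concentrated at low read depths: a planted FP
#' is a truth-negative call rewritten as a low-depth heterozygote, a
#' planted FN a truth-positive call rewritten as a low-depth call.
#'
#' @param cohort a [generate_cohort()] result.
#' @param n calls to sample (default 341).
#' @param fp_rate,fn_rate planted error fractions in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return data.frame with `truth`, `dosage`, `ad_ref`, `ad_alt`, `dp`,
#'   `planted_error`.
#' @export
emit_validation_set <- function(cohort, n = 341L, fp_rate = 0.05,
                                fn_rate = 0.05, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  gs <- cohort$genotypes
  called <- which(!is.na(gs$dosage))
  if (n > length(called)) stop("n exceeds available called genotypes")
  set.seed(seed)
  pick <- sample(called, n)
  d <- gs$dosage[pick]
  calls <- data.frame(truth = ifelse(d > 0L, "variant", "non_variant"),
                      dosage = d, ad_ref = gs$ad_ref[pick],
                      ad_alt = gs$ad_alt[pick], dp = gs$dp[pick],
                      planted_error = FALSE, stringsAsFactors = FALSE)
  lowdp <- function(k) {
    tot <- rpois(k, 8) + 2L
    a <- rbinom(k, tot, 0.5)
    list(dp = tot, alt = a, ref = tot - a)
  }
  neg <- which(calls$truth == "non_variant")
  n_fp <- round(fp_rate * length(neg))
  if (n_fp > 0L) {
    i <- sample(neg, n_fp)
    e <- lowdp(n_fp)
    calls$dosage[i] <- 1L
    calls$dp[i] <- e$dp; calls$ad_alt[i] <- e$alt; calls$ad_ref[i] <- e$ref
    calls$planted_error[i] <- TRUE
  }
  pos <- which(calls$truth == "variant" & !calls$planted_error)
  n_fn <- round(fn_rate * length(pos))
  if (n_fn > 0L) {
    i <- sample(pos, n_fn)
    e <- lowdp(n_fn)
    calls$dosage[i] <- 0L
    calls$dp[i] <- e$dp; calls$ad_ref[i] <- e$dp - 1L; calls$ad_alt[i] <- 1L
    calls$planted_error[i] <- TRUE
  }
  calls
}
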