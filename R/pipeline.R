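# End-to-end orchestration: simulate (optional) -> filter -> annotate ->
# ancestry -> population statistics -> profiling, with per-stage TSV
# outputs, a JSON summary and a provenance log.

#' Pipeline configuration
#'
#' Every analysis threshold is surfaced as a config key with its
#' published default: position-filter call rate 0.80 and fractional
#' allele depth 0.295, genotype-filter allele depth 11, MAF cutoffs
#' 0.01/0.05, significance level 0.05, minimum cluster size 20, and
#' 10,000 Fisher simulations.
#'
#' @param seed integer seed (mandatory).
#' @param outdir output directory.
#' @param simulate logical; when `TRUE` the input cohort is generated
#'   with [generate_cohort()] using `cohort` overrides.
#' @param cohort list of [cohort_config()] overrides for simulation.
#' @param ... threshold overrides (`min_call_rate`, `min_frac_depth`,
#'   `min_allele_depth`, `maf_rare`, `maf_common`, `alpha`,
#'   `min_cluster_size`, `n_sim`, `run_admixture`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, outdir = tempfile("germvar_run_"),
                            simulate = TRUE, cohort = list(), ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              simulate = simulate, cohort = cohort,
              min_call_rate = 0.80, min_frac_depth = 0.295,
              min_allele_depth = 11L,
              maf_rare = 0.01, maf_common = 0.05,
              alpha = 0.05, min_cluster_size = 20L, n_sim = 10000L,
              run_admixture = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed")
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> filter -> annotate -> ancestry ->
#' population statistics -> profiling, writing per-stage TSVs, a JSON
#' summary with the headline cohort numbers, and a log recording stage
#' timings, thresholds and the seed. Any stage failure aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @param cohort a [generate_cohort()] result; required when
#'   `config$simulate` is `FALSE`.
#' @return list of class `pipeline_result` with the stage outputs and
#'   `summary` (also written to `summary.json`).
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "pipeline.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(sprintf("stage %-10s done in %.1fs", name,
                proc.time()[["elapsed"]] - t0))
    out
  }
  tsv <- function(x, name) write.table(x, file.path(config$outdir, name),
                                       sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  say("seed=", config$seed,
      " thresholds: call_rate>=", config$min_call_rate,
      " frac_depth>", config$min_frac_depth,
      " allele_depth>", config$min_allele_depth,
      " maf ", config$maf_rare, "/", config$maf_common,
      " alpha=", config$alpha)

  if (config$simulate) {
    cohort <- stage("simulate", do.call(cohort_config,
                                        c(list(seed = config$seed),
                                          config$cohort)))
    cohort <- stage("simulate", generate_cohort(cohort))
  } else if (is.null(cohort)) {
    stop("stage 'simulate' skipped but no cohort supplied")
  }

  thr <- list(min_call_rate = config$min_call_rate,
              min_frac_depth = config$min_frac_depth,
              min_allele_depth = config$min_allele_depth)
  fres <- stage("filter", filter_genotypes(cohort$genotypes, thr))
  fgs <- fres$genotypes
  tsv(fres$mask_report, "mask_report.tsv")
  tsv(fres$site_quality, "site_quality.tsv")

  ann <- stage("annotate", {
    idx <- match(fgs$variants$id, cohort$annotations$id)
    cls <- assign_classes(cohort$truth$category[
      match(fgs$variants$id, cohort$genotypes$variants$id)],
      cohort$annotations$hgmd[idx], cohort$annotations$known[idx])
    cls$polyphen_bin <- bin_polyphen(cohort$annotations$polyphen[idx])
    cls
  })

  anc <- stage("ancestry", {
    if (config$run_admixture) {
      fit <- estimate_admixture(cohort$panel_dosage, cohort$panel$freqs)
      th <- cluster_thresholds()
      th$min_cluster_size <- config$min_cluster_size
      grp <- cluster_subjects(fit$Q, th)
      list(Q = fit$Q, groups = grp, loglik = fit$loglik)
    } else {
      list(Q = cohort$truth$Q,
           groups = factor(cohort$truth$group, levels = SUBPOP_LABELS),
           loglik = NULL)
    }
  })
  tsv(data.frame(subject_id = fgs$subjects$subject_id,
                 round(anc$Q, 6), group = anc$groups), "ancestry.tsv")

  pop <- stage("popstats", {
    if (all(anc$groups == "Other")) {
      say("all subjects in 'Other'; population statistics skipped")
      NULL
    } else {
      gft <- group_allele_counts(fgs, anc$groups)
      maf <- gft$overall_maf
      rarity <- classify_rarity(maf)
      common_any <- apply(replace(gft$freq, !is.finite(gft$freq), 0),
                          1L, max) > config$maf_common
      flips <- lapply(which(common_any), function(i)
        detect_flip(gft$alt[i, ], gft$total[i, ], alpha = config$alpha))
      is_flip <- vapply(flips, `[[`, TRUE, "is_flip")
      list(gft = gft, rarity = rarity,
           flip_ids = rownames(gft$alt)[which(common_any)[is_flip]],
           group_specific = group_specific_common(gft, config$maf_common),
           reference_minor = reference_minor_positions(gft))
    }
  })
  if (!is.null(pop)) {
    freq_out <- data.frame(pop$gft$variants[, c("chrom", "pos", "ref",
                                                "alt", "id")],
                           round(pop$gft$freq, 5), maf = pop$gft$overall_maf,
                           rarity = pop$rarity)
    tsv(freq_out, "group_frequencies.tsv")
  }

  prof <- stage("profiling", {
    rarity <- if (is.null(pop)) {
      af <- rowSums(!is.na(fgs$dosage) & fgs$dosage > 0L)
      classify_rarity(pmin(af / nrow(fgs$subjects), 0.5))
    } else pop$rarity
    ip <- individual_profile(fgs, ann, rarity)
    gp <- gene_profiles(fgs, cohort$models, classes = ann, rarity = rarity)
    vr <- variability_rate(gp)
    av <- if (!is.null(pop) && nlevels(droplevels(
      factor(anc$groups[anc$groups != "Other"]))) >= 2L)
      anova_by_group(ip, anc$groups, "n_total") else NULL
    list(individual = ip, gene = gp, rate = vr, anova_total = av)
  })
  tsv(prof$individual, "individual_profiles.tsv")
  tsv(prof$gene, "gene_profiles.tsv")

  summary <- list(
    seed = config$seed,
    n_subjects = nrow(fgs$subjects),
    n_sites_input = nrow(cohort$genotypes$variants),
    n_sites_kept = sum(fres$sites_kept),
    n_genotypes_masked = sum(fres$mask_report$reason == "genotype_filter"),
    n_nonsynonymous = sum(ann$nonsynonymous),
    n_deleterious = sum(ann$deleterious),
    n_hgmd = sum(ann$hgmd),
    n_vus = sum(ann$vus),
    n_novel = sum(ann$novel),
    mean_variants_per_person = mean(prof$individual$n_total),
    range_variants_per_person = range(prof$individual$n_total),
    group_sizes = as.list(table(anc$groups)),
    n_flips = if (is.null(pop)) NA else length(pop$flip_ids),
    flip_ids = if (is.null(pop)) NULL else pop$flip_ids,
    n_reference_minor = if (is.null(pop)) NA else
      length(pop$reference_minor),
    n_group_specific = if (is.null(pop)) NA else nrow(pop$group_specific),
    variants_per_kb = prof$rate$slope_per_kb,
    r_squared = prof$rate$r_squared,
    anova_total_p = if (is.null(prof$anova_total)) NA else
      prof$anova_total$p_value)
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 12, null = "null")
  writeLines(log_lines, logfile)
  structure(list(config = config, cohort = cohort, filter = fres,
                 classes = ann, ancestry = anc, popstats = pop,
                 profiling = prof, summary = summary),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<pipeline_result: %d subjects, %d/%d sites kept, ",
                     "mean %.1f variants/person, %s flips>\n"),
              s$n_subjects, s$n_sites_kept, s$n_sites_input,
              s$mean_variants_per_person, s$n_flips))
  invisible(x)
}
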