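# Supervised admixture estimation against a fixed six-population
# ancestral reference panel, and threshold-based clustering of subjects
# into labeled subpopulations.

#' Read an ancestral panel TSV
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, then one alt-allele-frequency
#' column per ancestral population (`f_African`, `f_European`,
#' `f_NativeAmerican`, `f_EastAsian`, `f_CentralAsian`, `f_Oceanic`).
#'
#' @param path TSV file path.
#' @return list with `markers` (data.frame) and `freqs` (markers x 6
#'   matrix).
#' @export
read_ancestral_panel <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  fcols <- paste0("f_", ANCESTRAL_POPS)
  miss <- setdiff(c("chrom", "pos", "ref", "alt", fcols), names(tab))
  if (length(miss))
    stop("panel missing column(s): ", paste(miss, collapse = ", "))
  key <- paste0(tab$chrom, ":", tab$pos, "_", tab$ref, ">", tab$alt)
  if (anyDuplicated(key)) stop("panel has duplicated marker keys")
  freqs <- as.matrix(tab[, fcols])
  colnames(freqs) <- ANCESTRAL_POPS
  if (any(freqs < 0 | freqs > 1)) stop("panel frequencies outside [0, 1]")
  list(markers = tab[, c("chrom", "pos", "ref", "alt")], freqs = freqs)
}

#' Estimate supervised admixture coefficients
#'
#' Maximises, for each subject independently, the binomial admixture
#' log-likelihood
#' `sum_l [ x_l log(sum_k q_k f_kl) + (2 - x_l) log(sum_k q_k (1 - f_kl)) ]`
#' over the probability simplex, with the ancestral allele frequencies
#' `f` held fixed, by EM from a uniform start. The likelihood is
#' non-decreasing at every iteration; iteration stops when the mean
#' per-subject log-likelihood improves by less than `tol` or after
#' `max_iter` iterations. Marker frequencies of exactly 0 or 1 are clipped to
#' `[eps, 1 - eps]` to keep the likelihood finite.
#'
#' @param dosages markers x subjects integer matrix of alt-allele dosages
#'   (0/1/2, `NA` = missing; missing markers drop out of that subject's
#'   likelihood).
#' @param freqs markers x K matrix of ancestral alt-allele frequencies.
#' @param tol convergence tolerance on the mean per-subject
#'   log-likelihood change.
#' @param max_iter iteration cap.
#' @param min_markers minimum non-missing panel markers per subject.
#' @param eps frequency clipping bound.
#' @return list of class `admixture_fit`: `Q` (subjects x K coefficient
#'   matrix, rows sum to 1), `loglik` (per-iteration summed
#'   log-likelihood), `iterations`, `converged`.
#' @export
estimate_admixture <- function(dosages, freqs, tol = 1e-3, max_iter = 300L,
                               min_markers = 100L, eps = 1e-6) {
  stopifnot(nrow(dosages) == nrow(freqs))
  n_obs <- colSums(!is.na(dosages))
  if (any(n_obs < min_markers))
    stop("subject(s) with fewer than ", min_markers, " called panel markers")
  K <- ncol(freqs)
  L <- nrow(freqs)
  N <- ncol(dosages)
  F1 <- pmin(pmax(freqs, eps), 1 - eps)          # L x K
  F0 <- 1 - F1
  X <- dosages
  obs <- !is.na(X)
  X[!obs] <- 0L
  Xc <- 2L - X
  Xc[!obs] <- 0L
  X <- X * 1.0; Xc <- Xc * 1.0
  Q <- matrix(1 / K, N, K, dimnames = list(colnames(dosages),
                                           colnames(freqs)))
  ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- F1 %*% t(Q)                             # L x N: alt prob
    Pc <- 1 - P
    ll_now <- sum(X * log(P) + Xc * log(Pc))
    ll <- c(ll, ll_now)
    if (it > 1L && abs(ll_now - ll[it - 1L]) < tol * N) {
      converged <- TRUE
      break
    }
    # EM update: expected ancestral origin of each observed allele
    Q <- Q * (crossprod(X / P, F1) + crossprod(Xc / Pc, F0)) / (2 * n_obs)
    Q <- Q / rowSums(Q)                          # guard rounding drift
  }
  structure(list(Q = Q, loglik = ll, iterations = length(ll),
                 converged = converged),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit: %d subject(s), %d population(s), %d EM %s%s>\n",
              nrow(x$Q), ncol(x$Q), x$iterations,
              "iteration(s)", if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Default subpopulation clustering thresholds
#'
#' Dominant-ancestry breakpoints (0.78 African, 0.83 European, 0.79 East
#' Asian, 0.79 Central Asian, 0.78 otherwise), the African-European
#' two-way admixture rule (African + European >= 0.95 of the total with
#' African in \[0.13, 0.75\]), and the Hispanic rule (Native American
#' component >= `hispanic_na_min` together with a European component and
#' at most 0.50 African).
#'
#' @return named list of thresholds.
#' @export
cluster_thresholds <- function() {
  list(dominant = c(African = 0.78, European = 0.83, NativeAmerican = 0.78,
                    EastAsian = 0.79, CentralAsian = 0.79, Oceanic = 0.78),
       afeu_sum = 0.95, afeu_african = c(0.13, 0.75),
       hispanic_na_min = 0.05, hispanic_eu_min = 0.02,
       hispanic_af_max = 0.50,
       min_cluster_size = 20L)
}

#' Cluster subjects into subpopulations from admixture coefficients
#'
#' Explicit threshold rule reflecting the breakpoints observed in the
#' admixture coefficients: (1) subjects whose maximum coefficient reaches
#' the ancestry-specific dominance breakpoint form one cluster per
#' dominant ancestry; (2) remaining subjects that are essentially two-way
#' African/European admixtures with an intermediate African fraction form
#' the African-European cluster; (3) remaining subjects with a Native
#' American plus European admixture and limited African ancestry form the
#' Hispanic cluster; (4) everything else is unassigned. Unassigned
#' subjects and any cluster smaller than `min_cluster_size` are merged
#' into `"Other"`.
#'
#' @param Q subjects x 6 admixture matrix with columns named by ancestral
#'   population (order of `estimate_admixture()` output).
#' @param thresholds list as from [cluster_thresholds()].
#' @return factor of subpopulation labels, one per subject, levels
#'   `c("African", "AfricanEuropean", "CentralAsian", "EastAsian",
#'   "European", "Hispanic", "Other")`.
#' @export
cluster_subjects <- function(Q, thresholds = cluster_thresholds()) {
  stopifnot(nrow(Q) >= 1L, all(ANCESTRAL_POPS %in% colnames(Q)))
  Q <- Q[, ANCESTRAL_POPS, drop = FALSE]
  th <- thresholds
  lab <- rep(NA_character_, nrow(Q))
  dom <- ANCESTRAL_POPS[max.col(Q, ties.method = "first")]
  dom_ok <- Q[cbind(seq_len(nrow(Q)), match(dom, ANCESTRAL_POPS))] >=
    th$dominant[dom]
  # dominant-ancestry clusters; admixed-group names come later
  cluster_name <- c(African = "African", European = "European",
                    EastAsian = "EastAsian", CentralAsian = "CentralAsian",
                    NativeAmerican = "NativeAmerican", Oceanic = "Oceanic")
  lab[dom_ok] <- cluster_name[dom[dom_ok]]
  rest <- is.na(lab)
  afeu <- rest &
    (Q[, "African"] + Q[, "European"]) >= th$afeu_sum &
    Q[, "African"] >= th$afeu_african[1L] &
    Q[, "African"] <= th$afeu_african[2L]
  lab[afeu] <- "AfricanEuropean"
  rest <- is.na(lab)
  hisp <- rest &
    Q[, "NativeAmerican"] >= th$hispanic_na_min &
    Q[, "European"] >= th$hispanic_eu_min &
    Q[, "African"] <= th$hispanic_af_max
  lab[hisp] <- "Hispanic"
  lab[is.na(lab)] <- "Other"
  small <- names(which(table(lab) < th$min_cluster_size))
  lab[lab %in% setdiff(small, "Other")] <- "Other"
  lab[!lab %in% SUBPOP_LABELS] <- "Other"
  factor(lab, levels = SUBPOP_LABELS)
}

#' Label clusters from self-reported birth country
#'
#' When a birth-country table is supplied the cluster label is the
#' majority geographic region among its members, excluding subjects born
#' in the United States; without a table (or when the exclusion empties
#' the vote, or the vote ties) the dominant-ancestry label from the
#' clustering rule is kept and a warning is emitted for ties/empty votes.
#'
#' @param clusters factor from [cluster_subjects()].
#' @param birth_region optional character vector (one region per subject,
#'   `"UnitedStates"` for US-born).
#' @return named character vector mapping each cluster to its label.
#' @export
label_clusters <- function(clusters, birth_region = NULL) {
  labs <- levels(droplevels(clusters))
  out <- setNames(labs, labs)
  if (is.null(birth_region)) return(out)
  stopifnot(length(birth_region) == length(clusters))
  for (cl in labs) {
    votes <- birth_region[clusters == cl & birth_region != "UnitedStates"]
    if (length(votes) == 0L) {
      warning("cluster ", cl, ": no non-US birth countries; keeping ",
              "ancestry-rule label")
      next
    }
    tab <- sort(table(votes), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) {
      warning("cluster ", cl, ": tied birth-region vote; keeping ",
              "ancestry-rule label")
      next
    }
    out[cl] <- names(tab)[1L]
  }
  out
}
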