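# Quality-control filters. Call-rate thresholds are strict (> threshold) and
# the MAF threshold inclusive (>= threshold), read literally from the usual
# GBS filter statement "sample call rate >0.8, MAF >= 0.05, SNP call rate
# >0.7". Filters are idempotent and always applied samples-first.

new_filter_report <- function(axis, n_in, n_out, removed, thresholds) {
  stopifnot(n_in - sum(unlist(removed)) <= n_out) # overlaps counted once
  structure(list(axis = axis, n_in = n_in, n_out = n_out,
                 removed = removed, thresholds = thresholds),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("QC filter (", x$axis, "): ", x$n_in, " in -> ", x$n_out, " out\n",
      sep = "")
  for (nm in names(x$removed)) {
    cat("  removed by ", nm, ": ", x$removed[[nm]], "\n", sep = "")
  }
  cat("  thresholds:",
      paste(names(x$thresholds), unlist(x$thresholds), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

sample_call_rates <- function(gm) rowMeans(!is.na(gm$calls))
marker_call_rates <- function(gm) colMeans(!is.na(gm$calls))

marker_mafs <- function(gm) {
  n_obs <- colSums(!is.na(gm$calls))
  p <- colSums(gm$calls, na.rm = TRUE) / (2 * n_obs)
  out <- pmin(p, 1 - p)
  out[n_obs == 0] <- NA_real_
  out
}

#' Filter samples by call rate
#'
#' Retains samples whose fraction of non-missing calls strictly exceeds the
#' threshold, preserving sample order.
#'
#' @param gm a [genotype_matrix()].
#' @param min_sample_call_rate call-rate threshold in `[0, 1]`; samples with
#'   call rate strictly greater are kept. Default 0.8.
#' @return list with elements `gm` (filtered panel) and `report`
#'   (a `filter_report`).
#' @export
filter_samples <- function(gm, min_sample_call_rate = 0.8) {
  stopifnot(is_genotype_matrix(gm),
            min_sample_call_rate >= 0, min_sample_call_rate <= 1)
  cr <- sample_call_rates(gm)
  keep <- cr > min_sample_call_rate | min_sample_call_rate == 0
  if (!any(keep)) {
    stop("sample call-rate filter at ", min_sample_call_rate,
         " removed every sample")
  }
  rep <- new_filter_report("samples", length(keep), sum(keep),
                           list(sample_call_rate = sum(!keep)),
                           list(min_sample_call_rate = min_sample_call_rate))
  list(gm = gm[keep, ], report = rep)
}

#' Filter markers by call rate and minor allele frequency
#'
#' A marker is retained iff its call rate strictly exceeds
#' `min_snp_call_rate` and its MAF (computed on the non-missing calls of the
#' current panel, i.e. after any sample filtering) is at least `min_maf`.
#'
#' @param gm a [genotype_matrix()].
#' @param min_snp_call_rate strict call-rate threshold, default 0.7.
#' @param min_maf inclusive MAF threshold, default 0.05.
#' @return list with elements `gm` and `report`.
#' @export
filter_markers <- function(gm, min_snp_call_rate = 0.7, min_maf = 0.05) {
  stopifnot(is_genotype_matrix(gm),
            min_snp_call_rate >= 0, min_snp_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  cr <- marker_call_rates(gm)
  maf <- marker_mafs(gm)
  fail_cr <- !(cr > min_snp_call_rate | min_snp_call_rate == 0)
  fail_maf <- is.na(maf) | maf < min_maf
  keep <- !fail_cr & !fail_maf
  rep <- new_filter_report(
    "markers", length(keep), sum(keep),
    list(snp_call_rate = sum(fail_cr), maf = sum(fail_maf)),
    list(min_snp_call_rate = min_snp_call_rate, min_maf = min_maf))
  if (!any(keep)) {
    message(paste(utils::capture.output(print(rep)), collapse = "\n"))
    stop("marker filters removed every marker")
  }
  list(gm = gm[, which(keep)], report = rep)
}

#' Apply the full QC filter chain
#'
#' Samples are filtered first, then markers (whose MAF and call rate are
#' recomputed on the retained samples), matching the conventional GBS
#' filtering order.
#'
#' @inheritParams filter_samples
#' @inheritParams filter_markers
#' @return list with `gm` and `reports` (sample and marker
#'   `filter_report`s).
#' @export
apply_qc <- function(gm, min_sample_call_rate = 0.8,
                     min_snp_call_rate = 0.7, min_maf = 0.05) {
  fs <- filter_samples(gm, min_sample_call_rate)
  fm <- filter_markers(fs$gm, min_snp_call_rate, min_maf)
  list(gm = fm$gm, reports = list(samples = fs$report, markers = fm$report))
}

#' Naive imputation of missing genotype calls
#'
#' Replaces missing calls per locus by the modal observed dosage
#' (`"locus_mode"`, ties broken toward the lower dosage) or by the rounded
#' locus mean (`"locus_mean"`). This is a deliberately simple completeness
#' step so downstream stages (EM, PCA, distance matrices) can require a
#' complete matrix; it makes no claim to the accuracy of haplotype-aware
#' imputation.
#'
#' @param gm a [genotype_matrix()].
#' @param mode `"locus_mode"` (default) or `"locus_mean"`.
#' @return a complete [genotype_matrix()].
#' @export
impute_naive <- function(gm, mode = c("locus_mode", "locus_mean")) {
  mode <- match.arg(mode)
  stopifnot(is_genotype_matrix(gm))
  calls <- gm$calls
  n_obs <- colSums(!is.na(calls))
  if (any(n_obs == 0)) {
    stop("locus ", gm$markers$id[which(n_obs == 0)[1]],
         " has no observed calls; filter markers before imputing")
  }
  for (j in which(colSums(is.na(calls)) > 0)) {
    obs <- calls[!is.na(calls[, j]), j]
    fill <- if (mode == "locus_mode") {
      tab <- table(obs)
      best <- tab == max(tab)
      min(as.numeric(names(tab)[best])) # tie -> lower dosage
    } else {
      round(mean(obs))
    }
    calls[is.na(calls[, j]), j] <- fill
  }
  genotype_matrix(calls, gm$markers)
}
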