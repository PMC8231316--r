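# End-to-end orchestration: QC filter -> imputation -> marker stats ->
# structure scan + Evanno -> PCA + dendrogram -> AMOVA -> diversity, with a
# report bundle mirroring the conventional three tables (chromosome
# distribution, AMOVA, allelic patterns) plus machine-readable artifacts.

#' Validate a pipeline configuration
#'
#' Fills in defaults, checks types and ranges (all violations reported
#' together) and rejects unknown keys. Defaults follow the standard GBS
#' workflow: sample call rate > 0.8, SNP call rate > 0.7, MAF >= 0.05,
#' K scanned 1..5 with 10 replicate restarts, 999 AMOVA permutations,
#' 3 PCs for the dendrogram.
#'
#' @param raw named list of configuration values; recognised keys are
#'   `input`, `format` ("hapmap"/"vcf"), `min_sample_call_rate`,
#'   `min_snp_call_rate`, `min_maf`, `impute_mode`, `k_min`, `k_max`,
#'   `replicates`, `seed`, `n_perm`, `pca_components`, `out_dir`,
#'   `em_max_iter`, `em_tol`.
#' @return validated configuration list of class `run_config`.
#' @export
validate_config <- function(raw = list()) {
  defaults <- list(input = NULL, format = "hapmap",
                   min_sample_call_rate = 0.8, min_snp_call_rate = 0.7,
                   min_maf = 0.05, impute_mode = "locus_mode",
                   k_min = 1L, k_max = 5L, replicates = 10L, seed = 1L,
                   n_perm = 999L, pca_components = 3L, out_dir = NULL,
                   em_max_iter = 2000L, em_tol = 1e-6)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw)
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  for (key in c("min_sample_call_rate", "min_snp_call_rate", "min_maf")) {
    chk(is.numeric(cfg[[key]]) && cfg[[key]] >= 0 && cfg[[key]] <= 1,
        paste(key, "must be in [0, 1]"))
  }
  chk(cfg$format %in% c("hapmap", "vcf"), "format must be hapmap or vcf")
  chk(cfg$impute_mode %in% c("locus_mode", "locus_mean"),
      "impute_mode must be locus_mode or locus_mean")
  chk(is.numeric(cfg$k_min) && cfg$k_min >= 1, "k_min must be >= 1")
  chk(is.numeric(cfg$k_max) && cfg$k_max >= cfg$k_min,
      "k_max must be >= k_min")
  chk(is.numeric(cfg$replicates) && cfg$replicates >= 2,
      "replicates must be >= 2")
  chk(is.numeric(cfg$n_perm) && cfg$n_perm >= 0, "n_perm must be >= 0")
  chk(is.numeric(cfg$pca_components) && cfg$pca_components >= 1,
      "pca_components must be >= 1")
  chk(is.numeric(cfg$seed), "seed must be numeric")
  chk(is.numeric(cfg$em_max_iter) && cfg$em_max_iter >= 1,
      "em_max_iter must be >= 1")
  chk(is.numeric(cfg$em_tol) && cfg$em_tol > 0, "em_tol must be > 0")
  if (length(errs) > 0) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  for (key in c("k_min", "k_max", "replicates", "seed", "n_perm",
                "pca_components", "em_max_iter")) {
    cfg[[key]] <- as.integer(cfg[[key]])
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full diversity and structure pipeline
#'
#' Executes filter -> impute -> marker stats -> K scan + Evanno -> subgroup
#' assignment -> PCA + dendrogram -> AMOVA -> diversity report, writing the
#' report bundle into `config$out_dir` when set: `filter_report.json`,
#' `chrom_distribution.tsv`, `marker_stats.tsv`, `evanno.tsv`,
#' `q_matrix.csv`, `dendrogram.nwk`, `amova.tsv`, `diversity.tsv`,
#' `manifest.json` (the replayable configuration plus stage dimensions and
#' methodological flags). A failing stage aborts with the stage name;
#' artifacts written before the failure are preserved.
#'
#' @param config a [validate_config()] result (or raw list, validated here).
#' @param gm optional [genotype_matrix()]; when `NULL` the panel is read
#'   from `config$input` in `config$format`.
#' @return list (class `popdiv_run`) with every stage result: `gm`
#'   (filtered, imputed panel), `filter_reports`, `marker_summary`,
#'   `chrom_distribution`, `k_scan`, `evanno`, `best_K`, `fit`, `groups`,
#'   `pca`, `dendrogram`, `amova`, `diversity`, `config`.
#' @export
run_pipeline <- function(config, gm = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(fn, ...) if (!is.null(out)) fn(...)

  if (is.null(gm)) {
    gm <- stage("read", {
      if (is.null(config$input) || !file.exists(config$input)) {
        stop("input file not found: ",
             if (is.null(config$input)) "<none>" else config$input)
      }
      if (config$format == "vcf") read_vcf(config$input)
      else read_hapmap(config$input)
    })
  }

  qc <- stage("qc_filter",
              apply_qc(gm, config$min_sample_call_rate,
                       config$min_snp_call_rate, config$min_maf))
  emit(function() {
    jsonlite::write_json(
      lapply(qc$reports, unclass), file.path(out, "filter_report.json"),
      auto_unbox = TRUE, pretty = TRUE)
  })
  gm_f <- stage("impute", impute_naive(qc$gm, config$impute_mode))

  ms <- stage("marker_stats", marker_summary(gm_f))
  cd <- stage("chrom_distribution", chromosome_distribution(gm_f))
  emit(function() {
    write.table(ms, file.path(out, "marker_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_chrom_distribution(cd, file.path(out, "chrom_distribution.tsv"))
  })

  scan <- stage("k_scan",
                run_k_scan(gm_f$calls, k_min = config$k_min,
                           k_max = config$k_max,
                           replicates = config$replicates,
                           base_seed = config$seed,
                           max_iter = config$em_max_iter,
                           tol = config$em_tol))
  ev <- stage("evanno", evanno_delta_k(scan))
  best_K <- attr(ev, "best_K")
  fits <- attr(scan, "fits")
  best_fits <- fits[scan$K == best_K]
  fit <- best_fits[[which.max(scan$logL[scan$K == best_K])]]
  groups <- stage("assign_subgroups", assign_subgroups(fit))
  emit(function() {
    write.table(as.data.frame(ev), file.path(out, "evanno.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    q <- data.frame(sample = rownames(fit$Q) %||% seq_len(nrow(fit$Q)),
                    fit$Q)
    names(q)[-1] <- paste0("Q", seq_len(fit$K))
    write.table(q, file.path(out, "q_matrix.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  })

  pc <- stage("pca", snp_pca(gm_f$calls))
  dnd <- stage("dendrogram",
               pc_dendrogram(pc, n_components = min(config$pca_components,
                                                    ncol(pc$scores))))
  emit(function() write_newick(dnd, file.path(out, "dendrogram.nwk")))

  am <- stage("amova", {
    D2 <- squared_distance_matrix(gm_f$calls)
    amova_one_level(D2, groups$group, n_perm = config$n_perm,
                    seed = config$seed)
  })
  emit(function() write_amova(am, file.path(out, "amova.tsv")))

  dv <- stage("diversity", diversity_report(gm_f, groups$group))
  emit(function() write_diversity(dv, file.path(out, "diversity.tsv")))

  emit(function() {
    manifest <- list(
      package = "popdiv",
      version = as.character(utils::packageVersion("popdiv")),
      config = unclass(config),
      dims = list(samples_in = n_samples(gm), markers_in = n_markers(gm),
                  samples_out = n_samples(gm_f),
                  markers_out = n_markers(gm_f)),
      best_K = best_K,
      flags = list(
        call_rate_bounds = "strict (>)", maf_bound = "inclusive (>=)",
        filter_order = "samples then markers",
        imputation = config$impute_mode,
        structure_method = "maximum-likelihood admixture EM (not MCMC)",
        evanno_sd_source = "replicate random restarts",
        distance = "squared Euclidean on minor-allele dosage",
        negative_Va = "truncated to 0",
        pca = "covariance, sign fixed by largest loading",
        dendrogram_components = config$pca_components))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  structure(list(gm = gm_f, filter_reports = qc$reports,
                 marker_summary = ms, chrom_distribution = cd,
                 k_scan = scan, evanno = ev, best_K = best_K, fit = fit,
                 groups = groups, pca = pc, dendrogram = dnd, amova = am,
                 diversity = dv, config = config),
            class = "popdiv_run")
}

#' @export
print.popdiv_run <- function(x, ...) {
  cat("popdiv pipeline run\n")
  cat("  panel after QC:", n_samples(x$gm), "samples x", n_markers(x$gm),
      "markers\n")
  cat("  best K (Evanno):", x$best_K, "\n")
  cat(sprintf("  AMOVA: PhiPT = %.4f (%s%% among, %s%% within)\n",
              x$amova$phi_pt, round(x$amova$pct_among),
              round(x$amova$pct_within)))
  nm <- x$amova$Nm
  cat("  Nm:", if (is.infinite(nm)) "unbounded" else sprintf("%.3f", nm),
      "\n")
  invisible(x)
}
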