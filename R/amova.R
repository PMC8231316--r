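# One-level analysis of molecular variance on squared Euclidean dosage
# distances (the codominant-genotypic convention). With N samples in k
# groups of sizes n_g:
#   SS_total  = (1/N) sum_{i<j} d2_ij
#   SS_within = sum_g (1/n_g) sum_{i<j in g} d2_ij
#   SS_among  = SS_total - SS_within
#   n0 = (N - sum n_g^2 / N) / (k - 1)
#   Va = max(0, (MS_among - MS_within) / n0),  Vw = MS_within
#   PhiPT = Va / (Va + Vw)
# The permutation p-value shuffles whole-individual group labels.

#' Squared Euclidean distance matrix on dosages
#'
#' `d2_ij = sum_l (x_il - x_jl)^2` on the minor-allele dosage matrix, the
#' standard codominant genotypic distance for AMOVA.
#'
#' @param X complete samples x loci dosage matrix or complete
#'   [genotype_matrix()].
#' @return symmetric samples x samples matrix of squared distances with a
#'   zero diagonal.
#' @export
squared_distance_matrix <- function(X) {
  if (is_genotype_matrix(X)) X <- X$calls
  X <- as.matrix(X)
  if (anyNA(X)) {
    stop("distance matrix needs complete data; run impute_naive() first")
  }
  D2 <- as.matrix(dist(X))^2
  dimnames(D2) <- list(rownames(X), rownames(X))
  D2
}

#' One-level AMOVA with PhiPT, permutation test and Nm
#'
#' Partitions the total molecular variance into among- and within-group
#' components from a squared-distance matrix, estimates PhiPT =
#' Va / (Va + Vw) (negative Va truncated to 0), and tests it by permuting
#' whole-individual group labels. Unequal group sizes enter through the
#' average-sample-size coefficient n0.
#'
#' @param D2 squared-distance matrix from [squared_distance_matrix()].
#' @param labels group label per sample (vector, >= 2 groups, each of
#'   size >= 2).
#' @param n_perm number of label permutations for the p-value (default 999;
#'   0 skips the test, p is then `NA`).
#' @param seed integer seed for the permutations.
#' @return object of class `amova_result` with `df_among`, `df_within`,
#'   `SS_among`, `SS_within`, `SS_total`, `MS_among`, `MS_within`, `n0`,
#'   `Va`, `Vw`, `phi_pt`, `pct_among`, `pct_within`, `p_value`, `Nm`,
#'   `n_perm`, `group_sizes`.
#' @export
amova_one_level <- function(D2, labels, n_perm = 999, seed = 1) {
  D2 <- as.matrix(D2)
  N <- nrow(D2)
  stopifnot(ncol(D2) == N, length(labels) == N)
  if (max(abs(D2 - t(D2))) > 1e-8 || any(abs(diag(D2)) > 1e-8)) {
    stop("D2 must be symmetric with a zero diagonal")
  }
  labels <- as.character(labels)
  sizes <- table(labels)
  k <- length(sizes)
  if (k < 2) stop("AMOVA needs at least 2 groups")
  if (any(sizes < 2)) {
    stop("every group needs >= 2 members (group ",
         names(sizes)[which(sizes < 2)[1]], " has ",
         min(sizes), ")")
  }
  upper <- upper.tri(D2)
  SS_total <- sum(D2[upper]) / N
  ss_within_for <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      s <- s + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    s
  }
  phi_for <- function(lab) {
    ssw <- ss_within_for(lab)
    ssa <- SS_total - ssw
    msa <- ssa / (k - 1)
    msw <- ssw / (N - k)
    va <- max(0, (msa - msw) / n0)
    if (va + msw == 0) 0 else va / (va + msw)
  }
  n0 <- (N - sum(sizes^2) / N) / (k - 1)
  SS_within <- ss_within_for(labels)
  SS_among <- SS_total - SS_within
  df_among <- k - 1
  df_within <- N - k
  MS_among <- SS_among / df_among
  MS_within <- SS_within / df_within
  Va <- max(0, (MS_among - MS_within) / n0)
  Vw <- MS_within
  phi_pt <- if (Va + Vw == 0) 0 else Va / (Va + Vw)
  pct_among <- 100 * phi_pt
  p_value <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (phi_for(sample(labels)) >= phi_pt) exceed <- exceed + 1L
    }
    p_value <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(df_among = df_among, df_within = df_within,
                 SS_among = SS_among, SS_within = SS_within,
                 SS_total = SS_total, MS_among = MS_among,
                 MS_within = MS_within, n0 = n0, Va = Va, Vw = Vw,
                 phi_pt = phi_pt, pct_among = pct_among,
                 pct_within = 100 - pct_among, p_value = p_value,
                 Nm = nm_haploid(Va, Vw), n_perm = n_perm,
                 group_sizes = as.vector(sizes), seed = seed),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  nm_chr <- if (is.infinite(x$Nm)) "unbounded" else sprintf("%.3f", x$Nm)
  tab <- data.frame(
    Source = c("Among Pops", "Within Pops", "Total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    SS = round(c(x$SS_among, x$SS_within, x$SS_total), 3),
    MS = c(round(x$MS_among, 3), round(x$MS_within, 3), NA),
    Est.Var. = round(c(x$Va, x$Vw, x$Va + x$Vw), 3),
    `%` = sprintf("%.0f%%", c(x$pct_among, x$pct_within, 100)),
    Nm = c(nm_chr, "", ""), check.names = FALSE)
  cat("AMOVA (", length(x$group_sizes), " groups, sizes ",
      paste(x$group_sizes, collapse = "/"), ")\n", sep = "")
  print(tab, row.names = FALSE)
  cat(sprintf("PhiPT = %.4f", x$phi_pt))
  if (!is.na(x$p_value)) {
    cat(sprintf("  (P = %.3g, %d permutations)", x$p_value, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' Haploid number of migrants from AMOVA variance components
#'
#' `Nm = [1 / (Va / (Va + Vw)) - 1] / 2`, algebraically `Vw / (2 Va)`: the
#' effective number of migrants per generation implied by the among- and
#' within-population variance components. `Va = 0` means no detectable
#' differentiation and unbounded gene flow; `Inf` is returned and reports
#' should print it as "unbounded".
#'
#' @param va among-population variance component (>= 0).
#' @param vw within-population variance component (>= 0).
#' @return the migrant number (possibly `Inf`).
#' @examples
#' nm_haploid(14.292, 2470.518) # 86.428
#' @export
nm_haploid <- function(va, vw) {
  stopifnot(va >= 0, vw >= 0)
  if (va == 0) return(Inf)
  (1 / (va / (va + vw)) - 1) / 2
}

#' Write an AMOVA result as a TSV table
#'
#' Uses the conventional column layout (Source, df, SS, MS, Est. Var., %,
#' Nm); an unbounded Nm is written as the string `unbounded`.
#'
#' @param x an [amova_one_level()] result.
#' @param path output path.
#' @export
write_amova <- function(x, path) {
  stopifnot(inherits(x, "amova_result"))
  nm_chr <- if (is.infinite(x$Nm)) "unbounded" else sprintf("%.3f", x$Nm)
  tab <- data.frame(
    Source = c("Among Pops", "Within Pops", "Total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    SS = round(c(x$SS_among, x$SS_within, x$SS_total), 3),
    MS = round(c(x$MS_among, x$MS_within, NA), 3),
    Est.Var. = round(c(x$Va, x$Vw, x$Va + x$Vw), 3),
    pct = round(c(x$pct_among, x$pct_within, 100), 2),
    Nm = c(nm_chr, "", ""),
    P = c(ifelse(is.na(x$p_value), "", format(x$p_value)), "", ""))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
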