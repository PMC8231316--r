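# Per-subpopulation allelic-pattern indices in the "haploid" convention
# appropriate for inbred lines: at each biallelic locus the two allele
# frequencies within a subpopulation are (1 - f, f) with
# f = sum(dosage) / (2 * n_obs), so a residual heterozygote contributes half
# a count to each allele. Per-locus indices:
#   Na = number of alleles with frequency > 0   (1 or 2)
#   Ne = 1 / (1 - h)       effective number of alleles
#   I  = -sum p ln p       Shannon information index (0 ln 0 = 0)
#   h  = 1 - sum p^2       haploid gene diversity
#   uh = n/(n-1) * h       unbiased gene diversity
# Each index is averaged across loci, with standard errors sd/sqrt(L).

#' Per-subpopulation allele frequencies
#'
#' @param gm a [genotype_matrix()].
#' @param labels subgroup label per sample.
#' @return object of class `pop_allele_freq`: `freq` (pops x loci frequency
#'   of the counted/minor allele), `n_obs` (pops x loci non-missing line
#'   counts), `n` (lines per pop), `excluded` (pops x loci logical, TRUE
#'   where a locus has no data in that pop and is excluded from its
#'   averages).
#' @export
pop_allele_frequencies <- function(gm, labels) {
  stopifnot(is_genotype_matrix(gm))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(gm$calls))
  pops <- sort(unique(labels))
  L <- ncol(gm$calls)
  freq <- n_obs <- matrix(NA_real_, length(pops), L,
                          dimnames = list(pops, gm$markers$id))
  for (i in seq_along(pops)) {
    rows <- gm$calls[labels == pops[i], , drop = FALSE]
    if (nrow(rows) == 0) stop("empty subpopulation: ", pops[i])
    nn <- colSums(!is.na(rows))
    n_obs[i, ] <- nn
    freq[i, ] <- ifelse(nn > 0, colSums(rows, na.rm = TRUE) / (2 * nn),
                        NA_real_)
  }
  excluded <- n_obs == 0
  if (any(excluded)) {
    warning(sum(excluded), " pop x locus cell(s) have no data and are ",
            "excluded from that pop's averages")
  }
  structure(list(freq = freq, n_obs = n_obs,
                 n = as.vector(table(factor(labels, levels = pops))),
                 pops = pops, excluded = excluded),
            class = "pop_allele_freq")
}

#' Per-locus allele count
#'
#' Number of alleles at a biallelic locus with frequency above a threshold:
#' with `threshold = 0` this is the direct count of observed alleles (Na);
#' with `threshold = 0.05` the "Na with frequency >= 5%" variant. Vectorized
#' over loci.
#'
#' @param f minor/counted-allele frequency per locus.
#' @param threshold inclusive frequency threshold (default 0 counts any
#'   allele present).
#' @export
allele_count <- function(f, threshold = 0) {
  if (threshold == 0) {
    (f > 0) + (f < 1)
  } else {
    (f >= threshold) + ((1 - f) >= threshold)
  }
}

#' Effective number of alleles per locus
#'
#' `Ne = 1 / (1 - He)` with `He = 1 - sum p^2`; a fixed locus has `Ne = 1`.
#'
#' @param f minor/counted-allele frequency per locus (vectorized).
#' @export
effective_alleles <- function(f) {
  he <- 2 * f * (1 - f)
  1 / (1 - he)
}

#' Shannon information index per locus
#'
#' `I = -sum p ln p` over the two allele frequencies, with zero-frequency
#' terms contributing 0.
#'
#' @inheritParams effective_alleles
#' @export
shannon_index <- function(f) {
  term <- function(p) ifelse(p > 0, -p * log(p), 0)
  term(f) + term(1 - f)
}

#' Haploid gene diversity and its unbiased version
#'
#' `h = 1 - sum p^2` (the probability that two random allele draws differ)
#' and `uh = n/(n-1) h`.
#'
#' @inheritParams effective_alleles
#' @param n sample size(s); `uh` is `NA` where `n < 2`.
#' @return list with vectors `h` and `uh`.
#' @export
haploid_diversity <- function(f, n) {
  h <- 2 * f * (1 - f)
  nn <- rep_len(n, length(h))
  uh <- ifelse(nn >= 2, nn / (nn - 1) * h, NA_real_)
  list(h = h, uh = uh)
}

#' Private alleles per subpopulation and per line
#'
#' An allele is private to subpopulation g at a locus if its frequency is
#' positive in g and zero in every other subpopulation. The subpopulation
#' statistic is the mean per-locus count of private alleles; per-line counts
#' are the number of loci at which a line carries at least one copy of an
#' allele private to its own subpopulation.
#'
#' @param paf a [pop_allele_frequencies()] result.
#' @param gm the [genotype_matrix()] the frequencies came from.
#' @param labels subgroup label per sample (same coding as `paf`).
#' @return list with `pa_mean` and `pa_se` (per pop, across loci),
#'   `lines_with_pa` (count per pop), `pa_range` (min-max of nonzero
#'   per-line counts per pop), `per_line` (data.frame sample/group/count).
#' @export
private_alleles <- function(paf, gm, labels) {
  stopifnot(inherits(paf, "pop_allele_freq"))
  labels <- as.character(labels)
  pops <- paf$pops
  if (length(pops) < 2) stop("private alleles need >= 2 subpopulations")
  f <- paf$freq
  L <- ncol(f)
  # counted (minor) allele present / major allele present, NA-safe
  minor_pres <- !is.na(f) & f > 0
  major_pres <- !is.na(f) & f < 1
  pa_minor <- pa_major <- matrix(FALSE, length(pops), L,
                                 dimnames = dimnames(f))
  for (i in seq_along(pops)) {
    others <- minor_pres[-i, , drop = FALSE]
    pa_minor[i, ] <- minor_pres[i, ] & colSums(others) == 0
    pa_major[i, ] <- major_pres[i, ] & colSums(major_pres[-i, , drop = FALSE]) == 0
  }
  pa_count <- pa_minor + pa_major # 0, 1 or 2 private alleles per locus
  pa_mean <- rowMeans(pa_count)
  pa_se <- apply(pa_count, 1, sd) / sqrt(L)
  per_line <- integer(nrow(gm$calls))
  for (s in seq_len(nrow(gm$calls))) {
    i <- match(labels[s], pops)
    d <- gm$calls[s, ]
    carries_minor <- pa_minor[i, ] & !is.na(d) & d >= 1
    carries_major <- pa_major[i, ] & !is.na(d) & d <= 1
    per_line[s] <- sum(carries_minor | carries_major)
  }
  per_line_df <- data.frame(sample = rownames(gm$calls), group = labels,
                            pa_count = per_line, stringsAsFactors = FALSE)
  lines_with <- vapply(pops, function(p) {
    sum(per_line[labels == p] > 0)
  }, integer(1))
  pa_range <- t(vapply(pops, function(p) {
    x <- per_line[labels == p]
    x <- x[x > 0]
    if (length(x) == 0) c(NA_integer_, NA_integer_) else range(x)
  }, integer(2)))
  colnames(pa_range) <- c("min", "max")
  list(pa_mean = setNames(pa_mean, pops), pa_se = setNames(pa_se, pops),
       lines_with_pa = lines_with, pa_range = pa_range,
       per_line = per_line_df)
}

#' Allelic-pattern and diversity report per subpopulation
#'
#' Computes, for each subpopulation and as an across-subpopulation
#' arithmetic mean, the indices Na, Na with frequency >= 5%, Ne, Shannon's
#' I, gene diversity h, unbiased diversity uh, and the private-allele
#' statistics. Standard errors are across-locus `sd / sqrt(L)`. For h/uh the
#' per-locus non-missing sample size is used.
#'
#' @param gm a [genotype_matrix()].
#' @param labels subgroup label per sample.
#' @param freq_threshold threshold for the restricted allele count
#'   (default 0.05).
#' @return object of class `diversity_report`: `table` (rows = indices,
#'   columns = subpopulations + Mean), `se` (matching standard errors),
#'   `private` (the [private_alleles()] list), `n` (lines per pop).
#' @export
diversity_report <- function(gm, labels, freq_threshold = 0.05) {
  paf <- pop_allele_frequencies(gm, labels)
  pops <- paf$pops
  idx_names <- c("Na", "Na_freq_ge_5pct", "Ne", "I", "h", "uh", "PA")
  tab <- se <- matrix(NA_real_, length(idx_names), length(pops),
                      dimnames = list(idx_names, pops))
  for (i in seq_along(pops)) {
    ok <- !paf$excluded[i, ]
    f <- paf$freq[i, ok]
    n <- paf$n_obs[i, ok]
    vals <- list(Na = allele_count(f),
                 Na_freq_ge_5pct = allele_count(f, freq_threshold),
                 Ne = effective_alleles(f),
                 I = shannon_index(f))
    hu <- haploid_diversity(f, n)
    vals$h <- hu$h
    vals$uh <- hu$uh
    for (v in names(vals)) {
      tab[v, i] <- mean(vals[[v]], na.rm = TRUE)
      se[v, i] <- sd(vals[[v]], na.rm = TRUE) / sqrt(sum(!is.na(vals[[v]])))
    }
  }
  priv <- private_alleles(paf, gm, labels)
  tab["PA", ] <- priv$pa_mean
  se["PA", ] <- priv$pa_se
  tab <- cbind(tab, Mean = rowMeans(tab))
  structure(list(table = tab, se = se, private = priv, n = paf$n,
                 pops = pops), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("Allelic patterns and diversity indexes (",
      paste(x$pops, collapse = ", "), "; n = ",
      paste(x$n, collapse = "/"), ")\n", sep = "")
  print(round(x$table, 4))
  cat("Lines with PA:", paste(x$private$lines_with_pa, collapse = " / "),
      "\n")
  rng <- x$private$pa_range
  cat("Range of PA:  ",
      paste(sprintf("%s-%s", rng[, "min"], rng[, "max"]), collapse = " / "),
      "\n")
  invisible(x)
}

#' Write a diversity report as TSV
#'
#' Rows follow the conventional table layout (Na, Na Freq. >= 5%, Ne, I, h,
#' uh, PA, Lines with PA, Range of PA), one column per subpopulation plus
#' the across-subpopulation Mean.
#'
#' @param x a [diversity_report()].
#' @param path output path.
#' @export
write_diversity <- function(x, path) {
  stopifnot(inherits(x, "diversity_report"))
  main <- format(round(x$table, 4), trim = TRUE)
  rng <- x$private$pa_range
  extra <- rbind(`Lines with PA` = c(x$private$lines_with_pa, ""),
                 `Range of PA` = c(sprintf("%s-%s", rng[, "min"],
                                           rng[, "max"]), ""))
  rownames(main) <- c("Na", "Na Freq. >= 5%", "Ne", "I", "h", "uh", "PA")
  out <- rbind(main, extra)
  df <- data.frame(Index = rownames(out), out, check.names = FALSE,
                   row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
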