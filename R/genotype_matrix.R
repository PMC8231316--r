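#' Genotype panel container
#'
#' A `genotype_matrix` holds biallelic SNP calls for a panel of (largely
#' inbred) lines as copies of the minor allele: 0 = homozygous major,
#' 1 = heterozygous, 2 = homozygous minor, `NA` = missing. Marker metadata
#' (id, chromosome, physical position in bp, major/minor allele) travels with
#' the calls. Markers are stored sorted by chromosome then position.
#'
#' @param calls numeric matrix, samples in rows and markers in columns, with
#'   values in \{0, 1, 2, NA\}. Row names are sample ids, column names marker
#'   ids (filled in from `markers$id` when absent).
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `major`, `minor` (single bases; `minor` may be `NA` for a locus whose
#'   second allele was never observed).
#' @return An object of class `genotype_matrix` with elements `calls` and
#'   `markers`.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("s1", "s2"), NULL)),
#'   data.frame(id = c("m1", "m2"), chrom = "1A", pos = c(100L, 200L),
#'              major = c("A", "C"), minor = c("G", "T"))
#' )
#' gm
#' @export
genotype_matrix <- function(calls, markers) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  stopifnot(is.data.frame(markers))
  required <- c("id", "chrom", "pos", "major", "minor")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0) {
    stop("markers is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(markers) != ncol(calls)) {
    stop("markers has ", nrow(markers), " rows but calls has ", ncol(calls),
         " columns")
  }
  bad <- !(calls %in% c(0, 1, 2) | is.na(calls))
  if (any(bad)) {
    stop("calls contains values outside {0, 1, 2, NA}: e.g. ",
         calls[which(bad)[1]])
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("sample_%03d", seq_len(nrow(calls)))
  }
  if (anyDuplicated(rownames(calls))) stop("sample ids must be unique")
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  if (anyDuplicated(markers$id)) stop("marker ids must be unique")
  if (any(markers$pos < 0)) stop("marker positions must be >= 0")
  same <- !is.na(markers$minor) & markers$major == markers$minor
  if (any(same)) {
    stop("major and minor allele identical for marker ",
         markers$id[which(same)[1]])
  }
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(markers) <- NULL
  colnames(calls) <- markers$id
  dup_pos <- duplicated(markers[, c("chrom", "pos")])
  if (any(dup_pos)) {
    warning(sum(dup_pos), " marker(s) share a chromosome position")
  }
  structure(list(calls = calls, markers = markers), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "markers\n")
  cat("  chromosomes:", length(unique(x$markers$chrom)), "\n")
  cr <- mean(!is.na(x$calls))
  cat(sprintf("  overall call rate: %.3f\n", cr))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  ms <- marker_summary(object)
  cat("genotype_matrix:", nrow(object$calls), "samples x",
      ncol(object$calls), "markers\n")
  ok <- !is.na(ms$maf)
  cat(sprintf("  MAF:  mean %.3f  range %.3f-%.3f\n",
              mean(ms$maf[ok]), min(ms$maf[ok]), max(ms$maf[ok])))
  cat(sprintf("  He:   mean %.4f  max %.4f\n",
              mean(ms$he_obs[ok]), max(ms$he_obs[ok])))
  cat(sprintf("  PIC:  mean %.3f  max %.3f\n",
              mean(ms$pic[ok]), max(ms$pic[ok])))
  invisible(ms)
}

#' @rdname genotype_matrix
#' @param x object to test or subset.
#' @export
is_genotype_matrix <- function(x) inherits(x, "genotype_matrix")

#' Subset a genotype panel
#'
#' @param x a [genotype_matrix()].
#' @param i sample index (logical, integer or character).
#' @param j marker index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(j)) j <- match(j, x$markers$id)
  genotype_matrix(x$calls[i, j, drop = FALSE], x$markers[j, , drop = FALSE])
}

#' @rdname genotype_matrix
#' @export
n_samples <- function(x) {
  stopifnot(is_genotype_matrix(x))
  nrow(x$calls)
}

#' @rdname genotype_matrix
#' @export
n_markers <- function(x) {
  stopifnot(is_genotype_matrix(x))
  ncol(x$calls)
}

#' @rdname genotype_matrix
#' @export
sample_ids <- function(x) {
  stopifnot(is_genotype_matrix(x))
  rownames(x$calls)
}

# Enforce the minor-allele convention per locus: flip any locus whose counted
# allele has frequency > 0.5 (ties broken so the alphabetically smaller base
# is the minor allele). Returns the polarized genotype_matrix.
polarize_minor <- function(gm) {
  calls <- gm$calls
  mk <- gm$markers
  n_obs <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * pmax(n_obs, 1))
  flip <- p > 0.5
  tie <- abs(p - 0.5) < 1e-12 & !is.na(mk$minor)
  # at exact 0.5 the minor allele is the alphabetically smaller base
  flip[tie] <- mk$minor[tie] > mk$major[tie]
  flip[n_obs == 0] <- FALSE
  if (any(flip)) {
    calls[, flip] <- 2 - calls[, flip]
    tmp <- mk$major[flip]
    mk$major[flip] <- mk$minor[flip]
    mk$minor[flip] <- tmp
  }
  genotype_matrix(calls, mk)
}
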