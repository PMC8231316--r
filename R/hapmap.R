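# TASSEL HapMap text format: 11 fixed metadata columns
# (rs#, alleles, chrom, pos, strand, assembly#, center, protLSID, assayLSID,
# panelLSID, QCcode) followed by one column per sample. Diploid genotypes are
# written either as single IUPAC codes (TASSEL style) or as two-letter pairs.

HAPMAP_META_COLS <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                      "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

# decode one genotype string to a two-character allele pair, or NA
decode_call <- function(g) {
  g <- toupper(g)
  n <- nchar(g)
  if (is.na(g) || g %in% c("N", "NA", "NN", "-", "--", "./.", ".")) {
    return(NA_character_)
  }
  if (n == 1) {
    if (g %in% c("A", "C", "G", "T")) return(paste0(g, g))
    if (g %in% names(IUPAC_HET)) return(IUPAC_HET[[g]])
    return(NA_character_)
  }
  if (n == 2) {
    a <- substr(g, 1, 1); b <- substr(g, 2, 2)
    if (all(c(a, b) %in% c("A", "C", "G", "T"))) {
      return(paste0(min(a, b), max(a, b)))
    }
    return(NA_character_)
  }
  NA_character_
}

#' Read a TASSEL HapMap genotype file
#'
#' Parses a tab-separated HapMap table into a [genotype_matrix()]. Genotype
#' calls may be single IUPAC codes (`A`, `R`, ...) or two-letter pairs
#' (`AA`, `AG`); `N`/`NA` are missing. The minor allele at each locus is
#' determined from the observed allele frequencies at read time (ties at
#' frequency 0.5 resolved to the alphabetically smaller base) and dosages
#' count copies of that minor allele. Rows with more than two observed
#' alleles are rejected with a warning. Positions are interpreted as base
#' pairs; when every position is small enough to be megabases (max <= 1e4 or
#' fractional), they are converted to bp and a message is emitted.
#'
#' @param path path to a HapMap text file.
#' @return a [genotype_matrix()].
#' @export
read_hapmap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty HapMap file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  for (col in c("rs#", "alleles", "chrom", "pos")) {
    if (!(col %in% header)) {
      stop("malformed HapMap header: missing column '", col, "'")
    }
  }
  n_meta <- max(match(c("rs#", "alleles", "chrom", "pos"), header),
                length(intersect(header, HAPMAP_META_COLS)))
  n_meta <- max(n_meta, 11L)
  samples <- header[-seq_len(min(n_meta, length(header) - 1))]
  if (length(samples) == 0) stop("HapMap file has no sample columns")
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (length(body) == 0) stop("HapMap file has a header but no markers")

  i_rs <- match("rs#", header); i_al <- match("alleles", header)
  i_ch <- match("chrom", header); i_po <- match("pos", header)
  i_smp <- seq.int(length(header) - length(samples) + 1L, length(header))

  n_mark <- length(body)
  ids <- chroms <- character(n_mark)
  pos_raw <- numeric(n_mark)
  keep <- logical(n_mark)
  dosage <- matrix(NA_real_, length(samples), n_mark)
  major <- minor <- character(n_mark)

  for (r in seq_len(n_mark)) {
    f <- body[[r]]
    if (length(f) < max(i_smp)) {
      warning("row ", r, " has too few fields; skipped")
      next
    }
    ids[r] <- f[i_rs]; chroms[r] <- f[i_ch]
    pos_raw[r] <- suppressWarnings(as.numeric(f[i_po]))
    pairs <- vapply(f[i_smp], decode_call, character(1), USE.NAMES = FALSE)
    alle <- unlist(strsplit(pairs[!is.na(pairs)], ""))
    counts <- sort(table(alle), decreasing = TRUE)
    if (length(counts) > 2) {
      warning("marker ", f[i_rs], " rejected: more than two alleles observed (",
              paste(names(counts), collapse = ","), ")")
      next
    }
    keep[r] <- TRUE
    declared <- toupper(strsplit(f[i_al], "/", fixed = TRUE)[[1]])
    declared <- declared[declared %in% c("A", "C", "G", "T")]
    if (length(counts) == 2) {
      # minor = rarer allele; ties -> alphabetically smaller base
      if (counts[1] == counts[2]) {
        minor[r] <- min(names(counts)); major[r] <- max(names(counts))
      } else {
        major[r] <- names(counts)[1]; minor[r] <- names(counts)[2]
      }
    } else if (length(counts) == 1) {
      major[r] <- names(counts)[1]
      other <- setdiff(declared, major[r])
      minor[r] <- if (length(other) >= 1) other[1] else NA_character_
    } else { # every call missing; fall back on the declared alleles
      major[r] <- if (length(declared) >= 1) declared[1] else "A"
      minor[r] <- if (length(declared) >= 2) declared[2] else NA_character_
    }
    ok <- !is.na(pairs)
    if (any(ok)) {
      cnt <- vapply(strsplit(pairs[ok], ""), function(ab) {
        sum(ab == minor[r])
      }, numeric(1))
      dosage[ok, r] <- cnt
    }
  }

  if (!any(keep)) stop("no usable biallelic markers in ", path)
  pos <- pos_raw[keep]
  if (any(is.na(pos))) stop("non-numeric positions in HapMap file")
  # positions printed in Mb (small magnitudes / fractional) are scaled to bp
  if (max(pos) <= 1e4 || any(pos != floor(pos))) {
    message("read_hapmap: positions look like Mb; converting to bp")
    pos <- round(pos * 1e6)
  }
  calls <- dosage[, keep, drop = FALSE]
  rownames(calls) <- samples
  genotype_matrix(calls,
                  data.frame(id = ids[keep], chrom = chroms[keep],
                             pos = as.integer(pos), major = major[keep],
                             minor = minor[keep], stringsAsFactors = FALSE))
}

#' Write a genotype panel as TASSEL HapMap
#'
#' Emits the 11-column TASSEL dialect (UTF-8, LF line endings) with single
#' IUPAC genotype letters; heterozygotes use the ambiguity code for the
#' allele pair and missing calls are written as `N`. [read_hapmap()] inverts
#' the file bit-exactly for calls, positions and allele metadata.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(gm, path) {
  stopifnot(is_genotype_matrix(gm))
  mk <- gm$markers
  het_code <- setNames(names(IUPAC_HET), IUPAC_HET)
  geno_letter <- function(d, a, b) {
    # d copies of minor allele b on a major-allele-a background
    if (is.na(d)) return("N")
    if (d == 0) return(a)
    if (d == 2) return(b)
    pair <- paste0(min(a, b), max(a, b))
    het_code[[pair]]
  }
  minor_chr <- ifelse(is.na(mk$minor), "N", mk$minor)
  rows <- vapply(seq_len(nrow(mk)), function(j) {
    g <- vapply(gm$calls[, j], geno_letter, character(1),
                a = mk$major[j], b = minor_chr[j])
    paste(c(mk$id[j], paste0(mk$major[j], "/", minor_chr[j]), mk$chrom[j],
            mk$pos[j], "+", rep("NA", 6), g), collapse = "\t")
  }, character(1))
  header <- paste(c(HAPMAP_META_COLS, rownames(gm$calls)), collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
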