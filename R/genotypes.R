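#' Genotype matrix container
#'
#' Stores biallelic pseudo-diploid SNP genotypes for a set of clones, coded
#' 0 (homozygous reference), 1 (heterozygous) and 2 (homozygous alternate),
#' with \code{NA} for missing calls.  Collapsing all heterozygous dosage
#' classes of a polyploid into the single code 1 is the usual
#' "pseudo-diploid" treatment of single-dose markers in sugarcane.
#' Per-locus genotype frequencies (p_AA, p_Aa, p_aa), computed over
#' non-missing calls, ride along because every NOIA quantity is a function
#' of them.
#'
#' @param codes integer matrix, clones in rows, SNPs in columns, entries in
#'   \{0, 1, 2, NA\}.  Row and column names are used as clone and SNP ids
#'   when present.
#' @param clone_ids,snp_ids optional identifier vectors overriding dimnames.
#' @return An object of class \code{geno_matrix}: a list with elements
#'   \code{codes}, \code{clone_ids}, \code{snp_ids} and \code{freqs}
#'   (n_snps x 3 matrix with columns \code{p_AA}, \code{p_Aa}, \code{p_aa}).
#' @export
geno_matrix <- function(codes, clone_ids = NULL, snp_ids = NULL) {
  codes <- as.matrix(codes)
  if (is.null(clone_ids)) {
    clone_ids <- rownames(codes)
    if (is.null(clone_ids)) clone_ids <- paste0("clone", seq_len(nrow(codes)))
  }
  if (is.null(snp_ids)) {
    snp_ids <- colnames(codes)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(codes)))
  }
  if (anyDuplicated(clone_ids)) stop("duplicate clone ids")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(codes)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype code at row %d (clone %s), column %d (%s)",
                 idx[1L], clone_ids[idx[1L]], idx[2L], snp_ids[idx[2L]]))
  }
  storage.mode(codes) <- "integer"
  dimnames(codes) <- list(clone_ids, snp_ids)
  obj <- list(codes = codes, clone_ids = clone_ids, snp_ids = snp_ids,
              freqs = genotype_freqs(codes))
  class(obj) <- "geno_matrix"
  obj
}

#' Per-locus genotype frequencies
#'
#' @param codes matrix of 0/1/2 codes with possible \code{NA}s.
#' @return matrix with one row per locus and columns p_AA, p_Aa, p_aa; rows
#'   sum to 1 over non-missing calls (\code{NaN} if a locus has no calls).
#' @export
genotype_freqs <- function(codes) {
  if (inherits(codes, "geno_matrix")) codes <- codes$codes
  n0 <- colSums(codes == 0L, na.rm = TRUE)
  n1 <- colSums(codes == 1L, na.rm = TRUE)
  n2 <- colSums(codes == 2L, na.rm = TRUE)
  tot <- n0 + n1 + n2
  out <- cbind(p_AA = n0 / tot, p_Aa = n1 / tot, p_aa = n2 / tot)
  rownames(out) <- colnames(codes)
  out
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$codes))
  cat(sprintf("geno_matrix: %d clones x %d SNPs (%.2f%% missing)\n",
              length(x$clone_ids), length(x$snp_ids), 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Mean-impute missing genotype codes
#'
#' Replaces missing calls at a locus by the mean of its observed codes
#' (a real value), the standard practice for relationship-matrix
#' construction: it preserves the locus allele-frequency expectation and
#' contributes nothing to the centred incidence columns on average.
#'
#' @param g a \code{geno_matrix}.
#' @return numeric matrix of (possibly fractional) codes without \code{NA}s.
#' @export
impute_codes <- function(g) {
  x <- g$codes
  storage.mode(x) <- "double"
  if (!anyNA(x)) return(x)
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2L]]
  x
}

#' Read genotypes from VCF or a clone x SNP matrix
#'
#' VCF input must contain biallelic SNPs with a GT field; diploid calls are
#' mapped 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2 and ./. -> NA.  The
#' \code{matrix_tsv} dialect is tab-separated with clone ids in the first
#' column and a header row of SNP ids; cells are 0/1/2/NA.
#'
#' @param path file path.
#' @param format \code{"vcf"} or \code{"matrix_tsv"}.
#' @return a \code{geno_matrix}.
#' @export
read_genotypes <- function(path, format = c("matrix_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(vcf)
    multi <- grepl(",", alt)
    if (any(multi)) {
      stop(sprintf("multi-allelic record at %s:%s (ALT=%s); only biallelic SNPs are supported",
                   vcfR::getCHROM(vcf)[multi][1L], vcfR::getPOS(vcf)[multi][1L],
                   alt[multi][1L]))
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    snp_ids <- rownames(gt)
    if (is.null(snp_ids) || anyNA(snp_ids)) {
      snp_ids <- paste0(vcfR::getCHROM(vcf), "_", vcfR::getPOS(vcf))
    }
    gt <- sub("\\|", "/", gt)
    map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    codes <- matrix(map[gt], nrow = nrow(gt))   # unmatched (./., .) -> NA
    codes <- t(codes)
    dimnames(codes) <- list(colnames(gt), snp_ids)
    geno_matrix(codes)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    clone_ids <- as.character(tab[[1L]])
    codes <- as.matrix(tab[, -1L, drop = FALSE])
    bad <- !(codes %in% c(0, 1, 2) | is.na(codes))
    if (any(bad)) {
      idx <- which(matrix(bad, nrow(codes)), arr.ind = TRUE)[1L, ]
      stop(sprintf("unknown genotype code '%s' at row %d, column %s",
                   codes[idx[1L], idx[2L]], idx[1L], colnames(codes)[idx[2L]]))
    }
    rownames(codes) <- clone_ids
    geno_matrix(codes)
  }
}

#' Write genotypes in the matrix_tsv dialect
#'
#' @param g a \code{geno_matrix}.
#' @param path output file path.
#' @export
write_genotypes <- function(g, path) {
  tab <- data.frame(clone = g$clone_ids, g$codes, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker and clone quality control
#'
#' Applies the standard pre-processing for array-genotyped clonal
#' populations: clones with low call rate are removed first, locus
#' statistics are recomputed, then loci failing the locus call-rate
#' threshold, loci whose alternate-allele frequency falls below
#' \code{maf_min}, and monomorphic loci are removed.  The alternate-allele
#' frequency is used exactly as defined (not folded to min(p, 1-p)): the
#' alternate allele is the one whose homozygote is coded 2.
#'
#' @param g a \code{geno_matrix}.
#' @param maf_min minimum alternate-allele frequency (default 0.01).
#' @param locus_call_min minimum locus call rate (default 0.90).
#' @param clone_call_min minimum clone call rate (default 0.90).
#' @return list with elements \code{genotypes} (filtered \code{geno_matrix},
#'   frequencies recomputed on retained calls) and \code{report}
#'   (\code{qc_report}).
#' @export
apply_qc <- function(g, maf_min = 0.01, locus_call_min = 0.90,
                     clone_call_min = 0.90) {
  stopifnot(maf_min >= 0, maf_min <= 1, locus_call_min >= 0,
            locus_call_min <= 1, clone_call_min >= 0, clone_call_min <= 1)
  codes <- g$codes
  n_clones_in <- nrow(codes); n_snps_in <- ncol(codes)

  clone_cr <- rowMeans(!is.na(codes))
  drop_clone <- clone_cr < clone_call_min
  dropped_clones <- data.frame(
    clone = g$clone_ids[drop_clone],
    reason = rep("low_call_rate", sum(drop_clone)),
    stringsAsFactors = FALSE)
  codes <- codes[!drop_clone, , drop = FALSE]

  locus_cr <- colMeans(!is.na(codes))
  fr <- genotype_freqs(codes)
  alt_freq <- fr[, "p_aa"] + fr[, "p_Aa"] / 2
  mono <- fr[, "p_AA"] == 1 | fr[, "p_Aa"] == 1 | fr[, "p_aa"] == 1 |
    is.nan(alt_freq)
  low_cr <- locus_cr < locus_call_min
  low_maf <- !is.nan(alt_freq) & alt_freq < maf_min
  # precedence: call rate, then rare alternate allele, then monomorphic
  reason <- rep(NA_character_, ncol(codes))
  reason[mono] <- "monomorphic"
  reason[low_maf] <- "low_maf"
  reason[low_cr] <- "low_call_rate"
  drop_snp <- !is.na(reason)
  dropped_snps <- data.frame(
    snp = colnames(codes)[drop_snp],
    reason = reason[drop_snp],
    stringsAsFactors = FALSE)
  codes <- codes[, !drop_snp, drop = FALSE]
  if (ncol(codes) == 0L) stop("empty genotype matrix after QC")

  report <- structure(list(
    n_snps_in = n_snps_in, n_snps_out = ncol(codes),
    n_clones_in = n_clones_in, n_clones_out = nrow(codes),
    dropped_snps = dropped_snps, dropped_clones = dropped_clones,
    thresholds = c(maf_min = maf_min, locus_call_min = locus_call_min,
                   clone_call_min = clone_call_min)),
    class = "qc_report")
  list(genotypes = geno_matrix(codes), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d -> %d SNPs, %d -> %d clones\n",
              x$n_snps_in, x$n_snps_out, x$n_clones_in, x$n_clones_out))
  if (nrow(x$dropped_snps))
    print(table(x$dropped_snps$reason))
  invisible(x)
}

#' Write a QC report as a tab-separated log
#'
#' @param report a \code{qc_report}.
#' @param path output file path.
#' @export
write_qc_report <- function(report, path) {
  items <- rbind(
    data.frame(axis = rep("snp", nrow(report$dropped_snps)),
               id = report$dropped_snps$snp,
               reason = report$dropped_snps$reason),
    data.frame(axis = rep("clone", nrow(report$dropped_clones)),
               id = report$dropped_clones$clone,
               reason = report$dropped_clones$reason))
  utils::write.table(items, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
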