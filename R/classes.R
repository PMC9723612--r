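# Core containers. Genotypes and haplotypes use a shared integer coding:
# 0 = missing, 1 = the SNP's reference allele, 2 = the alternative allele.

GENO_MISSING <- 0L
GENO_REF <- 1L
GENO_ALT <- 2L

PHASE_LEVELS <- c("unphased", "h1_ref", "h1_alt")

#' Ordered table of biallelic heterozygous SNPs on one chromosome
#'
#' The marker ladder everything else is indexed against. Positions are 1-based
#' base pairs and must be strictly increasing; both alleles must be single
#' bases from A/C/G/T and differ from each other. The `phase` column records,
#' when known, which allele haplotype 1 carries (`"h1_ref"` / `"h1_alt"`,
#' otherwise `"unphased"`).
#'
#' @param chrom chromosome name (recycled to one value for all records).
#' @param pos integer vector of 1-based positions, strictly increasing.
#' @param ref,alt single-base allele characters.
#' @param phase per-SNP phase code, one of `"unphased"`, `"h1_ref"`, `"h1_alt"`.
#' @return a `data.frame` of class `snp_table` with columns
#'   `chrom`, `pos`, `ref`, `alt`, `phase`.
#' @export
snp_table <- function(chrom, pos, ref, alt, phase = "unphased") {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  phase <- rep_len(as.character(phase), n)
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   phase = phase, stringsAsFactors = FALSE)
  class(df) <- c("snp_table", "data.frame")
  validate_snp_table(df)
  df
}

validate_snp_table <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (length(unique(x$chrom)) != 1L)
    stop("snp_table: all records must share one chromosome")
  if (any(x$pos < 1L)) stop("snp_table: positions must be >= 1")
  if (any(diff(x$pos) <= 0L))
    stop("snp_table: positions must be strictly increasing")
  bases <- c("A", "C", "G", "T")
  if (!all(x$ref %in% bases) || !all(x$alt %in% bases))
    stop("snp_table: alleles must be single bases A/C/G/T")
  if (any(x$ref == x$alt)) stop("snp_table: ref and alt alleles must differ")
  if (!all(x$phase %in% PHASE_LEVELS))
    stop("snp_table: phase must be one of ", paste(PHASE_LEVELS, collapse = ", "))
  invisible(x)
}

#' Sparse per-cell allele counts over a SNP ladder
#'
#' Cells are rows, SNPs are columns. `ref` and `alt` hold the number of reads
#' supporting the reference and alternative allele respectively; absent
#' entries are zero.
#'
#' @param snps [snp_table()] describing the columns.
#' @param barcodes character vector of unique, non-empty cell barcodes (rows).
#' @param ref,alt non-negative integer matrices (dense or sparse),
#'   `length(barcodes)` x `nrow(snps)`.
#' @return object of class `allele_counts`.
#' @export
allele_counts <- function(snps, barcodes, ref, alt) {
  barcodes <- check_barcodes(barcodes)
  ref <- as_count_matrix(ref)
  alt <- as_count_matrix(alt)
  if (!all(dim(ref) == c(length(barcodes), nrow(snps))) ||
      !all(dim(alt) == dim(ref)))
    stop("allele_counts: matrix dimensions must be cells x SNPs and match")
  rownames(ref) <- rownames(alt) <- barcodes
  structure(list(snps = snps, barcodes = barcodes, ref = ref, alt = alt),
            class = "allele_counts")
}

as_count_matrix <- function(m) {
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (any(m@x < 0)) stop("allele counts must be non-negative")
  if (any(m@x != round(m@x))) stop("allele counts must be integers")
  Matrix::drop0(m)
}

check_barcodes <- function(barcodes) {
  barcodes <- as.character(barcodes)
  if (length(barcodes) == 0L) stop("barcode list is empty")
  if (any(!nzchar(barcodes))) stop("barcodes must be non-empty strings")
  dup <- unique(barcodes[duplicated(barcodes)])
  if (length(dup))
    stop("duplicate barcode(s): ", paste(dup, collapse = ", "))
  barcodes
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d cells x %d SNPs (%s), %d / %d nonzero ref/alt entries\n",
              length(x$barcodes), nrow(x$snps),
              if (nrow(x$snps)) x$snps$chrom[1] else "?",
              length(x$ref@x), length(x$alt@x)))
  invisible(x)
}

#' Complement a haplotype (swap which allele haplotype 1 carries)
#'
#' Missing entries stay missing. Applying it twice is the identity.
#'
#' @param hap integer haplotype vector (0 missing / 1 ref / 2 alt).
#' @export
complement_haplotype <- function(hap) {
  nz <- hap != GENO_MISSING
  hap[nz] <- 3L - hap[nz]
  hap
}

#' Haplotype vector from the phase column of a SNP table
#'
#' @param snps [snp_table()].
#' @return integer vector: 1 where haplotype 1 carries ref, 2 where alt,
#'   0 where unphased.
#' @export
hap_from_phase <- function(snps) {
  h <- integer(nrow(snps))
  h[snps$phase == "h1_ref"] <- GENO_REF
  h[snps$phase == "h1_alt"] <- GENO_ALT
  h
}

#' Phase codes from a haplotype vector
#'
#' Inverse of [hap_from_phase()].
#' @param hap integer haplotype vector.
#' @export
phase_from_hap <- function(hap) {
  PHASE_LEVELS[match(hap, c(GENO_MISSING, GENO_REF, GENO_ALT))]
}

# allele letter carried by haplotype 1 at each SNP ("." when missing)
hap_allele_letter <- function(snps, hap) {
  out <- rep(".", nrow(snps))
  out[hap == GENO_REF] <- snps$ref[hap == GENO_REF]
  out[hap == GENO_ALT] <- snps$alt[hap == GENO_ALT]
  out
}
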