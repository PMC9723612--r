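# File formats: VCF in/out, barcode lists, barcoded-BAM allele counting,
# MatrixMarket sparse matrices, SNP annotation and segment tables.

#' Read biallelic heterozygous SNPs from a VCF
#'
#' Keeps biallelic SNVs whose first-sample genotype is heterozygous
#' (`0/1`, `1/0`, `0|1` or `1|0`) with `QUAL >= min_qual`, sorted by position.
#' Pipe-separated genotypes set the phase (`0|1` means haplotype 1 carries the
#' reference allele, `1|0` the alternative); slash genotypes are unphased.
#'
#' @param vcf_path path to a VCF (plain or bgzipped).
#' @param chrom chromosome to extract; an absent chromosome gives an empty
#'   table, not an error.
#' @param min_qual minimum QUAL; records with missing QUAL pass only when
#'   `min_qual <= 0`.
#' @return [snp_table()].
#' @export
read_hetsnps <- function(vcf_path, chrom, min_qual = 0) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  keep <- as.character(GenomicRanges::seqnames(rr)) == chrom
  empty <- snp_table(character(0), integer(0), character(0), character(0))
  if (!any(keep)) return(empty)
  vcf <- vcf[keep, ]
  rr <- rr[keep]
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  bial <- lengths(altl) == 1L
  alt <- rep(NA_character_, length(ref))
  alt[bial] <- as.character(unlist(altl[bial]))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", vcf_path)
  gt <- gt[, 1L]
  qual <- rr$QUAL
  qual[is.na(qual)] <- 0
  ok <- bial &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    gt %in% c("0/1", "1/0", "0|1", "1|0") &
    qual >= min_qual
  if (!any(ok)) return(empty)
  pos <- GenomicRanges::start(rr)[ok]
  o <- order(pos)
  phase <- c("0|1" = "h1_ref", "1|0" = "h1_alt",
             "0/1" = "unphased", "1/0" = "unphased")[gt[ok]]
  snp_table(chrom, pos[o], ref[ok][o], alt[ok][o], unname(phase)[o])
}

#' Read a cell-barcode list (one barcode per line)
#'
#' Blank lines are skipped; order is preserved; duplicates are an error.
#' @param path text file path.
#' @return character vector of barcodes.
#' @export
read_barcodes <- function(path) {
  if (!file.exists(path)) stop("cannot read barcode list: ", path)
  bc <- readLines(path)
  bc <- trimws(bc)
  bc <- bc[nzchar(bc)]
  check_barcodes(bc)
}

#' Count reference/alternative reads per cell at each SNP from a barcoded BAM
#'
#' Pileup-style counting restricted to the listed barcodes (CB tag).
#' Duplicate, secondary, supplementary and unmapped reads are ignored, as are
#' reads below `min_mapq`, bases below `min_baseq`, reads without a CB tag or
#' with a barcode not in `barcodes`, and bases that match neither allele
#' (including deletions and Ns at the SNP).
#'
#' @param bam_path coordinate-sorted, indexed BAM with CB tags.
#' @param snps [snp_table()].
#' @param barcodes character vector of barcodes to keep.
#' @param min_mapq,min_baseq quality thresholds (defaults 20 / 13).
#' @return [allele_counts()].
#' @export
count_alleles <- function(bam_path, snps, barcodes, min_mapq = 20L,
                          min_baseq = 13L) {
  barcodes <- check_barcodes(barcodes)
  if (!file.exists(bam_path)) stop("cannot read BAM: ", bam_path)
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index (.bai) not found for: ", bam_path)
  empty <- function() {
    z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(barcodes), nrow(snps)))
    allele_counts(snps, barcodes, z, z)
  }
  if (nrow(snps) == 0L) return(empty())
  chrom <- snps$chrom[1]
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (!chrom %in% names(hdr))
    stop("chromosome ", chrom, " absent from BAM header")
  which <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(min(snps$pos), max(snps$pos)))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isDuplicate = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("mapq", "seq", "qual"),
                                   tag = "CB", which = which)
  ga <- GenomicAlignments::readGAlignments(bam_path, param = param)
  mc <- S4Vectors::mcols(ga)
  mapq <- mc$mapq
  mapq[is.na(mapq)] <- -1L
  cb <- mc$CB
  keep <- mapq >= min_mapq & !is.na(cb) & cb %in% barcodes
  ga <- ga[keep]
  if (length(ga) == 0L) return(empty())
  mc <- S4Vectors::mcols(ga)
  # lay read sequences/qualities out in reference space (handles indels/clips)
  seq_ref <- GenomicAlignments::sequenceLayer(mc$seq, GenomicAlignments::cigar(ga))
  qual_ref <- GenomicAlignments::sequenceLayer(methods::as(mc$qual, "BStringSet"),
                                               GenomicAlignments::cigar(ga))
  snp_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(snps$pos, width = 1))
  read_gr <- GenomicRanges::granges(methods::as(ga, "GRanges"))
  hits <- GenomicRanges::findOverlaps(snp_gr, read_gr)
  if (length(hits) == 0L) return(empty())
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  off <- snps$pos[qh] - GenomicRanges::start(read_gr)[sh] + 1L
  base <- as.character(Biostrings::subseq(seq_ref[sh], start = off, width = 1))
  qchr <- as.character(Biostrings::subseq(qual_ref[sh], start = off, width = 1))
  baseq <- as.integer(charToRaw(paste(qchr, collapse = ""))) - 33L
  cells <- match(S4Vectors::mcols(ga)$CB[sh], barcodes)
  is_ref <- base == snps$ref[qh]
  is_alt <- base == snps$alt[qh]
  ok <- baseq >= min_baseq & (is_ref | is_alt)
  tally <- function(sel) {
    if (!any(sel))
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(length(barcodes), nrow(snps))))
    Matrix::sparseMatrix(i = cells[sel], j = qh[sel], x = rep(1, sum(sel)),
                         dims = c(length(barcodes), nrow(snps)))
  }
  allele_counts(snps, barcodes, tally(ok & is_ref), tally(ok & is_alt))
}

## --- MatrixMarket -----------------------------------------------------------

# Matrix::writeMM labels everything "real"; counts and state matrices are
# integer by contract, so the writer is done by hand and readMM does the read.
write_mtx <- function(path, m) {
  m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "TsparseMatrix")
  o <- order(m@j, m@i)
  i <- m@i[o] + 1L
  j <- m@j[o] + 1L
  x <- as.integer(m@x[o])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), length(x)), con)
  if (length(x)) writeLines(sprintf("%d %d %d", i, j, x), con)
  invisible(path)
}

read_mtx <- function(path) {
  if (!file.exists(path)) stop("cannot read MatrixMarket file: ", path)
  methods::as(methods::as(Matrix::readMM(path), "generalMatrix"), "CsparseMatrix")
}

## --- phase outputs ----------------------------------------------------------

#' Write phasing outputs (count matrices, SNP annotation, phased VCF)
#'
#' Produces `<prefix>_ref.mtx` / `<prefix>_alt.mtx` (MatrixMarket coordinate
#' integer, cells as rows), `<prefix>_snpAnnot.txt` (TSV with the inferred
#' haplotype-1 allele, `.` when missing), `<prefix>_barcodes.txt` and
#' `<prefix>_phased.vcf` (pipe-separated GT; SNPs with a missing haplotype
#' entry are omitted).
#'
#' @param prefix output path prefix.
#' @param counts [allele_counts()].
#' @param hap integer haplotype vector, one entry per SNP.
#' @return invisibly, the written file paths.
#' @export
write_phase_outputs <- function(prefix, counts, hap) {
  snps <- counts$snps
  if (length(hap) != nrow(snps))
    stop("haplotype length (", length(hap), ") does not match SNP count (",
         nrow(snps), ")")
  paths <- paste0(prefix, c("_ref.mtx", "_alt.mtx", "_snpAnnot.txt",
                            "_barcodes.txt", "_phased.vcf"))
  write_mtx(paths[1], counts$ref)
  write_mtx(paths[2], counts$alt)
  annot <- data.frame(chrom = snps$chrom, pos = snps$pos, ref = snps$ref,
                      alt = snps$alt, phase = snps$phase,
                      inferred_hap1_allele = hap_allele_letter(snps, hap),
                      stringsAsFactors = FALSE)
  utils::write.table(annot, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(counts$barcodes, paths[4])
  write_phased_vcf(paths[5], snps, hap)
  invisible(paths)
}

write_phased_vcf <- function(path, snps, hap) {
  keep <- hap != GENO_MISSING
  gt <- ifelse(hap[keep] == GENO_REF, "0|1", "1|0")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tdonor")
  body <- if (any(keep)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t%s",
            snps$chrom[keep], snps$pos[keep], snps$ref[keep], snps$alt[keep], gt)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

# unphased VCF with per-record QUAL (synthetic-data output)
write_unphased_vcf <- function(path, snps, qual = 999) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tdonor")
  body <- if (nrow(snps)) {
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT\t0/1",
            snps$chrom, snps$pos, snps$ref, snps$alt,
            format(rep_len(qual, nrow(snps)), trim = TRUE))
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back phasing outputs written by [write_phase_outputs()]
#'
#' Exact inverse of the writer: counts, SNP table (including the input phase
#' column) and the inferred haplotype are reproduced bit-identically.
#'
#' @param prefix path prefix used when writing.
#' @return list with elements `counts` ([allele_counts()]) and `hap`
#'   (integer haplotype vector).
#' @export
read_phase_outputs <- function(prefix) {
  annot <- utils::read.table(paste0(prefix, "_snpAnnot.txt"), sep = "\t",
                             header = TRUE, colClasses = c(
                               chrom = "character", pos = "integer",
                               ref = "character", alt = "character",
                               phase = "character",
                               inferred_hap1_allele = "character"))
  snps <- snp_table(annot$chrom, annot$pos, annot$ref, annot$alt, annot$phase)
  barcodes <- read_barcodes(paste0(prefix, "_barcodes.txt"))
  ref <- read_mtx(paste0(prefix, "_ref.mtx"))
  alt <- read_mtx(paste0(prefix, "_alt.mtx"))
  if (ncol(ref) != nrow(snps) || ncol(alt) != nrow(snps))
    stop("inconsistent dimensions: annotation has ", nrow(snps),
         " SNPs but matrices have ", ncol(ref), " / ", ncol(alt), " columns")
  if (nrow(ref) != length(barcodes) || nrow(alt) != length(barcodes))
    stop("inconsistent dimensions: matrix rows do not match barcode count")
  hap <- integer(nrow(snps))
  hap[annot$inferred_hap1_allele == snps$ref] <- GENO_REF
  hap[annot$inferred_hap1_allele == snps$alt] <- GENO_ALT
  list(counts = allele_counts(snps, barcodes, ref, alt), hap = hap)
}

## --- segment tables ---------------------------------------------------------

SEGMENT_COLS <- c("barcode", "chrom", "first_snp_pos", "last_snp_pos",
                  "state", "n_snps", "n_reads", "log_lik_ratio")

#' Write / read a Viterbi segment table
#'
#' TSV with the fixed column order `barcode, chrom, first_snp_pos,
#' last_snp_pos, state, n_snps, n_reads, log_lik_ratio` and a header line.
#'
#' @param segments data.frame of segments.
#' @param path file path.
#' @export
write_segments <- function(segments, path) {
  stopifnot(all(SEGMENT_COLS %in% names(segments)))
  utils::write.table(format(segments[, SEGMENT_COLS], digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("cannot read segment table: ", path)
  seg <- utils::read.table(path, sep = "\t", header = TRUE, colClasses = c(
    barcode = "character", chrom = "character", first_snp_pos = "integer",
    last_snp_pos = "integer", state = "character", n_snps = "integer",
    n_reads = "integer", log_lik_ratio = "numeric"))
  seg[, SEGMENT_COLS]
}
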