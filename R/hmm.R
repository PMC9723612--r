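# Two-state HMM for per-gamete crossover calling.
#
# Hidden states are the two parental haplotypes (H1 = 1, H2 = 2). At each
# covered hetSNP the observation is the pair (hap1-supporting reads,
# hap2-supporting reads); emissions are full binomial pmfs with success
# probability theta2 = P(hap1 read | state H1) or theta1 = P(hap1 read |
# state H2), which absorbs miscalls and mapping artefacts. The per-gap
# transition probability scales with genomic distance through an assumed
# recombination rate in centiMorgan per megabase (cmPmb), clamped to
# [p_min, p_max]. Zero-coverage SNPs carry no evidence and are omitted from
# each cell's chain.

#' HMM parameters
#'
#' @param theta1 P(hap1-supporting read | state H2); default 0.1.
#' @param theta2 P(hap1-supporting read | state H1); default 0.9.
#' @param cmPmb assumed recombination rate in cM/Mb used to scale per-gap
#'   transition probabilities; default 0.1.
#' @param p_min,p_max clamp bounds on the per-gap transition probability.
#' @param pi initial state distribution (H1, H2).
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(theta1 = 0.1, theta2 = 0.9, cmPmb = 0.1,
                       p_min = 1e-10, p_max = 0.25, pi = c(0.5, 0.5)) {
  stopifnot(theta1 > 0, theta1 < 0.5, theta2 > 0.5, theta2 < 1,
            p_min > 0, p_min <= p_max, p_max <= 0.5,
            length(pi) == 2L, all(pi > 0), abs(sum(pi) - 1) < 1e-12,
            cmPmb >= 0)
  structure(list(theta1 = theta1, theta2 = theta2, cmPmb = cmPmb,
                 p_min = p_min, p_max = p_max, pi = pi),
            class = "hmm_params")
}

#' Binomial emission log-probability
#'
#' Full binomial log-pmf (including the coefficient) of `h1_reads` successes
#' in `h1_reads + h2_reads` trials, with success probability `theta2` under
#' state H1 and `theta1` under state H2.
#'
#' @param h1_reads,h2_reads non-negative read counts (vectors recycle).
#' @param state 1 (H1) or 2 (H2).
#' @param params [hmm_params()].
#' @export
emission_logprob <- function(h1_reads, h2_reads, state, params = hmm_params()) {
  if (any(h1_reads < 0) || any(h2_reads < 0)) stop("negative read counts")
  stopifnot(all(state %in% c(1L, 2L)))
  p <- ifelse(state == 1L, params$theta2, params$theta1)
  stats::dbinom(h1_reads, h1_reads + h2_reads, p, log = TRUE)
}

#' Per-gap transition probability
#'
#' `p = clamp(gap_bp * cmPmb * 1e-8, p_min, p_max)`: the genomic gap in Mb
#' times the cM/Mb rate gives centiMorgans, and 1 cM = 0.01 recombination
#' probability. The 2x2 per-gap matrix is `[[1-p, p], [p, 1-p]]`.
#'
#' @param gap_bp gap size(s) in bp, >= 1.
#' @param params [hmm_params()].
#' @return probability vector, same length as `gap_bp`.
#' @export
transition_prob <- function(gap_bp, params = hmm_params()) {
  stopifnot(all(gap_bp >= 1))
  pmin(pmax(gap_bp * params$cmPmb * 1e-8, params$p_min), params$p_max)
}

#' Viterbi decoding for one gamete
#'
#' Maximises `log pi + sum(emissions) + sum(log transitions)` over state
#' paths, in log space. Ties break toward staying in the previous state; a
#' tie at the terminal state breaks toward H1.
#'
#' @param h1_reads,h2_reads read counts at the cell's covered SNPs
#'   (each position must have at least 1 read in total).
#' @param positions strictly increasing bp positions of those SNPs.
#' @param params [hmm_params()].
#' @return integer state sequence (1/2), one per covered SNP.
#' @export
viterbi_cell <- function(h1_reads, h2_reads, positions, params = hmm_params()) {
  n <- length(positions)
  if (n == 0L) return(integer(0))
  stopifnot(length(h1_reads) == n, length(h2_reads) == n,
            all(h1_reads + h2_reads >= 1), n < 2L || all(diff(positions) > 0))
  e1 <- emission_logprob(h1_reads, h2_reads, 1L, params)
  e2 <- emission_logprob(h1_reads, h2_reads, 2L, params)
  if (n == 1L) return(if (log(params$pi[2]) + e2[1] > log(params$pi[1]) + e1[1]) 2L else 1L)
  p <- transition_prob(diff(positions), params)
  lp <- log(p)
  lq <- log1p(-p)
  ptr <- matrix(0L, n, 2L)
  d1 <- log(params$pi[1]) + e1[1]
  d2 <- log(params$pi[2]) + e2[1]
  for (t in 2:n) {
    stay <- d1 + lq[t - 1L]; cross <- d2 + lp[t - 1L]
    if (stay >= cross) { nd1 <- stay; ptr[t, 1L] <- 1L } else { nd1 <- cross; ptr[t, 1L] <- 2L }
    stay <- d2 + lq[t - 1L]; cross <- d1 + lp[t - 1L]
    if (stay >= cross) { nd2 <- stay; ptr[t, 2L] <- 2L } else { nd2 <- cross; ptr[t, 2L] <- 1L }
    d1 <- nd1 + e1[t]
    d2 <- nd2 + e2[t]
  }
  states <- integer(n)
  states[n] <- if (d2 > d1) 2L else 1L
  for (t in n:2) states[t - 1L] <- ptr[t, states[t]]
  states
}

#' Segment a state sequence and attach log-likelihood-ratio confidence
#'
#' Contiguous same-state runs become segments. Each segment's confidence is
#' the full-path log-likelihood with the segment as decoded minus the full
#' path with every SNP in the segment flipped to the other state; only the
#' segment's emission terms, its boundary transition terms, and (for the
#' first segment) the initial-distribution term differ, so those are what is
#' summed.
#'
#' @param states integer state sequence from [viterbi_cell()].
#' @param h1_reads,h2_reads,positions as in [viterbi_cell()].
#' @param params [hmm_params()].
#' @return data.frame: `state`, `first_snp_pos`, `last_snp_pos`, `n_snps`,
#'   `n_reads`, `log_lik_ratio` (plus SNP index bounds `first_idx`,
#'   `last_idx`).
#' @export
segment_and_score <- function(states, h1_reads, h2_reads, positions,
                              params = hmm_params()) {
  n <- length(states)
  cols <- c("state", "first_idx", "last_idx", "first_snp_pos", "last_snp_pos",
            "n_snps", "n_reads", "log_lik_ratio")
  if (n == 0L) {
    out <- data.frame(state = integer(0), first_idx = integer(0),
                      last_idx = integer(0), first_snp_pos = integer(0),
                      last_snp_pos = integer(0), n_snps = integer(0),
                      n_reads = integer(0), log_lik_ratio = numeric(0))
    return(out[, cols])
  }
  e1 <- emission_logprob(h1_reads, h2_reads, 1L, params)
  e2 <- emission_logprob(h1_reads, h2_reads, 2L, params)
  ediff <- ifelse(states == 1L, e1 - e2, e2 - e1)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lp <- if (n > 1L) log(transition_prob(diff(positions), params)) else numeric(0)
  lq <- if (n > 1L) log1p(-transition_prob(diff(positions), params)) else numeric(0)
  llr <- vapply(seq_along(starts), function(s) {
    v <- sum(ediff[starts[s]:ends[s]])
    if (starts[s] > 1L) v <- v + lp[starts[s] - 1L] - lq[starts[s] - 1L]
    if (ends[s] < n) v <- v + lp[ends[s]] - lq[ends[s]]
    if (starts[s] == 1L)
      v <- v + log(params$pi[r$values[s]]) - log(params$pi[3L - r$values[s]])
    v
  }, numeric(1))
  tot <- h1_reads + h2_reads
  csum <- c(0, cumsum(tot))
  data.frame(state = r$values, first_idx = starts, last_idx = ends,
             first_snp_pos = positions[starts], last_snp_pos = positions[ends],
             n_snps = r$lengths,
             n_reads = as.integer(csum[ends + 1L] - csum[starts]),
             log_lik_ratio = llr)[, cols]
}

#' Call crossovers for every gamete from counts and a phased haplotype
#'
#' Re-expresses ref/alt counts as (hap1-supporting, hap2-supporting) reads
#' using the haplotype, drops SNPs with a missing haplotype entry, and runs
#' [viterbi_cell()] plus [segment_and_score()] per cell. Transitions between
#' consecutive segments are the crossover calls. Optionally writes
#' `<prefix>_vi.mtx` (sparse states, 1 = H1, 2 = H2, absent = uncovered) and
#' `<prefix>_segments.txt`.
#'
#' @param counts [allele_counts()].
#' @param hap integer haplotype vector (at least one phased SNP).
#' @param params [hmm_params()].
#' @param out_prefix optional output path prefix.
#' @return list of class `crossover_calls`: `segments` (one table for all
#'   cells), `states` (sparse cells x SNPs matrix), `snps`, `barcodes`,
#'   `params`.
#' @export
call_crossovers_dataset <- function(counts, hap, params = hmm_params(),
                                    out_prefix = NULL) {
  snps <- counts$snps
  stopifnot(length(hap) == nrow(snps))
  P <- which(hap != GENO_MISSING)
  if (length(P) == 0L) stop("haplotype has no phased SNPs")
  refP <- as.matrix(counts$ref[, P, drop = FALSE])
  altP <- as.matrix(counts$alt[, P, drop = FALSE])
  hP <- hap[P]
  h1m <- refP
  h2m <- altP
  swap <- hP == GENO_ALT
  h1m[, swap] <- altP[, swap]
  h2m[, swap] <- refP[, swap]
  posP <- snps$pos[P]
  chrom <- if (nrow(snps)) snps$chrom[1] else "?"
  nc <- length(counts$barcodes)
  seg_list <- vector("list", nc)
  sti <- stj <- stx <- vector("list", nc)
  for (cc in seq_len(nc)) {
    covered <- which(h1m[cc, ] + h2m[cc, ] >= 1)
    if (length(covered) == 0L) next
    st <- viterbi_cell(h1m[cc, covered], h2m[cc, covered], posP[covered], params)
    seg <- segment_and_score(st, h1m[cc, covered], h2m[cc, covered],
                             posP[covered], params)
    seg$barcode <- counts$barcodes[cc]
    seg$chrom <- chrom
    seg_list[[cc]] <- seg
    sti[[cc]] <- rep.int(cc, length(covered))
    stj[[cc]] <- P[covered]
    stx[[cc]] <- st
  }
  empty_cells <- counts$barcodes[vapply(seg_list, is.null, logical(1))]
  if (length(empty_cells))
    message("cells with zero covered phased SNPs: ",
            paste(empty_cells, collapse = ", "))
  segments <- do.call(rbind, seg_list[!vapply(seg_list, is.null, logical(1))])
  if (is.null(segments)) {
    segments <- data.frame(barcode = character(0), chrom = character(0),
                           first_snp_pos = integer(0), last_snp_pos = integer(0),
                           state = character(0), n_snps = integer(0),
                           n_reads = integer(0), log_lik_ratio = numeric(0))
  } else {
    segments$state <- paste0("H", segments$state)
    segments <- segments[, SEGMENT_COLS]
  }
  rownames(segments) <- NULL
  states <- Matrix::sparseMatrix(i = unlist(sti), j = unlist(stj),
                                 x = as.numeric(unlist(stx)),
                                 dims = c(nc, nrow(snps)))
  rownames(states) <- counts$barcodes
  out <- structure(list(segments = segments, states = states, snps = snps,
                        barcodes = counts$barcodes, params = params),
                   class = "crossover_calls")
  if (!is.null(out_prefix)) {
    write_mtx(paste0(out_prefix, "_vi.mtx"), states)
    write_segments(segments, paste0(out_prefix, "_segments.txt"))
  }
  out
}

#' Call crossovers straight from a BAM and a phased VCF
#'
#' The from-scratch route: counts alleles per barcode from the BAM, takes the
#' haplotype from the VCF's pipe-separated genotypes, and runs
#' [call_crossovers_dataset()]. Given equivalent inputs it produces segment
#' files identical to the counts-based route.
#'
#' @param bam_path barcoded BAM.
#' @param vcf_path phased VCF (pipe-separated GT).
#' @param barcodes character vector or path to a barcode list.
#' @param chrom chromosome name.
#' @param min_mapq,min_baseq counting thresholds (see [count_alleles()]).
#' @param params [hmm_params()].
#' @param out_prefix optional output prefix.
#' @param min_qual minimum VCF QUAL.
#' @return `crossover_calls` list.
#' @export
call_crossovers_bam <- function(bam_path, vcf_path, barcodes, chrom,
                                min_mapq = 20L, min_baseq = 13L,
                                params = hmm_params(), out_prefix = NULL,
                                min_qual = 0) {
  if (length(barcodes) == 1L && file.exists(barcodes))
    barcodes <- read_barcodes(barcodes)
  snps <- read_hetsnps(vcf_path, chrom, min_qual = min_qual)
  hap <- hap_from_phase(snps)
  keep <- hap != GENO_MISSING
  snps <- snps[keep, ]
  class(snps) <- c("snp_table", "data.frame")
  hap <- hap[keep]
  counts <- count_alleles(bam_path, snps, barcodes, min_mapq = min_mapq,
                          min_baseq = min_baseq)
  call_crossovers_dataset(counts, hap, params = params, out_prefix = out_prefix)
}
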