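# Donor haplotype inference from gamete genotype co-segregation.
#
# A gamete that inherited no crossover on a chromosome carries one parental
# haplotype intact, so its genotype sequence *is* a haplotype. Phasing
# therefore (1) calls per-cell genotypes from allele counts, (2) finds a pair
# of gametes whose genotype sequences agree (up to global complement - allele
# labels are arbitrary) and uses one as the template backbone, then (3) fills
# the template's missing SNPs by majority vote among gametes whose local
# flanking genotypes show which orientation they carry. Crossovers are rare
# per site, so short-range SNP linkage across many gametes is reliable.

#' Call per-cell genotypes from allele counts
#'
#' A cell/SNP entry is the majority allele when total coverage is at least
#' `min_total` and the majority fraction is at least `min_purity`; ties and
#' everything below threshold are missing.
#'
#' @param counts [allele_counts()].
#' @param min_total minimum reads per cell per SNP (default 1).
#' @param min_purity minimum majority fraction in (0.5, 1] (default 0.8).
#' @return integer matrix (cells x SNPs; 0 missing / 1 ref / 2 alt) with
#'   barcode rownames.
#' @export
call_genotypes <- function(counts, min_total = 1L, min_purity = 0.8) {
  stopifnot(min_total >= 1L, min_purity > 0.5, min_purity <= 1)
  r <- as.matrix(counts$ref)
  a <- as.matrix(counts$alt)
  tot <- r + a
  g <- matrix(GENO_MISSING, nrow(r), ncol(r))
  callable <- tot >= min_total & r != a & pmax(r, a) >= min_purity * tot
  g[callable & r > a] <- GENO_REF
  g[callable & a > r] <- GENO_ALT
  rownames(g) <- counts$barcodes
  g
}

#' Choose a template gamete from pairwise genotype concordance
#'
#' For every pair of cells with at least `min_shared` co-covered SNPs, the
#' concordance is the fraction of co-covered SNPs on which the two genotype
#' sequences agree, maximised over the two orientations (identical or fully
#' complementary - the two readings of the same haplotype). The pair
#' maximising (concordance, then shared SNPs) is chosen; the member covering
#' more SNPs becomes the template. When no pair reaches `min_concordance`,
#' the most-covered single cell is used and `fallback_used` is set - the
#' switch-correction stage exists precisely to repair a template that carries
#' crossovers. Ties break toward the lowest cell index.
#'
#' @param G genotype matrix from [call_genotypes()].
#' @param min_shared minimum co-covered SNPs per pair (default 30).
#' @param min_concordance concordance needed to accept a pair (default 0.99).
#' @return list of class `template_selection`: `template_cell`,
#'   `partner_cell`, `n_shared`, `concordance`, `fallback_used`.
#' @export
select_template <- function(G, min_shared = 30L, min_concordance = 0.99) {
  nc <- nrow(G)
  if (nc < 2L) stop("select_template needs at least 2 cells")
  A <- (G == GENO_REF) * 1
  B <- (G == GENO_ALT) * 1
  same <- Matrix::tcrossprod(A) + Matrix::tcrossprod(B)
  cov <- A + B
  shared <- Matrix::tcrossprod(cov)
  n_covered <- rowSums(cov)
  opp <- shared - same
  conc <- pmax(same, opp) / shared
  conc[shared == 0] <- 0
  pairs <- which(upper.tri(shared) & shared >= min_shared, arr.ind = TRUE)
  pick_fallback <- function() {
    tpl <- which.max(n_covered)
    structure(list(template_cell = tpl, partner_cell = tpl,
                   n_shared = NA_integer_, concordance = NA_real_,
                   fallback_used = TRUE),
              class = "template_selection")
  }
  if (nrow(pairs) == 0L) return(pick_fallback())
  pc <- conc[pairs]
  ps <- shared[pairs]
  o <- order(-pc, -ps, pairs[, 1], pairs[, 2])[1]
  if (pc[o] < min_concordance) return(pick_fallback())
  i <- pairs[o, 1]; j <- pairs[o, 2]
  # template = pair member with more genotyped SNPs (lower index on ties)
  tpl <- if (n_covered[j] > n_covered[i]) j else i
  structure(list(template_cell = unname(tpl),
                 partner_cell = unname(if (tpl == i) j else i),
                 n_shared = as.integer(ps[o]), concordance = unname(pc[o]),
                 fallback_used = FALSE),
            class = "template_selection")
}

#' @export
print.template_selection <- function(x, ...) {
  if (x$fallback_used)
    cat(sprintf("template_selection: fallback to most-covered cell %d\n",
                x$template_cell))
  else
    cat(sprintf("template_selection: cells (%d, %d), %d shared SNPs, concordance %.4f\n",
                x$template_cell, x$partner_cell, x$n_shared, x$concordance))
  invisible(x)
}

#' Template haplotype: the template cell's genotype sequence
#'
#' @param G genotype matrix.
#' @param sel [select_template()] result.
#' @return integer haplotype vector (missing genotypes propagate).
#' @export
template_haplotype <- function(G, sel) {
  unname(G[sel$template_cell, ])
}

#' Fill missing template SNPs from local SNP linkage across gametes
#'
#' For a missing SNP t, each gamete covering t compares its genotypes with the
#' current haplotype over the nearest `window` phased SNPs it covers on each
#' side (at least 2 co-covered in total). A gamete in the same orientation
#' (local concordance >= `link_threshold`) votes its own genotype at t; one in
#' the complementary orientation (concordance <= 1 - `link_threshold`) votes
#' the complement; anything in between abstains. The majority allele is
#' assigned when at least `min_link_cells` votes agree and the majority
#' fraction reaches `link_threshold`. Passes repeat until no SNP changes;
#' already-phased entries are never overwritten, so the phased set only grows.
#'
#' @param G genotype matrix.
#' @param hap integer haplotype vector (the template backbone).
#' @param window flank size in phased SNPs per side (default 10).
#' @param min_link_cells minimum agreeing votes (default 2).
#' @param link_threshold orientation / majority threshold in (0.5, 1]
#'   (default 0.8).
#' @return completed integer haplotype vector.
#' @export
impute_missing <- function(G, hap, window = 10L, min_link_cells = 2L,
                           link_threshold = 0.8) {
  stopifnot(window >= 1L, link_threshold > 0.5, link_threshold <= 1)
  nc <- nrow(G)
  S <- ncol(G)
  stopifnot(length(hap) == S)
  repeat {
    P <- which(hap != GENO_MISSING)
    miss <- which(hap == GENO_MISSING)
    if (length(miss) == 0L || length(P) == 0L) break
    vref <- numeric(S)
    valt <- numeric(S)
    for (cc in seq_len(nc)) {
      gc <- G[cc, ]
      covP <- P[gc[P] != GENO_MISSING]
      if (length(covP) < 2L) next
      targets <- miss[gc[miss] != GENO_MISSING]
      if (length(targets) == 0L) next
      cs <- c(0L, cumsum(gc[covP] == hap[covP]))
      n <- length(covP)
      pos <- findInterval(targets, covP)
      nl <- pmin(pos, window)
      nr <- pmin(n - pos, window)
      ntot <- nl + nr
      m <- (cs[pos + 1L] - cs[pos + 1L - nl]) + (cs[pos + nr + 1L] - cs[pos + 1L])
      ok <- ntot >= 2L
      gt <- gc[targets]
      # compare both orientations' fractions against the threshold directly
      # (label-swap symmetric, no 1 - threshold rounding)
      vote_same <- ok & m >= link_threshold * ntot
      vote_comp <- ok & (ntot - m) >= link_threshold * ntot
      vr <- (vote_same & gt == GENO_REF) | (vote_comp & gt == GENO_ALT)
      va <- (vote_same & gt == GENO_ALT) | (vote_comp & gt == GENO_REF)
      vref[targets] <- vref[targets] + vr
      valt[targets] <- valt[targets] + va
    }
    win <- pmax(vref[miss], valt[miss])
    tot <- vref[miss] + valt[miss]
    assign <- miss[win >= min_link_cells & tot > 0 &
                     win / tot >= link_threshold &
                     vref[miss] != valt[miss]]
    if (length(assign) == 0L) break
    hap[assign] <- ifelse(vref[assign] > valt[assign], GENO_REF, GENO_ALT)
  }
  hap
}

#' One-step phasing: genotypes, template selection, imputation
#'
#' Convenience composition of [call_genotypes()], [select_template()],
#' [template_haplotype()] and [impute_missing()].
#'
#' @param counts [allele_counts()].
#' @param min_total,min_purity genotype-calling thresholds.
#' @param min_shared,min_concordance template-selection thresholds.
#' @param window,min_link_cells,link_threshold imputation parameters.
#' @return list of class `gamete_phase`: `hap`, `genotypes`, `selection`,
#'   `snps`, `barcodes`.
#' @export
phase_gametes <- function(counts, min_total = 1L, min_purity = 0.8,
                          min_shared = 30L, min_concordance = 0.99,
                          window = 10L, min_link_cells = 2L,
                          link_threshold = 0.8) {
  G <- call_genotypes(counts, min_total = min_total, min_purity = min_purity)
  sel <- select_template(G, min_shared = min_shared,
                         min_concordance = min_concordance)
  hap <- template_haplotype(G, sel)
  hap <- impute_missing(G, hap, window = window,
                        min_link_cells = min_link_cells,
                        link_threshold = link_threshold)
  structure(list(hap = hap, genotypes = G, selection = sel,
                 snps = counts$snps, barcodes = counts$barcodes),
            class = "gamete_phase")
}

#' Per-cell match-vs-template diagnostic codes
#'
#' Long table of each genotyped cell/SNP entry coded by whether it matches the
#' haplotype (`match`), its complement (`mismatch`), or falls on an unphased
#' SNP (`unphased`) - the data behind switch-error diagnostic plots.
#'
#' @param G genotype matrix.
#' @param hap integer haplotype vector.
#' @return data.frame with columns `cell`, `snp_index`, `code`.
#' @export
phase_diagnostics <- function(G, hap) {
  idx <- which(G != GENO_MISSING, arr.ind = TRUE)
  h <- hap[idx[, 2]]
  code <- ifelse(h == GENO_MISSING, "unphased",
                 ifelse(G[idx] == h, "match", "mismatch"))
  cells <- if (is.null(rownames(G))) as.character(idx[, 1]) else rownames(G)[idx[, 1]]
  o <- order(idx[, 1], idx[, 2])
  data.frame(cell = cells[o], snp_index = unname(idx[o, 2]), code = code[o],
             stringsAsFactors = FALSE)
}
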