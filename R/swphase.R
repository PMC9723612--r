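# Switch-error detection and repair.
#
# A switch error complements the inferred haplotype from some SNP onward.
# Candidate sites are phased SNPs whose adjacent-pair linkage support across
# gametes is weak; each candidate gets a switch score contrasting, per gamete,
# the best "orientation flips here" reading of its flanking genotypes against
# the best "same orientation throughout" reading under a symmetric per-SNP
# genotype error rate epsilon. Positive scores favour a switch.

#' Candidate switch-error sites
#'
#' Returns phased SNP indices k where, among cells covering both k and the
#' previous phased SNP, the fraction whose genotype pair is haplotype-
#' consistent (both match the haplotype, or both match its complement) falls
#' below `link_ratio_threshold` - or where fewer than 2 cells cover the pair.
#'
#' @param G genotype matrix (cells x SNPs).
#' @param hap integer haplotype vector.
#' @param link_ratio_threshold minimum linkage support (default 0.7).
#' @return increasing integer vector of SNP indices (subset of phased indices).
#' @export
candidate_sites <- function(G, hap, link_ratio_threshold = 0.7) {
  P <- which(hap != GENO_MISSING)
  if (length(P) < 2L) return(integer(0))
  GP <- G[, P, drop = FALSE]
  covP <- GP != GENO_MISSING
  matchP <- covP & GP == matrix(hap[P], nrow(G), length(P), byrow = TRUE)
  nP <- length(P)
  both <- covP[, -nP, drop = FALSE] & covP[, -1L, drop = FALSE]
  consistent <- both & (matchP[, -nP, drop = FALSE] == matchP[, -1L, drop = FALSE])
  n_both <- colSums(both)
  frac <- ifelse(n_both > 0, colSums(consistent) / n_both, 0)
  P[-1L][n_both < 2L | frac < link_ratio_threshold]
}

#' Switch scores for candidate sites
#'
#' For each candidate k and each cell with at least 2 co-covered phased SNPs
#' in each flank (left: nearest `window` phased SNPs before k that the cell
#' covers; right: k and the following phased SNPs it covers, `window` in
#' total), flank log-likelihoods under orientation h are
#' `m*log(1-eps) + (n-m)*log(eps)` with m the haplotype-matching genotypes
#' out of n. The score sums, over cells, the best flipped-orientation reading
#' minus the best same-orientation reading:
#' `max_h(L_left(h) + L_right(!h)) - max_h(L_left(h) + L_right(h))`.
#' Cells without informative flanks contribute 0.
#'
#' @param G genotype matrix.
#' @param hap integer haplotype vector.
#' @param k integer vector of candidate SNP indices (must be phased).
#' @param window flank size in phased SNPs (default 10, must be >= 2).
#' @param epsilon assumed per-SNP genotype error rate in (0, 0.5)
#'   (default 0.1).
#' @return numeric scores, one per candidate.
#' @export
switch_score_track <- function(G, hap, k, window = 10L, epsilon = 0.1) {
  stopifnot(window >= 2L, epsilon > 0, epsilon < 0.5)
  if (length(k) == 0L) return(numeric(0))
  P <- which(hap != GENO_MISSING)
  if (!all(k %in% P)) stop("candidate indices must be phased SNPs")
  la <- log(1 - epsilon)
  lb <- log(epsilon)
  scores <- numeric(length(k))
  for (cc in seq_len(nrow(G))) {
    gc <- G[cc, ]
    covP <- P[gc[P] != GENO_MISSING]
    n <- length(covP)
    if (n < 4L) next
    cs <- c(0L, cumsum(gc[covP] == hap[covP]))
    pos <- findInterval(k - 1L, covP)          # covered phased SNPs before k
    nl <- pmin(pos, window)
    nr <- pmin(n - pos, window)
    ok <- nl >= 2L & nr >= 2L
    if (!any(ok)) next
    ml <- cs[pos + 1L] - cs[pos + 1L - nl]
    mr <- cs[pos + nr + 1L] - cs[pos + 1L]
    Ll_s <- ml * la + (nl - ml) * lb
    Ll_c <- (nl - ml) * la + ml * lb
    Lr_s <- mr * la + (nr - mr) * lb
    Lr_c <- (nr - mr) * la + mr * lb
    contrib <- pmax(Ll_s + Lr_c, Ll_c + Lr_s) - pmax(Ll_s + Lr_s, Ll_c + Lr_c)
    scores <- scores + ifelse(ok, contrib, 0)
  }
  scores
}

#' @rdname switch_score_track
#' @export
switch_score <- function(G, hap, k, window = 10L, epsilon = 0.1) {
  stopifnot(length(k) == 1L)
  switch_score_track(G, hap, k, window = window, epsilon = epsilon)
}

#' Pick switch positions from a score track
#'
#' Non-maximum suppression: candidates with score at least `min_score` are
#' accepted greedily in descending score order; once a site is accepted,
#' further candidates within `min_gap` SNP indices of it are suppressed, so
#' each accepted site is the local score maximum of its neighbourhood.
#'
#' @param candidates increasing SNP indices.
#' @param scores matching score values.
#' @param min_score detection threshold (default `log(1e4)`, i.e. 10^4:1
#'   evidence for a switch).
#' @param min_gap suppression radius in SNP indices (default 20).
#' @return list of class `switch_call`: `positions` (increasing SNP indices)
#'   and `scores_at_switch`.
#' @export
find_switches <- function(candidates, scores, min_score = log(1e4),
                          min_gap = 20L) {
  stopifnot(min_gap >= 1L, length(candidates) == length(scores))
  n <- length(candidates)
  if (n == 0L)
    return(structure(list(positions = integer(0), scores_at_switch = numeric(0)),
                     class = "switch_call"))
  idx <- which(scores >= min_score)
  idx <- idx[order(-scores[idx], candidates[idx])]
  taken <- integer(0)
  for (i in idx) {
    if (all(abs(candidates[i] - candidates[taken]) >= min_gap))
      taken <- c(taken, i)
  }
  taken <- taken[order(candidates[taken])]
  structure(list(positions = candidates[taken],
                 scores_at_switch = scores[taken]),
            class = "switch_call")
}

#' Apply switch corrections to a haplotype
#'
#' Each position complements the haplotype from that SNP onward, so a SNP
#' preceded by an odd number of switch positions ends up complemented;
#' missing entries stay missing.
#'
#' @param hap integer haplotype vector.
#' @param positions SNP indices (from [find_switches()] `positions`, or an
#'   integer vector).
#' @export
apply_switches <- function(hap, positions) {
  if (inherits(positions, "switch_call")) positions <- positions$positions
  if (length(positions) == 0L) return(hap)
  stopifnot(all(positions >= 1L), all(positions <= length(hap)))
  flips <- integer(length(hap))
  flips[positions] <- flips[positions] + 1L
  odd <- cumsum(flips) %% 2L == 1L
  hap[odd] <- complement_haplotype(hap[odd])
  hap
}

#' Detect and repair switch errors in an inferred haplotype
#'
#' Iterative greedy repair: candidate sites are screened and scored against
#' the current haplotype, the single best-supported switch (if any reaches
#' `min_score`) is applied, and the track is recomputed - a switch changes
#' the evidence at every other site, so rescoring after each correction
#' keeps shoulders of an already-repaired switch from being read as
#' additional switches. Sites within `min_gap` of an accepted switch are not
#' revisited. Stops when no candidate reaches `min_score`.
#'
#' @param G genotype matrix.
#' @param hap integer haplotype vector.
#' @param link_ratio_threshold candidate-screening threshold.
#' @param window,epsilon score parameters.
#' @param min_score,min_gap peak-picking parameters.
#' @param max_switches safety cap on accepted switches (default 50).
#' @return list of class `switch_correction`: corrected `hap`, `candidates`
#'   and `scores` (the first-round track, for diagnostics), `switches`
#'   (a `switch_call` of all accepted positions).
#' @export
correct_switches <- function(G, hap, link_ratio_threshold = 0.7,
                             window = 10L, epsilon = 0.1,
                             min_score = log(1e4), min_gap = 20L,
                             max_switches = 50L) {
  accepted <- integer(0)
  accepted_scores <- numeric(0)
  first_cand <- NULL
  first_scores <- NULL
  repeat {
    cand <- candidate_sites(G, hap, link_ratio_threshold = link_ratio_threshold)
    if (length(accepted))
      cand <- cand[vapply(cand, function(k) all(abs(k - accepted) >= min_gap),
                          logical(1))]
    scores <- switch_score_track(G, hap, cand, window = window,
                                 epsilon = epsilon)
    if (is.null(first_cand)) {
      first_cand <- cand
      first_scores <- scores
    }
    call <- find_switches(cand, scores, min_score = min_score,
                          min_gap = min_gap)
    if (length(call$positions) == 0L || length(accepted) >= max_switches) break
    best <- which.max(call$scores_at_switch)
    accepted <- c(accepted, call$positions[best])
    accepted_scores <- c(accepted_scores, call$scores_at_switch[best])
    hap <- apply_switches(hap, call$positions[best])
  }
  o <- order(accepted)
  structure(list(hap = hap, candidates = first_cand, scores = first_scores,
                 switches = structure(list(positions = accepted[o],
                                           scores_at_switch = accepted_scores[o]),
                                      class = "switch_call")),
            class = "switch_correction")
}

#' Phase then repair switch errors in one call
#'
#' Runs [phase_gametes()] followed by [correct_switches()]; the result is
#' identical to running the two stages separately with the same parameters.
#'
#' @inheritParams phase_gametes
#' @inheritParams correct_switches
#' @return `gamete_phase` list with the corrected `hap` and an extra
#'   `switch_correction` element.
#' @export
autophase_gametes <- function(counts, min_total = 1L, min_purity = 0.8,
                              min_shared = 30L, min_concordance = 0.99,
                              window = 10L, min_link_cells = 2L,
                              link_threshold = 0.8,
                              link_ratio_threshold = 0.7, epsilon = 0.1,
                              min_score = log(1e4), min_gap = 20L) {
  ph <- phase_gametes(counts, min_total = min_total, min_purity = min_purity,
                      min_shared = min_shared,
                      min_concordance = min_concordance, window = window,
                      min_link_cells = min_link_cells,
                      link_threshold = link_threshold)
  sw <- correct_switches(ph$genotypes, ph$hap,
                         link_ratio_threshold = link_ratio_threshold,
                         window = window, epsilon = epsilon,
                         min_score = min_score, min_gap = min_gap)
  ph$hap <- sw$hap
  ph$switch_correction <- sw
  ph
}
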