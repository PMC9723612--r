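# Crossover-landscape analysis: segment filtering, interval counting,
# genetic distances, resampling comparisons, phasing diagnostics.

#' Crossover filtering parameters
#'
#' `min_cell_snps` / `max_raw_co` act on whole cells (per chromosome);
#' the `min_seg_*` thresholds act on the segments flanking each candidate
#' crossover.
#'
#' @param min_cell_snps minimum covered SNPs per cell per chromosome
#'   (default 200).
#' @param max_raw_co maximum unfiltered crossovers per cell per chromosome
#'   (default 10).
#' @param min_seg_snps minimum SNPs per flanking segment (default 3).
#' @param min_seg_llr minimum log-likelihood ratio per flanking segment
#'   (default 10).
#' @param min_seg_bp minimum bp span per flanking segment (default 1e5).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_cell_snps = 200, max_raw_co = 10,
                          min_seg_snps = 3, min_seg_llr = 10,
                          min_seg_bp = 1e5) {
  stopifnot(min_cell_snps >= 0, max_raw_co >= 0, min_seg_snps >= 0,
            min_seg_llr >= 0, min_seg_bp >= 0)
  structure(list(min_cell_snps = min_cell_snps, max_raw_co = max_raw_co,
                 min_seg_snps = min_seg_snps, min_seg_llr = min_seg_llr,
                 min_seg_bp = min_seg_bp),
            class = "filter_params")
}

seg_fails <- function(seg, filters) {
  seg$n_snps < filters$min_seg_snps |
    seg$log_lik_ratio < filters$min_seg_llr |
    (seg$last_snp_pos - seg$first_snp_pos + 1) < filters$min_seg_bp
}

#' Crossovers from a filtered segment table
#'
#' Cells failing `min_cell_snps` or exceeding `max_raw_co` are dropped whole.
#' Within a kept cell, segments failing any `min_seg_*` threshold are merged
#' away (lowest-LLR failing segment first): an interior failing segment is
#' absorbed together with its two same-state neighbours into one segment
#' (summed SNPs and reads, summed neighbour LLRs), an edge segment into its
#' single neighbour. Every state change between the remaining segments is a
#' crossover whose confidence is the smaller flanking LLR.
#'
#' @param segments segment table (as written by [call_crossovers_dataset()]),
#'   ordered by position within each cell and chromosome.
#' @param filters [filter_params()].
#' @return list of class `crossover_set`: `crossovers` (data.frame `cell`,
#'   `chrom`, `left_pos`, `right_pos`, `confidence`) and `qc` (per-cell
#'   table with raw/retained counts and drop reasons).
#' @export
crossovers_from_segments <- function(segments, filters = filter_params()) {
  stopifnot(all(SEGMENT_COLS %in% names(segments)))
  key <- paste(segments$barcode, segments$chrom, sep = "\r")
  groups <- split(seq_len(nrow(segments)), factor(key, levels = unique(key)))
  co_list <- list()
  qc_list <- list()
  for (g in groups) {
    seg <- segments[g, ]
    if (is.unsorted(seg$first_snp_pos, strictly = TRUE) ||
        any(seg$last_snp_pos < seg$first_snp_pos))
      stop("segments not ordered by position for cell ", seg$barcode[1])
    raw_co <- nrow(seg) - 1L
    total_snps <- sum(seg$n_snps)
    reason <- NA_character_
    if (total_snps < filters$min_cell_snps) {
      reason <- "low_snp_coverage"
    } else if (raw_co > filters$max_raw_co) {
      reason <- "excess_crossovers"
    }
    retained <- 0L
    if (is.na(reason)) {
      while (nrow(seg) > 1L && any(seg_fails(seg, filters))) {
        bad <- which(seg_fails(seg, filters))
        k <- bad[which.min(seg$log_lik_ratio[bad])]
        if (k > 1L && k < nrow(seg)) {
          # neighbours share a state (segments alternate): fuse all three
          seg$last_snp_pos[k - 1L] <- seg$last_snp_pos[k + 1L]
          seg$n_snps[k - 1L] <- sum(seg$n_snps[(k - 1L):(k + 1L)])
          seg$n_reads[k - 1L] <- sum(seg$n_reads[(k - 1L):(k + 1L)])
          seg$log_lik_ratio[k - 1L] <-
            seg$log_lik_ratio[k - 1L] + seg$log_lik_ratio[k + 1L]
          seg <- seg[-c(k, k + 1L), ]
        } else {
          nb <- if (k == 1L) 2L else k - 1L
          seg$first_snp_pos[nb] <- min(seg$first_snp_pos[c(k, nb)])
          seg$last_snp_pos[nb] <- max(seg$last_snp_pos[c(k, nb)])
          seg$n_snps[nb] <- seg$n_snps[k] + seg$n_snps[nb]
          seg$n_reads[nb] <- seg$n_reads[k] + seg$n_reads[nb]
          seg <- seg[-k, ]
        }
      }
      retained <- nrow(seg) - 1L
      if (retained > 0L) {
        co_list[[length(co_list) + 1L]] <- data.frame(
          cell = seg$barcode[1], chrom = seg$chrom[1],
          left_pos = seg$last_snp_pos[-nrow(seg)],
          right_pos = seg$first_snp_pos[-1L],
          confidence = pmin(seg$log_lik_ratio[-nrow(seg)],
                            seg$log_lik_ratio[-1L]),
          stringsAsFactors = FALSE)
      }
    }
    qc_list[[length(qc_list) + 1L]] <- data.frame(
      cell = seg$barcode[1], chrom = seg$chrom[1], n_snps = total_snps,
      raw_co = raw_co, retained_co = retained,
      dropped = !is.na(reason), reason = reason, stringsAsFactors = FALSE)
  }
  crossovers <- if (length(co_list)) do.call(rbind, co_list) else
    data.frame(cell = character(0), chrom = character(0),
               left_pos = integer(0), right_pos = integer(0),
               confidence = numeric(0))
  rownames(crossovers) <- NULL
  structure(list(crossovers = crossovers, qc = do.call(rbind, qc_list)),
            class = "crossover_set")
}

#' Tile a region into fixed-size bins
#'
#' @param chrom chromosome name.
#' @param from,to region bounds in bp.
#' @param bin_bp bin size in bp (last bin is truncated at `to`).
#' @return data.frame `chrom`, `start`, `end` (1-based, inclusive).
#' @export
tile_bins <- function(chrom, from, to, bin_bp) {
  starts <- seq(from, to, by = bin_bp)
  data.frame(chrom = chrom, start = starts,
             end = pmin(starts + bin_bp - 1, to), stringsAsFactors = FALSE)
}

#' Count crossovers over genomic intervals
#'
#' A crossover is only localised to the interval between its flanking SNPs,
#' so each contributes total mass 1 split across bins proportionally to the
#' overlap of `[left_pos, right_pos)` with each bin (or assigned wholly to
#' the bin containing its midpoint with `assign = "midpoint"`). Mass falling
#' outside every bin is dropped with a warning.
#'
#' @param crossovers crossover data.frame (from [crossovers_from_segments()]
#'   `$crossovers`, or equivalent columns) or a `crossover_set`.
#' @param intervals data.frame `chrom`, `start`, `end`; non-overlapping and
#'   sorted.
#' @param cells barcodes defining the columns (cells without crossovers get
#'   zero columns).
#' @param assign `"proportional"` (default) or `"midpoint"`.
#' @return list of class `crossover_matrix`: `intervals`, `cells`, `counts`
#'   (intervals x cells), `labels` (NULL until set).
#' @export
count_cos <- function(crossovers, intervals, cells,
                      assign = c("proportional", "midpoint")) {
  assign <- match.arg(assign)
  if (inherits(crossovers, "crossover_set")) crossovers <- crossovers$crossovers
  cells <- check_barcodes(cells)
  o <- order(intervals$start)
  intervals <- intervals[o, ]
  if (nrow(intervals) > 1L &&
      any(intervals$start[-1L] <= intervals$end[-nrow(intervals)]))
    stop("overlapping bins")
  counts <- matrix(0, nrow(intervals), length(cells))
  lost <- 0
  for (i in seq_len(nrow(crossovers))) {
    cell <- match(crossovers$cell[i], cells)
    if (is.na(cell)) next
    l <- crossovers$left_pos[i]
    r <- crossovers$right_pos[i]
    if (assign == "midpoint") {
      mid <- (l + r) / 2
      b <- which(intervals$start <= mid & mid <= intervals$end)
      if (length(b)) counts[b[1], cell] <- counts[b[1], cell] + 1 else lost <- lost + 1
    } else {
      ov <- pmax(0, pmin(r, intervals$end + 1) - pmax(l, intervals$start))
      w <- ov / (r - l)
      counts[, cell] <- counts[, cell] + w
      lost <- lost + max(0, 1 - sum(w))
    }
  }
  if (lost > 1e-9)
    warning(sprintf("%.3f crossover mass fell outside all intervals and was dropped", lost))
  structure(list(intervals = intervals, cells = cells, counts = counts,
                 labels = NULL),
            class = "crossover_matrix")
}

#' Map a recombination fraction to genetic distance
#'
#' Kosambi: `25 * log((1 + 2r) / (1 - 2r))`; Haldane: `-50 * log(1 - 2r)`;
#' both in centiMorgans. Defined for `0 <= r < 0.5`; with `clamp = TRUE`
#' larger fractions are pulled just below 0.5 instead of erroring.
#'
#' @param r recombination fraction(s).
#' @param method `"kosambi"` (default) or `"haldane"`.
#' @param clamp clamp `r` into `[0, 0.5)` instead of erroring.
#' @return distance(s) in cM.
#' @export
map_distance <- function(r, method = c("kosambi", "haldane"), clamp = FALSE) {
  method <- match.arg(method)
  if (clamp) r <- pmin(pmax(r, 0), 0.5 - 1e-9)
  if (any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must be in [0, 0.5); use clamp = TRUE to force")
  switch(method,
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
         haldane = -50 * log(1 - 2 * r))
}

#' Per-bin and cumulative genetic distances per group
#'
#' The recombination fraction of a bin for a group is the group's total
#' crossover mass in the bin divided by its cell count; the mapping function
#' converts it to cM, and the cumulative distance runs along the chromosome.
#'
#' @param m [count_cos()] result.
#' @param method mapping function (see [map_distance()]).
#' @param group_by optional per-cell labels (defaults to `m$labels`, else one
#'   group `"all"`).
#' @return data.frame: interval columns plus `group`, `rate`, `cM`, `cum_cM`.
#' @export
cal_genetic_dist <- function(m, method = c("kosambi", "haldane"),
                             group_by = NULL) {
  method <- match.arg(method)
  labels <- group_by %||% m$labels %||% rep("all", length(m$cells))
  stopifnot(length(labels) == length(m$cells))
  out <- lapply(unique(labels), function(g) {
    cols <- which(labels == g)
    if (length(cols) == 0L) stop("group with 0 cells: ", g)
    r <- rowSums(m$counts[, cols, drop = FALSE]) / length(cols)
    cm <- map_distance(r, method = method, clamp = TRUE)
    cbind(m$intervals,
          data.frame(group = g, rate = r, cM = cm, cum_cM = cumsum(cm),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

total_genetic_dist <- function(counts, cols, method) {
  r <- rowSums(counts[, cols, drop = FALSE]) / length(cols)
  sum(map_distance(r, method = method, clamp = TRUE))
}

#' Bootstrap confidence interval for a two-group difference in map length
#'
#' Cells are resampled with replacement within each group `B` times; the
#' statistic is total genetic distance (sum of per-bin cM) of group 1 minus
#' group 2, and the interval is the percentile 95% CI.
#'
#' @param m [count_cos()] result.
#' @param labels per-cell labels with exactly two levels.
#' @param B number of resamples (>= 100; default 1000).
#' @param seed RNG seed (optional).
#' @param method mapping function.
#' @return list of class `group_comparison` with `observed_diff`, `ci_low`,
#'   `ci_high`, `n_resamples`, `seed`.
#' @export
bootstrap_dist <- function(m, labels, B = 1000L, seed = NULL,
                           method = c("kosambi", "haldane")) {
  method <- match.arg(method)
  stopifnot(B >= 100L, length(labels) == length(m$cells))
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must define exactly two groups")
  g1 <- which(labels == lv[1])
  g2 <- which(labels == lv[2])
  if (length(g1) < 2L || length(g2) < 2L)
    warning("a group has fewer than 2 cells; bootstrap is degenerate")
  if (!is.null(seed)) set.seed(seed)
  obs <- total_genetic_dist(m$counts, g1, method) -
    total_genetic_dist(m$counts, g2, method)
  diffs <- vapply(seq_len(B), function(b) {
    s1 <- sample(g1, length(g1), replace = TRUE)
    s2 <- sample(g2, length(g2), replace = TRUE)
    total_genetic_dist(m$counts, s1, method) -
      total_genetic_dist(m$counts, s2, method)
  }, numeric(1))
  ci <- unname(stats::quantile(diffs, c(0.025, 0.975)))
  structure(list(observed_diff = obs, ci_low = ci[1], ci_high = ci[2],
                 p_value = NA_real_, n_resamples = as.integer(B),
                 seed = seed, resamples = diffs),
            class = "group_comparison")
}

#' Permutation test for a two-group difference in map length
#'
#' Group labels are permuted `B` times; the two-sided empirical p-value is
#' `(1 + #{|diff_perm| >= |diff_obs|}) / (B + 1)`, which is always in (0, 1].
#'
#' @inheritParams bootstrap_dist
#' @param B number of permutations (>= 100; default 199).
#' @return `group_comparison` list with `observed_diff`, `p_value`.
#' @export
permute_dist <- function(m, labels, B = 199L, seed = NULL,
                         method = c("kosambi", "haldane")) {
  method <- match.arg(method)
  stopifnot(B >= 100L, length(labels) == length(m$cells))
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must define exactly two groups")
  n1 <- sum(labels == lv[1])
  nc <- length(labels)
  if (!is.null(seed)) set.seed(seed)
  g1 <- which(labels == lv[1])
  obs <- total_genetic_dist(m$counts, g1, method) -
    total_genetic_dist(m$counts, setdiff(seq_len(nc), g1), method)
  diffs <- vapply(seq_len(B), function(b) {
    p1 <- sample.int(nc, n1)
    total_genetic_dist(m$counts, p1, method) -
      total_genetic_dist(m$counts, setdiff(seq_len(nc), p1), method)
  }, numeric(1))
  p <- (1 + sum(abs(diffs) >= abs(obs))) / (B + 1)
  structure(list(observed_diff = obs, ci_low = NA_real_, ci_high = NA_real_,
                 p_value = p, n_resamples = as.integer(B), seed = seed,
                 permutations = diffs),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: observed diff %.4f cM", x$observed_diff))
  if (!is.na(x$ci_low))
    cat(sprintf(", bootstrap 95%% CI [%.4f, %.4f]", x$ci_low, x$ci_high))
  if (!is.na(x$p_value))
    cat(sprintf(", permutation p = %.4f", x$p_value))
  cat(sprintf(" (%d resamples)\n", x$n_resamples))
  invisible(x)
}

#' Phasing accuracy against a truth haplotype
#'
#' Haplotype labels are arbitrary, so the inferred haplotype is first
#' oriented to the truth by whole-chromosome majority vote over co-phased
#' SNPs; accuracy is then the concordant fraction, overall and in bins of
#' `bin_snps` consecutive co-phased SNPs.
#'
#' @param inferred,truth integer haplotype vectors over the same SNP table.
#' @param bin_snps SNPs per bin (default 100).
#' @return list: `overall` accuracy, `n_phased` (non-missing inferred
#'   entries), `n_discordant`, `per_bin` data.frame (`bin`, `n`, `accuracy`).
#' @export
phasing_accuracy <- function(inferred, truth, bin_snps = 100L) {
  stopifnot(length(inferred) == length(truth), bin_snps >= 1L)
  co <- which(inferred != GENO_MISSING & truth != GENO_MISSING)
  if (length(co) == 0L) stop("no SNP phased in both haplotypes")
  agree <- inferred[co] == truth[co]
  if (mean(agree) < 0.5) agree <- !agree
  bin <- ceiling(seq_along(co) / bin_snps)
  per_bin <- data.frame(bin = unique(bin),
                        n = as.integer(table(bin)),
                        accuracy = as.numeric(tapply(agree, bin, mean)))
  list(overall = mean(agree), n_phased = sum(inferred != GENO_MISSING),
       n_discordant = sum(!agree), per_bin = per_bin)
}

#' Contradictory-allele read frequency (CAF) in SNP bins
#'
#' Within each bin of `bin_snps` consecutive phased SNPs and each gamete,
#' reads are classified as supporting haplotype 1 or haplotype 2 through the
#' haplotype; the contradictory alleles are the minority class, and the CAF
#' is their fraction of the bin's reads (always <= 0.5). Gamete/bin pairs
#' with no reads are omitted.
#'
#' @param counts [allele_counts()].
#' @param hap integer haplotype vector.
#' @param bin_snps SNPs per bin (default 1000).
#' @return data.frame: `cell`, `bin`, `n_reads`, `caf`.
#' @export
caf_bins <- function(counts, hap, bin_snps = 1000L) {
  stopifnot(bin_snps >= 1L, length(hap) == nrow(counts$snps))
  P <- which(hap != GENO_MISSING)
  if (length(P) == 0L) stop("haplotype has no phased SNPs")
  refP <- as.matrix(counts$ref[, P, drop = FALSE])
  altP <- as.matrix(counts$alt[, P, drop = FALSE])
  h1 <- refP
  h2 <- altP
  swap <- hap[P] == GENO_ALT
  h1[, swap] <- altP[, swap]
  h2[, swap] <- refP[, swap]
  bin <- ceiling(seq_along(P) / bin_snps)
  agg <- function(mm) t(rowsum(t(mm), bin))
  n1 <- agg(h1)
  n2 <- agg(h2)
  tot <- n1 + n2
  idx <- which(tot > 0, arr.ind = TRUE)
  o <- order(idx[, 1], idx[, 2])
  idx <- idx[o, , drop = FALSE]
  data.frame(cell = counts$barcodes[idx[, 1]],
             bin = as.integer(colnames(n1))[idx[, 2]],
             n_reads = as.integer(tot[idx]),
             caf = pmin(n1[idx], n2[idx]) / tot[idx],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
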