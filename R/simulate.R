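# Synthetic gamete datasets with known truth: two parental haplotypes over a
# SNP ladder, per-gamete crossover placements, sparse Poisson read sampling
# with an allele-miscall rate, and optional inserted template switch errors.

#' Simulation configuration
#'
#' Defaults reproduce the validation scenario used throughout the package's
#' tests: 100 gametes over ~21,000 hetSNPs spanning a 5 Mb region, 6
#' crossovers per gamete, sparse coverage (0.5 expected reads per cell per
#' SNP) and a 0.5% allele miscall rate.
#'
#' @param n_cells number of gametes.
#' @param n_snps number of hetSNPs.
#' @param region_bp genomic span in bp.
#' @param snp_positions optional sorted bp positions (default: distinct
#'   uniform draws over the region).
#' @param crossovers_per_cell crossovers per gamete: a single integer, a
#'   per-cell integer vector, or a function(n_cells) returning one.
#' @param crossover_gaps optional fixed SNP-gap indices for the crossovers
#'   (vector applied to every cell, or a list with one vector per cell);
#'   overrides random placement.
#' @param min_co_gap_snps minimum separation between crossovers of one
#'   gamete, in SNP gaps (default 100). Random placements are re-drawn until
#'   all pairs satisfy it, emulating crossover interference; 0 disables the
#'   constraint.
#' @param coverage_mean expected reads per cell per SNP (Poisson).
#' @param miscall_rate probability a sampled read reports the wrong allele,
#'   in [0, 0.5).
#' @param template_switch_positions optional SNP indices used by
#'   [insert_template_switch()].
#' @param chrom chromosome name for the synthetic region.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 100L, n_snps = 21000L, region_bp = 5e6,
                       snp_positions = NULL, crossovers_per_cell = 6L,
                       crossover_gaps = NULL, min_co_gap_snps = 100L,
                       coverage_mean = 0.5, miscall_rate = 0.005,
                       template_switch_positions = NULL, chrom = "chrS",
                       seed = 1L) {
  stopifnot(n_cells >= 1L, n_snps >= 2L, region_bp >= n_snps,
            coverage_mean > 0, miscall_rate >= 0, miscall_rate < 0.5,
            min_co_gap_snps >= 0L)
  if (!is.null(snp_positions))
    stopifnot(length(snp_positions) == n_snps, !is.unsorted(snp_positions, strictly = TRUE))
  structure(list(n_cells = as.integer(n_cells), n_snps = as.integer(n_snps),
                 region_bp = region_bp, snp_positions = snp_positions,
                 crossovers_per_cell = crossovers_per_cell,
                 crossover_gaps = crossover_gaps,
                 min_co_gap_snps = as.integer(min_co_gap_snps),
                 coverage_mean = coverage_mean, miscall_rate = miscall_rate,
                 template_switch_positions = template_switch_positions,
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

co_counts_from_cfg <- function(cfg) {
  x <- cfg$crossovers_per_cell
  k <- if (is.function(x)) x(cfg$n_cells) else rep_len(as.integer(x), cfg$n_cells)
  stopifnot(all(k >= 0L), all(k < cfg$n_snps))
  as.integer(k)
}

# uniform draw of k gap indices, all pairs >= min_sep apart and >= min_sep
# gaps away from both chromosome ends (interference-style spacing that also
# keeps every crossover identifiable)
draw_gaps <- function(n_gaps, k, min_sep) {
  if (k == 0L) return(integer(0))
  lo <- min_sep + 1L
  hi <- n_gaps - min_sep
  if (hi < lo || (k - 1L) * min_sep >= hi - lo + 1L)
    stop("cannot place ", k, " crossovers with separation ", min_sep,
         " among ", n_gaps, " SNP gaps")
  if (k == 1L) return(sample(lo:hi, 1L))
  repeat {
    g <- sort(sample(lo:hi, k))
    if (min_sep == 0L || all(diff(g) >= min_sep)) return(g)
  }
}

#' Simulate ground truth: donor haplotype and per-gamete crossovers
#'
#' Haplotype-1 alleles are drawn uniformly ref/alt per SNP. Each gamete gets
#' crossover breakpoints at random SNP gaps (respecting `min_co_gap_snps`,
#' or at `crossover_gaps` if supplied); its haplotype state starts from a
#' fair coin and alternates at each breakpoint. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg [sim_config()].
#' @return list of class `truth_set`: `snps` (unphased [snp_table()]),
#'   `hap_truth` (integer haplotype), `cell_states` (cells x SNPs matrix of
#'   1/2), `breakpoints` (list per cell of data.frame `gap_index`, `bp` -
#'   the gap's left SNP index and the gap midpoint), `barcodes`, `config`.
#' @export
simulate_truth <- function(cfg) {
  set.seed(cfg$seed)
  S <- cfg$n_snps
  pos <- cfg$snp_positions %||% sort(sample.int(cfg$region_bp, S))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  snps <- snp_table(cfg$chrom, pos, ref, unname(alt))
  hap_truth <- sample(c(GENO_REF, GENO_ALT), S, replace = TRUE)
  k <- co_counts_from_cfg(cfg)
  fixed <- cfg$crossover_gaps
  if (!is.null(fixed) && !is.list(fixed)) fixed <- rep(list(fixed), cfg$n_cells)
  cell_states <- matrix(0L, cfg$n_cells, S)
  breakpoints <- vector("list", cfg$n_cells)
  for (cc in seq_len(cfg$n_cells)) {
    gaps <- if (!is.null(fixed)) sort(as.integer(fixed[[cc]])) else
      draw_gaps(S - 1L, k[cc], cfg$min_co_gap_snps)
    stopifnot(all(gaps >= 1L), all(gaps <= S - 1L), !anyDuplicated(gaps))
    start <- sample(c(1L, 2L), 1L)
    flips <- integer(S)
    flips[gaps + 1L] <- 1L
    st <- (start - 1L + cumsum(flips)) %% 2L + 1L
    cell_states[cc, ] <- st
    breakpoints[[cc]] <- data.frame(
      gap_index = gaps,
      bp = as.integer(floor((pos[gaps] + pos[gaps + 1L]) / 2)))
  }
  barcodes <- sprintf("CELL%04d", seq_len(cfg$n_cells))
  rownames(cell_states) <- barcodes
  structure(list(snps = snps, hap_truth = hap_truth,
                 cell_states = cell_states, breakpoints = breakpoints,
                 barcodes = barcodes, config = cfg),
            class = "truth_set")
}

#' Sample sparse allele counts from a truth set
#'
#' Per cell per SNP the read count is Poisson(`coverage_mean`); each read
#' reports the gamete's true allele with probability `1 - miscall_rate`,
#' else the other allele. Continues the RNG stream of [simulate_truth()] -
#' seed once via the config (or use [simulate_gametes()]).
#'
#' @param truth [simulate_truth()] result.
#' @return [allele_counts()].
#' @export
sample_counts <- function(truth) {
  cfg <- truth$config
  nc <- cfg$n_cells
  S <- cfg$n_snps
  N <- matrix(stats::rpois(nc * S, cfg$coverage_mean), nc, S)
  wrong <- matrix(stats::rbinom(nc * S, N, cfg$miscall_rate), nc, S)
  # gamete's true allele code: hap1 allele in state 1, the other in state 2
  hapm <- matrix(truth$hap_truth, nc, S, byrow = TRUE)
  true_is_ref <- (truth$cell_states == 1L) == (hapm == GENO_REF)
  refc <- ifelse(true_is_ref, N - wrong, wrong)
  allele_counts(truth$snps, truth$barcodes, refc, N - refc)
}

#' Insert template switch errors into a truth set
#'
#' Adds `hap_corrupted` - the true haplotype complemented from each given
#' SNP index onward - for exercising switch-error correction; the original
#' truth is retained and the positions are recorded in `switch_positions`.
#'
#' @param truth `truth_set`.
#' @param positions SNP indices (default: the config's
#'   `template_switch_positions`).
#' @return the `truth_set` with `hap_corrupted` and `switch_positions` added.
#' @export
insert_template_switch <- function(truth, positions = NULL) {
  positions <- positions %||% truth$config$template_switch_positions %||% integer(0)
  positions <- sort(as.integer(positions))
  stopifnot(all(positions >= 1L), all(positions <= length(truth$hap_truth)))
  truth$hap_corrupted <- apply_switches(truth$hap_truth, positions)
  truth$switch_positions <- positions
  truth
}

#' Simulate a full synthetic gamete dataset
#'
#' [simulate_truth()] + [sample_counts()] (+ [insert_template_switch()] when
#' the config asks for switches) under one seed; byte-identical outputs for
#' identical configs.
#'
#' @param cfg [sim_config()].
#' @return list of class `gamete_sim`: `truth`, `counts`.
#' @export
simulate_gametes <- function(cfg) {
  truth <- simulate_truth(cfg)
  counts <- sample_counts(truth)
  if (!is.null(cfg$template_switch_positions))
    truth <- insert_template_switch(truth)
  structure(list(truth = truth, counts = counts), class = "gamete_sim")
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Emits the unphased VCF, the barcode list, the sparse count matrices plus
#' SNP annotation (readable with [read_phase_outputs()]), and truth tables
#' (`<prefix>_truth_hap.txt`, `<prefix>_truth_crossovers.txt`).
#'
#' @param sim [simulate_gametes()] result.
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
write_sim_inputs <- function(sim, prefix) {
  truth <- sim$truth
  paths <- write_phase_outputs(prefix, sim$counts,
                               integer(nrow(truth$snps)))
  vcf <- paste0(prefix, ".vcf")
  write_unphased_vcf(vcf, truth$snps)
  hap_path <- paste0(prefix, "_truth_hap.txt")
  utils::write.table(
    data.frame(pos = truth$snps$pos,
               hap1_allele = hap_allele_letter(truth$snps, truth$hap_truth)),
    hap_path, sep = "\t", quote = FALSE, row.names = FALSE)
  co <- do.call(rbind, lapply(seq_along(truth$breakpoints), function(cc)
    if (nrow(truth$breakpoints[[cc]]))
      cbind(data.frame(cell = truth$barcodes[cc]), truth$breakpoints[[cc]])))
  co_path <- paste0(prefix, "_truth_crossovers.txt")
  utils::write.table(co %||% data.frame(cell = character(0), gap_index = integer(0),
                                        bp = integer(0)),
                     co_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, vcf, hap_path, co_path))
}
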