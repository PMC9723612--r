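# Fixture builders and independent oracles used across the suite.

# snp_table with evenly spaced positions
toy_snps <- function(n, chrom = "chr1", spacing = 100L, ref = "A", alt = "C") {
  snp_table(chrom, seq(100L, by = spacing, length.out = n),
            rep_len(ref, n), rep_len(alt, n))
}

# allele_counts from dense ref/alt matrices
toy_counts <- function(ref, alt, snps = NULL, barcodes = NULL) {
  ref <- as.matrix(ref)
  if (is.null(snps)) snps <- toy_snps(ncol(ref))
  if (is.null(barcodes)) barcodes <- sprintf("BC%03d", seq_len(nrow(ref)))
  allele_counts(snps, barcodes, ref, as.matrix(alt))
}

rand_counts <- function(n_cells, n_snps, seed, density = 0.4) {
  set.seed(seed)
  r <- matrix(rbinom(n_cells * n_snps, 3, density / 3), n_cells, n_snps)
  a <- matrix(rbinom(n_cells * n_snps, 3, density / 3), n_cells, n_snps)
  toy_counts(r, a)
}

## --- exhaustive-path HMM oracle --------------------------------------------

oracle_path_loglik <- function(st, h1, h2, pos, params) {
  n <- length(st)
  v <- log(params$pi[st[1]]) + sum(emission_logprob(h1, h2, st, params))
  if (n > 1L) {
    p <- transition_prob(diff(pos), params)
    v <- v + sum(ifelse(st[-1L] != st[-n], log(p), log1p(-p)))
  }
  v
}

oracle_viterbi <- function(h1, h2, pos, params) {
  n <- length(pos)
  grid <- as.matrix(expand.grid(rep(list(1:2), n)))
  ll <- apply(grid, 1L, oracle_path_loglik, h1 = h1, h2 = h2, pos = pos,
              params = params)
  list(best = max(ll), states = grid[which.max(ll), ])
}

## --- brute-force template-selection oracle ----------------------------------

oracle_select_template <- function(G, min_shared, min_concordance) {
  nc <- nrow(G)
  n_cov <- rowSums(G != 0L)
  best <- NULL
  for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
    co <- G[i, ] != 0L & G[j, ] != 0L
    ns <- sum(co)
    if (ns < min_shared) next
    eq <- sum(G[i, co] == G[j, co])
    conc <- max(eq, ns - eq) / ns
    cand <- list(i = i, j = j, ns = ns, conc = conc)
    if (is.null(best) || conc > best$conc ||
        (conc == best$conc && ns > best$ns)) best <- cand
  }
  if (is.null(best) || best$conc < min_concordance) {
    tpl <- which.max(n_cov)
    return(list(template = tpl, partner = tpl, fallback = TRUE,
                conc = NA_real_, ns = NA_integer_))
  }
  tpl <- if (n_cov[best$j] > n_cov[best$i]) best$j else best$i
  list(template = tpl, partner = if (tpl == best$i) best$j else best$i,
       fallback = FALSE, conc = best$conc, ns = best$ns)
}

## --- tiny VCF / SAM fixtures ------------------------------------------------

write_test_vcf <- function(path, chrom, pos, ref, alt, qual, gt) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT\t%s",
                  chrom, pos, ref, alt, qual, gt)
  writeLines(c(header, body), path)
  path
}

# hand-written SAM -> sorted, indexed BAM. Reads are 10 bp M-only unless a
# cigar is given; quality defaults to Q40 ('I').
make_test_bam <- function(reads, dir = tempfile("bam"), ln = 10000L) {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:chr1\tLN:%d", ln))
  rows <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    qual <- if (is.null(r$qual) || is.na(r$qual)) strrep("I", nchar(r$seq)) else r$qual
    cigar <- if (is.null(r$cigar) || is.na(r$cigar)) paste0(nchar(r$seq), "M") else r$cigar
    flag <- if (!is.null(r$flag) && !is.na(r$flag)) r$flag else 0L
    paste(sprintf("r%03d", i), flag, "chr1", r$pos, r$mapq, cigar, "*", 0, 0,
          r$seq, qual, paste0("CB:Z:", r$cb), sep = "\t")
  }, character(1))
  writeLines(c(header, rows[order(reads$pos)]), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                   indexDestination = TRUE)
}

# half the smallest true inter-breakpoint distance of a cell (matching radius
# under which every called crossover pairs with at most one true breakpoint)
match_radius <- function(bps, region_bp) {
  if (length(bps) < 2L) return(region_bp / 4)
  min(diff(sort(bps))) / 2
}

# discovery check: exactly the right number of retained calls and a one-to-one
# match of true breakpoints to call intervals expanded by the matching radius
crossovers_discovered <- function(truth, crossovers) {
  all(vapply(seq_along(truth$barcodes), function(cc) {
    bps <- truth$breakpoints[[cc]]$bp
    co <- crossovers[crossovers$cell == truth$barcodes[cc], ]
    if (nrow(co) != length(bps)) return(FALSE)
    rad <- match_radius(bps, truth$config$region_bp)
    used <- rep(FALSE, nrow(co))
    for (b in bps) {
      j <- which(!used & co$left_pos - rad <= b & b < co$right_pos + rad)
      if (length(j) == 0L) return(FALSE)
      used[j[1]] <- TRUE
    }
    TRUE
  }, logical(1)))
}
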