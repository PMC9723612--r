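mk_seg <- function(cell, states, first, last, n_snps, llr, chrom = "chr1") {
  data.frame(barcode = cell, chrom = chrom, first_snp_pos = as.integer(first),
             last_snp_pos = as.integer(last), state = states,
             n_snps = as.integer(n_snps), n_reads = as.integer(n_snps),
             log_lik_ratio = llr, stringsAsFactors = FALSE)
}

test_that("weak segments are absorbed and whole cells can be dropped", {
  f <- filter_params(min_cell_snps = 50, max_raw_co = 10, min_seg_snps = 3,
                     min_seg_llr = 5, min_seg_bp = 0)
  # blip between two solid segments of the same state -> no crossover
  seg <- mk_seg("c1", c("H1", "H2", "H1"), c(100, 5100, 5400),
                c(5000, 5300, 9000), c(50, 1, 60), c(200, 3, 250))
  out <- crossovers_from_segments(seg, f)
  expect_identical(nrow(out$crossovers), 0L)
  expect_identical(out$qc$retained_co, 0L)
  expect_identical(out$qc$raw_co, 2L)
  # a cell with too many raw crossovers is dropped with a reason
  many <- mk_seg("c2", rep(c("H1", "H2"), 21)[1:41], seq(1, by = 100, length.out = 41),
                 seq(60, by = 100, length.out = 41), rep(5, 41), rep(50, 41))
  out2 <- crossovers_from_segments(many, filter_params(min_cell_snps = 10,
                                                       max_raw_co = 10,
                                                       min_seg_bp = 0))
  expect_true(out2$qc$dropped)
  expect_identical(out2$qc$reason, "excess_crossovers")
  expect_identical(nrow(out2$crossovers), 0L)
  # two clean alternating segments -> exactly one crossover, min-LLR confidence
  seg3 <- mk_seg("c3", c("H1", "H2"), c(100, 6000), c(5000, 9000),
                 c(40, 30), c(120, 80))
  out3 <- crossovers_from_segments(seg3, f)
  expect_identical(nrow(out3$crossovers), 1L)
  expect_equal(out3$crossovers$left_pos, 5000)
  expect_equal(out3$crossovers$right_pos, 6000)
  expect_equal(out3$crossovers$confidence, 80)
  expect_error(crossovers_from_segments(seg3[2:1, ], f), "not ordered")
})

test_that("tightening any filter never increases retained crossovers", {
  set.seed(17)
  base <- filter_params(min_cell_snps = 10, max_raw_co = 20, min_seg_snps = 1,
                        min_seg_llr = 0, min_seg_bp = 0)
  segs <- do.call(rbind, lapply(1:8, function(i) {
    k <- sample(1:6, 1)
    bounds <- sort(sample(seq(100, 99000, by = 100), 2 * k))
    mk_seg(sprintf("c%d", i), rep(c("H1", "H2"), k)[1:k],
           bounds[seq(1, 2 * k, 2)], bounds[seq(2, 2 * k, 2)],
           sample(1:50, k, replace = TRUE), runif(k, 0, 60))
  }))
  n_retained <- function(f) nrow(crossovers_from_segments(segs, f)$crossovers)
  n0 <- n_retained(base)
  for (tighter in list(list(min_cell_snps = 120), list(max_raw_co = 2),
                       list(min_seg_snps = 10), list(min_seg_llr = 30),
                       list(min_seg_bp = 2e4))) {
    f <- do.call(filter_params, utils::modifyList(unclass(base), tighter))
    expect_lte(n_retained(f), n0)
  }
})

test_that("crossover mass is spread proportionally and conserved over tilings", {
  bins <- tile_bins("chr1", 1, 1000, 500)  # [1,500], [501,1000]
  co <- data.frame(cell = c("a", "a"), chrom = "chr1",
                   left_pos = c(101, 301), right_pos = c(201, 801),
                   confidence = 50)
  m <- count_cos(co, bins, c("a", "b"))
  expect_equal(m$counts[, 1], c(1 + 0.4, 0.6))   # 1 inside; 40%/60% split
  expect_equal(m$counts[, 2], c(0, 0))
  expect_equal(sum(m$counts), 2)                  # conservation
  mid <- count_cos(co, bins, c("a", "b"), assign = "midpoint")
  expect_equal(mid$counts[, 1], c(1, 1))          # midpoints 151 and 551
  expect_warning(count_cos(data.frame(cell = "a", chrom = "chr1",
                                      left_pos = 1500, right_pos = 1600,
                                      confidence = 1), bins, "a"),
                 "outside")
  expect_error(count_cos(co, data.frame(chrom = "chr1", start = c(1, 400),
                                        end = c(500, 900)), "a"),
               "overlapping")
})

test_that("mapping functions match closed forms and their small-r limit", {
  expect_identical(map_distance(0), 0)
  expect_equal(map_distance(0.1, "kosambi"), 25 * log(1.5), tolerance = 1e-12)
  expect_equal(map_distance(0.1, "haldane"), -50 * log(0.8), tolerance = 1e-12)
  expect_equal(map_distance(0.1, "kosambi"), 10.137, tolerance = 1e-3)
  expect_equal(map_distance(0.1, "haldane"), 11.157, tolerance = 1e-3)
  # small-r limit: both converge to 100 r (Haldane's relative error is ~r,
  # so the 1% band holds up to r ~ 0.01)
  r <- c(1e-4, 1e-3, 5e-3)
  expect_true(all(abs(map_distance(r, "kosambi") - 100 * r) <= 0.01 * 100 * r))
  expect_true(all(abs(map_distance(r, "haldane") - 100 * r) <= 0.01 * 100 * r))
  expect_lt(abs(map_distance(0.01, "kosambi") / 1 - 1), 0.01)
  expect_error(map_distance(0.5), "0.5")
  expect_equal(map_distance(0.7, "haldane", clamp = TRUE),
               map_distance(0.5 - 1e-9, "haldane"))
})

test_that("genetic distances compose counting and mapping per group", {
  bins <- tile_bins("chr1", 1, 2000, 1000)
  counts <- matrix(0, 2, 100)
  counts[1, 1:10] <- 1                      # bin 1: total mass 10 over 100 cells
  m <- structure(list(intervals = bins, cells = sprintf("c%d", 1:100),
                      counts = counts, labels = NULL),
                 class = "crossover_matrix")
  d <- cal_genetic_dist(m)
  expect_equal(d$cM, c(25 * log(1.5), 0), tolerance = 1e-12)
  expect_equal(d$cum_cM[2], 25 * log(1.5))
  # two identical groups give identical curves
  d2 <- cal_genetic_dist(m, group_by = rep(c("g1", "g2"), 50))
  halves <- split(d2$cM, d2$group)
  expect_equal(halves[[1]], halves[[2]])
})

test_that("resampling comparisons are deterministic and sane under the null", {
  bins <- tile_bins("chr1", 1, 1000, 500)
  counts <- matrix(1, 2, 20)               # identical constant cells
  m <- structure(list(intervals = bins, cells = sprintf("c%d", 1:20),
                      counts = counts, labels = NULL),
                 class = "crossover_matrix")
  labels <- rep(c("a", "b"), each = 10)
  bt <- bootstrap_dist(m, labels, B = 200, seed = 1)
  expect_equal(bt$observed_diff, 0)
  expect_equal(c(bt$ci_low, bt$ci_high), c(0, 0))
  bt2 <- bootstrap_dist(m, labels, B = 200, seed = 1)
  expect_identical(bt[c("ci_low", "ci_high")], bt2[c("ci_low", "ci_high")])
  pm <- permute_dist(m, labels, B = 199, seed = 2)
  expect_equal(pm$p_value, 1)              # zero observed difference
  set.seed(33)
  counts2 <- matrix(runif(2 * 20), 2, 20)
  m2 <- structure(list(intervals = bins, cells = m$cells, counts = counts2,
                       labels = NULL), class = "crossover_matrix")
  for (s in 1:5) {
    p <- permute_dist(m2, labels, B = 199, seed = s)$p_value
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
  expect_warning(bootstrap_dist(m, rep(c("a", "b"), c(1, 19)), B = 100),
                 "fewer than 2")
})

test_that("phasing accuracy orients by majority before comparing", {
  truth <- c(1L, 2L, 1L, 1L, 2L)
  expect_equal(phasing_accuracy(truth, truth)$overall, 1)
  expect_equal(phasing_accuracy(complement_haplotype(truth), truth)$overall, 1)
  inferred <- rep(c(1L, 2L), 50)
  truth2 <- inferred
  truth2[7] <- 3L - truth2[7]
  res <- phasing_accuracy(inferred, truth2, bin_snps = 100L)
  expect_equal(res$per_bin$accuracy, 0.99)
  expect_identical(res$n_discordant, 1L)
  expect_identical(res$n_phased, 100L)
  expect_error(phasing_accuracy(c(1L, 0L), c(0L, 1L)), "no SNP")
})

test_that("contradictory-allele read frequencies take the minority fraction", {
  counts <- toy_counts(ref = rbind(c(3, 4, 2), c(9, 0, 0)),
                       alt = rbind(c(0, 0, 0), c(1, 0, 0)))
  hap <- rep(1L, 3)
  caf <- caf_bins(counts, hap, bin_snps = 3L)
  expect_equal(caf$caf[caf$cell == "BC001"], 0)
  expect_equal(caf$caf[caf$cell == "BC002"], 0.1)
  set.seed(6)
  counts2 <- rand_counts(6, 50, seed = 6)
  caf2 <- caf_bins(counts2, sample(1:2, 50, replace = TRUE), bin_snps = 10L)
  expect_true(all(caf2$caf <= 0.5))
  expect_true(all(caf2$n_reads > 0))
})
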