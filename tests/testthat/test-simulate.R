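test_that("simulation is fully reproducible from its seed", {
  cfg <- sim_config(n_cells = 20, n_snps = 300, region_bp = 1e5,
                    crossovers_per_cell = 2, min_co_gap_snps = 30, seed = 5)
  a <- simulate_gametes(cfg)
  b <- simulate_gametes(cfg)
  expect_identical(a$truth$snps, b$truth$snps)
  expect_identical(a$truth$cell_states, b$truth$cell_states)
  expect_identical(a$truth$breakpoints, b$truth$breakpoints)
  expect_identical(as.matrix(a$counts$ref), as.matrix(b$counts$ref))
  expect_identical(as.matrix(a$counts$alt), as.matrix(b$counts$alt))
})

test_that("gamete states flip exactly at the drawn breakpoints", {
  cfg0 <- sim_config(n_cells = 10, n_snps = 200, region_bp = 5e4,
                     crossovers_per_cell = 0, seed = 2)
  t0 <- simulate_truth(cfg0)
  expect_true(all(apply(t0$cell_states, 1, function(s) length(unique(s)) == 1L)))
  cfg6 <- sim_config(n_cells = 10, n_snps = 2100, region_bp = 5e5,
                     crossovers_per_cell = 6, min_co_gap_snps = 100, seed = 3)
  t6 <- simulate_truth(cfg6)
  for (cc in 1:10) {
    st <- t6$cell_states[cc, ]
    flips <- which(diff(st) != 0L)
    expect_identical(flips, t6$breakpoints[[cc]]$gap_index)
    expect_length(flips, 6L)
    expect_true(all(diff(t6$breakpoints[[cc]]$gap_index) >= 100L))
    bp <- t6$breakpoints[[cc]]$bp
    expect_true(all(t6$snps$pos[flips] <= bp & bp < t6$snps$pos[flips + 1L]))
  }
  expect_error(simulate_truth(sim_config(n_cells = 2, n_snps = 50,
                                         region_bp = 1e4,
                                         crossovers_per_cell = 40,
                                         min_co_gap_snps = 10, seed = 1)),
               "cannot place")
})

test_that("sampled counts follow the configured noise and coverage model", {
  cfg <- sim_config(n_cells = 80, n_snps = 2000, region_bp = 5e5,
                    crossovers_per_cell = 1, coverage_mean = 0.3,
                    miscall_rate = 0.02, seed = 8)
  sim <- simulate_gametes(cfg)
  r <- as.matrix(sim$counts$ref)
  a <- as.matrix(sim$counts$alt)
  n_reads <- sum(r) + sum(a)
  # contradictory reads (supporting the non-inherited allele) ~ miscall rate
  hapm <- matrix(sim$truth$hap_truth, 80, 2000, byrow = TRUE)
  true_ref <- (sim$truth$cell_states == 1L) == (hapm == 1L)
  contradictory <- sum(r[!true_ref]) + sum(a[true_ref])
  expect_lt(abs(contradictory / n_reads - 0.02),
            3 * sqrt(0.02 * 0.98 / n_reads))
  # nonzero entries per cell ~ n_snps * (1 - exp(-coverage))
  frac_nonzero <- mean((r + a) > 0)
  p <- 1 - exp(-0.3)
  expect_lt(abs(frac_nonzero - p), 3 * sqrt(p * (1 - p) / (80 * 2000)))
})

test_that("noise-free high coverage lets genotypes recover gamete states", {
  cfg <- sim_config(n_cells = 12, n_snps = 150, region_bp = 4e4,
                    crossovers_per_cell = 1, min_co_gap_snps = 20,
                    coverage_mean = 6, miscall_rate = 0, seed = 10)
  sim <- simulate_gametes(cfg)
  G <- call_genotypes(sim$counts)
  covered <- G != 0L
  hapm <- matrix(sim$truth$hap_truth, 12, 150, byrow = TRUE)
  expected <- ifelse(sim$truth$cell_states == 1L, hapm, 3L - hapm)
  expect_identical(G[covered], expected[covered])
  expect_gt(mean(covered), 0.99)
})

test_that("template switches corrupt a copy and record their positions", {
  cfg <- sim_config(n_cells = 5, n_snps = 100, region_bp = 3e4,
                    crossovers_per_cell = 0, seed = 4)
  truth <- simulate_truth(cfg)
  none <- insert_template_switch(truth, integer(0))
  expect_identical(none$hap_corrupted, truth$hap_truth)
  full <- insert_template_switch(truth, 1L)
  expect_identical(full$hap_corrupted, complement_haplotype(truth$hap_truth))
  two <- insert_template_switch(truth, c(80L, 30L))
  expect_identical(two$switch_positions, c(30L, 80L))
  expect_identical(two$hap_corrupted,
                   apply_switches(truth$hap_truth, c(30L, 80L)))
  expect_identical(two$hap_truth, truth$hap_truth)
})

test_that("simulated datasets are written in the pipeline's input formats", {
  cfg <- sim_config(n_cells = 4, n_snps = 60, region_bp = 2e4,
                    crossovers_per_cell = 1, min_co_gap_snps = 5, seed = 6)
  sim <- simulate_gametes(cfg)
  prefix <- file.path(tempfile("simout"), "d")
  dir.create(dirname(prefix))
  paths <- write_sim_inputs(sim, prefix)
  expect_true(all(file.exists(paths)))
  snps <- read_hetsnps(paste0(prefix, ".vcf"), "chrS")
  expect_identical(snps$pos, sim$truth$snps$pos)
  expect_true(all(snps$phase == "unphased"))
  back <- read_phase_outputs(prefix)
  expect_identical(as.matrix(back$counts$ref), as.matrix(sim$counts$ref))
  expect_identical(back$counts$barcodes, sim$truth$barcodes)
})
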