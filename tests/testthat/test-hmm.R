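test_that("binomial emissions match closed forms and are symmetric", {
  p <- hmm_params()
  expect_equal(emission_logprob(3, 0, 1L, p), 3 * log(0.9), tolerance = 1e-12)
  expect_equal(emission_logprob(3, 0, 1L, p), -0.31608, tolerance = 1e-4)
  expect_equal(emission_logprob(9, 1, 1L, p),
               log(10) + 9 * log(0.9) + log(0.1), tolerance = 1e-12)
  expect_equal(emission_logprob(9, 1, 1L, p), -0.94824, tolerance = 1e-4)
  # theta1 = 1 - theta2: swapping counts is the same as swapping states
  for (ab in list(c(0, 2), c(3, 1), c(5, 5))) {
    expect_equal(emission_logprob(ab[1], ab[2], 1L, p),
                 emission_logprob(ab[2], ab[1], 2L, p))
  }
  expect_error(emission_logprob(-1, 2, 1L, p), "negative")
})

test_that("transition probabilities scale with distance and clamp", {
  p <- hmm_params(cmPmb = 0.1)
  expect_equal(transition_prob(1e6, p), 1e-3, tolerance = 1e-15)
  expect_equal(transition_prob(1, hmm_params(cmPmb = 0)), 1e-10)   # floor
  expect_equal(transition_prob(1e12, p), 0.25)                     # ceiling
  expect_equal(transition_prob(c(1e5, 2e5), p), c(1e-4, 2e-4))
})

test_that("Viterbi matches exhaustive path enumeration on small instances", {
  p <- hmm_params()
  # dominance: uniform strong evidence, no transitions
  expect_identical(viterbi_cell(rep(2, 5), rep(0, 5), (1:5) * 1e4, p),
                   rep(1L, 5))
  # one clean crossover in the middle
  st <- viterbi_cell(c(2, 2, 2, 0, 0, 0), c(0, 0, 0, 2, 2, 2), (1:6) * 1e5, p)
  expect_identical(st, c(1L, 1L, 1L, 2L, 2L, 2L))
  ora <- oracle_viterbi(c(2, 2, 2, 0, 0, 0), c(0, 0, 0, 2, 2, 2), (1:6) * 1e5, p)
  expect_identical(st, unname(ora$states))
  # random instances: path log-probability equals the enumerated maximum
  set.seed(31)
  for (i in 1:40) {
    n <- sample(1:8, 1)
    h1 <- rpois(n, 1.2)
    h2 <- rpois(n, 1.2)
    tot <- h1 + h2
    h1[tot == 0] <- 1
    pos <- cumsum(sample(100:50000, n))
    pp <- hmm_params(cmPmb = sample(c(0.05, 0.1, 1), 1))
    st <- viterbi_cell(h1, h2, pos, pp)
    expect_equal(oracle_path_loglik(st, h1, h2, pos, pp),
                 oracle_viterbi(h1, h2, pos, pp)$best, tolerance = 1e-9)
  }
})

test_that("segment scores equal the flipped-path likelihood difference", {
  p <- hmm_params()
  # single whole-chromosome segment: no boundary terms
  seg <- segment_and_score(rep(1L, 3), rep(2, 3), rep(0, 3), (1:3) * 1e4, p)
  expect_identical(nrow(seg), 1L)
  expect_equal(seg$log_lik_ratio, 6 * (log(0.9) - log(0.1)), tolerance = 1e-12)
  expect_equal(seg$log_lik_ratio, 13.183, tolerance = 1e-3)
  # equal evidence both ways: emission contribution is zero
  seg0 <- segment_and_score(rep(1L, 4), rep(1, 4), rep(1, 4), (1:4) * 1e4, p)
  expect_equal(seg0$log_lik_ratio, 0)
  # randomized: LLR == direct two-path recomputation, every segment
  set.seed(55)
  for (i in 1:30) {
    n <- sample(2:9, 1)
    h1 <- rpois(n, 1); h2 <- rpois(n, 1)
    tot <- h1 + h2; h1[tot == 0] <- 1
    pos <- cumsum(sample(500:30000, n))
    st <- viterbi_cell(h1, h2, pos, p)
    segs <- segment_and_score(st, h1, h2, pos, p)
    for (s in seq_len(nrow(segs))) {
      flipped <- st
      idx <- segs$first_idx[s]:segs$last_idx[s]
      flipped[idx] <- 3L - flipped[idx]
      expect_equal(segs$log_lik_ratio[s],
                   oracle_path_loglik(st, h1, h2, pos, p) -
                     oracle_path_loglik(flipped, h1, h2, pos, p),
                   tolerance = 1e-9)
    }
  }
})

test_that("crossover count is segments minus one; cmPmb acts monotonically", {
  cfg <- sim_config(n_cells = 30, n_snps = 800, region_bp = 2e5,
                    crossovers_per_cell = 2, min_co_gap_snps = 60,
                    coverage_mean = 0.6, miscall_rate = 0.01, seed = 9)
  sim <- simulate_gametes(cfg)
  prev <- -1L
  for (cm in c(0.01, 0.1, 1, 10)) {
    res <- call_crossovers_dataset(sim$counts, sim$truth$hap_truth,
                                   hmm_params(cmPmb = cm))
    n_seg <- table(res$segments$barcode)
    n_co <- sum(n_seg - 1L)
    expect_gte(n_co, prev)
    prev <- n_co
  }
})

test_that("complementing the haplotype swaps labels but not boundaries", {
  cfg <- sim_config(n_cells = 10, n_snps = 400, region_bp = 1e5,
                    crossovers_per_cell = 1, min_co_gap_snps = 50,
                    coverage_mean = 0.8, miscall_rate = 0.01, seed = 14)
  sim <- simulate_gametes(cfg)
  a <- call_crossovers_dataset(sim$counts, sim$truth$hap_truth)
  b <- call_crossovers_dataset(sim$counts,
                               complement_haplotype(sim$truth$hap_truth))
  expect_identical(a$segments$first_snp_pos, b$segments$first_snp_pos)
  expect_identical(a$segments$state,
                   c(H1 = "H2", H2 = "H1")[b$segments$state], ignore_attr = TRUE)
  expect_equal(a$segments$log_lik_ratio, b$segments$log_lik_ratio)
})

test_that("noise-free cells give one segment; uncovered cells are logged", {
  counts <- toy_counts(ref = rbind(c(2, 1, 2), c(0, 0, 0)),
                       alt = rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_message(res <- call_crossovers_dataset(counts, rep(1L, 3)),
                 "zero covered")
  expect_identical(nrow(res$segments), 1L)
  expect_identical(res$segments$state, "H1")
  expect_identical(res$segments$n_reads, 5L)
})
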