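test_that("neutral SFS sampling matches its closed form", {
  f <- sample_neutral_frequencies(1e5, 10, seed = 42)
  expect_true(all(f > 0 & f < 1))
  expected_singleton <- 1 / sum(1 / (1:9))
  expect_lt(abs(mean(f == 0.1) - expected_singleton), 0.01)
  expect_identical(f, sample_neutral_frequencies(1e5, 10, seed = 42))
  expect_error(sample_neutral_frequencies(10, 2), "at least 4")
})

test_that("the generator is fully deterministic under its seed", {
  d <- sim_design(n_per_cell = 5, n_sites = c("2RL" = 300), seed = 9,
                  sweeps = list(sweep_config("2RL", 5e4, 2e4, freq = 0.4,
                                             name = "sw")))
  s1 <- simulate_cohorts(d)
  s2 <- simulate_cohorts(d)
  expect_identical(s1$sets[["2RL"]]$H, s2$sets[["2RL"]]$H)
  expect_identical(s1$frame, s2$frame)
  expect_identical(s1$truth, s2$truth)
  d$seed <- 10L
  expect_false(identical(simulate_cohorts(d)$sets[["2RL"]]$H,
                         s1$sets[["2RL"]]$H))
})

test_that("simulated output survives a VCF/metadata round-trip", {
  sim <- simulate_cohorts(sim_design(n_per_cell = 4,
                                     n_sites = c("X" = 200), seed = 5))
  dir <- tempfile()
  paths <- write_sim(sim, dir)
  rt <- read_vcf(paths$vcf[["X"]])
  expect_identical(rt$hap$H, sim$sets[["X"]]$H)
  meta <- read_metadata(paths$metadata, samples = rt$hap$samples)
  expect_equal(meta$sample_id, sim$frame$sample_id)
  expect_true(file.exists(paths$truth))
})

test_that("without household effects allele counts are independent of household", {
  sim <- simulate_cohorts(sim_design(n_per_cell = 40, regions = "East",
                                     rounds = "baseline", arms = "PBO",
                                     n_sites = c("2RL" = 150),
                                     d = 0, sigma_h = 0,
                                     household_mean_size = 5, seed = 21))
  hap <- sim$sets[["2RL"]]
  hh <- sim$frame$household[match(hap_samples(hap), sim$frame$sample_id)]
  seg <- which(segregating_mask(hap))
  seg <- seg[rowSums(hap$H[seg, , drop = FALSE]) >= 8]  # enough counts
  seg <- head(seg, 100)
  pvals <- vapply(seg, function(s) {
    suppressWarnings(chisq.test(table(hh, hap$H[s, ]))$p.value)
  }, 0)
  expect_gte(mean(pvals >= 0.05), 0.9)
})

test_that("panmictic simulation gives unbiased windowed Hudson F_ST", {
  sim <- simulate_cohorts(sim_design(n_per_cell = 50, rounds = "baseline",
                                     arms = "PBO",
                                     n_sites = c("2RL" = 5000),
                                     d = 0, sigma_h = 0, seed = 31))
  hap <- sim$sets[["2RL"]]
  w <- make_windows(hap, 50)
  east <- subset_samples(hap, sim$frame$sample_id[sim$frame$region == "East"])
  west <- subset_samples(hap, sim$frame$sample_id[sim$frame$region == "West"])
  tr <- fst_scan(east, west, w, "hudson")
  expect_equal(nrow(tr), 100L)
  expect_lt(abs(mean(tr$value, na.rm = TRUE)), 0.005)
})

test_that("neutral genome-wide Tajima's D averages to zero", {
  sim <- simulate_cohorts(sim_design(n_per_cell = 10, rounds = "baseline",
                                     arms = "PBO",
                                     n_sites = c("2RL" = 10000),
                                     d = 0, sigma_h = 0, seed = 11))
  div <- diversity_scan(sim$sets[["2RL"]],
                        make_windows(sim$sets[["2RL"]], 50))
  expect_equal(nrow(div), 200L)
  expect_lt(abs(mean(div$tajimas_d, na.rm = TRUE)), 0.15)
})

test_that("hard-sweep injection realises the target core frequency exactly", {
  set.seed(6)
  hap <- make_hap(rand_window(40, 200), pos = seq(500, by = 500,
                                                  length.out = 200))
  cfg <- sweep_config("chr", 50000, 15000, n_core = 1, freq = 0.5,
                      erosion = 0)
  swept <- inject_sweep(hap, seq_len(40), cfg, seed = 99)
  core <- which(swept$pos >= 35000 & swept$pos <= 65000)
  spec <- hap_freq_spectrum(swept$H[core, , drop = FALSE])
  expect_equal(spec$freq[1], 0.5)
  # tag SNP fixed alternate on carriers
  tag <- core[which.min(abs(swept$pos[core] - 50000))]
  expect_equal(sum(swept$H[tag, ]), sum(swept$H[tag, ] == 1L))
  expect_gte(sum(swept$H[tag, ]), 20)
  expect_error(inject_sweep(hap, 1:40, sweep_config("chr", 9e6, 100)),
               "contains no sites")
})

test_that("soft sweeps put the pooled core frequency on top", {
  set.seed(7)
  hap <- make_hap(rand_window(40, 100), pos = seq(500, by = 500,
                                                  length.out = 100))
  cfg <- sweep_config("chr", 25000, 10000, n_core = 2, freq = 0.5,
                      erosion = 0)
  swept <- inject_sweep(hap, seq_len(40), cfg, seed = 98)
  core <- which(swept$pos >= 15000 & swept$pos <= 35000)
  g <- garud_h(hap_freq_spectrum(swept$H[core, , drop = FALSE]))
  expect_gte(g["H12"], g["H1"])
  spec <- hap_freq_spectrum(swept$H[core, , drop = FALSE])
  expect_gte(spec$freq[1] + spec$freq[2], 0.5)
})

test_that("swept-window H12 dominates the neutral genome", {
  pos <- seq(1000, by = 1000, length.out = 2000)
  d <- sim_design(n_per_cell = 25, regions = "East", rounds = "baseline",
                  arms = "PBO", n_sites = c("2RL" = 2000), d = 0,
                  sigma_h = 0, seed = 13, positions = list("2RL" = pos),
                  sweeps = list(sweep_config("2RL", 1000500, 150500,
                                             freq = 0.5, name = "sw")))
  sim <- simulate_cohorts(d)
  tr <- h12_scan(sim$sets[["2RL"]], make_windows(sim$sets[["2RL"]], 100))
  swept <- tr$bp_start >= 850000 & tr$bp_end <= 1151000
  expect_gt(min(tr$value[swept]), max(tr$value[!swept]))
})

test_that("planted frequency shifts hit their per-round targets", {
  sim <- simulate_cohorts(sim_design(n_per_cell = 50, regions = "East",
                                     arms = "PBO",
                                     n_sites = c("2RL" = 100),
                                     d = 0, sigma_h = 0, seed = 17))
  hap <- inject_frequency_shift(sim$sets[["2RL"]], sim$frame, sites = 7,
                                freq_by_round = c(baseline = 0.2,
                                                  round5 = 0.6),
                                seed = 1)
  rnd <- sim$frame$round[match(hap_samples(hap), sim$frame$sample_id)]
  expect_equal(mean(hap$H[7, rnd == "baseline"]), 0.2)
  expect_equal(mean(hap$H[7, rnd == "round5"]), 0.6)
})
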