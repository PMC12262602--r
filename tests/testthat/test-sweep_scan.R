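test_that("haplotype spectra count distinct window haplotypes exactly", {
  H <- matrix(1L, 4, 6)
  expect_equal(hap_freq_spectrum(H)$freq, 1)
  # 10 haplotypes: 4+3+2+1 copies of four types
  base <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  H <- t(base[rep(1:4, 4:1), ])
  spec <- hap_freq_spectrum(H)
  expect_equal(spec$freq, c(0.4, 0.3, 0.2, 0.1))
  expect_error(hap_freq_spectrum(matrix(integer(0), 0, 4)), "empty window")
})

test_that("Garud statistics match their plug-in values", {
  expect_equal(unname(garud_h(1)), c(1, 1, 1, 0))
  expect_equal(unname(garud_h(c(0.5, 0.5))), c(0.5, 1, 1, 0.5))
  g <- garud_h(c(0.4, 0.3, 0.2, 0.1))
  expect_equal(unname(g), c(0.30, 0.54, 0.82, 0.14 / 0.30))
  expect_error(garud_h(c(0.2, 0.5)), "sorted descending")
})

test_that("H statistics agree with brute-force counting on random windows", {
  set.seed(30)
  for (rep in 1:40) {
    H <- rand_window(sample(4:20, 1), sample(3:20, 1))
    spec <- hap_freq_spectrum(H)
    g <- garud_h(spec)
    o <- oracle_garud(H)
    expect_equal(unname(g["H1"]), o$H1, tolerance = 1e-14)
    expect_equal(unname(g["H1"]), o$H1_pairs, tolerance = 1e-14)
    expect_equal(unname(g["H12"]), o$H12, tolerance = 1e-14)
    expect_equal(unname(g["H123"]), o$H123, tolerance = 1e-14)
    expect_equal(unname(g["H2_H1"]), o$H2_H1, tolerance = 1e-14)
    # algebraic identities
    p <- spec$freq
    p2 <- if (length(p) > 1) p[2] else 0
    expect_equal(unname(g["H12"]), unname(g["H1"]) + 2 * p[1] * p2)
    expect_true(g["H1"] <= g["H12"] && g["H12"] <= g["H123"] &&
                  g["H123"] <= 1 + 1e-12)
  }
})

test_that("H1X is the keyed frequency cross-product", {
  A <- hap_freq_spectrum(cbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L)))
  B <- hap_freq_spectrum(cbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 1L)))
  # A = {00: .5, 11: .5}, B = {00: .5, 01: .5} -> shared 00 only
  expect_equal(h1x(A, B), 0.25)
  expect_equal(h1x(A, A), unname(garud_h(A)["H1"]))
  expect_equal(h1x(A, B), h1x(B, A))
  mono_a <- hap_freq_spectrum(matrix(0L, 3, 4))
  mono_b <- hap_freq_spectrum(matrix(0L, 3, 6))
  expect_equal(h1x(mono_a, mono_b), 1)
  disjoint <- hap_freq_spectrum(matrix(1L, 3, 4))
  expect_equal(h1x(mono_a, disjoint), 0)
  # Cauchy-Schwarz bound on random cohorts
  set.seed(31)
  for (rep in 1:10) {
    HA <- rand_window(10, 6); HB <- rand_window(12, 6)
    sa <- hap_freq_spectrum(HA); sb <- hap_freq_spectrum(HB)
    expect_lte(h1x(sa, sb),
               sqrt(garud_h(sa)["H1"] * garud_h(sb)["H1"]) + 1e-12)
  }
  wrong <- hap_freq_spectrum(rand_window(8, 9))
  expect_error(h1x(sa, wrong), "site sets differ")
})

test_that("top-quantile thresholding interpolates as stated", {
  expect_equal(top_quantile_threshold(1:100, 0.01), 99.01)
  expect_equal(top_quantile_threshold(rep(3.2, 50), 0.01), 3.2)
  expect_equal(top_quantile_threshold(c(5, 1, 9, 4), 0), 9)
})

test_that("peak calling groups runs, honours gaps, and respects contigs", {
  w <- data.frame(contig = "c", snp_first = seq(1, 41, 10),
                  snp_last = seq(10, 50, 10), n_snps = 10,
                  bp_start = seq(1, 41, 10) * 100,
                  bp_end = seq(10, 50, 10) * 100)
  tr <- scan_track(w, c(0.1, 0.6, 0.7, 0.2, 0.55), "H12")
  pk <- call_peaks(tr, 0.5)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$win_first, c(2L, 5L))
  expect_equal(pk$win_last, c(3L, 5L))
  expect_equal(pk$summit_win[1], 3L)
  pk1 <- call_peaks(tr, 0.5, max_gap_windows = 1)
  expect_equal(nrow(pk1), 1L)
  expect_equal(c(pk1$win_first, pk1$win_last), c(2L, 5L))
  # same values split across two contigs never merge
  w2 <- w; w2$contig <- c("c1", "c1", "c2", "c2", "c2")
  tr2 <- scan_track(w2, c(0.6, 0.7, 0.8, 0.2, 0.55), "H12")
  pk2 <- call_peaks(tr2, 0.5, max_gap_windows = 5)
  expect_equal(pk2$contig, c("c1", "c2"))
  # idempotence: peaks of the track reduced to its peak windows reproduce
  keep <- tr$value >= 0.5
  tr_red <- scan_track(w[keep, ], tr$value[keep], "H12")
  pk_red <- call_peaks(tr_red, 0.5)
  expect_equal(nrow(pk_red), nrow(pk))
  expect_equal(pk_red$bp_start, pk$bp_start)
  expect_equal(pk_red$bp_end, pk$bp_end)
  expect_equal(pk_red$summit_value, pk$summit_value)
})

test_that("delta-H12 subtracts tracks with the documented sign convention", {
  w <- data.frame(contig = "c", snp_first = c(1, 11), snp_last = c(10, 20),
                  n_snps = 10, bp_start = c(1, 11), bp_end = c(10, 20))
  pre <- scan_track(w, c(0.2, 0.3), "H12")
  post <- scan_track(w, c(0.5, 0.1), "H12")
  d <- delta_h12(pre, post)
  expect_equal(d$value, c(0.3, -0.2))
  expect_equal(delta_h12(post, pre)$value, -d$value)
  expect_equal(delta_h12(pre, post, convention = "pre_minus_post")$value,
               -d$value)
  expect_equal(delta_h12(pre, pre)$value, c(0, 0))
  w_other <- w; w_other$snp_first <- c(2, 12)
  expect_error(delta_h12(pre, scan_track(w_other, c(1, 1), "H12")),
               "different window")
})

test_that("delta peak threshold is 3x the (P98 - median) spread", {
  set.seed(32)
  v <- rnorm(500)
  res <- delta_peak_threshold(v)
  thr <- 3 * (quantile(v, 0.98, type = 7) - median(v))
  expect_equal(res$threshold, unname(thr))
  # two-pass brute force over a random track
  expect_equal(res$peak_pos, unname(v - median(v) > thr))
  expect_equal(res$peak_neg, unname(v - median(v) < -thr))
  all_eq <- delta_peak_threshold(rep(0.3, 10))
  expect_equal(all_eq$threshold, 0)
  expect_false(any(all_eq$peak_pos))
})

test_that("the fast windowed H12 path equals the direct scan", {
  set.seed(33)
  hap <- make_hap(rand_window(40, 200))
  w <- make_windows(hap, 25)
  ids_pre <- hap$samples[1:10]
  ids_post <- hap$samples[11:20]
  res <- delta_permutation_test(hap, ids_pre, ids_post, w, n_perm = 19,
                                seed = 1)
  expect_equal(res$h12_pre,
               h12_scan(subset_samples(hap, ids_pre), w)$value)
  expect_equal(res$h12_post,
               h12_scan(subset_samples(hap, ids_post), w)$value)
  expect_equal(res$delta, res$h12_post - res$h12_pre)
})

test_that("the permutation test is seeded, bounded, and flags real shifts", {
  pos <- seq(1000, by = 1000, length.out = 1000)
  d <- sim_design(n_per_cell = 30, regions = "East", arms = "PBO",
                  n_sites = c("2RL" = 1000), d = 0, sigma_h = 0,
                  seed = 41, positions = list("2RL" = pos),
                  sweeps = list(sweep_config(
                    "2RL", 500500, 125500,
                    freq = list("baseline:PBO" = 0.3, "round5:PBO" = 0.7),
                    name = "sw")))
  sim <- simulate_cohorts(d)
  hap <- sim$sets[["2RL"]]
  w <- make_windows(hap, 50)
  pre <- sim$frame$sample_id[sim$frame$round == "baseline"]
  post <- sim$frame$sample_id[sim$frame$round == "round5"]
  r1 <- delta_permutation_test(hap, pre, post, w, n_perm = 199, seed = 5)
  r2 <- delta_permutation_test(hap, pre, post, w, n_perm = 199, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(all(r1$p_value >= 1 / 200 & r1$p_value <= 1))
  locus <- r1$bp_start >= 400000 & r1$bp_end <= 610000
  expect_true(any(r1$delta[locus] > 0 & r1$p_value[locus] == 1 / 200))
  expect_true(all(r1$significant == (r1$p_value < 0.01)))
  expect_error(delta_permutation_test(hap, pre, post, w, n_perm = 0),
               "n_perm")
})
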