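test_that("noise-free simulation reproduces the expected-signal model exactly", {
  cal <- signal_calibration()
  g <- diploid_genome(2L, 100L)
  sim <- simulate_sample(g, sample_model(mode = "normal"), cal,
                         noise_spec(log_signal_sd = 1e-12), seed = 1)
  expect_equal(sim$signals$signal, rep(2, 200), tolerance = 1e-9)

  ## contaminated sample: every signal at beta * (2 alpha + (1-alpha) S0(c))
  g2 <- implant_cnvs(diploid_genome(1L, 200L), n = 2L, size_range = c(20L, 30L),
                     cn_values = c(0L, 4L), seed = 2)
  m <- sample_model(alpha = 0.48, beta = 1, mode = "tumor")
  sim2 <- simulate_sample(g2, m, cal, noise_spec(log_signal_sd = 1e-12), seed = 3)
  expect_equal(sim2$signals$signal, expected_signal(sim2$truth$cn, m, cal),
               tolerance = 1e-9)
  ## the contamination confound: CN 0 at alpha = 0.48 sits near the CN 1
  ## anchor, CN 4 near the CN 3 anchor
  cn0 <- sim2$signals$signal[sim2$truth$cn == 0]
  cn4 <- sim2$signals$signal[sim2$truth$cn == 4]
  if (length(cn0)) expect_lt(abs(mean(cn0) - 1.14), 0.05)
  if (length(cn4)) expect_lt(abs(mean(cn4) - 2.72), 0.05)
})

test_that("male X probes outside the pseudoautosomal region are single copy", {
  par <- data.frame(chrom = "chrX", start = 1, end = 3e6)
  g <- diploid_genome(1L, 500L, include_x = TRUE, is_male = TRUE)
  g$pseudoautosomal <- par
  sim <- simulate_sample(g, sample_model(mode = "normal"), seed = 4)
  x <- sim$truth[sim$truth$chrom == "chrX", ]
  expect_true(all(x$cn[x$pos > 3e6] == 1L))
  expect_true(all(x$cn[x$pos <= 3e6] == 2L))
  expect_true(all(sim$truth$cn[sim$truth$chrom == "chr1"] == 2L))
})

test_that("mixing is linear in signal with identity limits", {
  g <- aneuploid_genome(2L, 500L, seed = 5)
  cancer <- simulate_sample(g, sample_model(mode = "cell_line"), seed = 6)
  normal <- simulate_sample(diploid_genome(2L, 500L), sample_model(mode = "normal"),
                            seed = 7)
  expect_equal(mix_samples(cancer$signals, normal$signals, 0)$signal,
               cancer$signals$signal)
  expect_equal(mix_samples(cancer$signals, normal$signals, 1)$signal,
               normal$signals$signal)
  mx <- mix_samples(cancer$signals, normal$signals, 0.48)
  expect_equal(mx$signal, 0.52 * cancer$signals$signal + 0.48 * normal$signals$signal)
  expect_equal(attr(mx, "true_alpha"), 0.48)
  ## a CN = 4 level (3.41) mixed with diploid 2.0 lands at ~2.73, i.e. CN 3
  expect_equal(0.52 * 3.41 + 0.48 * 2, 2.7332, tolerance = 1e-12)
  expect_error(mix_samples(cancer$signals[-1, ], normal$signals, 0.5), "differ")
})

test_that("call evaluation counts spurious and missed alterations as specified", {
  truth <- data.frame(chrom = "chr1", pos = 1:3000, cn = 2L)
  ## 100 true alterations of 10 probes each
  for (i in 0:99) truth$cn[(i * 30 + 1):(i * 30 + 10)] <- 1L
  calls <- truth
  ev <- evaluate_calls(truth, calls)
  expect_equal(ev$false_alteration_rate, 0)
  expect_equal(ev$concordance, 100)
  ## one extra spurious 10-probe segment: (1+0)/(100+1) ~= 0.99%
  calls2 <- calls
  calls2$cn[2985:2994] <- 3L
  ev2 <- evaluate_calls(truth, calls2)
  expect_equal(ev2$false_alteration_rate, 100 / 101, tolerance = 1e-9)
  ## everything shifted by one copy: zero concordance
  calls3 <- truth
  calls3$cn <- truth$cn + 1L
  ev3 <- evaluate_calls(truth, calls3, baseline_cn = 2L)
  expect_equal(ev3$concordance, 0)
  ## a missed 10-probe alteration counts against the rate
  calls4 <- truth
  calls4$cn[1:10] <- 2L
  ev4 <- evaluate_calls(truth, calls4)
  expect_equal(ev4$n_missed, 1L)
  expect_equal(ev4$false_alteration_rate, 1)
})

test_that("simulated panels hit the platform-typical variance statistics", {
  pan <- simulate_reference_panel(n_samples = 48L, n_snps = 2000L, seed = 77L)
  fit <- suppressWarnings(fit_reference_panel(pan$probes, pan$genotypes, pan$samples))
  ps <- fit$probe_sets[fit$probe_sets$excluded == FALSE, ]
  expect_gt(median(ps$panel_var), 0.03)
  expect_lt(median(ps$panel_var), 0.05)
  ## inverse-variance weighting buys roughly a twofold variance reduction
  ratio <- median((ps$s_i2 / ps$n_quartets) / ps$sigma_i2)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("trio children inherit only parental copy-number events", {
  set.seed(31)
  tr <- simulate_trio(base = diploid_genome(2L, 1500L), n_cnvs = 3L, seed = 31)
  child_alt <- tr$child$truth[tr$child$truth$cn != 2L, ]
  parent_alt <- rbind(tr$father$truth[tr$father$truth$cn != 2L, ],
                      tr$mother$truth[tr$mother$truth$cn != 2L, ])
  if (nrow(child_alt)) {
    key <- paste(child_alt$chrom, child_alt$pos, child_alt$cn)
    pkey <- paste(parent_alt$chrom, parent_alt$pos, parent_alt$cn)
    expect_true(all(key %in% pkey))
  }
  expect_true(nrow(tr$inherited) <= 6L)
})

test_that("panel trios have Mendelian-consistent genotypes", {
  pan <- simulate_reference_panel(n_samples = 12L, n_snps = 300L, n_trios = 2L,
                                  seed = 13L)
  g <- pan$genotypes
  wide <- reshape(g, idvar = "snp_id", timevar = "sample_id", direction = "wide")
  auto <- pan$truth$snp_id[pan$truth$chrom != "chrX"]
  for (t in 0:1) {
    f <- wide[[paste0("genotype.S", sprintf("%03d", 3 * t + 1))]]
    m <- wide[[paste0("genotype.S", sprintf("%03d", 3 * t + 2))]]
    k <- wide[[paste0("genotype.S", sprintf("%03d", 3 * t + 3))]]
    ok <- wide$snp_id %in% auto & f != "NC" & m != "NC" & k != "NC"
    ## a child cannot be homozygous for an allele absent in a parent
    expect_false(any(k[ok] == "AA" & (f[ok] == "BB" | m[ok] == "BB")))
    expect_false(any(k[ok] == "BB" & (f[ok] == "AA" | m[ok] == "AA")))
  }
})
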