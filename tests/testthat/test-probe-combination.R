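make_records <- function(di, size = 200L, subarray = "Nsp", mm = 100) {
  n <- length(di)
  data.frame(snp_id = sprintf("rs%03d", rep(seq_len(ceiling(n / 2)), each = 2L))[1:n],
             quartet = 1L, allele = rep(c("A", "B"), length.out = n),
             pm = mm + di, mm = mm,
             amplicon_size = rep_len(size, n), subarray = subarray)
}

test_that("amplicon-size normalization divides by the size-group mean", {
  ## one group, identical dI: everything normalizes to 1
  r <- make_records(rep(500, 10))
  out <- size_normalize(r, min_group = 1L)
  expect_equal(out$norm, rep(1, 10))

  ## two groups: a dI of 600 in a group with mean 400 gives 1.5
  di200 <- c(rep(400, 8), 200, 600)  # mean exactly 400
  r2 <- rbind(make_records(di200, size = 200L),
              make_records(rep(800, 10), size = 500L))
  out2 <- size_normalize(r2, min_group = 1L)
  expect_equal(out2[out2$amplicon_size == 200][["norm"]], di200 / 400)
  expect_equal(max(out2[out2$amplicon_size == 200][["norm"]]), 1.5)
  expect_equal(out2[out2$amplicon_size == 500][["norm"]], rep(1, 10))

  ## negative dI passes through as a negative normalized value
  r3 <- make_records(c(rep(400, 9), -100))
  out3 <- size_normalize(r3, min_group = 1L)
  expect_equal(min(out3$norm), -100 / mean(c(rep(400, 9), -100)))
  expect_true(any(out3$norm < 0))

  ## a group whose mean dI is non-positive is unusable
  r4 <- rbind(make_records(rep(400, 20), size = 200L),
              make_records(rep(-50, 20), size = 900L))
  expect_warning(out4 <- size_normalize(r4, min_group = 1L), "non-positive")
  expect_true(all(out4$amplicon_size == 200))
  expect_equal(nrow(attr(out4, "unusable_sizes")), 1L)

  expect_error(size_normalize(make_records(500)[0, ]), "no quartet records")
})

test_that("sparse size groups fall back to the nearest well-populated size", {
  r <- rbind(make_records(rep(100, 40), size = 200L),
             make_records(rep(900, 40), size = 800L),
             make_records(rep(500, 2), size = 300L))  # sparse, nearest is 200
  out <- size_normalize(r, min_group = 20L)
  ## the sparse probes are normalized by the pooled mean of sizes {200, 300}
  pooled_mean <- mean(c(rep(100, 40), rep(500, 2)))
  expect_equal(out[out$amplicon_size == 300][["norm"]], rep(500 / pooled_mean, 2))
  expect_equal(out[out$amplicon_size == 800][["norm"]], rep(1, 40))
})

test_that("closed-form allele parameters match hand-derived cases", {
  p <- estimate_allele_params(c(24, 0, 24), c(2, 0, 0), c(0, 0, 2))
  expect_equal(c(p$k_a, p$k_b), c(1, 1))
  ## doubling the signal halves the parameters
  p2 <- estimate_allele_params(c(24, 0, 24), c(4, 0, 0), c(0, 0, 4))
  expect_equal(c(p2$k_a, p2$k_b), c(0.5, 0.5))
  p3 <- estimate_allele_params(c(10, 20, 10), c(2.2, 1.0, 0.1), c(0.1, 1.2, 2.4))
  expect_equal(c(p3$k_a, p3$k_b), c(0.9078, 0.8328), tolerance = 1e-4)
})

test_that("closed-form allele parameters agree with an independent grid search", {
  set.seed(11)
  for (i in 1:30) {
    d <- random_allele_design()
    p <- estimate_allele_params(d$n_geno, d$x_med, d$y_med)
    g <- grid_min_allele(d$n_geno, d$x_med, d$y_med)
    expect_lt(abs(p$k_a - g$k_a), 1e-3)
    expect_lt(abs(p$k_b - g$k_b), 1e-3)
    ## the closed form is at least as good as every grid point
    e_closed <- allele_param_objective(p$k_a, p$k_b, d$n_geno, d$x_med, d$y_med)
    expect_lte(e_closed, g$e + 1e-9)
  }
})

test_that("degenerate and monomorphic designs are excluded with reasons", {
  mono <- estimate_allele_params(c(48, 0, 0), c(2.1, 0, 0), c(0.1, 0, 0))
  expect_true(mono$excluded)
  expect_equal(mono$reason, "monomorphic")
  ## two genotype classes with proportional medians: singular normal equations
  dg <- estimate_allele_params(c(24, 24, 0), c(1, 2, 0), c(1, 2, 0))
  expect_true(dg$excluded)
  expect_equal(dg$reason, "degenerate design")
})

test_that("inverse-variance weights and combined variance follow the formulas", {
  w <- fit_quartet_weights(c(1, 1))
  expect_equal(w$weights, c(0.5, 0.5))
  expect_equal(w$sigma_i2, 0.5)

  w2 <- fit_quartet_weights(c(1, 3))
  expect_equal(w2$weights, c(0.75, 0.25))
  expect_equal(w2$sigma_i2, 0.75)
  expect_equal(w2$s_i2, 2)

  w3 <- fit_quartet_weights(0.2)
  expect_equal(w3$weights, 1)
  expect_equal(w3$sigma_i2, 0.2)

  expect_warning(w4 <- fit_quartet_weights(c(0, 1)), "floored")
  expect_true(all(w4$sigma_q2 > 0))

  ## matrix input: variances computed across panel samples
  set.seed(1)
  m <- cbind(rnorm(200, 2, 1), rnorm(200, 2, 2))
  w5 <- fit_quartet_weights(m)
  expect_equal(w5$sigma_q2, apply(m, 2, var))
  expect_gt(w5$weights[1], w5$weights[2])
})

test_that("quartet combination reproduces the weighted-sum design points", {
  ints <- data.frame(quartet = rep(1:2, each = 2), allele = rep(c("A", "B"), 2),
                     norm = 1)
  expect_equal(combine_to_snp_signal(ints, 1, 1, c(`1` = 0.5, `2` = 0.5)), 2)
  ## weights {0.75, 0.25} with S_q = {2, 4}
  ints2 <- data.frame(quartet = rep(1:2, each = 2), allele = rep(c("A", "B"), 2),
                      norm = c(1, 1, 2, 2))
  expect_equal(combine_to_snp_signal(ints2, 1, 1, c(`1` = 0.75, `2` = 0.25)), 2.5)
  ## missing quartet: remaining weights renormalized
  expect_warning(
    s <- combine_to_snp_signal(ints2[ints2$quartet == 1, ], 1, 1,
                               c(`1` = 0.75, `2` = 0.25)),
    "renormalized")
  expect_equal(s, 2)
})

test_that("panel-variance QC excludes noisy probe sets and keeps typical ones", {
  ps <- data.frame(snp_id = c("a", "b", "c"),
                   panel_var = c(0.30, 0.0376, 0.1),
                   excluded = c(FALSE, FALSE, TRUE),
                   reason = c(NA, NA, "monomorphic"))
  out <- qc_filter(ps)
  expect_equal(out$excluded, c(TRUE, FALSE, TRUE))
  expect_equal(out$reason[1], "high panel variance")
  expect_equal(out$reason[3], "monomorphic")  # earlier reason kept
})

test_that("a fitted simulated panel recovers diploid signal, variances, and allelic bias", {
  pan <- simulate_reference_panel(n_samples = 48L, n_snps = 600L, seed = 42L)
  fit <- suppressWarnings(
    fit_reference_panel(pan$probes, pan$genotypes, pan$samples))
  ps <- fit$probe_sets[fit$probe_sets$excluded == FALSE &
                         is.na(fit$probe_sets$merged_into), ]

  ## weighted combination never beats nothing: sigma_i2 <= s_i2 and
  ## <= the smallest quartet variance
  expect_true(all(ps$sigma_i2 <= ps$s_i2 + 1e-12))
  qmin <- tapply(fit$quartets$sigma_q2, fit$quartets$snp_id, min)
  expect_true(all(ps$sigma_i2 <= qmin[ps$snp_id] + 1e-12))
  ## weights sum to 1 per SNP
  wsum <- tapply(fit$quartets$w, fit$quartets$snp_id, sum)
  expect_true(all(abs(wsum - 1) < 1e-9))

  ## a held-back diploid sample combines to a mean signal near 2
  s <- suppressWarnings(
    snp_signals(fit, pan$probes[pan$probes$sample_id == "S002", ]))
  expect_gt(mean(s$signal), 1.95)
  expect_lt(mean(s$signal), 2.05)

  ## recovered allelic bias tracks the generating bias
  m <- merge(ps, pan$truth, by = "snp_id")
  bias_true <- median(pmax(m$gain_a / m$gain_b, m$gain_b / m$gain_a))
  bias_fit <- median(pmax(m$k_a / m$k_b, m$k_b / m$k_a))
  expect_lt(abs(bias_fit / bias_true - 1), 0.05)

  ## multi-SNP amplicons are reported once, on the lowest-position SNP
  merged <- fit$probe_sets[!is.na(fit$probe_sets$merged_into), ]
  expect_gt(nrow(merged), 0)
  expect_false(any(merged$snp_id %in% s$snp_id))
  for (i in seq_len(min(5L, nrow(merged)))) {
    tgt <- fit$probe_sets[fit$probe_sets$snp_id == merged$merged_into[i], ]
    expect_lte(tgt$pos, merged$pos[i])
    expect_equal(tgt$amplicon_id, merged$amplicon_id[i])
  }
})
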