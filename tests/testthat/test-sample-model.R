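test_that("window smoothing takes the geometric mean with truncated edges", {
  ## constant track is unchanged
  s <- signal_df(rep(2, 300))
  sm <- smooth_signal(s)
  expect_equal(sm$smoothed, rep(2, 300))

  ## alternating 1/4: interior windows hold equal counts of each,
  ## so the smoothed value is the geometric mean 2
  s2 <- signal_df(rep(c(1, 4), 150))
  sm2 <- smooth_signal(s2, window = 101L)
  interior <- 51:250
  expect_equal(sm2$smoothed[interior],
               exp((50 * log(1) + 50 * log(4) + log(rep(c(1, 4), 150))[interior]) / 101),
               tolerance = 1e-12)

  ## short chromosome: every window is truncated; check against direct sums
  set.seed(5)
  x <- runif(10, 0.5, 4)
  sm3 <- smooth_signal(signal_df(x), window = 101L)
  direct <- vapply(1:10, function(i) exp(mean(log(x[max(1, i - 50):min(10, i + 50)]))),
                   numeric(1))
  expect_equal(sm3$smoothed, direct)

  ## windows never span chromosomes
  s4 <- rbind(signal_df(rep(1, 120), "chr1"), signal_df(rep(4, 120), "chr2"))
  sm4 <- smooth_signal(s4)
  expect_equal(sm4$smoothed[1], exp(mean(log(rep(1, 51)))))
  expect_equal(sm4$smoothed[121], exp(mean(log(rep(4, 51)))))

  expect_warning(smooth_signal(signal_df(2, "chrTiny")), "fewer than 2")
})

test_that("histogram peak detection finds modes and merges plateaus", {
  ## unimodal diploid sample: a single peak near 2
  set.seed(3)
  sm <- smooth_signal(signal_df(2 * exp(rnorm(5000, 0, 0.097))))
  pk <- find_signal_peaks(sm)
  main <- pk[pk$height == max(pk$height), ]
  expect_equal(nrow(main), 1L)
  expect_lt(abs(main$position - 2), 0.1)

  ## two equal-height adjacent bins form one mode, not two
  tv <- c(rep(1.02, 10), rep(1.12, 10), rep(1.55, 3))
  pk2 <- find_signal_peaks(list2DF(list(smoothed = tv, snp_id = seq_along(tv))))
  expect_equal(sum(pk2$height > 0.2), 1L)  # the plateau is one peak
  ## interpolated position stays within the plateau's two bins
  expect_gte(pk2$position[which.max(pk2$height)], 1.0)
  expect_lte(pk2$position[which.max(pk2$height)], 1.2)

  expect_error(find_signal_peaks(data.frame(smoothed = numeric(0))), "empty")
})

test_that("a seven-mode track yields seven peaks at the mode positions", {
  ## masses placed at the seven levels reported for a 7-peak ovarian
  ## cell-line histogram, with heights in rough proportion
  lv <- c(0.32, 1.02, 1.72, 2.42, 3.02, 3.62, 4.32)
  ht <- c(200, 5300, 25800, 11200, 2800, 500, 30)
  tv <- rep(lv, ht)
  pk <- find_signal_peaks(data.frame(smoothed = tv, snp_id = seq_along(tv)),
                          min_height = 2e-4)
  expect_equal(nrow(pk), 7L)
  expect_true(all(abs(pk$position - (lv + 0.03)) < 0.06))
  expect_false(any(pk$flagged))  # even the 0.065% peak clears the floor

  ## a peak below the height floor is kept but flagged
  tv2 <- c(tv, rep(5.02, 5))  # 5 / 45835 ~= 0.011% of probes
  pk2 <- find_signal_peaks(data.frame(smoothed = tv2, snp_id = seq_along(tv2)),
                           min_height = 2e-4)
  expect_equal(nrow(pk2), 8L)
  expect_true(pk2$flagged[8])
})

test_that("peak anchoring rules fire in order and are idempotent", {
  ## rule 1: single maximum is diploid
  p1 <- anchor_peaks(make_peaks(2.05, 1))
  expect_equal(p1$anchored_cn, 2L)

  ## rule 2: low call rate marks the first peak as homozygous deletion
  p2 <- anchor_peaks(make_peaks(c(0.35, 2.05), c(0.091, 0.5),
                                call_rate = c(36.7, 82), het = c(9.1, 14.2)))
  expect_equal(p2$anchored_cn[1], 0L)

  ## rule 3: low heterozygosity marks the first peak as single copy
  p3 <- anchor_peaks(make_peaks(c(1.05, 2.05), c(0.053, 0.258),
                                call_rate = c(90.2, 88.1), het = c(1.2, 8)))
  expect_equal(p3$anchored_cn[1], 1L)

  ## rule 4: first peak CN 0 and low-het second peak -> second is CN 1
  p4 <- anchor_peaks(make_peaks(c(0.35, 1.05, 2.05), c(0.09, 0.05, 0.26),
                                call_rate = c(36, 90, 88), het = c(9, 1.2, 8)))
  expect_equal(p4$anchored_cn[1:2], c(0L, 1L))

  ## rule 5: dominant peak (>= 2x the runner-up) is diploid
  p5 <- anchor_peaks(make_peaks(c(1.75, 2.45), c(0.40, 0.15)))
  expect_equal(p5$anchored_cn, c(2L, NA_integer_))

  ## conflicting assignment keeps the earlier rule's anchor, with a warning
  expect_warning(
    p6 <- anchor_peaks(make_peaks(c(0.35, 2.05), c(0.40, 0.15),
                                  call_rate = c(36, 85), het = c(9, 20))),
    "already")
  expect_equal(p6$anchored_cn[1], 0L)

  ## agilent mode: genotype rules disabled, height rule still active
  p7 <- anchor_peaks(make_peaks(c(1.05, 2.05), c(0.10, 0.45),
                                call_rate = c(90.2, 88), het = c(1.2, 8)),
                     mode = "agilent")
  expect_equal(p7$anchored_cn, c(NA_integer_, 2L))

  ## idempotence
  expect_identical(anchor_peaks(p4), p4)
  expect_identical(suppressWarnings(anchor_peaks(p5)), p5)
})

test_that("grid fit recovers contamination and genome-size factor from exact peaks", {
  cal <- signal_calibration()
  ## peaks placed exactly at beta * S(c) for c in 1..3 at (0.30, 1.10)
  pos <- 1.1 * (2 * 0.3 + 0.7 * expected_signal_s0(1:3, cal))
  f <- fit_alpha_beta(make_peaks(pos, c(0.3, 0.4, 0.3)), cal, mode = "tumor")
  expect_lte(abs(f$alpha - 0.30), 0.01)
  expect_lte(abs(f$beta - 1.10), 0.005)
  expect_equal(f$assigned_cn, 1:3)

  ## single anchored peak in normal mode
  pk <- make_peaks(2.0, 1)
  pk$anchored_cn <- 2L
  fn <- fit_alpha_beta(pk, cal, mode = "normal")
  expect_equal(c(fn$alpha, fn$beta), c(0, 1))

  ## peaks exactly at S0(c): the zero-contamination limit
  f0 <- fit_alpha_beta(make_peaks(expected_signal_s0(c(1, 2, 4), cal),
                                  c(0.2, 0.5, 0.3)), cal, mode = "tumor")
  expect_lte(f0$alpha, 0.01)
  expect_lte(abs(f0$beta - 1), 0.005)
})

test_that("the returned grid point minimizes E1 over a full re-scan", {
  cal <- signal_calibration()
  pos <- 1.04 * (2 * 0.22 + 0.78 * expected_signal_s0(c(1, 2, 3), cal)) *
    exp(c(0.01, -0.015, 0.02))  # perturbed peaks
  pk <- make_peaks(pos, c(0.25, 0.5, 0.25))
  f <- fit_alpha_beta(pk, cal, mode = "tumor", alpha_step = 0.05, beta_step = 0.05)
  e1_at <- function(a, b) {
    lm <- log(pmax(2 * a + (1 - a) * expected_signal_s0(0:70, cal), 0.01))
    sum(pk$height * vapply(log(pk$position) - log(b),
                           function(t) min((t - lm)^2), numeric(1)))
  }
  for (a in seq(0, 0.99, 0.05)) for (b in seq(0.5, 2, 0.05))
    expect_gte(e1_at(a, b) + 1e-12, f$e1)
})
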