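# Independent oracles used by the unit and acceptance tests.

# Exhaustive path decoding: minimizes the same cost as the DP
# (sum of squared log-residuals / (2 sigma^2) plus break_penalty per state
# change) by enumerating every path.  Only usable for small state counts
# and probe counts.
enum_decode <- function(signal, model, cal, config) {
  ns <- config$max_cn + 1L
  n <- length(signal)
  log_s <- log(pmax(signal, config$eps))
  log_mu <- log(pmax(expected_signal(0:config$max_cn, model, cal), config$eps))
  emis <- outer(log_mu, log_s, function(m, s) (s - m)^2) / (2 * model$sigma2)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(ns)), n)))
  cost <- numeric(nrow(paths))
  for (t in seq_len(n)) cost <- cost + emis[cbind(paths[, t], t)]
  if (n > 1L) for (t in 2:n)
    cost <- cost + config$break_penalty * (paths[, t] != paths[, t - 1L])
  unname(paths[which.min(cost), ] - 1L)
}

# Coarse-to-fine grid search minimizing the allele-parameter objective; an
# independent check of the closed-form minimizer.
grid_min_allele <- function(n_geno, x_med, y_med, lo = 0.1, hi = 5,
                            steps = 200L, zooms = 3L) {
  rng_a <- rng_b <- c(lo, hi)
  for (z in seq_len(zooms)) {
    ka <- seq(rng_a[1L], rng_a[2L], length.out = steps)
    kb <- seq(rng_b[1L], rng_b[2L], length.out = steps)
    e <- outer(ka, kb, function(a, b) {
      n_geno[1L] * (a * x_med[1L] + b * y_med[1L] - 2)^2 +
        n_geno[2L] * (a * x_med[2L] + b * y_med[2L] - 2)^2 +
        n_geno[3L] * (a * x_med[3L] + b * y_med[3L] - 2)^2
    })
    ij <- which(e == min(e), arr.ind = TRUE)[1L, ]
    sa <- diff(rng_a) / (steps - 1L); sb <- diff(rng_b) / (steps - 1L)
    best <- c(ka[ij[1L]], kb[ij[2L]])
    rng_a <- best[1L] + c(-2, 2) * sa
    rng_b <- best[2L] + c(-2, 2) * sb
  }
  list(k_a = best[1L], k_b = best[2L], e = min(e))
}

# random genotype-median design for allele-parameter tests
random_allele_design <- function() {
  n <- as.vector(stats::rmultinom(1L, 48L, c(0.3, 0.4, 0.3)))
  list(n_geno = n,
       x_med = c(stats::runif(1, 1.5, 3), stats::runif(1, 0.8, 1.5),
                 stats::runif(1, 0, 0.3)),
       y_med = c(stats::runif(1, 0, 0.3), stats::runif(1, 0.8, 1.5),
                 stats::runif(1, 1.5, 3)))
}

# build a peak_set directly (bypassing the histogram) for anchoring tests
make_peaks <- function(position, height, call_rate = NA_real_,
                       het = NA_real_) {
  ps <- data.frame(position = position, bin_index = floor(position / 0.1),
                   height = height,
                   call_rate = rep_len(call_rate, length(position)),
                   heterozygosity = rep_len(het, length(position)),
                   flagged = FALSE, anchored_cn = NA_integer_)
  class(ps) <- c("peak_set", "data.frame")
  ps
}

# one-chromosome signal data.frame from a vector of signals
signal_df <- function(signal, chrom = "chr1") {
  data.frame(snp_id = sprintf("s%05d", seq_along(signal)), chrom = chrom,
             pos = seq_along(signal) * 1000L, signal = signal)
}
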