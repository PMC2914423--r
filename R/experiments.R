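## Benchmark experiments run entirely on simulated data: the false-call
## experiment (germline-CNV genomes in normal mode) and the contamination
## robustness experiment (tumor-normal admixture series).  Both are used by
## the test suite and by scripts/acceptance.R.

#' False-alteration-rate experiment on simulated normal genomes
#'
#' Simulates `n_genomes` diploid genomes each carrying `n_cnvs` implanted
#' germline events, calls them in normal mode with default parameters, and
#' measures the combined rate of spurious and missed alterations of at
#' least `min_probes` probes over all genomes.
#'
#' @param n_genomes number of replicate genomes.
#' @param n_chrom,snps_per_chrom genome dimensions.
#' @param n_cnvs implanted events per genome.
#' @param size_range event length range (probes).
#' @param cn_values event copy numbers.
#' @param noise a [noise_spec()].
#' @param min_probes minimum alteration length scored.
#' @param seed RNG seed (per-genome seeds are derived from it).
#' @param config a [run_config()] (mode is forced to `normal`).
#' @return list with `rate` (percent), totals, and a per-genome data.frame.
#' @export
experiment_false_alteration_rate <- function(n_genomes = 20L, n_chrom = 4L,
                                             snps_per_chrom = 5000L,
                                             n_cnvs = 10L,
                                             size_range = c(7L, 50L),
                                             cn_values = c(1L, 3L),
                                             noise = noise_spec(),
                                             min_probes = 7L, seed = 1L,
                                             config = run_config(mode = "normal")) {
  config$mode <- "normal"
  per <- vector("list", n_genomes)
  for (r in seq_len(n_genomes)) {
    s <- (seed * 1000L + r) %% .Machine$integer.max
    g <- implant_cnvs(diploid_genome(n_chrom, snps_per_chrom),
                      n = n_cnvs, size_range = size_range,
                      cn_values = cn_values, seed = s)
    sim <- simulate_sample(g, sample_model(mode = "normal"), noise = noise,
                           seed = s + 1L)
    seg <- run_call_pipeline(sim$signals, config,
                             annotations = sim$annotations)
    ev <- evaluate_calls(sim$truth, seg$probes, min_probes = min_probes)
    per[[r]] <- data.frame(genome = r, n_true = ev$n_true,
                           n_spurious = ev$n_spurious, n_missed = ev$n_missed)
  }
  per <- do.call(rbind, per)
  denom <- sum(per$n_true) + sum(per$n_spurious)
  list(rate = if (denom > 0) 100 * (sum(per$n_spurious) + sum(per$n_missed)) / denom else 0,
       n_true = sum(per$n_true), n_spurious = sum(per$n_spurious),
       n_missed = sum(per$n_missed),
       n_probes = n_genomes * n_chrom * snps_per_chrom, per_genome = per)
}

#' Contamination-robustness experiment on simulated admixtures
#'
#' Simulates one aneuploid cancer genome (copy numbers 0..6, genome-size
#' factor drawn from `beta_range`) and a matched diploid genome, mixes them
#' at each contamination level, calls pure and mixed samples with the full
#' pipeline, and reports per-level probe concordance against the pure-sample
#' calls plus the contamination-estimate errors.  The mixed samples are
#' called without genotype annotations (genotyping of a mixture is not
#' informative for the anchoring rules), so anchoring relies on the
#' dominant-peak rule.
#'
#' @param alphas contamination levels to test.
#' @param n_chrom,snps_per_chrom genome dimensions.
#' @param beta_range range the cancer genome-size factor is drawn from.
#' @param noise a [noise_spec()].
#' @param seed RNG seed.
#' @param config a [run_config()] (mode forced to `cell_line` for the pure
#'   sample and `tumor` for mixtures).
#' @return list with `per_alpha` (data.frame `alpha`, `alpha_hat`,
#'   `beta_hat`, `concordance`), `min_concordance`,
#'   `mean_abs_alpha_error`, and `beta_true`.
#' @export
experiment_contamination_robustness <- function(alphas = seq(0.1, 0.7, by = 0.1),
                                                n_chrom = 4L,
                                                snps_per_chrom = 5000L,
                                                beta_range = c(0.9, 1.2),
                                                noise = noise_spec(),
                                                seed = 1L,
                                                config = run_config()) {
  set.seed(seed)
  beta_c <- stats::runif(1, beta_range[1L], beta_range[2L])
  g <- aneuploid_genome(n_chrom, snps_per_chrom, seed = seed + 1L)
  cancer <- simulate_sample(g, sample_model(alpha = 0, beta = beta_c,
                                            mode = "cell_line"),
                            noise = noise, seed = seed + 2L)
  normal <- simulate_sample(diploid_genome(n_chrom, snps_per_chrom),
                            sample_model(mode = "normal"),
                            noise = noise, seed = seed + 3L)
  cfg_pure <- config; cfg_pure$mode <- "cell_line"
  pure <- run_call_pipeline(cancer$signals, cfg_pure,
                            annotations = cancer$annotations)
  cfg_mix <- config; cfg_mix$mode <- "tumor"
  per <- vector("list", length(alphas))
  for (i in seq_along(alphas)) {
    a <- alphas[i]
    mix <- mix_samples(cancer$signals, normal$signals, a)
    seg <- run_call_pipeline(mix, cfg_mix)
    ev <- evaluate_calls(pure$probes, seg$probes)
    per[[i]] <- data.frame(alpha = a, alpha_hat = seg$model$alpha,
                           beta_hat = seg$model$beta,
                           concordance = ev$concordance)
  }
  per <- do.call(rbind, per)
  list(per_alpha = per, min_concordance = min(per$concordance),
       mean_abs_alpha_error = mean(abs(per$alpha_hat - per$alpha)),
       beta_true = beta_c)
}
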