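## Simulated reference panel: diploid samples with quartet-level PM/MM
## intensities carrying an amplicon-size effect, uneven allele
## amplification, and heterogeneous per-quartet noise, plus a matching
## genotype table.  The probe-combination pipeline fitted on such a panel
## should recover ~2.0 diploid signals and the generating allelic biases.

#' Simulate a reference panel of diploid samples
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium with per-SNP allele
#' frequencies uniform on (0.1, 0.9); optional trios make children inherit
#' one parental allele each.  Quartet-level intensity differences are
#' generated as `dI = amplicon_effect * gain_X * dosage_X * (1 + e_q)` plus
#' a small additive noise floor, where the amplicon effect is specific to
#' (sample, subarray, amplicon size), the allelic gains have a log-normal
#' ratio, and the per-quartet noise sd is drawn from
#' `noise$quartet_sd_range`.  X-chromosome SNPs are hemizygous in males.
#'
#' @param n_samples panel size (default 48).
#' @param n_snps number of SNPs.
#' @param noise a [noise_spec()].
#' @param n_trios number of father/mother/child triples at the start of the
#'   sample list (founders are unrelated).
#' @param seed RNG seed.
#' @param frac_x fraction of SNPs placed on chrX.
#' @param multi_snp_frac fraction of SNPs sharing an amplicon with the next
#'   SNP.
#' @param no_call_rate genotype no-call rate.
#' @return list with `probes` (quartet table, including `amplicon_id`),
#'   `genotypes`, `samples` (`sample_id`, `sex`), and `truth` (per-SNP
#'   allelic gains and frequencies).
#' @export
simulate_reference_panel <- function(n_samples = 48L, n_snps = 250L,
                                     noise = noise_spec(), n_trios = 0L,
                                     seed = 1L, frac_x = 0.1,
                                     multi_snp_frac = 0.05,
                                     no_call_rate = 0.01) {
  stopifnot(3L * n_trios <= n_samples)
  set.seed(seed)
  sample_id <- sprintf("S%03d", seq_len(n_samples))
  sex <- rep(c("male", "female"), length.out = n_samples)
  if (n_trios > 0L) {
    trio_role <- rep(c("father", "mother", "child"), n_trios)
    sex[seq_len(3L * n_trios)] <-
      ifelse(trio_role == "father", "male",
             ifelse(trio_role == "mother", "female",
                    sample(c("male", "female"), 3L * n_trios, replace = TRUE)))
  }
  samples <- data.frame(sample_id = sample_id, sex = sex)

  ## SNP metadata
  n_x <- round(frac_x * n_snps)
  chrom <- c(sample(paste0("chr", 1:4), n_snps - n_x, replace = TRUE),
             rep("chrX", n_x))
  snp <- data.frame(snp_id = sprintf("rs%06d", seq_len(n_snps)),
                    chrom = chrom,
                    pos = sample.int(1e8, n_snps))
  snp <- snp[order(snp$chrom, snp$pos), ]
  snp$freq <- stats::runif(n_snps, 0.1, 0.9)
  z <- stats::rnorm(n_snps, 0, noise$allelic_bias_sd)
  snp$gain_a <- exp(z / 2)
  snp$gain_b <- exp(-z / 2)
  snp$subarray <- sample(c("Nsp", "Sty"), n_snps, replace = TRUE)
  snp$n_quartets <- sample(c(6L, 10L), n_snps, replace = TRUE)
  size_pool <- sort(sample(100:1143, 25L))
  snp$amplicon_size <- sample(size_pool, n_snps, replace = TRUE)
  ## amplicon identity; a fraction of consecutive same-subarray SNPs share one
  snp$amplicon_id <- sprintf("amp%06d", seq_len(n_snps))
  share <- which(stats::runif(n_snps - 1L) < multi_snp_frac &
                   snp$subarray[-n_snps] == snp$subarray[-1L] &
                   snp$chrom[-n_snps] == snp$chrom[-1L])
  share <- share[!(share %in% (share + 1L))]  # no 3-SNP chains
  snp$amplicon_id[share + 1L] <- snp$amplicon_id[share]
  snp$amplicon_size[share + 1L] <- snp$amplicon_size[share]

  ## genotypes: founders HWE, trio children Mendelian
  is_x <- snp$chrom == "chrX"
  draw_allele <- function(p) ifelse(stats::runif(length(p)) < p, "A", "B")
  hap <- function() draw_allele(snp$freq)
  haplos <- vector("list", n_samples)  # list of (h1, h2); males: X second NA
  for (s in seq_len(n_samples)) {
    role <- if (n_trios > 0L && s <= 3L * n_trios)
      c("father", "mother", "child")[(s - 1L) %% 3L + 1L] else "founder"
    if (role == "child") {
      f <- haplos[[s - 2L]]; m <- haplos[[s - 1L]]
      pickf <- ifelse(stats::runif(n_snps) < 0.5, f$h1, f$h2)
      pickf[is_x] <- f$h1[is_x]  # father transmits his single X (to daughters)
      pickm <- ifelse(stats::runif(n_snps) < 0.5, m$h1, m$h2)
      haplos[[s]] <- list(h1 = pickf, h2 = pickm)
    } else {
      haplos[[s]] <- list(h1 = hap(), h2 = hap())
    }
  }
  geno_list <- lapply(seq_len(n_samples), function(s) {
    h <- haplos[[s]]
    g <- paste0(pmin(h$h1, h$h2), pmax(h$h1, h$h2))
    g[g == "BA"] <- "AB"
    if (sex[s] == "male") g[is_x] <- paste0(h$h2[is_x], h$h2[is_x])
    g[stats::runif(n_snps) < no_call_rate] <- "NC"
    data.frame(snp_id = snp$snp_id, sample_id = sample_id[s], genotype = g)
  })
  genotypes <- do.call(rbind, geno_list)

  ## quartet intensities
  qgrid <- data.table::CJ(si = seq_len(n_snps), quartet = seq_len(10L))
  qgrid <- qgrid[quartet <= snp$n_quartets[si]]
  qgrid[, tau := stats::runif(.N, noise$quartet_sd_range[1L],
                              noise$quartet_sd_range[2L])]

  probe_list <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    g <- genotypes$genotype[genotypes$sample_id == sample_id[s]]
    g <- g[match(snp$snp_id, genotypes$snp_id[genotypes$sample_id == sample_id[s]])]
    dos_a <- (g == "AA") * 2 + (g == "AB") * 1
    dos_b <- (g == "BB") * 2 + (g == "AB") * 1
    male_x <- is_x & sex[s] == "male"
    dos_a[male_x] <- (g[male_x] == "AA") * 1
    dos_b[male_x] <- (g[male_x] == "BB") * 1
    ## NC genotypes still hybridize; use a heterozygote dose
    nc <- g == "NC"
    dos_a[nc] <- ifelse(male_x[nc], 0.5, 1)
    dos_b[nc] <- ifelse(male_x[nc], 0.5, 1)

    amp <- stats::runif(length(size_pool) * 2,
                        noise$amplicon_effect_range[1L],
                        noise$amplicon_effect_range[2L]) * 500
    names(amp) <- paste(rep(c("Nsp", "Sty"), each = length(size_pool)),
                        rep(size_pool, 2L))
    a_s <- amp[paste(snp$subarray, snp$amplicon_size)]

    d <- qgrid[, {
      i <- si
      n <- .N
      mk <- function(dose, gain) {
        a_s[i] * (gain[i] * dose[i] * (1 + stats::rnorm(n, 0, tau)) +
                    0.05 * stats::rnorm(n, 0, tau))
      }
      .(snp_i = i, quartet = quartet,
        di_a = mk(dos_a, snp$gain_a), di_b = mk(dos_b, snp$gain_b))
    }]
    long <- data.table::melt(d, id.vars = c("snp_i", "quartet"),
                             measure.vars = c("di_a", "di_b"),
                             variable.name = "allele", value.name = "di")
    long[, allele := data.table::fifelse(allele == "di_a", "A", "B")]
    mm <- stats::runif(nrow(long), 50, 150)
    probe_list[[s]] <- data.table::data.table(
      snp_id = snp$snp_id[long$snp_i], sample_id = sample_id[s],
      chrom = snp$chrom[long$snp_i], pos = snp$pos[long$snp_i],
      quartet = long$quartet, allele = long$allele,
      pm = pmax(mm + long$di, 0), mm = mm,
      amplicon_size = snp$amplicon_size[long$snp_i],
      subarray = snp$subarray[long$snp_i],
      amplicon_id = snp$amplicon_id[long$snp_i])
  }
  probes <- data.table::rbindlist(probe_list)

  out <- list(probes = as.data.frame(probes), genotypes = genotypes,
              samples = samples,
              truth = snp[, c("snp_id", "chrom", "pos", "freq",
                              "gain_a", "gain_b", "amplicon_id")])
  attr(out, "seed") <- seed
  out
}
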