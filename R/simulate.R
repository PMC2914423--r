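## Seeded simulator for everything the caller consumes: reference panels of
## diploid samples with quartet-level intensities, genomes with
## segment-structured integer copy numbers, per-probe signal tables with
## log-normal noise, tumor-normal admixtures, and evaluation utilities.

#' Noise specification for the simulator
#'
#' Defaults emulate the noise structure of a 500K-class SNP array:
#' `log_signal_sd = 0.097` makes the diploid linear-scale panel variance
#' `E[(S_i - 2)^2]` come out near 0.0376 (the platform-typical median), and
#' `allelic_bias_sd = 0.499` makes the median of
#' `max(k_A / k_B, k_B / k_A)` come out near 1.4 (typical uneven allele
#' amplification).  `quartet_sd_range` spreads per-quartet noise so that
#' inverse-variance weighting roughly halves the combined variance, and
#' `amplicon_effect_range` spans the sample-specific amplicon-size effect.
#'
#' @param log_signal_sd sd of the log-normal per-probe signal noise.
#' @param allelic_bias_sd sd of the log allelic gain ratio.
#' @param quartet_sd_range range of per-quartet relative noise sds.
#' @param amplicon_effect_range range of multiplicative per-size effects.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(log_signal_sd = 0.097, allelic_bias_sd = 0.499,
                       quartet_sd_range = c(0.12, 0.72),
                       amplicon_effect_range = c(0.5, 2)) {
  stopifnot(log_signal_sd > 0, allelic_bias_sd > 0,
            all(quartet_sd_range > 0), all(amplicon_effect_range > 0))
  structure(list(log_signal_sd = log_signal_sd,
                 allelic_bias_sd = allelic_bias_sd,
                 quartet_sd_range = quartet_sd_range,
                 amplicon_effect_range = amplicon_effect_range),
            class = "noise_spec")
}

#' Genome specification: chromosomes tiled by constant-copy-number segments
#'
#' @param chromosomes data.frame `name`, `n_snps`, `length_bp`.
#' @param segments data.frame `chrom`, `start_probe`, `end_probe` (1-based
#'   probe indices within the chromosome), `cn`; segments must tile each
#'   chromosome exactly.
#' @param is_male male samples carry a single X outside the
#'   pseudoautosomal regions regardless of the autosomal segment spec.
#' @param pseudoautosomal optional data.frame `chrom`, `start`, `end`
#'   (1-based bp, inclusive) of regions that stay diploid in males.
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes, segments, is_male = FALSE,
                        pseudoautosomal = NULL) {
  chromosomes <- as.data.frame(chromosomes)
  segments <- as.data.frame(segments)
  stopifnot(all(c("name", "n_snps", "length_bp") %in% names(chromosomes)),
            all(c("chrom", "start_probe", "end_probe", "cn") %in% names(segments)),
            all(segments$cn >= 0), all(segments$cn <= 70))
  for (i in seq_len(nrow(chromosomes))) {
    s <- segments[segments$chrom == chromosomes$name[i], , drop = FALSE]
    s <- s[order(s$start_probe), , drop = FALSE]
    if (nrow(s) == 0L || s$start_probe[1L] != 1L ||
        s$end_probe[nrow(s)] != chromosomes$n_snps[i] ||
        (nrow(s) > 1L && any(s$start_probe[-1L] != s$end_probe[-nrow(s)] + 1L)))
      stop("segments do not tile chromosome ", chromosomes$name[i])
  }
  structure(list(chromosomes = chromosomes, segments = segments,
                 is_male = is_male, pseudoautosomal = pseudoautosomal),
            class = "genome_spec")
}

#' All-diploid genome, optionally with an X chromosome
#'
#' @param n_chrom number of autosomes.
#' @param snps_per_chrom probes per chromosome.
#' @param length_bp chromosome length.
#' @param include_x add an X chromosome (half the probe count).
#' @param is_male passed to [genome_spec()].
#' @return a `genome_spec` with every segment at CN = 2.
#' @export
diploid_genome <- function(n_chrom = 4L, snps_per_chrom = 5000L,
                           length_bp = 1e8, include_x = FALSE,
                           is_male = FALSE) {
  nm <- paste0("chr", seq_len(n_chrom))
  ns <- rep.int(snps_per_chrom, n_chrom)
  if (include_x) {
    nm <- c(nm, "chrX")
    ns <- c(ns, as.integer(snps_per_chrom / 2))
  }
  chromosomes <- data.frame(name = nm, n_snps = ns, length_bp = length_bp)
  segments <- data.frame(chrom = nm, start_probe = 1L, end_probe = ns, cn = 2L)
  genome_spec(chromosomes, segments, is_male = is_male)
}

#' Implant copy-number variants into a genome
#'
#' Places `n` non-overlapping constant-CN events of `size_range` probes on
#' the autosomes, with copy numbers drawn from `cn_values`.
#'
#' @param genome a `genome_spec`.
#' @param n number of events.
#' @param size_range event length range in probes (inclusive).
#' @param cn_values copy numbers to draw events from.
#' @param seed RNG seed.
#' @return The modified `genome_spec`.
#' @export
implant_cnvs <- function(genome, n = 10L, size_range = c(7L, 50L),
                         cn_values = c(1L, 3L), seed = 1L) {
  set.seed(seed)
  autos <- genome$chromosomes[tolower(sub("^chr", "", genome$chromosomes$name)) != "x", ]
  taken <- lapply(seq_len(nrow(autos)), function(i) integer(0))
  events <- list()
  tries <- 0L
  while (length(events) < n && tries < 1000L) {
    tries <- tries + 1L
    ci <- sample.int(nrow(autos), 1L)
    len <- sample(size_range[1L]:size_range[2L], 1L)
    if (autos$n_snps[ci] < len + 2L) next
    start <- sample.int(autos$n_snps[ci] - len - 1L, 1L) + 1L
    span <- start:(start + len - 1L)
    if (length(intersect(span, taken[[ci]]))) next
    ## keep one diploid probe between events so they stay distinct runs
    taken[[ci]] <- c(taken[[ci]], (start - 1L):(start + len))
    events[[length(events) + 1L]] <-
      data.frame(chrom = autos$name[ci], start_probe = start,
                 end_probe = start + len - 1L,
                 cn = sample(rep(cn_values, 2L), 1L))
  }
  if (length(events) < n) warning("placed only ", length(events), " of ", n, " events")
  ev <- do.call(rbind, events)
  segments <- genome$segments
  for (i in seq_len(nrow(ev))) {
    segments <- split_segment(segments, ev$chrom[i], ev$start_probe[i],
                              ev$end_probe[i], ev$cn[i])
  }
  genome_spec(genome$chromosomes, segments, genome$is_male,
              genome$pseudoautosomal)
}

# carve [start, end] out of the (single, constant) covering segment
split_segment <- function(segments, chrom, start, end, cn) {
  i <- which(segments$chrom == chrom & segments$start_probe <= start &
               segments$end_probe >= end)
  stopifnot(length(i) == 1L)
  s <- segments[i, ]
  parts <- list()
  if (s$start_probe < start)
    parts[[length(parts) + 1L]] <- data.frame(chrom = chrom,
      start_probe = s$start_probe, end_probe = start - 1L, cn = s$cn)
  parts[[length(parts) + 1L]] <- data.frame(chrom = chrom, start_probe = start,
                                            end_probe = end, cn = cn)
  if (s$end_probe > end)
    parts[[length(parts) + 1L]] <- data.frame(chrom = chrom,
      start_probe = end + 1L, end_probe = s$end_probe, cn = s$cn)
  rbind(segments[-i, ], do.call(rbind, parts))
}

#' Random aneuploid genome
#'
#' Tiles each autosome with segments of `seg_size_range` probes; each
#' segment is diploid with probability `diploid_frac`, otherwise its copy
#' number is drawn uniformly from `cn_values`.
#'
#' @inheritParams diploid_genome
#' @param seg_size_range segment length range in probes.
#' @param cn_values non-diploid copy numbers to draw from.
#' @param diploid_frac probability that a segment is CN = 2.
#' @param seed RNG seed.
#' @return a `genome_spec`.
#' @export
aneuploid_genome <- function(n_chrom = 4L, snps_per_chrom = 5000L,
                             length_bp = 1e8, seg_size_range = c(200L, 800L),
                             cn_values = c(0L, 1L, 3L, 4L, 5L, 6L),
                             diploid_frac = 0.6, seed = 1L) {
  set.seed(seed)
  nm <- paste0("chr", seq_len(n_chrom))
  chromosomes <- data.frame(name = nm, n_snps = snps_per_chrom,
                            length_bp = length_bp)
  segs <- list()
  for (ci in seq_len(n_chrom)) {
    at <- 1L
    prev_cn <- -1L
    while (at <= snps_per_chrom) {
      len <- sample(seg_size_range[1L]:seg_size_range[2L], 1L)
      end <- min(at + len - 1L, snps_per_chrom)
      cn <- if (stats::runif(1) < diploid_frac) 2L
            else sample(cn_values, 1L)
      if (cn == prev_cn) cn <- 2L  # keep adjacent segments distinct-ish
      segs[[length(segs) + 1L]] <- data.frame(chrom = nm[ci], start_probe = at,
                                              end_probe = end, cn = cn)
      prev_cn <- cn
      at <- end + 1L
    }
  }
  segments <- do.call(rbind, segs)
  ## merge accidental equal-CN neighbours so segments partition cleanly
  genome_spec(chromosomes, segments, is_male = FALSE)
}

# per-probe truth table (snp_id, chrom, pos, cn) from a genome_spec
genome_truth <- function(genome) {
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    ch <- genome$chromosomes[i, ]
    pos <- round(seq(1, ch$length_bp, length.out = ch$n_snps))
    pos <- pos + seq_len(ch$n_snps) - 1L  # guarantee strictly increasing
    cn <- integer(ch$n_snps)
    segs <- genome$segments[genome$segments$chrom == ch$name, , drop = FALSE]
    for (j in seq_len(nrow(segs)))
      cn[segs$start_probe[j]:segs$end_probe[j]] <- segs$cn[j]
    if (genome$is_male && tolower(sub("^chr", "", ch$name)) == "x") {
      nonpar <- is_x_nonpar(rep(ch$name, ch$n_snps), pos, genome$pseudoautosomal)
      cn[nonpar] <- 1L
    }
    data.frame(snp_id = sprintf("%s_s%06d", ch$name, seq_len(ch$n_snps)),
               chrom = ch$name, pos = pos, cn = cn)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a per-probe signal table for one sample
#'
#' Forward model: `S_i = S(c_i) * exp(N(0, log_signal_sd))` with `S(c)` the
#' contamination/ploidy-adjusted expected signal.  Genotype annotations are
#' generated consistently with the anchoring rules: regions with no
#' cancer-cell DNA give low call rates (~35 percent), single-copy regions
#' give low heterozygosity (~1 percent); both revert toward diploid levels
#' as the benign fraction of DNA at the locus grows.
#'
#' @param genome a [genome_spec()].
#' @param model a [sample_model()] (its `alpha`, `beta` drive the expected
#'   signal).
#' @param cal a [signal_calibration()].
#' @param noise a [noise_spec()].
#' @param seed RNG seed.
#' @param annotations generate a genotype annotation table?
#' @return list with `signals` (`snp_id`, `chrom`, `pos`, `signal`),
#'   `truth` (`snp_id`, `chrom`, `pos`, `cn`), and `annotations`
#'   (`snp_id`, `genotype`, or `NULL`); the seed is attached as an
#'   attribute.
#' @export
simulate_sample <- function(genome, model, cal = signal_calibration(),
                            noise = noise_spec(), seed = 1L,
                            annotations = TRUE) {
  set.seed(seed)
  truth <- genome_truth(genome)
  mu <- expected_signal(truth$cn, model, cal)
  signal <- mu * exp(stats::rnorm(nrow(truth), 0, noise$log_signal_sd))
  signals <- data.frame(snp_id = truth$snp_id, chrom = truth$chrom,
                        pos = truth$pos, signal = signal)
  ann <- NULL
  if (annotations) {
    cr_pure <- c(`0` = 0.35, `1` = 0.90)  # others 0.88
    het_pure <- c(`0` = 0.09, `1` = 0.01) # others 0.20
    cr0 <- ifelse(truth$cn <= 1, cr_pure[as.character(truth$cn)], 0.88)
    het0 <- ifelse(truth$cn <= 1, het_pure[as.character(truth$cn)], 0.20)
    ## fraction of DNA at the locus coming from the diploid (benign) cells
    f <- 2 * model$alpha /
      (2 * model$alpha + (1 - model$alpha) * expected_signal_s0(truth$cn, cal))
    cr <- f * 0.88 + (1 - f) * cr0
    het <- f * 0.20 + (1 - f) * het0
    u <- stats::runif(nrow(truth))
    g <- ifelse(u > cr, "NC",
                ifelse(stats::runif(nrow(truth)) < het, "AB",
                       ifelse(stats::runif(nrow(truth)) < 0.5, "AA", "BB")))
    ann <- data.frame(snp_id = truth$snp_id, genotype = g)
  }
  out <- list(signals = signals, truth = truth, annotations = ann)
  attr(out, "seed") <- seed
  attr(out, "model") <- model
  out
}

#' Mix a cancer and a diploid signal table
#'
#' DNA quantity is additive, so mixing happens on the linear signal scale:
#' `S_mix = (1 - alpha) * S_cancer + alpha * S_normal`.
#'
#' @param cancer,normal signal data.frames over the same probe set.
#' @param alpha diploid (contaminating) fraction.
#' @return The mixed signal data.frame; `alpha` is attached as attribute
#'   `true_alpha`.
#' @export
mix_samples <- function(cancer, normal, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (nrow(cancer) != nrow(normal) ||
      !identical(cancer$snp_id, normal$snp_id) ||
      !identical(cancer$pos, normal$pos))
    stop("probe sets differ between the two samples")
  out <- cancer
  out$signal <- (1 - alpha) * cancer$signal + alpha * normal$signal
  attr(out, "true_alpha") <- alpha
  out
}

#' Simulate a parent-parent-child trio at the signal level
#'
#' Each parent receives `n_cnvs` implanted events (heterozygous deletions
#' and single-copy gains); the child inherits each parental event
#' independently with probability 1/2, emulating Mendelian transmission of
#' germline copy-number variants.
#'
#' @param base a diploid [genome_spec()] shared by the trio.
#' @param n_cnvs events per parent.
#' @param size_range event length range in probes.
#' @param cn_values event copy numbers.
#' @param model,cal,noise forwarded to [simulate_sample()].
#' @param seed RNG seed.
#' @return list with `father`, `mother`, `child` (each a
#'   [simulate_sample()] result) and `inherited` (the child's event table).
#' @export
simulate_trio <- function(base = diploid_genome(2L, 3000L), n_cnvs = 3L,
                          size_range = c(30L, 80L), cn_values = c(1L, 3L),
                          model = sample_model(mode = "normal"),
                          cal = signal_calibration(), noise = noise_spec(),
                          seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 5L)
  father_g <- implant_cnvs(base, n_cnvs, size_range, cn_values, seed = seeds[1L])
  mother_g <- implant_cnvs(base, n_cnvs, size_range, cn_values, seed = seeds[2L])
  pick <- function(g) g$segments[g$segments$cn != 2L, , drop = FALSE]
  set.seed(seeds[3L])
  cand <- rbind(pick(father_g), pick(mother_g))
  inherited <- cand[stats::runif(nrow(cand)) < 0.5, , drop = FALSE]
  child_g <- base
  segs <- child_g$segments
  for (i in seq_len(nrow(inherited))) {
    segs2 <- try(split_segment(segs, inherited$chrom[i],
                               inherited$start_probe[i],
                               inherited$end_probe[i], inherited$cn[i]),
                 silent = TRUE)
    if (!inherits(segs2, "try-error")) segs <- segs2
  }
  child_g <- genome_spec(base$chromosomes, segs, base$is_male,
                         base$pseudoautosomal)
  list(father = simulate_sample(father_g, model, cal, noise, seed = seeds[4L] %% 2^30),
       mother = simulate_sample(mother_g, model, cal, noise, seed = seeds[5L] %% 2^30),
       child = simulate_sample(child_g, model, cal, noise, seed = seed + 7L),
       inherited = inherited)
}

#' Compare called copy numbers against truth
#'
#' Alterations are maximal runs of probes whose copy number differs from
#' the baseline (the modal truth copy number unless given).  Among runs of
#' at least `min_probes` probes, a called run is spurious if it overlaps no
#' truly altered probe, and a true run is missed if it overlaps no called
#' altered probe.  The false-alteration rate is
#' `100 * (spurious + missed) / (true_runs + spurious)`.
#'
#' @param truth data.frame `chrom`, `pos`, `cn` (true copy numbers).
#' @param calls data.frame `chrom`, `pos`, `cn` (called copy numbers) over
#'   the same probes.
#' @param min_probes minimum run length considered an alteration.
#' @param baseline_cn baseline copy number; default: modal truth CN.
#' @param true_model,fitted_model optional [sample_model()]s used to report
#'   `alpha_error` and `beta_error`.
#' @return list with `false_alteration_rate` and `concordance` (both in
#'   percent), counts, and (if models given) `alpha_error`, `beta_error`.
#' @export
evaluate_calls <- function(truth, calls, min_probes = 7L, baseline_cn = NULL,
                           true_model = NULL, fitted_model = NULL) {
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  if (nrow(truth) != nrow(calls) || !identical(truth$pos, calls$pos))
    stop("probe sets differ between truth and calls")
  if (is.null(baseline_cn)) {
    tab <- table(truth$cn)
    baseline_cn <- as.integer(names(tab)[which.max(tab)])
  }
  concordance <- 100 * mean(truth$cn == calls$cn)

  runs <- function(cn, chrom) {
    alt <- cn != baseline_cn
    r <- rle(paste(chrom, alt))
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    keep <- alt[lo]
    data.frame(lo = lo[keep], hi = hi[keep])[hi[keep] - lo[keep] + 1L >= min_probes, ]
  }
  tr <- runs(truth$cn, truth$chrom)
  cr <- runs(calls$cn, calls$chrom)
  t_alt <- truth$cn != baseline_cn
  c_alt <- calls$cn != baseline_cn
  spurious <- sum(vapply(seq_len(nrow(cr)), function(i)
    !any(t_alt[cr$lo[i]:cr$hi[i]]), logical(1)))
  missed <- sum(vapply(seq_len(nrow(tr)), function(i)
    !any(c_alt[tr$lo[i]:tr$hi[i]]), logical(1)))
  denom <- nrow(tr) + spurious
  out <- list(false_alteration_rate = if (denom > 0) 100 * (spurious + missed) / denom else 0,
              concordance = concordance,
              n_true = nrow(tr), n_called = nrow(cr),
              n_spurious = spurious, n_missed = missed)
  if (!is.null(true_model) && !is.null(fitted_model)) {
    out$alpha_error <- fitted_model$alpha - true_model$alpha
    out$beta_error <- fitted_model$beta - true_model$beta
  }
  out
}
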