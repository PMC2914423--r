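## Quartet-level intensity combination: amplicon-size normalization,
## allele-specific rescaling (k_A, k_B), inverse-variance quartet weighting.
## All parameters are fitted on a reference panel of diploid samples, so that
## the combined per-SNP signal S_i has expectation 2 at copy number 2.

# lower median: for even counts take the lower of the two central order
# statistics, so that panel summaries are deterministic
lower_median <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x, partial = (n + 1L) %/% 2L)[(n + 1L) %/% 2L]
}

#' Amplicon-size normalization of quartet intensities
#'
#' For each probe the mismatch intensity is subtracted from the perfect-match
#' intensity, `dI = pm - mm`, and the difference is divided by the average
#' `dI` over all quartets and alleles of SNPs residing on PCR amplicons of
#' the same size within the same subarray.  Amplicon size is a strong
#' sample-specific intensity covariate; this normalization removes it.
#'
#' Size groups with fewer than `min_group` quartet observations are pooled
#' with the nearest size's group (ties toward the smaller size).  A group
#' whose mean `dI` is not positive carries no usable signal; its probes are
#' dropped and the sizes are reported in the `unusable_sizes` attribute.
#'
#' @param records data.frame of quartet records for one sample with columns
#'   `snp_id`, `quartet`, `allele`, `pm`, `mm`, `amplicon_size`, `subarray`.
#' @param min_group minimum quartet observations per exact-size group.
#' @return A `data.table` with the input keys and a `norm` column
#'   (`dI / mean(dI)` of the probe's size group).  Negative values are
#'   passed through; clamping happens later at the signal level.
#' @export
size_normalize <- function(records, min_group = 20L) {
  records <- as.data.frame(records)
  need <- c("snp_id", "quartet", "allele", "pm", "mm", "amplicon_size", "subarray")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("no quartet records supplied")
  dt <- data.table::as.data.table(records)
  dt[, di := pm - mm]
  dt[, size_group := map_size_groups(amplicon_size, as.integer(min_group)),
     by = subarray]
  dt[, group_mean := mean(di), by = .(subarray, size_group)]
  bad <- dt[group_mean <= 0,
            unique(data.frame(subarray = subarray, amplicon_size = amplicon_size))]
  if (nrow(bad))
    warning(nrow(bad), " amplicon-size group(s) with non-positive mean dI dropped")
  dt <- dt[group_mean > 0]
  dt[, norm := di / group_mean]
  out <- dt[, .(snp_id, quartet, allele, amplicon_size, subarray, norm)]
  data.table::setattr(out, "unusable_sizes", bad)
  out[]
}

# map each amplicon size to the representative size of its normalization
# group: exact size if the group has >= min_group observations, otherwise the
# nearest well-populated size (ties toward the smaller size); if no group is
# well populated everything is pooled
map_size_groups <- function(sizes, min_group) {
  tab <- table(sizes)
  vals <- as.integer(names(tab))
  good <- vals[tab >= min_group]
  if (length(good) == 0L) return(rep.int(vals[1L], length(sizes)))
  idx <- vapply(vals, function(s) {
    d <- abs(good - s)
    good[which(d == min(d))[1L]]  # sorted, so first hit is the smaller size
  }, integer(1))
  idx[match(sizes, vals)]
}

#' Allele normalization parameters from a diploid reference panel
#'
#' Solves for the per-SNP rescaling factors `(k_A, k_B)` that make the
#' quartet signal `S_q = k_A * I_A + k_B * I_B` close to 2 regardless of
#' genotype, by minimizing
#' `E = sum_G N_G * (k_A * x_G + k_B * y_G - 2)^2` over the three genotype
#' classes G = AA, AB, BB, where `N_G` is the class count and `x_G`, `y_G`
#' are the class medians of the normalized A- and B-allele intensities.
#' The minimizer is closed form:
#' `k_A = 2 (C_x C_yy - C_y C_xy) / (C_xx C_yy - C_xy^2)` and symmetrically
#' for `k_B`, with `C_*` the N-weighted moments of the medians.  The ratio
#' `k_A / k_B` measures uneven allele amplification.
#'
#' @param n_geno counts of panel samples per genotype, in AA, AB, BB order.
#' @param x_med,y_med per-genotype medians of the normalized A-allele and
#'   B-allele intensities (same order; use 0 for empty classes).
#' @return list with `k_a`, `k_b`, `excluded` (logical) and `reason`
#'   (`"monomorphic"` when fewer than two genotype classes are observed,
#'   `"degenerate design"` when the normal-equation determinant vanishes).
#' @examples
#' estimate_allele_params(c(24, 0, 24), c(2, 0, 0), c(0, 0, 2))  # k = (1, 1)
#' @export
estimate_allele_params <- function(n_geno, x_med, y_med) {
  stopifnot(length(n_geno) == 3L, length(x_med) == 3L, length(y_med) == 3L)
  out <- list(k_a = NA_real_, k_b = NA_real_, excluded = FALSE, reason = NA_character_)
  if (sum(n_geno > 0) < 2L) {
    out$excluded <- TRUE; out$reason <- "monomorphic"
    return(out)
  }
  cx  <- sum(n_geno * x_med);         cy  <- sum(n_geno * y_med)
  cxy <- sum(n_geno * x_med * y_med)
  cxx <- sum(n_geno * x_med * x_med); cyy <- sum(n_geno * y_med * y_med)
  den <- cxx * cyy - cxy * cxy
  if (abs(den) <= 1e-10 * max(1, abs(cxx * cyy))) {
    out$excluded <- TRUE; out$reason <- "degenerate design"
    return(out)
  }
  out$k_a <- 2 * (cx * cyy - cy * cxy) / den
  out$k_b <- 2 * (cy * cxx - cx * cxy) / den
  out
}

# the objective the closed form minimizes; kept separate so tests can check
# optimality against a grid search
allele_param_objective <- function(k_a, k_b, n_geno, x_med, y_med) {
  e <- 0
  for (g in 1:3)
    e <- e + n_geno[g] * (k_a * x_med[g] + k_b * y_med[g] - 2)^2
  e
}

#' Inverse-variance quartet weights
#'
#' Each quartet's combined signal `S_q` is an independent estimate of the
#' same quantity; the minimum-variance linear combination weights each
#' quartet by the reciprocal of its panel variance:
#' `w_q = (1 / sigma_q^2) / sum_p (1 / sigma_p^2)`, giving a combined
#' variance `sigma_i^2 = 1 / sum_q (1 / sigma_q^2)`.  The equal-weight
#' variance estimate `s_i^2 = (1 / n) * sum_q sigma_q^2` is reported for
#' comparison.
#'
#' @param x either a samples-by-quartets matrix of `S_q` values (variances
#'   are computed per column) or a numeric vector of per-quartet variances.
#' @param eps floor applied to zero variances (with a warning).
#' @return list with `weights` (sums to 1), `sigma_q2`, `sigma_i2`, `s_i2`.
#' @examples
#' fit_quartet_weights(c(1, 3))  # weights 0.75 / 0.25
#' @export
fit_quartet_weights <- function(x, eps = 1e-6) {
  sigma_q2 <- if (is.matrix(x)) apply(x, 2L, stats::var) else as.numeric(x)
  if (any(is.na(sigma_q2))) stop("undefined quartet variance")
  if (any(sigma_q2 < 0)) stop("negative quartet variance")
  if (any(sigma_q2 == 0)) {
    warning("zero quartet variance floored at ", eps)
    sigma_q2[sigma_q2 == 0] <- eps
  }
  inv <- 1 / sigma_q2
  list(weights = inv / sum(inv),
       sigma_q2 = sigma_q2,
       sigma_i2 = 1 / sum(inv),
       s_i2 = mean(sigma_q2))
}

#' Combine one SNP's quartet intensities into a single signal
#'
#' Computes `S_q = k_A * I_A + k_B * I_B` per quartet and the weighted sum
#' `S_i = sum_q w_q S_q`.  Quartets missing from `intensities` are dropped
#' and the remaining weights renormalized (with a warning).
#'
#' @param intensities data.frame with columns `quartet`, `allele` (`"A"` /
#'   `"B"`) and `norm` (size-normalized intensity) for one SNP in one sample.
#' @param k_a,k_b allele normalization parameters.
#' @param weights named numeric vector of quartet weights (names = quartet
#'   indices), summing to 1.
#' @return The combined signal `S_i` (a single number).
#' @export
combine_to_snp_signal <- function(intensities, k_a, k_b, weights) {
  dt <- data.table::as.data.table(intensities)
  wide <- data.table::dcast(dt, quartet ~ allele, value.var = "norm")
  if (!all(c("A", "B") %in% names(wide))) stop("both alleles required")
  wide[, sq := k_a * A + k_b * B]
  w <- weights[as.character(wide$quartet)]
  if (any(is.na(w))) stop("intensities for unknown quartet")
  if (length(w) < length(weights)) {
    warning("missing quartets; weights renormalized")
    w <- w / sum(w)
  }
  sum(w * wide$sq)
}

#' Panel-variance QC filter
#'
#' Marks probe sets as excluded when their empirical panel variance
#' `mean((S_i - 2)^2)` exceeds `cutoff` (noisy probes), keeping previously
#' assigned exclusions (monomorphic, degenerate) intact.
#'
#' @param probe_sets data.frame with columns `panel_var`, `excluded`,
#'   `reason` as produced by [fit_reference_panel()].
#' @param cutoff panel-variance cutoff (default 0.25).
#' @return `probe_sets` with updated `excluded` / `reason`.
#' @export
qc_filter <- function(probe_sets, cutoff = 0.25) {
  noisy <- !probe_sets$excluded & !is.na(probe_sets$panel_var) &
    probe_sets$panel_var > cutoff
  probe_sets$excluded[noisy] <- TRUE
  probe_sets$reason[noisy] <- "high panel variance"
  probe_sets
}

#' Fit all probe-combination parameters on a reference panel
#'
#' Runs the full panel calibration: amplicon-size normalization per sample,
#' per-SNP allele parameters from genotype-class medians, per-quartet
#' variances and inverse-variance weights, panel-variance QC, and multi-SNP
#' amplicon bookkeeping.  For X-chromosome SNPs outside the pseudoautosomal
#' regions only female panel samples are used (males are hemizygous there,
#' so their intensities would bias the diploid calibration).
#'
#' @param probes quartet-intensity table for all panel samples (columns
#'   `snp_id`, `sample_id`, `chrom`, `pos`, `quartet`, `allele`, `pm`, `mm`,
#'   `amplicon_size`, `subarray`, optionally `amplicon_id`).
#' @param genotypes genotype table (`snp_id`, `sample_id`, `genotype` in
#'   AA/AB/BB/NC).
#' @param samples data.frame with `sample_id` and `sex` (`"male"`/`"female"`).
#' @param sigma2_cutoff panel-variance QC cutoff.
#' @param min_group minimum observations per amplicon-size group.
#' @param eps_var floor for zero quartet variances.
#' @param pseudoautosomal optional data.frame (`chrom`, `start`, `end`,
#'   1-based inclusive) of pseudoautosomal intervals exempt from the
#'   female-only X rule.
#' @return An object of class `panel_fit`: list with `probe_sets`
#'   (per-SNP parameters, variances, exclusions, amplicon merge targets),
#'   `quartets` (per-quartet variances and weights), and `n_samples`.
#' @export
fit_reference_panel <- function(probes, genotypes, samples,
                                sigma2_cutoff = 0.25, min_group = 20L,
                                eps_var = 1e-6, pseudoautosomal = NULL) {
  probes <- data.table::as.data.table(probes)
  genotypes <- data.table::as.data.table(genotypes)
  samples <- as.data.frame(samples)
  stopifnot(all(c("sample_id", "sex") %in% names(samples)))
  if (!"amplicon_id" %in% names(probes)) probes[, amplicon_id := NA_character_]

  ## per-sample amplicon-size normalization
  norm <- probes[, {
    sn <- size_normalize(.SD, min_group = min_group)
    sn[, .(snp_id, quartet, allele, norm)]
  }, by = sample_id]

  ## SNP metadata
  meta <- unique(probes[, .(snp_id, chrom, pos, subarray, amplicon_id)])
  if (anyDuplicated(meta$snp_id)) stop("inconsistent SNP metadata")
  meta[, is_x := is_x_nonpar(chrom, pos, pseudoautosomal)]

  ## female-only rule for X outside PAR
  females <- samples$sample_id[tolower(samples$sex) %in% c("female", "f")]
  norm <- merge(norm, meta[, .(snp_id, is_x)], by = "snp_id")
  norm <- norm[!is_x | sample_id %in% females]

  ## allele-wide layout: one row per (snp, sample, quartet)
  wide <- data.table::dcast(norm, snp_id + sample_id + quartet ~ allele,
                            value.var = "norm")
  wide <- merge(wide, genotypes, by = c("snp_id", "sample_id"), all.x = TRUE)
  wide <- wide[!is.na(genotype) & genotype != "NC" & !is.na(A) & !is.na(B)]

  ## genotype-class medians and closed-form allele parameters
  med <- wide[, .(x = lower_median(A), y = lower_median(B),
                  n = data.table::uniqueN(sample_id)),
              by = .(snp_id, genotype)]
  params <- med[, {
    n3 <- x3 <- y3 <- numeric(3)
    gi <- match(genotype, c("AA", "AB", "BB"))
    n3[gi] <- n; x3[gi] <- x; y3[gi] <- y
    p <- estimate_allele_params(n3, x3, y3)
    .(k_a = p$k_a, k_b = p$k_b, excluded = p$excluded, reason = p$reason)
  }, by = snp_id]

  ## quartet signals, variances, weights
  wide <- merge(wide, params[excluded == FALSE, .(snp_id, k_a, k_b)], by = "snp_id")
  wide[, sq := k_a * A + k_b * B]
  qvar <- wide[, .(sigma_q2 = stats::var(sq), n_obs = .N), by = .(snp_id, quartet)]
  qvar <- qvar[!is.na(sigma_q2)]
  n_floored <- qvar[sigma_q2 <= 0, .N]
  if (n_floored > 0) {
    warning(n_floored, " zero quartet variance(s) floored at ", eps_var)
    qvar[sigma_q2 <= 0, sigma_q2 := eps_var]
  }
  qvar[, w := (1 / sigma_q2) / sum(1 / sigma_q2), by = snp_id]
  snpvar <- qvar[, .(sigma_i2 = 1 / sum(1 / sigma_q2),
                     s_i2 = mean(sigma_q2), n_quartets = .N), by = snp_id]

  ## combined panel signals and empirical panel variance
  si <- merge(wide, qvar[, .(snp_id, quartet, w)], by = c("snp_id", "quartet"))
  si <- si[, .(s_i = sum(w * sq)), by = .(snp_id, sample_id)]
  pvar <- si[, .(panel_var = mean((s_i - 2)^2)), by = snp_id]

  probe_sets <- Reduce(function(a, b) merge(a, b, by = "snp_id", all.x = TRUE),
                       list(merge(meta, params, by = "snp_id", all.x = TRUE),
                            snpvar, pvar))
  probe_sets[is.na(excluded), `:=`(excluded = TRUE, reason = "no usable panel data")]
  probe_sets <- qc_filter(probe_sets, cutoff = sigma2_cutoff)

  ## multi-SNP amplicons: signal will be averaged onto the lowest-position
  ## SNP; the others are merged away
  probe_sets[, merged_into := NA_character_]
  has_amp <- probe_sets[!is.na(amplicon_id) & excluded == FALSE]
  if (nrow(has_amp)) {
    data.table::setorder(has_amp, amplicon_id, pos)
    keep <- has_amp[, .(snp_id, target = snp_id[1L]), by = amplicon_id]
    merged <- keep[snp_id != target]
    if (nrow(merged))
      probe_sets[merged, merged_into := i.target, on = "snp_id"]
  }
  data.table::setorder(probe_sets, chrom, pos)

  structure(list(probe_sets = probe_sets[],
                 quartets = qvar[, .(snp_id, quartet, sigma_q2, w)],
                 n_samples = length(unique(probes$sample_id))),
            class = "panel_fit")
}

#' @export
print.panel_fit <- function(x, ...) {
  ps <- x$probe_sets
  cat(sprintf("panel_fit: %d SNPs (%d retained, %d excluded, %d merged-away), %d panel samples\n",
              nrow(ps), sum(!ps$excluded & is.na(ps$merged_into)),
              sum(ps$excluded), sum(!is.na(ps$merged_into)), x$n_samples))
  invisible(x)
}

is_x_nonpar <- function(chrom, pos, pseudoautosomal = NULL) {
  on_x <- tolower(sub("^chr", "", chrom)) == "x"
  if (!is.null(pseudoautosomal) && nrow(pseudoautosomal) > 0) {
    for (i in seq_len(nrow(pseudoautosomal))) {
      p <- pseudoautosomal[i, ]
      in_par <- tolower(sub("^chr", "", chrom)) ==
        tolower(sub("^chr", "", p$chrom)) & pos >= p$start & pos <= p$end
      on_x <- on_x & !in_par
    }
  }
  on_x
}

#' Per-SNP signals for a new sample from fitted panel parameters
#'
#' Applies amplicon-size normalization to the sample's quartet records,
#' combines alleles and quartets with the panel-fitted `(k_A, k_B)` and
#' weights, averages SNPs sharing an amplicon onto the lowest-position SNP,
#' and floors the result at `eps` (signals enter the model on a log scale).
#'
#' @param fit a [fit_reference_panel()] result.
#' @param records quartet-intensity table for one sample.
#' @param eps signal floor.
#' @param min_group passed to [size_normalize()].
#' @return data.frame `snp_id`, `chrom`, `pos`, `signal`, ordered by
#'   chromosome and position, restricted to retained SNPs.
#' @export
snp_signals <- function(fit, records, eps = 0.01, min_group = 20L) {
  stopifnot(inherits(fit, "panel_fit"))
  norm <- size_normalize(records, min_group = min_group)
  ps <- fit$probe_sets[excluded == FALSE]
  wide <- data.table::dcast(norm, snp_id + quartet ~ allele, value.var = "norm")
  wide <- merge(wide, ps[, .(snp_id, k_a, k_b)], by = "snp_id")
  wide <- wide[!is.na(A) & !is.na(B)]
  wide[, sq := k_a * A + k_b * B]
  wide <- merge(wide, fit$quartets[, .(snp_id, quartet, w)],
                by = c("snp_id", "quartet"))
  n_q <- fit$quartets[, .(n_expected = .N), by = snp_id]
  obs <- wide[, .(n_seen = .N), by = snp_id]
  short <- merge(n_q, obs, by = "snp_id")[n_seen < n_expected]
  if (nrow(short))
    warning(nrow(short), " SNP(s) with missing quartets; weights renormalized")
  sig <- wide[, .(signal = sum(w * sq) / sum(w)), by = snp_id]
  sig <- merge(ps[, .(snp_id, chrom, pos, merged_into)], sig, by = "snp_id")

  ## average multi-SNP amplicons onto their target SNP
  sig[, target := data.table::fifelse(is.na(merged_into), snp_id, merged_into)]
  sig <- sig[, .(signal = mean(signal)), by = target]
  data.table::setnames(sig, "target", "snp_id")
  sig <- merge(ps[is.na(merged_into), .(snp_id, chrom, pos)], sig, by = "snp_id")
  sig[, signal := pmax(signal, eps)]
  data.table::setorder(sig, chrom, pos)
  as.data.frame(sig)
}
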