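## Estimation of contamination (alpha) and genome-size factor (beta) from
## the histogram of window-smoothed signals: peak detection, rule-based
## anchoring of peaks to copy numbers, and grid minimization of the
## weighted squared log-distance E1 between peak positions and model
## expectations.

#' Window-smoothed signal track
#'
#' Computes `log(T_i) = (1/N) * sum_j log(S_j)` over a centered window of
#' `window` probes (default 101), truncated -- never wrapped -- at chromosome
#' ends.  `T_i` is thus the geometric mean signal of the window.  Natural
#' logs are used throughout; signals are floored at `eps` before the log.
#'
#' @param signals data.frame with `chrom`, `pos`, `signal`, ordered (or
#'   orderable) by chromosome and position.
#' @param window window size N (odd).
#' @param eps signal floor applied before taking logs.
#' @return The input with a `smoothed` column appended, ordered by
#'   chromosome and position.  Chromosomes with fewer than 2 probes are
#'   passed through unsmoothed with a warning.
#' @export
smooth_signal <- function(signals, window = 101L, eps = 0.01) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  dt <- data.table::as.data.table(signals)
  stopifnot(all(c("chrom", "pos", "signal") %in% names(dt)))
  data.table::setorder(dt, chrom, pos)
  h <- (window - 1L) %/% 2L
  dt[, smoothed := {
    n <- .N
    if (n < 2L) {
      warning("chromosome ", chrom[1L], " has fewer than 2 probes; not smoothed")
      signal
    } else {
      cs <- cumsum(log(pmax(signal, eps)))
      lo <- pmax(seq_len(n) - h, 1L)
      hi <- pmin(seq_len(n) + h, n)
      exp((cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L))
    }
  }, by = chrom]
  as.data.frame(dt)
}

#' Histogram of smoothed signals and local-maximum detection
#'
#' Bins the smoothed track into `[k*bin, (k+1)*bin)` intervals (default bin
#' 0.1), then finds local maxima: a bin strictly higher than both neighbors
#' after merging equal-height plateaus (the plateau's central bin is taken;
#' maxima at the edge of the occupied range count).  Peak heights are the
#' fraction of probes in the peak bin.  Peaks lower than `min_height` are
#' retained but flagged, since genuinely small copy-number classes can
#' produce very small peaks.  If a per-probe genotype annotation is given,
#' each peak also gets the genotyping call rate and heterozygosity of the
#' probes whose smoothed signal falls within the peak bin plus/minus one bin.
#'
#' @param smoothed data.frame from [smooth_signal()] (needs `smoothed`; for
#'   annotations also `snp_id`).
#' @param bin histogram bin width.
#' @param min_height flagging threshold on peak height (fraction of probes).
#' @param annotations optional data.frame `snp_id`, `genotype`
#'   (AA/AB/BB/NC) for this sample.
#' @return A `peak_set`: data.frame with `position` (bin center), `height`
#'   (fraction), `call_rate` and `heterozygosity` (percent, `NA` without
#'   annotations), `flagged`, and `anchored_cn` (all `NA` until
#'   [anchor_peaks()]).
#' @export
find_signal_peaks <- function(smoothed, bin = 0.1, min_height = 2e-4,
                              annotations = NULL) {
  tvals <- smoothed$smoothed
  if (is.null(tvals) || length(tvals) == 0L) stop("empty smoothed track")
  idx <- floor(tvals / bin)
  rng <- min(idx):max(idx)
  counts <- tabulate(idx - rng[1L] + 1L, nbins = length(rng))
  height <- counts / length(tvals)

  ## merge equal-height plateaus, compare each run against its neighbors
  r <- rle(height)
  nr <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  left <- c(-Inf, r$values[-nr])
  right <- c(r$values[-1L], -Inf)
  is_peak <- r$values > left & r$values > right & r$values > 0
  centers <- (starts + ends) %/% 2L  # lower-central bin of even plateaus
  peak_bins <- rng[centers[is_peak]]

  ## sub-bin peak positions by parabolic interpolation through the peak bin
  ## and its neighbors; bin-center quantization (+/- half a bin) is
  ## comparable to the peak spacing in heavily contaminated samples, where
  ## it would dominate the parameter fit
  ctr <- centers[is_peak]
  h0 <- height[ctr]
  hl <- ifelse(ctr > 1L, height[ctr - 1L], 0)
  hr <- ifelse(ctr < length(height), height[ctr + 1L], 0)
  den <- hl - 2 * h0 + hr
  delta <- ifelse(abs(den) > 0, 0.5 * (hl - hr) / den, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)

  ps <- data.frame(position = (peak_bins + 0.5 + delta) * bin,
                   bin_index = peak_bins,
                   height = height[centers[is_peak]],
                   call_rate = NA_real_, heterozygosity = NA_real_,
                   flagged = height[centers[is_peak]] < min_height,
                   anchored_cn = NA_integer_)
  ps <- ps[order(ps$position), , drop = FALSE]
  rownames(ps) <- NULL

  if (!is.null(annotations) && nrow(ps)) {
    ann <- merge(data.frame(snp_id = smoothed$snp_id, bin_idx = idx),
                 annotations[, c("snp_id", "genotype")], by = "snp_id")
    for (i in seq_len(nrow(ps))) {
      g <- ann$genotype[abs(ann$bin_idx - ps$bin_index[i]) <= 1L]
      if (length(g)) {
        called <- g != "NC"
        ps$call_rate[i] <- 100 * mean(called)
        ps$heterozygosity[i] <- if (any(called)) 100 * mean(g[called] == "AB") else 0
      }
    }
  }
  class(ps) <- c("peak_set", "data.frame")
  ps
}

# assign an anchor unless the peak already carries a different one, in which
# case the earlier rule wins and we warn
assign_anchor <- function(peaks, k, cn, rule) {
  cur <- peaks$anchored_cn[k]
  if (!is.na(cur) && cur != cn) {
    warning(sprintf("rule %s would anchor peak %d to CN=%d but it is already CN=%d; keeping earlier anchor",
                    rule, k, cn, cur))
    return(peaks)
  }
  peaks$anchored_cn[k] <- cn
  peaks
}

#' Anchor histogram peaks to copy numbers
#'
#' Applies, in order, the rules that pin peaks to copy numbers before the
#' (alpha, beta) fit:
#' (1) a single maximum is CN = 2;
#' (2) if the first maximum has genotyping call rate below 60 percent it is
#'     CN = 0 (genotyping fails where no DNA remains);
#' (3) if the first maximum has heterozygosity below 3 percent it is CN = 1
#'     (one remaining allele cannot be heterozygous);
#' (4) if the first maximum is CN = 0 and the second has heterozygosity
#'     below 3 percent, the second is CN = 1;
#' (5) if the highest maximum is at least twice the second highest it is
#'     CN = 2 (the dominant state of a genome is diploid).
#' Rules 2-4 need genotype annotations and are disabled in `agilent` mode
#' (or when call rate / heterozygosity are missing).  Conflicting
#' assignments keep the earlier rule's anchor with a warning.  The function
#' is idempotent: anchors already present are kept.
#'
#' @param peaks a `peak_set` from [find_signal_peaks()].
#' @param mode sample mode; `"agilent"` disables rules 2-4.
#' @param call_rate_min,het_min,height_ratio rule thresholds (percent,
#'   percent, ratio).
#' @return The `peak_set` with `anchored_cn` filled in where a rule fired.
#' @export
anchor_peaks <- function(peaks, mode = "tumor", call_rate_min = 60,
                         het_min = 3, height_ratio = 2) {
  n <- nrow(peaks)
  if (n == 0L) stop("no peaks to anchor")
  genotype_rules <- mode != "agilent"
  if (n == 1L)
    peaks <- assign_anchor(peaks, 1L, 2L, "1")
  if (genotype_rules && n > 1L && !is.na(peaks$call_rate[1L]) &&
      peaks$call_rate[1L] < call_rate_min)
    peaks <- assign_anchor(peaks, 1L, 0L, "2")
  if (genotype_rules && n > 1L && !is.na(peaks$heterozygosity[1L]) &&
      peaks$heterozygosity[1L] < het_min)
    peaks <- assign_anchor(peaks, 1L, 1L, "3")
  if (genotype_rules && n > 2L && !is.na(peaks$anchored_cn[1L]) &&
      peaks$anchored_cn[1L] == 0L && !is.na(peaks$heterozygosity[2L]) &&
      peaks$heterozygosity[2L] < het_min)
    peaks <- assign_anchor(peaks, 2L, 1L, "4")
  if (n > 1L) {
    ord <- order(peaks$height, decreasing = TRUE)
    if (peaks$height[ord[1L]] >= height_ratio * peaks$height[ord[2L]])
      peaks <- assign_anchor(peaks, ord[1L], 2L, "5")
  }
  peaks
}

# log expected signal for c = 0..max_cn at one alpha (beta enters additively
# on the log scale); values floored to keep logs finite
log_mix_vector <- function(alpha, cal, eps = 0.01) {
  log(pmax(2 * alpha + (1 - alpha) * s0_vector(cal), eps))
}

# nearest copy number to each log-target given the log expected-signal
# vector; ties go to the smaller copy number
nearest_cn <- function(log_target, log_mix) {
  mid <- (log_mix[-1L] + log_mix[-length(log_mix)]) / 2
  cn <- findInterval(log_target, mid)
  pos <- which(cn > 0L)
  lower_ok <- pos[abs(log_target[pos] - log_mix[cn[pos]]) <=
                    abs(log_target[pos] - log_mix[cn[pos] + 1L]) + 1e-12]
  cn[lower_ok] <- cn[lower_ok] - 1L
  cn
}

#' Fit contamination and genome-size factor to histogram peaks
#'
#' Minimizes `E1(alpha, beta) = sum_k H(T_k) * (log T_k - log S(c_k))^2`
#' over a direct-enumeration grid (`alpha` in steps of `alpha_step` over
#' `[0, 0.99]`, `beta` in steps of `beta_step` over `[0.5, 2]`).  Anchored
#' peaks keep their copy number; each unanchored peak is assigned, per grid
#' point, the copy number minimizing `|log T_k - log S(c)|` (ties to the
#' smaller c).  Ties in E1 resolve to the smaller alpha, then smaller beta.
#' `normal` mode returns (0, 1) directly; `cell_line` mode fixes alpha = 0
#' and scans beta only.
#'
#' Because peak positions are measured from a binned histogram, distinct
#' peak-to-copy-number assignments can fit E1 almost equally well in
#' heavily contaminated samples; the best grid point of every assignment
#' encountered is therefore also returned (`candidates`), so the caller can
#' arbitrate between them with the full-likelihood residual E2 after
#' decoding (see [run_call_pipeline()]).
#'
#' @param peaks an anchored `peak_set`.
#' @param cal a [signal_calibration()].
#' @param mode sample mode.
#' @param alpha_step,beta_step grid resolutions.
#' @return list with `alpha`, `beta`, `e1`, `assigned_cn` (per peak, at the
#'   optimum), `mode`, and `candidates` (data.frame `alpha`, `beta`, `e1`,
#'   one row per distinct peak assignment, ordered by `e1`).
#' @export
fit_alpha_beta <- function(peaks, cal = signal_calibration(), mode = "tumor",
                           alpha_step = 0.01, beta_step = 0.005) {
  stopifnot(nrow(peaks) >= 1L)
  log_t <- log(peaks$position)
  h <- peaks$height
  anchored <- !is.na(peaks$anchored_cn)

  alphas <- switch(mode,
                   normal = 0,
                   cell_line = 0,
                   seq(0, 0.99, by = alpha_step))
  betas <- if (mode == "normal") 1 else seq(0.5, 2, by = beta_step)
  log_b <- log(betas)

  best <- list(e1 = Inf, alpha = NA_real_, beta = NA_real_)
  by_assignment <- new.env(parent = emptyenv())
  for (a in alphas) {
    lm <- log_mix_vector(a, cal)
    ## E1 as a function of beta, vectorized over the beta grid
    e1 <- numeric(length(betas))
    cn_mat <- matrix(0L, length(betas), length(log_t))
    for (k in seq_along(log_t)) {
      target <- log_t[k] - log_b
      cn <- if (anchored[k]) rep.int(peaks$anchored_cn[k], length(betas))
            else nearest_cn(target, lm)
      cn_mat[, k] <- cn
      e1 <- e1 + h[k] * (target - lm[cn + 1L])^2
    }
    j <- which.min(e1)
    if (e1[j] < best$e1) best <- list(e1 = e1[j], alpha = a, beta = betas[j])
    ## best grid point per distinct assignment vector
    keys <- do.call(paste, c(as.data.frame(cn_mat), sep = ","))
    for (key in unique(keys)) {
      jj <- which(keys == key)
      jbest <- jj[which.min(e1[jj])]
      cur <- by_assignment[[key]]
      if (is.null(cur) || e1[jbest] < cur[1L])
        by_assignment[[key]] <- c(e1[jbest], a, betas[jbest])
    }
  }
  cand <- do.call(rbind, as.list(by_assignment))
  cand <- data.frame(e1 = cand[, 1L], alpha = cand[, 2L], beta = cand[, 3L])
  cand <- cand[order(cand$e1, cand$alpha, cand$beta), c("alpha", "beta", "e1")]
  rownames(cand) <- NULL

  lm <- log_mix_vector(best$alpha, cal)
  target <- log_t - log(best$beta)
  assigned <- ifelse(anchored, peaks$anchored_cn, nearest_cn(target, lm))
  list(alpha = best$alpha, beta = best$beta, e1 = best$e1,
       assigned_cn = as.integer(assigned), mode = mode, candidates = cand)
}
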