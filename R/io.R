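## Readers and writers for the tab-delimited dialects the tool consumes and
## emits, plus the top-level calling workflow.  Input positions are 1-based;
## BED-like segment output is 0-based half-open; per-probe output keeps the
## 1-based input positions.

`%||%` <- function(a, b) if (is.null(a)) b else a

read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop("file ", path, ", column ", cc, ": non-numeric value at row ", bad[1L])
    df[[cc]] <- v
  }
  df
}

#' Read a quartet-level probe-intensity table
#'
#' Tab-delimited with header `snp_id, sample_id, chrom, pos, quartet,
#' allele, pm, mm, amplicon_size, subarray` (an optional `amplicon_id`
#' column identifies multi-SNP amplicons).  Duplicate
#' (snp, sample, quartet, allele) keys are an error.
#'
#' @param path file path.
#' @return data.frame of validated records.
#' @export
read_probe_table <- function(path) {
  df <- read_tsv_checked(path,
    required = c("snp_id", "sample_id", "chrom", "pos", "quartet", "allele",
                 "pm", "mm", "amplicon_size", "subarray"),
    numeric_cols = c("pos", "quartet", "pm", "mm", "amplicon_size"))
  if (any(df$pm < 0, na.rm = TRUE) || any(df$mm < 0, na.rm = TRUE))
    stop("negative PM/MM intensities in ", path)
  key <- paste(df$snp_id, df$sample_id, df$quartet, df$allele)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (snp, sample, quartet, allele) key at row ", dup[1L],
         ": ", key[dup[1L]])
  if (!all(df$allele %in% c("A", "B"))) stop("allele must be A or B")
  df
}

#' Read a genotype annotation table
#'
#' Tab-delimited `snp_id, sample_id, genotype` with genotype in
#' AA/AB/BB/NC.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_genotype_table <- function(path) {
  df <- read_tsv_checked(path, required = c("snp_id", "sample_id", "genotype"))
  bad <- which(!df$genotype %in% c("AA", "AB", "BB", "NC"))
  if (length(bad)) stop("invalid genotype at row ", bad[1L], ": ", df$genotype[bad[1L]])
  dup <- which(duplicated(paste(df$snp_id, df$sample_id)))
  if (length(dup)) stop("duplicated (snp, sample) key at row ", dup[1L])
  df
}

#' Read a per-probe signal table
#'
#' Tab-delimited with header `snp_id` (or `probe_id`), `chrom`, `pos`,
#' `signal`.  Alternatively a two-channel table with `test` and `reference`
#' columns (vendor-processed two-color output) is accepted; the signal is
#' then computed as `2 * test / reference`, putting the diploid state at 2.
#'
#' @param path file path.
#' @return data.frame `snp_id`, `chrom`, `pos`, `signal` ordered by
#'   chromosome and position.  If the file carried two-channel columns the
#'   attribute `agilent` is set to `TRUE`.
#' @export
read_signal_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if ("probe_id" %in% names(df) && !"snp_id" %in% names(df))
    names(df)[names(df) == "probe_id"] <- "snp_id"
  two_channel <- all(c("test", "reference") %in% names(df))
  if (two_channel) df$signal <- 2 * df$test / df$reference
  df <- read_tsv_checked_df(df, path, c("snp_id", "chrom", "pos", "signal"),
                            c("pos", "signal"))
  dup <- which(duplicated(df$snp_id))
  if (length(dup)) stop("duplicated snp_id at row ", dup[1L])
  df <- df[order(df$chrom, df$pos), c("snp_id", "chrom", "pos", "signal")]
  rownames(df) <- NULL
  attr(df, "agilent") <- two_channel
  df
}

read_tsv_checked_df <- function(df, path, required, numeric_cols) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop("file ", path, ", column ", cc, ": non-numeric value at row ", bad[1L])
    df[[cc]] <- v
  }
  df
}

#' Write tables in the package's TSV dialects
#'
#' `write_signal_table` writes `snp_id, chrom, pos, signal` (1-based
#' positions).  `write_probe_cn` writes `snp_id, chrom, pos, signal, cn`.
#' `write_segments_bed` writes `chrom, start, end, cn, n_probes,
#' mean_signal` with 0-based half-open coordinates.
#'
#' @param x the object to write (signal data.frame, probe data.frame, or a
#'   `cn_segmentation`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(x, path) {
  utils::write.table(x[, c("snp_id", "chrom", "pos", "signal")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_table
#' @export
write_probe_cn <- function(x, path) {
  if (inherits(x, "cn_segmentation")) x <- x$probes
  utils::write.table(x[, c("snp_id", "chrom", "pos", "signal", "cn")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_table
#' @export
write_segments_bed <- function(x, path) {
  if (inherits(x, "cn_segmentation")) x <- x$segments
  bed <- data.frame(chrom = x$chrom, start = x$start_pos - 1L,
                    end = x$end_pos, cn = x$cn, n_probes = x$n_probes,
                    mean_signal = x$mean_signal)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like segment table back
#' @param path file path.
#' @return data.frame with 1-based inclusive `start_pos` / `end_pos`.
#' @export
read_segments_bed <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "cn", "n_probes"),
                         c("start", "end", "cn", "n_probes", "mean_signal"))
  data.frame(chrom = df$chrom, start_pos = df$start + 1L, end_pos = df$end,
             cn = as.integer(df$cn), n_probes = as.integer(df$n_probes),
             mean_signal = df$mean_signal)
}

#' Run configuration with the method's default constants
#'
#' @param mode sample mode.
#' @param window smoothing window (probes).
#' @param bin histogram bin width.
#' @param call_rate_min,het_min,height_ratio peak-anchoring thresholds.
#' @param sigma2_cutoff panel-variance QC cutoff.
#' @param alpha_step,beta_step fitting grid resolutions.
#' @param break_penalty HMM break penalty `-ln(gamma)`.
#' @param max_cn largest copy number.
#' @param min_peak_height flagging threshold for small peaks.
#' @param contamination_adjust if `FALSE`, force `alpha = 0` (exposes the
#'   failure mode that motivates the contamination adjustment).
#' @param seed RNG seed recorded in reports.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = "tumor", window = 101L, bin = 0.1,
                       call_rate_min = 60, het_min = 3, height_ratio = 2,
                       sigma2_cutoff = 0.25, alpha_step = 0.01,
                       beta_step = 0.005, break_penalty = 54, max_cn = 70L,
                       min_peak_height = 2e-4, contamination_adjust = TRUE,
                       n_restarts = 3L, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Full copy-number calling workflow on a signal table
#'
#' Smooths the signal, finds and anchors histogram peaks, fits
#' `(alpha, beta)` by grid enumeration, decodes the integer copy-number
#' path per chromosome, and refines the model until convergence.  With
#' `annotations = NULL` (or in `agilent` mode) the genotype-based anchoring
#' rules are disabled.
#'
#' @param signals data.frame `snp_id`, `chrom`, `pos`, `signal`.
#' @param config a [run_config()].
#' @param annotations optional genotype annotation data.frame (`snp_id`,
#'   `genotype`) for this sample.
#' @param cal a [signal_calibration()].
#' @param output_dir if given, the segment BED, per-probe table and model
#'   JSON are written there.
#' @param prefix file-name prefix for outputs.
#' @return A `cn_segmentation` (see [refine_cn()]); the peak report is
#'   attached as attribute `peaks`.
#' @export
run_call_pipeline <- function(signals, config = run_config(),
                              annotations = NULL, cal = signal_calibration(),
                              output_dir = NULL, prefix = "sample") {
  mode <- config$mode
  sm <- smooth_signal(signals, window = config$window)
  peaks <- find_signal_peaks(sm, bin = config$bin,
                             min_height = config$min_peak_height,
                             annotations = annotations)
  if (nrow(peaks) == 0L)
    stop("peak detection found no histogram maxima; signal track is flat or empty")
  peaks <- anchor_peaks(peaks, mode = mode,
                        call_rate_min = config$call_rate_min,
                        het_min = config$het_min,
                        height_ratio = config$height_ratio)
  fit_mode <- if (!config$contamination_adjust && mode %in% c("tumor", "agilent"))
    "cell_line" else mode
  fit <- fit_alpha_beta(peaks, cal = cal, mode = fit_mode,
                        alpha_step = config$alpha_step,
                        beta_step = config$beta_step)
  hc <- hmm_config(max_cn = config$max_cn, break_penalty = config$break_penalty,
                   alpha_step = config$alpha_step, beta_step = config$beta_step)
  ## refine from the best few E1 basins (distinct peak assignments) and let
  ## the full-likelihood residual E2 arbitrate; peak positions from a binned
  ## histogram can make a wrong assignment look marginally better in E1
  n_restarts <- max(1L, config$n_restarts %||% 1L)
  cand <- utils::head(fit$candidates, n_restarts)
  seg <- NULL
  for (i in seq_len(nrow(cand))) {
    init <- sample_model(alpha = cand$alpha[i], beta = cand$beta[i],
                         mode = fit_mode)
    s <- refine_cn(signals, init, cal = cal, config = hc,
                   window = config$window)
    if (is.null(seg) || s$e2 < seg$e2 - 1e-12) seg <- s
  }
  peaks$assigned_cn <- fit$assigned_cn
  attr(seg, "peaks") <- peaks
  attr(seg, "initial_fit") <- fit

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_segments_bed(seg, file.path(output_dir, paste0(prefix, "_segments.bed")))
    write_probe_cn(seg, file.path(output_dir, paste0(prefix, "_probes.tsv")))
    report <- list(mode = mode, alpha = seg$model$alpha, beta = seg$model$beta,
                   sigma2 = seg$model$sigma2, e2 = seg$e2,
                   iterations = seg$iterations, converged = seg$converged,
                   seed = config$seed,
                   peaks = peaks)
    jsonlite::write_json(report, file.path(output_dir, paste0(prefix, "_model.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  seg
}
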