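#' Signal-to-copy-number calibration
#'
#' Encodes the expected normalized signal intensity `S0(c)` as a function of
#' integer copy number `c`.  The response is tabulated for low copy numbers
#' (where it was measured on samples of known karyotype), continues linearly
#' for high copy numbers (where it was calibrated against qPCR), and is
#' bridged by two interpolated knots at c = 6, 7 where no direct measurement
#' exists.
#'
#' The default table anchors are 0.36, 1.14, 2.0, 2.72, 3.41 and 4.1 for
#' c = 0..5, with linear regime `0.314 * c + 3.41` for c >= 8.  Note that
#' `S0(0) > 0`: a homozygous deletion still yields background signal on the
#' array.
#'
#' @param table named or plain numeric vector of length 6, expected signal at
#'   c = 0..5.
#' @param slope,intercept coefficients of the linear regime used for c >= 8.
#' @param knots expected signal at c = 6 and 7.  Default: linear interpolation
#'   between `table[6]` (c = 5) and the linear-regime value at c = 8, which
#'   keeps the curve monotone and nearly continuous.
#' @param max_cn largest copy number the calibration covers.
#' @return An object of class `signal_calibration`.
#' @examples
#' cal <- signal_calibration()
#' expected_signal_s0(0:5, cal)
#' @export
signal_calibration <- function(table = c(0.36, 1.14, 2.0, 2.72, 3.41, 4.1),
                               slope = 0.314, intercept = 3.41,
                               knots = NULL, max_cn = 70L) {
  stopifnot(length(table) == 6L, is.numeric(table),
            is.numeric(slope), is.numeric(intercept), max_cn >= 8L)
  table <- unname(as.numeric(table))
  if (is.null(knots)) {
    s8 <- slope * 8 + intercept
    knots <- table[6L] + (s8 - table[6L]) * c(1, 2) / 3
  }
  stopifnot(length(knots) == 2L)
  cal <- structure(list(table = table, slope = slope, intercept = intercept,
                        knots = unname(as.numeric(knots)),
                        max_cn = as.integer(max_cn)),
                   class = "signal_calibration")
  s0 <- s0_vector(cal)
  if (any(diff(s0) <= 0))
    stop("calibration is not strictly increasing in copy number")
  cal
}

#' @export
print.signal_calibration <- function(x, ...) {
  cat("signal_calibration: S0(0..5) =", paste(x$table, collapse = ", "), "\n")
  cat("  knots S0(6,7) =", paste(round(x$knots, 4), collapse = ", "),
      "; S0(c) =", x$slope, "* c +", x$intercept, "for c >= 8\n")
  invisible(x)
}

# S0 for c = 0..max_cn as a plain vector (index c + 1)
s0_vector <- function(cal) {
  c(cal$table, cal$knots, cal$slope * (8:cal$max_cn) + cal$intercept)
}

#' Expected signal at a given copy number, uncontaminated diploid scale
#'
#' @param c integer copy number (vectorized), in `[0, max_cn]`.
#' @param cal a [signal_calibration()].
#' @return Numeric vector of expected signals.
#' @export
expected_signal_s0 <- function(c, cal = signal_calibration()) {
  stopifnot(inherits(cal, "signal_calibration"))
  c <- as.integer(c)
  if (any(is.na(c)) || any(c < 0L) || any(c > cal$max_cn))
    stop("copy number outside [0, ", cal$max_cn, "]")
  s0_vector(cal)[c + 1L]
}

#' Per-sample model: contamination, genome-size factor, residual variance
#'
#' A sample is described by the fraction `alpha` of diploid (benign) DNA it
#' contains, a global rescaling `beta` compensating for the average copy
#' number of an aneuploid genome differing from 2, the residual variance
#' `sigma2` of the log signal, and a mode flag.  `normal` mode fixes
#' `alpha = 0, beta = 1`; `cell_line` mode fixes `alpha = 0` (a cell line has
#' no benign-tissue admixture); `tumor` fits both; `agilent` behaves like
#' `tumor` but disables the genotype-based peak anchoring rules.
#'
#' @param alpha contamination fraction in `[0, 1)`.
#' @param beta genome-size factor in `[0.5, 2]`.
#' @param sigma2 residual variance of the log signal (> 0), or `NA` if not
#'   yet estimated.
#' @param mode one of `"normal"`, `"cell_line"`, `"tumor"`, `"agilent"`.
#' @return An object of class `sample_model`.
#' @export
sample_model <- function(alpha = 0, beta = 1, sigma2 = NA_real_,
                         mode = c("tumor", "normal", "cell_line", "agilent")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha < 1,
            is.numeric(beta), length(beta) == 1L, beta >= 0.5, beta <= 2)
  if (!is.na(sigma2) && sigma2 <= 0) stop("sigma2 must be > 0")
  if (mode == "normal" && (alpha != 0 || beta != 1))
    stop("normal mode requires alpha = 0 and beta = 1")
  if (mode == "cell_line" && alpha != 0)
    stop("cell_line mode requires alpha = 0")
  structure(list(alpha = alpha, beta = beta, sigma2 = sigma2, mode = mode),
            class = "sample_model")
}

#' @export
print.sample_model <- function(x, ...) {
  cat(sprintf("sample_model [%s]: alpha = %.3f, beta = %.4f, sigma2 = %s\n",
              x$mode, x$alpha, x$beta,
              if (is.na(x$sigma2)) "NA" else format(x$sigma2, digits = 4)))
  invisible(x)
}

#' Expected signal under contamination and genome-size adjustment
#'
#' The expected signal for a probe in a region of copy number `c` in a sample
#' with contamination `alpha` and genome-size factor `beta` is
#' `S(c) = beta * (2 * alpha + (1 - alpha) * S0(c))`: the benign fraction
#' contributes diploid signal, the cancer fraction contributes `S0(c)`, and
#' the whole is rescaled by `beta`.
#'
#' @inheritParams expected_signal_s0
#' @param model a [sample_model()], or a list with `alpha` and `beta`.
#' @return Numeric vector of expected signals.
#' @export
expected_signal <- function(c, model, cal = signal_calibration()) {
  model$beta * (2 * model$alpha + (1 - model$alpha) * expected_signal_s0(c, cal))
}

#' Copy number from qPCR threshold cycles
#'
#' Computes `CN = 2 ^ (1 - CTgc + CTrc + CTgr - CTrr)` from the threshold
#' cycles of the assayed gene (g) and a two-copy reference gene (r) in the
#' cell line of interest (c) and in a diploid reference sample (r).  Used to
#' calibrate the high-copy-number end of the signal response.
#'
#' @param ct_gene_cellline,ct_ref_cellline,ct_gene_refsample,ct_ref_refsample
#'   threshold-cycle values (finite, vectorized).
#' @return Estimated copy number (real-valued).
#' @examples
#' qpcr_copy_number(20, 22, 25, 25)  # 8
#' @export
qpcr_copy_number <- function(ct_gene_cellline, ct_ref_cellline,
                             ct_gene_refsample, ct_ref_refsample) {
  ct <- c(ct_gene_cellline, ct_ref_cellline, ct_gene_refsample, ct_ref_refsample)
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  2 ^ (1 - ct_gene_cellline + ct_ref_cellline + ct_gene_refsample - ct_ref_refsample)
}

#' Read / write a calibration as JSON
#'
#' @param cal a [signal_calibration()].
#' @param path file path.
#' @return `read_calibration_json` returns a `signal_calibration`;
#'   `write_calibration_json` returns `path` invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "signal_calibration"))
  jsonlite::write_json(list(table = cal$table, slope = cal$slope,
                            intercept = cal$intercept, knots = cal$knots,
                            max_cn = cal$max_cn),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  signal_calibration(table = x$table, slope = x$slope, intercept = x$intercept,
                     knots = x$knots, max_cn = x$max_cn)
}
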