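## Integer copy-number segmentation: joint maximum-a-posteriori path
## decoding under a hidden Markov model whose states are copy numbers
## 0..max_cn, with Gaussian log-signal emissions around log S(c) and a
## uniform break penalty for every change of state, followed by iterative
## refinement of (alpha, beta, sigma^2).

#' HMM configuration
#'
#' @param max_cn largest copy number considered (default 70).
#' @param break_penalty cost `-ln(gamma)` of changing copy number between
#'   adjacent probes (default 54); `gamma` is the prior probability that
#'   adjacent probes differ in copy number.
#' @param eps signal floor applied before logs.
#' @param max_iter maximum refinement iterations.
#' @param alpha_step,beta_step grid resolutions for the E2 minimization.
#' @return list of class `hmm_config`.
#' @export
hmm_config <- function(max_cn = 70L, break_penalty = 54, eps = 0.01,
                       max_iter = 20L, alpha_step = 0.01, beta_step = 0.005) {
  stopifnot(max_cn >= 2L, break_penalty > 0)
  structure(list(max_cn = as.integer(max_cn), break_penalty = break_penalty,
                 eps = eps, max_iter = as.integer(max_iter),
                 alpha_step = alpha_step, beta_step = beta_step),
            class = "hmm_config")
}

#' Most likely copy-number path for one chromosome
#'
#' Maximizes the path likelihood whose log equals (up to a constant)
#' `-sum_i (log S_i - log S(c_i))^2 / (2 sigma^2) - lambda * #changes`,
#' with `lambda` the break penalty, by dynamic programming over states
#' 0..`max_cn`.  Deterministic: cost ties prefer staying in the current
#' state, and the final state ties resolve to the smaller copy number.
#'
#' @param signal numeric vector of per-probe signals, ordered by position,
#'   for a single chromosome.
#' @param model a [sample_model()] with `sigma2` set.
#' @param cal a [signal_calibration()].
#' @param config an [hmm_config()].
#' @return Integer vector of copy numbers, one per probe.
#' @export
decode_cn_path <- function(signal, model, cal = signal_calibration(),
                           config = hmm_config()) {
  if (is.na(model$sigma2) || model$sigma2 <= 0) stop("sigma2 must be > 0")
  n <- length(signal)
  if (n == 0L) return(integer(0))
  ns <- config$max_cn + 1L
  lam <- config$break_penalty
  log_s <- log(pmax(signal, config$eps))
  log_mu <- log(pmax(expected_signal(0:config$max_cn, model, cal), config$eps))
  ## emission cost matrix: states x probes
  emis <- outer(log_mu, log_s, function(m, s) (s - m)^2) / (2 * model$sigma2)

  ptr <- matrix(0L, ns, n)
  cost <- emis[, 1L]
  ptr[, 1L] <- seq_len(ns)
  if (n > 1L) for (t in 2:n) {
    b <- which.min(cost)          # smallest index on ties
    jump <- cost[b] + lam
    stay <- cost <= jump          # ties prefer staying (no spurious breaks)
    ptr[, t] <- ifelse(stay, seq_len(ns), b)
    cost <- ifelse(stay, cost, jump) + emis[, t]
  }
  path <- integer(n)
  path[n] <- which.min(cost)      # ties -> smaller CN
  if (n > 1L) for (t in n:2) path[t - 1L] <- ptr[path[t], t]
  path - 1L
}

#' Mean squared log-residual of a copy-number path
#'
#' `E2(alpha, beta) = (1/N) * sum_i (log S_i - log S(c_i))^2` for a fixed
#' path; this is both the objective refined over (alpha, beta) and the
#' estimator of the emission variance `sigma^2`.
#'
#' @param signal per-probe signals.
#' @param path integer copy-number path of the same length.
#' @param alpha,beta model parameters at which to evaluate.
#' @param cal a [signal_calibration()].
#' @param eps signal floor.
#' @return The mean squared log-residual (a single number).
#' @export
estimate_e2 <- function(signal, path, alpha, beta, cal = signal_calibration(),
                        eps = 0.01) {
  stopifnot(length(signal) == length(path), length(signal) > 0L)
  mu <- beta * (2 * alpha + (1 - alpha) * expected_signal_s0(path, cal))
  mean((log(pmax(signal, eps)) - log(pmax(mu, eps)))^2)
}

# grid minimization of E2 with the path fixed, using per-copy-number
# sufficient statistics so the grid scan is O(grid x distinct CNs)
minimize_e2_grid <- function(signal, path, cal, mode, config) {
  log_s <- log(pmax(signal, config$eps))
  n <- length(signal)
  cs <- sort(unique(path))
  stats <- vapply(cs, function(cc) {
    v <- log_s[path == cc]
    c(length(v), sum(v), sum(v^2))
  }, numeric(3))
  n_c <- stats[1L, ]; s_c <- stats[2L, ]; ss_c <- stats[3L, ]
  s0c <- expected_signal_s0(cs, cal)

  alphas <- if (mode %in% c("normal", "cell_line")) 0
            else seq(0, 0.99, by = config$alpha_step)
  betas <- if (mode == "normal") 1 else seq(0.5, 2, by = config$beta_step)
  log_b <- log(betas)
  best <- list(e2 = Inf, alpha = NA_real_, beta = NA_real_)
  for (a in alphas) {
    lmix <- log(pmax(2 * a + (1 - a) * s0c, config$eps))  # length(cs)
    ## E2(beta) = (1/n) sum_c [ ss_c - 2 L_c s_c + n_c L_c^2 ], L_c = log_b + lmix_c
    lb2 <- outer(log_b, lmix, `+`)                         # betas x cs
    e2 <- (sum(ss_c) - 2 * (lb2 %*% s_c) + (lb2^2 %*% n_c)) / n
    j <- which.min(e2)
    if (e2[j] < best$e2) best <- list(e2 = e2[j], alpha = a, beta = betas[j])
  }
  best
}

# initial sigma^2: residuals of the raw log signal around the expected
# signal of the copy number nearest to each probe's smoothed level
initial_sigma2 <- function(signal, smoothed, alpha, beta, cal,
                           eps = 0.01, floor = 1e-4) {
  lm <- log(beta) + log_mix_vector(alpha, cal, eps)
  cn <- nearest_cn(log(pmax(smoothed, eps)), lm)
  max(mean((log(pmax(signal, eps)) - lm[cn + 1L])^2), floor)
}

#' Decode and iteratively refine a sample's copy-number profile
#'
#' Alternates (a) per-chromosome maximum-a-posteriori decoding at the
#' current `(alpha, beta, sigma^2)`, (b) grid minimization of the mean
#' squared log-residual E2 over `(alpha, beta)` with the path fixed, and
#' (c) updating `sigma^2 = E2`, until the change in `alpha` is below 0.03
#' (absolute) and the relative change in `beta` is below 0.001, or
#' `max_iter` is reached.  If an `(alpha, beta)` pair recurs without
#' convergence the best-E2 iterate is returned with `converged = FALSE`.
#' `normal`-mode samples are decoded once with `alpha = 0, beta = 1`.
#' After convergence the path is re-decoded once at the final parameters.
#'
#' @param signals data.frame `snp_id` (optional), `chrom`, `pos`, `signal`.
#' @param init a [sample_model()] giving the starting `(alpha, beta)`
#'   (e.g. from [fit_alpha_beta()]); `sigma2` may be `NA`, in which case it
#'   is initialized from the smoothed track.
#' @param cal a [signal_calibration()].
#' @param config an [hmm_config()].
#' @param window smoothing window used only for the `sigma^2` initialization.
#' @return An object of class `cn_segmentation`: list with `probes` (the
#'   input plus a `cn` column), `segments` (per-segment table with 1-based
#'   inclusive `start_pos` / `end_pos`), `model` (final [sample_model()]),
#'   `e2`, `iterations`, `converged`.
#' @export
refine_cn <- function(signals, init, cal = signal_calibration(),
                      config = hmm_config(), window = 101L) {
  signals <- as.data.frame(signals)
  stopifnot(all(c("chrom", "pos", "signal") %in% names(signals)))
  signals <- signals[order(signals$chrom, signals$pos), , drop = FALSE]
  mode <- init$mode
  alpha <- init$alpha; beta <- init$beta
  sigma2 <- init$sigma2
  if (is.na(sigma2)) {
    sm <- smooth_signal(signals, window = window, eps = config$eps)
    sigma2 <- initial_sigma2(sm$signal, sm$smoothed, alpha, beta, cal, config$eps)
  }

  decode_all <- function(alpha, beta, sigma2) {
    m <- list(alpha = alpha, beta = beta, sigma2 = sigma2)
    unlist(lapply(split(signals$signal, signals$chrom, drop = TRUE),
                  decode_cn_path, model = m, cal = cal, config = config),
           use.names = FALSE)
  }

  iterations <- 0L
  converged <- (mode == "normal")
  seen <- character(0)
  best <- list(e2 = Inf)
  trace <- list()
  path <- decode_all(alpha, beta, sigma2)
  if (mode != "normal") {
    repeat {
      iterations <- iterations + 1L
      opt <- minimize_e2_grid(signals$signal, path, cal, mode, config)
      trace[[iterations]] <- data.frame(iteration = iterations,
                                        alpha = opt$alpha, beta = opt$beta,
                                        e2 = as.numeric(opt$e2))
      d_alpha <- abs(opt$alpha - alpha)
      d_beta <- abs(opt$beta - beta) / beta
      if (opt$e2 < best$e2)
        best <- list(e2 = opt$e2, alpha = opt$alpha, beta = opt$beta,
                     sigma2 = max(opt$e2, 1e-4), path = path)
      alpha <- opt$alpha; beta <- opt$beta
      sigma2 <- max(opt$e2, 1e-4)
      if (d_alpha < 0.03 && d_beta < 0.001) { converged <- TRUE; break }
      key <- paste(alpha, beta)
      if (key %in% seen) { converged <- FALSE; break }  # oscillation
      seen <- c(seen, key)
      if (iterations >= config$max_iter) { converged <- FALSE; break }
      path <- decode_all(alpha, beta, sigma2)
    }
    if (!converged && is.finite(best$e2)) {
      alpha <- best$alpha; beta <- best$beta; sigma2 <- best$sigma2
    }
    path <- decode_all(alpha, beta, sigma2)
  }
  e2 <- estimate_e2(signals$signal, path, alpha, beta, cal, config$eps)

  probes <- signals
  probes$cn <- path
  model <- sample_model(alpha = alpha, beta = beta,
                        sigma2 = max(e2, 1e-4), mode = mode)
  structure(list(probes = probes, segments = path_to_segments(probes),
                 model = model, e2 = e2, iterations = iterations,
                 converged = converged,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(iteration = integer(0),
                                         alpha = numeric(0), beta = numeric(0),
                                         e2 = numeric(0))),
            class = "cn_segmentation")
}

#' @export
print.cn_segmentation <- function(x, ...) {
  cat(sprintf("cn_segmentation: %d probes, %d segments; alpha = %.2f, beta = %.3f, sigma2 = %.4g; %d iteration(s), converged = %s\n",
              nrow(x$probes), nrow(x$segments), x$model$alpha, x$model$beta,
              x$model$sigma2, x$iterations, x$converged))
  invisible(x)
}

#' Collapse a per-probe copy-number path into segments
#'
#' @param probes data.frame with `chrom`, `pos`, `cn` (and optionally
#'   `signal`), ordered by chromosome and position.
#' @return data.frame `chrom`, `start_pos`, `end_pos` (1-based, inclusive,
#'   probe positions), `cn`, `n_probes`, `mean_signal`.  Segments partition
#'   each chromosome's probes and adjacent segments differ in `cn`.
#' @export
path_to_segments <- function(probes) {
  probes <- as.data.frame(probes)
  out <- lapply(split(probes, probes$chrom, drop = TRUE), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    r <- rle(d$cn)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    data.frame(chrom = d$chrom[1L], start_pos = d$pos[lo], end_pos = d$pos[hi],
               cn = r$values, n_probes = r$lengths,
               mean_signal = if ("signal" %in% names(d))
                 vapply(seq_along(lo), function(i) mean(d$signal[lo[i]:hi[i]]),
                        numeric(1)) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
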