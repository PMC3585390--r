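#' Photobleaching correction
#'
#' Dye bleaching produces a slow multiplicative decay of fluorescence. Each
#' trace is divided by a per-cell drift curve
#' \deqn{d(t) = c_0 + c_1 t + c_2 e^{-t/\tau},}
#' a combination of a linear and an exponential component, fitted by least
#' squares to the baseline (LG1 and LG2) samples only, so the glucose
#' response cannot be absorbed into the drift. The fit is linear in
#' `c0, c1, c2` for fixed `tau`; `tau` is profiled over a log-spaced grid and
#' refined by golden-section search, which is deterministic and always
#' converges. The trace is divided by `d(t)/d(0)`, preserving the initial
#' fluorescence level. If the fitted drift is non-positive anywhere, the fit
#' falls back to linear-only (and, failing that, to no correction), and the
#' affected cells are recorded in `flags$bleach_fallback`.
#'
#' @param traces a raw-stage [trace_set()].
#' @param schedule a [regime_schedule()] providing the LG1 and LG2 windows.
#' @param baseline_regimes regimes treated as response-free baseline.
#' @return A corrected [trace_set()], still at stage `"raw"`.
#' @export
correct_bleaching <- function(traces, schedule,
                              baseline_regimes = c("LG1", "LG2")) {
  stopifnot(inherits(traces, "trace_set"))
  if (traces$stage != "raw")
    stop("correct_bleaching expects stage 'raw'")
  mask <- rep(FALSE, length(traces$times))
  for (rg in baseline_regimes) {
    iv <- schedule_interval(schedule, rg)
    mask <- mask | (traces$times >= iv[1L] & traces$times < iv[2L])
  }
  if (sum(mask) < 5L) stop("too few baseline frames for the drift fit")
  tb <- traces$times[mask]
  tall <- traces$times

  fit_tau <- function(f, tau) {
    X <- cbind(1, tb, exp(-tb / tau))
    cf <- stats::lm.fit(X, f)$coefficients
    cf[is.na(cf)] <- 0
    resid <- f - X %*% cf
    list(coef = cf, sse = sum(resid^2))
  }

  vals <- traces$values
  out <- vals
  fallback <- character(0)
  tau_grid <- exp(seq(log(30), log(3000), length.out = 25L))
  for (i in seq_len(nrow(vals))) {
    f <- vals[i, ]
    if (anyNA(f) || any(!is.finite(f)))
      stop(sprintf("trace '%s' contains NaN/non-finite frames",
                   rownames(vals)[i]))
    fb <- f[mask]
    sse <- vapply(tau_grid, function(tau) fit_tau(fb, tau)$sse, numeric(1L))
    k <- which.min(sse)
    lo <- tau_grid[max(1L, k - 1L)]
    hi <- tau_grid[min(length(tau_grid), k + 1L)]
    tau <- stats::optimize(function(tau) fit_tau(fb, tau)$sse,
                           lower = lo, upper = hi)$minimum
    cf <- fit_tau(fb, tau)$coef
    d <- cf[1L] + cf[2L] * tall + cf[3L] * exp(-tall / tau)
    if (any(d <= 0)) {
      lin <- stats::lm.fit(cbind(1, tb), fb)$coefficients
      d <- lin[1L] + lin[2L] * tall
      fallback <- c(fallback, rownames(vals)[i])
      if (any(d <= 0)) d <- rep(1, length(tall))  # leave uncorrected
    }
    out[i, ] <- f / (d / d[1L])
  }
  flags <- traces$flags
  if (length(fallback)) flags$bleach_fallback <- fallback
  trace_set(traces$times, out, frame_rate_hz = traces$frame_rate_hz,
            stage = "raw", flags = flags)
}

#' F/F0 normalization
#'
#' Divides each trace by its initial fluorescence level `F0`, the per-cell
#' mean over `f0_window_s` (by default the first 60 s of the recording, well
#' inside the pre-stimulation low-glucose regime).
#'
#' @param traces a raw-stage (optionally bleach-corrected) [trace_set()].
#' @param f0_window_s numeric length-2 window `[start, end)` in seconds.
#' @return A [trace_set()] at stage `"f_over_f0"`.
#' @export
f_over_f0 <- function(traces, f0_window_s = c(0, 60)) {
  stopifnot(inherits(traces, "trace_set"))
  if (traces$stage != "raw")
    stop("f_over_f0 expects stage 'raw' (optionally bleach-corrected)")
  sel <- traces$times >= f0_window_s[1L] & traces$times < f0_window_s[2L]
  if (!any(sel)) stop("F0 window contains no frames")
  f0 <- rowMeans(traces$values[, sel, drop = FALSE])
  if (any(f0 <= 0))
    stop(sprintf("nonpositive F0 for cell(s): %s",
                 paste(cell_ids(traces)[f0 <= 0], collapse = ", ")))
  trace_set(traces$times, traces$values / f0,
            frame_rate_hz = traces$frame_rate_hz, stage = "f_over_f0",
            flags = traces$flags)
}

#' Rescale each trace to the unit interval
#'
#' Applies `(x - min) / (max - min)` per cell. Pearson correlations are
#' invariant under this affine map, so downstream network results are
#' unchanged; rescaling only standardizes plotting and thresholds. Constant
#' traces are mapped to all zeros and listed in `flags$constant_cells`.
#'
#' @param traces a [trace_set()].
#' @return A [trace_set()] at stage `"unit"`.
#' @export
rescale_unit <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  if (any(!is.finite(traces$values))) stop("traces must be finite")
  rng_min <- apply(traces$values, 1L, min)
  rng_max <- apply(traces$values, 1L, max)
  span <- rng_max - rng_min
  const <- span == 0
  span[const] <- 1
  out <- (traces$values - rng_min) / span
  out[const, ] <- 0
  flags <- traces$flags
  if (any(const)) flags$constant_cells <- cell_ids(traces)[const]
  trace_set(traces$times, out, frame_rate_hz = traces$frame_rate_hz,
            stage = "unit", flags = flags)
}

#' Default cell-classification criteria
#'
#' @param hg_rise_factor the HG mean must exceed the LG1 mean by at least
#'   this factor for a beta call.
#' @param lg_return_band relative band around the LG1 mean within which the
#'   LG2 mean must return (reversibility).
#' @param osc_m multiplier of the noise scale defining an oscillation
#'   excursion in LG1.
#' @param osc_score_max maximal tolerated fraction of LG1 frames beyond the
#'   excursion bound for a non-oscillating call.
#' @return A named list of thresholds.
#' @export
classification_criteria <- function(hg_rise_factor = 1.2,
                                    lg_return_band = 0.2,
                                    osc_m = 3,
                                    osc_score_max = 0.05) {
  list(hg_rise_factor = hg_rise_factor, lg_return_band = lg_return_band,
       osc_m = osc_m, osc_score_max = osc_score_max)
}

# Fraction of frames deviating beyond m x (robust noise scale) from a
# linearly detrended segment. The noise scale comes from first differences
# (MAD(diff)/sqrt(2)), so slow oscillations do not inflate it.
oscillation_score <- function(x, t, m) {
  resid <- stats::lm.fit(cbind(1, t), x)$residuals
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (sigma == 0) return(ifelse(any(resid != 0), 1, 0))
  mean(abs(resid) > m * sigma)
}

#' Classify cells by their glucose-response phenotype
#'
#' Beta cells are identified by the canonical response signature: a quiet
#' baseline in low glucose, a sustained rise under high glucose, and a return
#' to the pre-stimulation level afterwards. A cell is labelled `beta` iff
#' (i) its LG1 oscillation score is at most `osc_score_max`, (ii) its HG mean
#' exceeds its LG1 mean by `hg_rise_factor`, and (iii) its LG2 mean returns
#' to within `lg_return_band` of the LG1 mean. Cells failing (i) — i.e.
#' oscillating in low glucose, characteristic of alpha/delta cells at the
#' islet periphery — are labelled `non_beta`; remaining cells are
#' `unresponsive`.
#'
#' @param traces a [trace_set()] at stage `"f_over_f0"` or `"unit"`.
#' @param schedule a [regime_schedule()] naming LG1, HG, LG2.
#' @param criteria a [classification_criteria()] list.
#' @return A named character vector (one of `"beta"`, `"non_beta"`,
#'   `"unresponsive"` per cell).
#' @export
classify_cells <- function(traces, schedule,
                           criteria = classification_criteria()) {
  stopifnot(inherits(traces, "trace_set"))
  if (!traces$stage %in% c("f_over_f0", "unit"))
    stop("classify_cells expects stage 'f_over_f0' or 'unit'")
  lg1 <- segment_regime(traces, schedule, "LG1")
  hg <- segment_regime(traces, schedule, "HG")
  lg2 <- segment_regime(traces, schedule, "LG2")
  labels <- character(n_cells(traces))
  for (i in seq_len(n_cells(traces))) {
    osc <- oscillation_score(lg1$values[i, ], lg1$times, criteria$osc_m)
    m_lg1 <- mean(lg1$values[i, ])
    m_hg <- mean(hg$values[i, ])
    m_lg2 <- mean(lg2$values[i, ])
    quiet <- osc <= criteria$osc_score_max
    rises <- m_hg > criteria$hg_rise_factor * m_lg1
    returns <- abs(m_lg2 - m_lg1) <= criteria$lg_return_band * abs(m_lg1)
    labels[i] <- if (quiet && rises && returns) "beta"
    else if (!quiet) "non_beta"
    else "unresponsive"
  }
  stats::setNames(labels, cell_ids(traces))
}
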