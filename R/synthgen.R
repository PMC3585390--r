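#' Simulation parameters for a synthetic islet recording
#'
#' Bundles every knob of the synthetic generator. The defaults reproduce the
#' acquisition and protocol conditions the analysis expects: 0.5 Hz imaging
#' over a 1800-s recording, a 20-µm beta-cell diameter, glucose activation
#' with per-cell onset delays of up to a few tens of seconds, a high-glucose
#' plateau carrying slow oscillations whose per-cell phases lag behind a
#' traveling calcium wave, spatially coherent local fluctuations that make
#' nearby cells more alike than remote ones, multiplicative photobleaching
#' drift (linear plus exponential), and i.i.d. Gaussian imaging noise.
#'
#' All amplitudes are expressed as fractions of a cell's baseline
#' fluorescence; each cell draws its own absolute baseline `F0` from
#' `f0_range` (several-fold loading differences do not affect time profiles).
#'
#' @param n_cells number of cells (>= 3).
#' @param cell_diameter_um typical beta-cell diameter in µm.
#' @param frame_rate_hz image acquisition rate in Hz.
#' @param schedule a [regime_schedule()]; also fixes total duration.
#' @param osc_period_s period of the plateau calcium oscillations in seconds.
#' @param wave_speed_um_s calcium-wave speed in µm/s; `NULL` samples one
#'   speed per realization log-uniformly from `wave_speed_range`, `Inf`
#'   gives zero phase lag everywhere.
#' @param wave_speed_range range (µm/s) of the log-uniform wave-speed draw.
#' @param onset_delay_max_s maximal per-cell activation delay (s).
#' @param offset_delay_max_s maximal per-cell deactivation delay (s);
#'   deactivation lags are shorter than activation lags.
#' @param rise_dur_s,fall_dur_s durations of the sigmoidal activation rise
#'   and deactivation fall (s); the smoothstep gate is exactly 0 before a
#'   cell's onset and exactly 1 once the rise completes.
#' @param plateau_amp plateau elevation over baseline (fraction of baseline).
#' @param osc_amp amplitude of the plateau oscillation.
#' @param field_amp amplitude of the spatially coherent plateau fluctuations.
#' @param field_scale_um spatial correlation length of those fluctuations.
#' @param field_tau_s temporal correlation time of those fluctuations.
#' @param shared_amp amplitude of the islet-wide slow fluctuation present in
#'   all regimes (weighted per cell by a uniform draw on `shared_weight_range`).
#' @param shared_weight_range per-cell weight range of the shared fluctuation.
#' @param shared_tau_s correlation time of the shared fluctuation (s).
#' @param noise_sd standard deviation of the additive per-cell imaging noise.
#' @param common_noise_sd standard deviation of the frame-wide common-mode
#'   intensity fluctuation (illumination/focus jitter shared by all ROIs,
#'   spectrally flat); each cell couples to it with its own gain drawn from
#'   `common_gain_range`. This is what gives baseline (low-glucose) frames
#'   their residual pairwise correlation.
#' @param common_gain_range per-cell gain range on the common-mode noise.
#' @param common_gain_power skew of the gain draw: `g = lo + (hi - lo) u^power`
#'   with `u` uniform, so most cells couple weakly and a few strongly.
#' @param bleach_linear linear bleaching rate (1/s).
#' @param bleach_exp_amp amplitude of the exponential bleaching component.
#' @param bleach_exp_tau_s time constant of the exponential component (s).
#' @param nonbeta_fraction fraction of cells that are non-beta (placed in the
#'   outermost annulus; they oscillate in low glucose and ignore the stimulus).
#' @param nonbeta_osc_amp,nonbeta_period_s amplitude and period of the
#'   non-beta low-glucose oscillations.
#' @param f0_range range of per-cell baseline fluorescence (arbitrary units).
#' @param islet_radius_um islet cross-section radius; `NULL` (default) picks
#'   `cell_diameter_um * sqrt(n_cells / 2)`, leaving the mean
#'   nearest-neighbour spacing close to one cell diameter.
#' @param seed integer seed; identical parameters (including the seed) give
#'   bit-identical geometries and traces.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_cells = 140,
                       cell_diameter_um = 20,
                       frame_rate_hz = 0.5,
                       schedule = default_schedule(),
                       osc_period_s = 40,
                       wave_speed_um_s = NULL,
                       wave_speed_range = c(20, 200),
                       onset_delay_max_s = 30,
                       offset_delay_max_s = 10,
                       rise_dur_s = 20,
                       fall_dur_s = 30,
                       plateau_amp = 1,
                       osc_amp = 0.15,
                       field_amp = 0.18,
                       field_scale_um = 25,
                       field_tau_s = 30,
                       shared_amp = 0.02,
                       shared_weight_range = c(0, 1),
                       shared_tau_s = 60,
                       noise_sd = 0.03,
                       common_noise_sd = 0.05,
                       common_gain_range = c(0.1, 1.5),
                       common_gain_power = 3,
                       bleach_linear = 5e-5,
                       bleach_exp_amp = 0.1,
                       bleach_exp_tau_s = 300,
                       nonbeta_fraction = 0.08,
                       nonbeta_osc_amp = 0.3,
                       nonbeta_period_s = 35,
                       f0_range = c(80, 240),
                       islet_radius_um = NULL,
                       seed = 1L) {
  stopifnot(inherits(schedule, "regime_schedule"))
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (osc_period_s < 2 / frame_rate_hz)
    stop("osc_period_s violates the Nyquist bound 2/frame_rate_hz")
  if (onset_delay_max_s < 0 || offset_delay_max_s < 0)
    stop("onset/offset delays must be nonnegative")
  if (!is.null(wave_speed_um_s) && wave_speed_um_s <= 0)
    stop("wave_speed_um_s must be positive")
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

#' Generate a synthetic islet geometry
#'
#' Places `n_cells` cell centers inside a circular islet cross-section by
#' dart throwing with minimum-distance rejection: candidate positions are
#' drawn uniformly and accepted only if at least `0.8 * cell_diameter_um`
#' from every accepted cell. Non-beta cells (alpha/delta-like) are confined
#' to the outermost annulus of width 1.5 cell diameters, mirroring their
#' peripheral sequestration in mouse islets; beta cells fill the disc.
#'
#' The islet radius is `cell_diameter_um * sqrt(n_cells / 2)`, which leaves
#' the mean nearest-neighbour spacing close to one cell diameter.
#'
#' @param params a [sim_params()].
#' @return A data frame of class `islet_geometry` with columns `cell_id`,
#'   `x_um`, `y_um`, `is_beta`, and attribute `islet_radius_um`.
#' @export
generate_geometry <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_cells
  if (n < 3L) stop("n_cells must be >= 3")
  d <- params$cell_diameter_um
  min_dist <- 0.8 * d
  radius <- if (is.null(params$islet_radius_um)) d * sqrt(n / 2)
  else params$islet_radius_um
  n_nonbeta <- round(params$nonbeta_fraction * n)
  annulus_inner <- max(0, radius - 1.5 * d)

  with_seed(params$seed, {
    xs <- ys <- numeric(0)
    sample_in <- function(r_lo, r_hi) {
      # uniform by area within the annulus [r_lo, r_hi]
      r <- sqrt(stats::runif(1L, r_lo^2, r_hi^2))
      th <- stats::runif(1L, 0, 2 * pi)
      c(r * cos(th), r * sin(th))
    }
    place <- function(k, r_lo, r_hi) {
      placed <- 0L
      attempts <- 0L
      max_attempts <- 4000L * k
      while (placed < k && attempts < max_attempts) {
        attempts <- attempts + 1L
        pt <- sample_in(r_lo, r_hi)
        if (length(xs) == 0L ||
            min((xs - pt[1L])^2 + (ys - pt[2L])^2) >= min_dist^2) {
          xs <<- c(xs, pt[1L]); ys <<- c(ys, pt[2L])
          placed <- placed + 1L
        }
      }
      placed
    }
    got_nb <- place(n_nonbeta, annulus_inner, radius)
    got_b <- place(n - n_nonbeta, 0, radius)
    if (got_nb < n_nonbeta || got_b < n - n_nonbeta)
      stop(sprintf(paste0("packing failure: placed only %d of %d cells at ",
                          "min spacing %.1f um in radius %.1f um"),
                   got_nb + got_b, n, min_dist, radius))
    geom <- data.frame(
      cell_id = seq_len(n),
      x_um = xs, y_um = ys,
      is_beta = c(rep(FALSE, n_nonbeta), rep(TRUE, n - n_nonbeta)))
    # id order follows position draw order; relabel so ids are not grouped
    # by type (beta/non-beta interleaved as in a real ROI list)
    perm <- sample.int(n)
    geom <- geom[perm, ]
    geom$cell_id <- seq_len(n)
    rownames(geom) <- NULL
    attr(geom, "islet_radius_um") <- radius
    attr(geom, "cell_diameter_um") <- d
    class(geom) <- c("islet_geometry", "data.frame")
    geom
  })
}

# drift curve shared by the generator and documented for the corrector
bleach_drift <- function(t, linear, exp_amp, exp_tau) {
  (1 - linear * t) * (1 - exp_amp * (1 - exp(-t / exp_tau)))
}

#' Simulate calcium fluorescence traces for a synthetic islet
#'
#' Produces raw fluorescence traces for every cell in `geom` under the
#' glucose protocol in `params$schedule`. Beta-cell dynamics, expressed as a
#' fraction of baseline, are
#' \deqn{s_i(t) = 1 + g_i(t)\,[A + m \sin(2\pi (t - d_i/v)/T) + f_i(t)]
#'       + a_i h(t),}
#' where `g_i` is a sigmoidal (smoothstep) gate opening at the cell's
#' activation onset (ON-regime start plus a per-cell delay) and closing at
#' its deactivation time, `A` the plateau elevation, the sine the plateau oscillation with
#' phase lag `d_i/v` set by the cell's distance to a randomly placed wave
#' source and the wave speed `v`, `f_i` a spatially coherent Gaussian-kernel
#' field (nearby cells share fluctuations), and `a_i h(t)` a weak islet-wide
#' slow fluctuation present in every regime. Non-beta cells oscillate in low
#' glucose and do not respond to the stimulus. Raw fluorescence is
#' `F0_i * s_i(t) * drift(t) + F0_i * noise`, with multiplicative
#' photobleaching drift `(1 - a t)(1 - b(1 - e^{-t/tau}))`.
#'
#' @param geom an [generate_geometry()] result.
#' @param params a [sim_params()].
#' @return A [trace_set()] at stage `"raw"`, with attributes
#'   `"wave_speed_um_s"`, `"wave_source_um"`, and `"true_labels"` (the
#'   generator's ground-truth `beta` / `non_beta` assignment).
#' @export
simulate_traces <- function(geom, params) {
  stopifnot(inherits(geom, "islet_geometry"), inherits(params, "sim_params"))
  sch <- params$schedule
  if (nrow(sch) == 0L) stop("schedule is empty")
  total_s <- schedule_total_s(sch)
  dt <- 1 / params$frame_rate_hz
  n_frames <- floor(total_s / dt + 1e-9)
  times <- (seq_len(n_frames) - 1L) * dt
  n <- nrow(geom)

  # without an ON (OFF) regime the stimulus never starts (never ends)
  on_start <- if ("ON" %in% sch$name) schedule_interval(sch, "ON")[1L]
  else Inf
  off_start <- if ("OFF" %in% sch$name) schedule_interval(sch, "OFF")[1L]
  else Inf

  with_seed(params$seed + 1L, {
    v <- params$wave_speed_um_s
    if (is.null(v)) {
      rng <- params$wave_speed_range
      v <- exp(stats::runif(1L, log(rng[1L]), log(rng[2L])))
    }
    radius <- attr(geom, "islet_radius_um")
    src_r <- sqrt(stats::runif(1L)) * radius
    src_th <- stats::runif(1L, 0, 2 * pi)
    src <- c(src_r * cos(src_th), src_r * sin(src_th))
    d_src <- sqrt((geom$x_um - src[1L])^2 + (geom$y_um - src[2L])^2)

    onset <- on_start + stats::runif(n, 0, params$onset_delay_max_s)
    offset <- off_start + stats::runif(n, 0, params$offset_delay_max_s)

    # spatially coherent field: K Gaussian bumps x AR(1) temporal processes
    K <- max(4L, round(n / 3))
    ctr_r <- sqrt(stats::runif(K)) * radius
    ctr_th <- stats::runif(K, 0, 2 * pi)
    cx <- ctr_r * cos(ctr_th); cy <- ctr_r * sin(ctr_th)
    W <- exp(-(outer(geom$x_um, cx, "-")^2 +
                 outer(geom$y_um, cy, "-")^2) /
               (2 * params$field_scale_um^2))
    wnorm <- sqrt(rowSums(W^2))
    wnorm[wnorm == 0] <- 1
    W <- W / wnorm
    G <- if (params$field_amp > 0)
      t(vapply(seq_len(K), function(k)
        ar1_process(n_frames, params$field_tau_s, dt), numeric(n_frames)))
    else matrix(0, K, n_frames)
    field <- params$field_amp * (W %*% G)

    h <- if (params$shared_amp > 0)
      ar1_process(n_frames, params$shared_tau_s, dt) else numeric(n_frames)
    a_i <- stats::runif(n, params$shared_weight_range[1L],
                        params$shared_weight_range[2L])

    f0 <- stats::runif(n, params$f0_range[1L], params$f0_range[2L])
    nb_phase <- stats::runif(n, 0, 2 * pi)
    common <- if (params$common_noise_sd > 0)
      stats::rnorm(n_frames, sd = params$common_noise_sd)
    else numeric(n_frames)
    gain <- params$common_gain_range[1L] +
      diff(params$common_gain_range) *
      stats::runif(n)^params$common_gain_power

    drift <- bleach_drift(times, params$bleach_linear,
                          params$bleach_exp_amp, params$bleach_exp_tau_s)
    omega <- 2 * pi / params$osc_period_s

    vals <- matrix(0, n, n_frames)
    for (i in seq_len(n)) {
      if (geom$is_beta[i]) {
        gate <- smoothstep(times, onset[i], params$rise_dur_s) *
          (1 - smoothstep(times, offset[i], params$fall_dur_s))
        lag <- if (is.finite(v)) d_src[i] / v else 0
        plateau <- params$plateau_amp +
          params$osc_amp * sin(omega * (times - lag)) + field[i, ]
        shape <- 1 + gate * plateau + params$shared_amp * a_i[i] * h
      } else {
        shape <- 1 + params$nonbeta_osc_amp *
          sin(2 * pi * times / params$nonbeta_period_s + nb_phase[i])
      }
      noise <- if (params$noise_sd > 0)
        stats::rnorm(n_frames, sd = params$noise_sd) else 0
      vals[i, ] <- f0[i] * (shape * drift + gain[i] * common + noise)
    }
    rownames(vals) <- paste0("cell_", geom$cell_id)

    out <- trace_set(times, vals, frame_rate_hz = params$frame_rate_hz,
                     stage = "raw")
    attr(out, "wave_speed_um_s") <- v
    attr(out, "wave_source_um") <- src
    attr(out, "true_labels") <-
      stats::setNames(ifelse(geom$is_beta, "beta", "non_beta"),
                      rownames(vals))
    out
  })
}

#' Write a synthetic islet to disk as a plain-text fixture
#'
#' Writes three files in `dir`: `traces.csv` (header `time_s,cell_<id>,...`,
#' one row per frame), `positions.csv` (`cell_id,x_um,y_um,is_beta`), and
#' `schedule.json`. Doubles are serialized at full precision so that
#' [read_fixture()] reproduces them exactly.
#'
#' @param traces a [trace_set()].
#' @param geom an `islet_geometry` (or any data frame with `cell_id`,
#'   `x_um`, `y_um`, `is_beta`).
#' @param schedule a [regime_schedule()].
#' @param dir output directory; created if missing.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(traces, geom, schedule, dir) {
  stopifnot(inherits(traces, "trace_set"))
  ids_tr <- cell_ids(traces)
  ids_geom <- paste0("cell_", geom$cell_id)
  if (!setequal(ids_tr, ids_geom))
    stop("cell ids of traces and geometry do not match")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- data.frame(time_s = traces$times,
                   t(traces$values[ids_geom, , drop = FALSE]),
                   check.names = FALSE)
  write_csv_exact(tr, file.path(dir, "traces.csv"))
  pos <- data.frame(cell_id = geom$cell_id, x_um = geom$x_um,
                    y_um = geom$y_um, is_beta = geom$is_beta)
  write_csv_exact(pos, file.path(dir, "positions.csv"))
  write_schedule_json(schedule, file.path(dir, "schedule.json"))
  invisible(dir)
}

#' Read an islet fixture written by [write_fixture()]
#'
#' @param dir directory holding `traces.csv`, `positions.csv`,
#'   `schedule.json`.
#' @return A list with elements `traces` (a raw-stage [trace_set()]),
#'   `geometry` (data frame), and `schedule` (a [regime_schedule()]).
#' @export
read_fixture <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  pos <- utils::read.csv(file.path(dir, "positions.csv"))
  sch <- read_schedule_json(file.path(dir, "schedule.json"))
  vals <- t(as.matrix(tr[, -1L, drop = FALSE]))
  traced <- rownames(vals)
  known <- paste0("cell_", pos$cell_id)
  if (!all(traced %in% known))
    stop(sprintf("positions missing for traced cell(s): %s",
                 paste(setdiff(traced, known), collapse = ", ")))
  pos$is_beta <- as.logical(pos$is_beta)
  list(traces = trace_set(tr$time_s, vals, stage = "raw"),
       geometry = pos, schedule = sch)
}
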