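#' Fluorescence trace container
#'
#' A `trace_set` holds the ROI time series of one islet recording: a
#' cells-by-frames matrix of fluorescence values together with the common
#' frame timestamps. The `stage` field records how far the traces have been
#' conditioned: `"raw"` (dye fluorescence, possibly bleach-corrected),
#' `"f_over_f0"` (divided by the initial fluorescence level), or `"unit"`
#' (each trace affinely mapped to the unit interval).
#'
#' @param times numeric vector of frame times in seconds, strictly increasing
#'   and uniformly spaced.
#' @param values numeric matrix, cells in rows and frames in columns; row
#'   names are the cell identifiers.
#' @param frame_rate_hz acquisition rate in Hz; defaults to the inverse of
#'   the median frame interval.
#' @param stage one of `"raw"`, `"f_over_f0"`, `"unit"`.
#' @param flags named list of per-cell processing flags (e.g. cells whose
#'   bleach fit fell back to linear, or constant traces found by
#'   [rescale_unit()]).
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(times, values, frame_rate_hz = NULL,
                      stage = c("raw", "f_over_f0", "unit"),
                      flags = list()) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be a numeric matrix")
  if (length(times) != ncol(values))
    stop(sprintf("length(times) (%d) != number of frames (%d)",
                 length(times), ncol(values)))
  if (length(times) >= 2L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * max(dt))
      stop("times must be uniformly spaced (tolerance 1e-6)")
    if (is.null(frame_rate_hz)) frame_rate_hz <- 1 / stats::median(dt)
  }
  if (is.null(frame_rate_hz)) stop("frame_rate_hz required for < 2 frames")
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("cell_", seq_len(nrow(values)))
  structure(list(times = as.numeric(times), values = values,
                 frame_rate_hz = frame_rate_hz, stage = stage,
                 flags = flags),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d cells x %d frames, %.3g Hz, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz, x$stage))
  if (ncol(x$values) > 0L)
    cat(sprintf("  time span [%g, %g] s\n", x$times[1L],
                x$times[length(x$times)]))
  if (length(x$flags))
    cat("  flags:", paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trace_set <- function(x) dim(x$values)

n_cells <- function(ts) nrow(ts$values)
cell_ids <- function(ts) rownames(ts$values)

#' Extract the frames of one regime
#'
#' Returns the sub-`trace_set` of frames whose timestamps fall inside the
#' named regime's half-open interval `[t_start, t_end)`. With the default
#' schedule at 0.5 Hz the HG slice has 200 frames and the ON slice 60.
#'
#' @param traces a [trace_set()].
#' @param schedule a [regime_schedule()].
#' @param regime regime name, e.g. `"HG"`.
#' @return A [trace_set()] restricted to the regime's frames, carrying the
#'   window bounds in attribute `"window"`.
#' @export
segment_regime <- function(traces, schedule, regime) {
  stopifnot(inherits(traces, "trace_set"))
  iv <- schedule_interval(schedule, regime)
  keep <- traces$times >= iv[1L] & traces$times < iv[2L]
  if (!any(keep))
    stop(sprintf("regime '%s' [%g, %g) contains no frames", regime,
                 iv[1L], iv[2L]))
  out <- trace_set(traces$times[keep], traces$values[, keep, drop = FALSE],
                   frame_rate_hz = traces$frame_rate_hz,
                   stage = traces$stage, flags = traces$flags)
  attr(out, "window") <- iv
  attr(out, "regime") <- regime
  out
}
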