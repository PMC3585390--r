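#' Stimulation-protocol schedule
#'
#' A regime schedule names the half-open time intervals `[t_start_s, t_end_s)`
#' into which an islet recording is segmented: low glucose before stimulation
#' (`LG1`), activation (`ON`), sustained activity in high glucose (`HG`),
#' deactivation (`OFF`), and low glucose after stimulation (`LG2`). Gaps
#' between intervals (e.g. solution-exchange transients) are allowed and
#' simply excluded from regime analyses.
#'
#' @param name character vector of regime names.
#' @param t_start_s,t_end_s numeric vectors of interval bounds in seconds;
#'   each interval is half-open, `t_start_s <= t < t_end_s`.
#' @return A `regime_schedule` data frame with columns `name`, `t_start_s`,
#'   `t_end_s`, ordered by start time.
#' @examples
#' regime_schedule(c("LG1", "HG"), c(0, 600), c(300, 1000))
#' @export
regime_schedule <- function(name, t_start_s, t_end_s) {
  stopifnot(is.character(name), length(name) == length(t_start_s),
            length(name) == length(t_end_s))
  if (length(name) == 0L) stop("schedule is empty")
  if (anyDuplicated(name)) stop("duplicate regime names in schedule")
  if (any(!is.finite(t_start_s)) || any(!is.finite(t_end_s)))
    stop("schedule bounds must be finite")
  if (any(t_end_s <= t_start_s))
    stop("each regime must have t_end_s > t_start_s")
  ord <- order(t_start_s)
  sch <- data.frame(name = name[ord], t_start_s = t_start_s[ord],
                    t_end_s = t_end_s[ord], stringsAsFactors = FALSE)
  if (nrow(sch) > 1L && any(sch$t_start_s[-1L] < sch$t_end_s[-nrow(sch)]))
    stop("schedule intervals overlap")
  class(sch) <- c("regime_schedule", "data.frame")
  sch
}

#' Default glucose-stimulation schedule
#'
#' The canonical protocol: 6 mM glucose at rest, a step to 12 mM driving
#' activation, a sustained high-glucose plateau, and a step back to 6 mM.
#' Windows between regimes (420-600 s, 1000-1080 s, 1200-1400 s) cover the
#' perifusion transients and are not analyzed.
#'
#' @return A [regime_schedule()] with LG1 = \[0, 300), ON = \[300, 420),
#'   HG = \[600, 1000), OFF = \[1080, 1200), LG2 = \[1400, 1800).
#' @export
default_schedule <- function() {
  regime_schedule(c("LG1", "ON", "HG", "OFF", "LG2"),
                  c(0, 300, 600, 1080, 1400),
                  c(300, 420, 1000, 1200, 1800))
}

#' @export
print.regime_schedule <- function(x, ...) {
  cat("Regime schedule (half-open intervals, seconds):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

schedule_interval <- function(schedule, regime) {
  stopifnot(inherits(schedule, "regime_schedule"))
  i <- match(regime, schedule$name)
  if (is.na(i))
    stop(sprintf("regime '%s' not present in schedule (have: %s)",
                 regime, paste(schedule$name, collapse = ", ")))
  c(schedule$t_start_s[i], schedule$t_end_s[i])
}

schedule_total_s <- function(schedule) max(schedule$t_end_s)

#' Write or read a schedule as JSON
#'
#' Serialized as a list of `{name, t_start_s, t_end_s}` records, the on-disk
#' dialect used by [write_fixture()].
#'
#' @param schedule a [regime_schedule()].
#' @param path file path for the JSON document.
#' @return `write_schedule_json()` returns `path` invisibly;
#'   `read_schedule_json()` returns a [regime_schedule()].
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "regime_schedule"))
  jsonlite::write_json(as.data.frame(schedule), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  regime_schedule(d$name, d$t_start_s, d$t_end_s)
}
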