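# Sensorgrams: biosensor response (nm) versus time (s), with optional
# per-sample step annotations once aligned to an assay schedule.

#' Construct a sensorgram
#'
#' @param times Sample times in seconds; strictly increasing, finite.
#' @param responses Responses in nm; finite, same length as `times`.
#' @param step_index Optional integer vector mapping each sample to a row of
#'   an [assay_schedule()] step table (`NA` for samples outside the
#'   schedule); set by [align_to_assay_clock()].
#' @param schedule Optional [assay_schedule()] the annotation refers to.
#' @return An object of class `sensorgram`.
#' @export
sensorgram <- function(times, responses, step_index = NULL, schedule = NULL) {
  times <- as.numeric(times); responses <- as.numeric(responses)
  if (length(times) != length(responses))
    scbli_error("times and responses must have equal length", "validation")
  if (anyNA(times) || any(!is.finite(times)))
    scbli_error("sensorgram times must all be finite", "validation")
  if (anyNA(responses) || any(!is.finite(responses)))
    scbli_error("sensorgram responses must all be finite", "validation")
  if (length(times) > 1 && any(diff(times) <= 0))
    scbli_error("sensorgram times must be strictly increasing", "validation")
  if (!is.null(step_index)) {
    step_index <- as.integer(step_index)
    if (length(step_index) != length(times))
      scbli_error("step_index must match sample count", "validation")
  }
  structure(list(times = times, responses = responses,
                 step_index = step_index, schedule = schedule),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("Sensorgram: %d samples, t = [%g, %g] s, response = [%.4g, %.4g] nm%s\n",
              length(x$times), min(x$times), max(x$times),
              min(x$responses), max(x$responses),
              if (is.null(x$step_index)) " (not aligned)" else " (aligned)"))
  invisible(x)
}

#' @export
length.sensorgram <- function(x) length(x$times)

#' Coerce a sensorgram to a data frame
#' @param x A `sensorgram`.
#' @param ... Unused.
#' @return A `data.frame` with columns `time_s`, `response_nm` and, when the
#'   trace is aligned, `step_index`.
#' @export
as.data.frame.sensorgram <- function(x, ...) {
  d <- data.frame(time_s = x$times, response_nm = x$responses)
  if (!is.null(x$step_index)) d$step_index <- x$step_index
  d
}

#' Read a sensorgram from a tidy CSV table
#'
#' Expects a header with at least a time column (seconds) and a response
#' column (nm); extra columns are ignored. This is the package's native
#' exchange format -- conversion from proprietary instrument exports is the
#' caller's responsibility.
#'
#' @param path CSV file path.
#' @param time_column,response_column Column names (defaults `time_s`,
#'   `response_nm`).
#' @return A `sensorgram`.
#' @export
read_sensorgram_table <- function(path, time_column = "time_s",
                                  response_column = "response_nm") {
  if (!file.exists(path))
    scbli_error(sprintf("sensorgram file not found: %s", path), "config")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (col in c(time_column, response_column))
    if (!col %in% names(tab))
      scbli_error(sprintf("column '%s' not found in %s", col, path), "format")
  if (nrow(tab) < 4)
    scbli_error("sensorgram table needs at least 4 rows", "format")
  parse_col <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) > 0)
      scbli_error(sprintf("non-numeric value '%s' in column '%s', row %d",
                          tab[[col]][bad[1]], col, bad[1]), "parse")
    v
  }
  sensorgram(parse_col(time_column), parse_col(response_column))
}

#' Write a sensorgram as a tidy CSV table
#'
#' Times and responses are written at full double precision so that a write
#' then read round-trip reproduces the values bit-for-bit.
#'
#' @param sg A `sensorgram`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_sensorgram_table <- function(sg, path) {
  lines <- c("time_s,response_nm",
             sprintf("%.17g,%.17g", sg$times, sg$responses))
  writeLines(lines, path)
  invisible(path)
}

#' Align a sensorgram to the assay clock
#'
#' Shifts the time axis so that the first sample of the first association
#' step falls at t = 0 (the single-cycle clock convention) and annotates
#' every sample with its schedule step. The raw trace is assumed to begin at
#' the start of the schedule's first step; pre-analyte samples are retained
#' with negative times and flagged non-kinetic via their step annotation.
#'
#' @param sg A `sensorgram` starting at the schedule's first step.
#' @param schedule The [assay_schedule()] that was run.
#' @param tolerance_s Acquisition-jitter allowance when checking coverage;
#'   defaults to one median sample interval.
#' @return An aligned `sensorgram` (same sample count and spacing).
#' @export
align_to_assay_clock <- function(sg, schedule, tolerance_s = NULL) {
  st <- schedule$steps
  dt <- if (length(sg$times) > 1) stats::median(diff(sg$times)) else 1
  tolerance_s <- tolerance_s %||% dt
  pre <- -min(st$start_s)   # duration of pre-analyte steps
  times <- sg$times - sg$times[1] - pre
  if (max(times) < schedule_kinetic_end(schedule) - tolerance_s)
    scbli_error(sprintf(
      "sensorgram (%.4g s) does not cover the scheduled duration (%.4g s)",
      max(times) + pre, schedule_kinetic_end(schedule) + pre), "coverage")
  idx <- step_index_for(times, schedule)
  sensorgram(times, sg$responses, step_index = idx, schedule = schedule)
}

# Map clock times onto schedule rows: step i covers [start_i, end_i), the
# last step is closed on the right; times outside the schedule map to NA.
step_index_for <- function(times, schedule) {
  st <- schedule$steps
  idx <- findInterval(times, c(st$start_s, st$end_s[nrow(st)]),
                      rightmost.closed = TRUE)
  idx[idx < 1 | idx > nrow(st)] <- NA_integer_
  as.integer(idx)
}

#' Subtract a reference-sensor trace
#'
#' Pointwise subtraction of a matched control sensor (used to remove drift,
#' bulk-refractive offsets or non-specific binding). When the two traces were
#' not acquired on the same grid the reference is linearly interpolated onto
#' the assay grid.
#'
#' @param assay,reference `sensorgram`s aligned to the same schedule.
#' @return The corrected `sensorgram` (assay annotations preserved).
#' @export
subtract_reference <- function(assay, reference) {
  if (max(reference$times) < min(assay$times) ||
      min(reference$times) > max(assay$times))
    scbli_error("assay and reference time ranges do not overlap", "alignment")
  ref <- stats::approx(reference$times, reference$responses,
                       xout = assay$times, rule = 2)$y
  sensorgram(assay$times, assay$responses - ref,
             step_index = assay$step_index, schedule = assay$schedule)
}

#' Remove rigid inter-step offsets (bulk shifts)
#'
#' Bulk-refractive differences between wells appear as jumps at step
#' boundaries. Each kinetic segment after the first is rigidly offset so that
#' its first sample coincides with the last sample of the preceding kinetic
#' segment; the first kinetic segment is never moved. Off by default in the
#' fitting pipeline -- enable it only when a matched reference has confirmed
#' bulk shifts.
#'
#' @param sg An aligned `sensorgram`.
#' @param schedule The [assay_schedule()] (defaults to the one attached at
#'   alignment).
#' @return The corrected `sensorgram`.
#' @export
correct_interstep_shifts <- function(sg, schedule = sg$schedule) {
  if (is.null(sg$step_index) || is.null(schedule))
    scbli_error("sensorgram must be aligned before shift correction",
                "validation")
  st <- schedule$steps
  kin <- which(st$kinetic)
  resp <- sg$responses
  prev_last <- NA_real_
  for (k in kin) {
    sel <- which(!is.na(sg$step_index) & sg$step_index == k)
    if (length(sel) == 0) next
    if (!is.na(prev_last)) {
      resp[sel] <- resp[sel] + (prev_last - resp[sel[1]])
    }
    prev_last <- resp[sel[length(sel)]]
  }
  sensorgram(sg$times, resp, step_index = sg$step_index, schedule = schedule)
}

#' Overlay plot of sensorgrams
#'
#' Basic base-graphics overlay of one or more traces with step boundaries.
#'
#' @param x A `sensorgram`.
#' @param ... Further `sensorgram`s to overlay.
#' @param main Plot title.
#' @export
plot.sensorgram <- function(x, ..., main = "Sensorgram") {
  others <- Filter(function(o) inherits(o, "sensorgram"), list(...))
  all_sg <- c(list(x), others)
  xr <- range(unlist(lapply(all_sg, `[[`, "times")))
  yr <- range(unlist(lapply(all_sg, `[[`, "responses")))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "time (s)",
                 ylab = "response (nm)", main = main)
  for (i in seq_along(all_sg))
    graphics::lines(all_sg[[i]]$times, all_sg[[i]]$responses, col = i)
  if (!is.null(x$schedule))
    graphics::abline(v = x$schedule$steps$start_s, col = "grey80", lty = 3)
  invisible(x)
}
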