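# Assay schedules for single-cycle (kinetic-titration) BLI runs.
#
# A schedule is the programmed sequence of sensor steps: optional
# pre-analyte steps (loading, blocking, baseline) followed by the kinetic
# steps proper -- association wells at strictly increasing analyte
# concentrations, short "mini-dissociation" buffer transfers between wells,
# and a single terminal dissociation. The assay clock is continuous and
# starts (t = 0) when the sensor enters the first analyte well; pre-analyte
# steps carry negative clock times and are excluded from kinetic fitting.

STEP_KINDS <- c("LOADING", "BLOCKING", "BASELINE", "ASSOCIATION",
                "MINI_DISSOCIATION", "FINAL_DISSOCIATION")
KINETIC_KINDS <- c("ASSOCIATION", "MINI_DISSOCIATION", "FINAL_DISSOCIATION")
DISSOCIATION_KINDS <- c("MINI_DISSOCIATION", "FINAL_DISSOCIATION")

#' Create a single assay step
#'
#' @param kind Step kind, one of `"LOADING"`, `"BLOCKING"`, `"BASELINE"`,
#'   `"ASSOCIATION"`, `"MINI_DISSOCIATION"`, `"FINAL_DISSOCIATION"`.
#'   Case-insensitive.
#' @param duration_s Step dwell time in seconds; strictly positive.
#' @param concentration_M Analyte concentration in molar. Required for
#'   (and only allowed on) `ASSOCIATION` steps.
#' @param label Optional free-text label.
#' @return A one-row `data.frame` describing the step.
#' @export
assay_step <- function(kind, duration_s, concentration_M = NA_real_,
                       label = "") {
  kind <- toupper(as.character(kind)[1])
  if (!kind %in% STEP_KINDS)
    scbli_error(sprintf("unknown step kind '%s'", kind), "validation")
  if (!is_scalar_number(duration_s) || duration_s <= 0)
    scbli_error("step duration must be strictly positive and finite",
                "validation")
  conc <- suppressWarnings(as.numeric(concentration_M)[1])
  if (kind == "ASSOCIATION") {
    if (is.na(conc) || !is.finite(conc) || conc < 0)
      scbli_error("ASSOCIATION steps require a finite concentration >= 0",
                  "validation")
  } else if (!is.na(conc)) {
    scbli_error(sprintf("concentration given on a %s step (only ASSOCIATION steps carry one)",
                        kind), "validation")
  }
  data.frame(kind = kind, duration_s = as.numeric(duration_s),
             concentration_M = conc, label = as.character(label)[1],
             stringsAsFactors = FALSE)
}

#' Assemble and validate an assay schedule
#'
#' Validates the single-cycle layout rules: at least one association; analyte
#' concentrations strictly increasing along the run (sensors move from the
#' lowest to the highest concentration well); every association except
#' possibly the last is followed by a mini-dissociation; exactly one final
#' dissociation, placed last.
#'
#' @param steps A list of [assay_step()] rows (or a single `data.frame` of
#'   such rows, e.g. from `rbind`).
#' @return An object of class `assay_schedule`: the validated step table
#'   plus the derived clock (per-step entry/exit times with t = 0 at the
#'   first association).
#' @export
assay_schedule <- function(steps) {
  if (is.data.frame(steps)) tab <- steps
  else tab <- do.call(rbind, steps)
  if (is.null(tab) || nrow(tab) == 0)
    scbli_error("schedule has no steps", "validation")
  # re-validate each row through assay_step
  tab <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    assay_step(tab$kind[i], tab$duration_s[i], tab$concentration_M[i],
               if ("label" %in% names(tab)) tab$label[i] else "")))

  assoc <- which(tab$kind == "ASSOCIATION")
  if (length(assoc) == 0)
    scbli_error("schedule contains no ASSOCIATION step", "validation")
  fin <- which(tab$kind == "FINAL_DISSOCIATION")
  if (length(fin) != 1 || fin != nrow(tab))
    scbli_error("schedule must contain exactly one FINAL_DISSOCIATION, as its last step",
                "validation")
  conc <- tab$concentration_M[assoc]
  if (length(conc) > 1 && any(diff(conc) <= 0))
    scbli_error(paste("association concentrations must strictly increase:",
                      "single-cycle sensors move from lowest to highest",
                      "concentration wells"), "validation")
  # association -> mini-dissociation pairing (last association may run
  # straight into the final dissociation)
  for (i in utils::head(assoc, -1)) {
    if (i == nrow(tab) || tab$kind[i + 1] != "MINI_DISSOCIATION")
      scbli_error("each ASSOCIATION except possibly the last must be followed by a MINI_DISSOCIATION",
                  "validation")
  }
  if (any(tab$kind[seq_len(assoc[1] - 1)] %in% KINETIC_KINDS))
    scbli_error("dissociation steps cannot precede the first ASSOCIATION",
                "validation")

  # Continuous assay clock: t = 0 at entry into the first association.
  ends <- cumsum(tab$duration_s)
  starts <- c(0, utils::head(ends, -1))
  shift <- starts[assoc[1]]
  tab$start_s <- starts - shift
  tab$end_s <- ends - shift
  tab$kinetic <- tab$kind %in% KINETIC_KINDS

  structure(list(steps = tab), class = "assay_schedule")
}

#' @export
print.assay_schedule <- function(x, ...) {
  cat(sprintf("Single-cycle assay schedule: %d steps, t_off = %g s, kinetic end = %g s\n",
              nrow(x$steps), schedule_t_off(x), schedule_kinetic_end(x)))
  tab <- x$steps
  tab$concentration_nM <- tab$concentration_M * 1e9
  print(tab[, c("kind", "duration_s", "concentration_nM",
                "start_s", "end_s")], row.names = FALSE)
  invisible(x)
}

# -- derived clock quantities -------------------------------------------------

#' Entry time of the final dissociation on the assay clock
#' @param schedule An [assay_schedule()].
#' @return Seconds since the first analyte well was entered.
#' @export
schedule_t_off <- function(schedule) {
  st <- schedule$steps
  st$start_s[st$kind == "FINAL_DISSOCIATION"]
}

#' End of the scheduled kinetic window on the assay clock
#' @param schedule An [assay_schedule()].
#' @return Seconds; the exit time of the final dissociation.
#' @export
schedule_kinetic_end <- function(schedule) {
  max(schedule$steps$end_s)
}

#' Association well summary
#' @param schedule An [assay_schedule()].
#' @return A `data.frame` with one row per analyte well: entry time `t_i`
#'   (s), dwell `tau_a` (s), and concentration (M).
#' @export
schedule_associations <- function(schedule) {
  st <- schedule$steps
  a <- st[st$kind == "ASSOCIATION", ]
  data.frame(t_i = a$start_s, tau_a = a$duration_s,
             concentration_M = a$concentration_M)
}

# -- config IO ---------------------------------------------------------------

#' Read an assay schedule from a YAML or JSON config
#'
#' The config holds a `steps` list (or is itself a list of steps), each with
#' `kind`, `duration_s`, optional `concentration_nM` (associations only) and
#' optional `label`. Concentrations are given in nM in configs and held in
#' molar internally.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [assay_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path))
    scbli_error(sprintf("schedule config not found: %s", path), "config")
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = FALSE),
    scbli_error(sprintf("unsupported schedule format '.%s' (use YAML or JSON)",
                        ext), "format"))
  steps <- cfg$steps %||% cfg
  if (!is.list(steps) || length(steps) == 0)
    scbli_error("schedule config declares no steps", "format")
  rows <- lapply(steps, function(s) {
    conc <- if (!is.null(s$concentration_nM)) as.numeric(s$concentration_nM) * 1e-9
            else if (!is.null(s$concentration_M)) as.numeric(s$concentration_M)
            else NA_real_
    assay_step(s$kind %||% scbli_error("step missing 'kind'", "format"),
               s$duration_s %||% scbli_error("step missing 'duration_s'", "format"),
               conc, s$label %||% "")
  })
  assay_schedule(rows)
}

#' Write an assay schedule config
#'
#' Inverse of [read_schedule()]; concentrations are written in nM.
#'
#' @param schedule An [assay_schedule()].
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  st <- schedule$steps
  steps <- lapply(seq_len(nrow(st)), function(i) {
    s <- list(kind = st$kind[i], duration_s = st$duration_s[i])
    if (!is.na(st$concentration_M[i]))
      s$concentration_nM <- st$concentration_M[i] * 1e9
    if (nzchar(st$label[i])) s$label <- st$label[i]
    s
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml"))
    yaml::write_yaml(list(steps = steps), path, precision = 17L)
  else if (ext == "json")
    jsonlite::write_json(list(steps = steps), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  else scbli_error(sprintf("unsupported schedule format '.%s'", ext), "format")
  invisible(path)
}
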