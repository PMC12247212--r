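# Synthetic single-cycle sensorgrams: the noiseless piecewise model plus a
# simple instrument-artefact model (iid Gaussian read noise, linear drift,
# and cumulative bulk-refractive offsets at step boundaries). Everything is
# seeded so that simulated fixtures are exactly reproducible.

#' Instrument noise model for simulation
#'
#' @param sigma Gaussian read-noise SD per sample, nm (default 0.005 nm,
#'   in the middle of typical single-cycle fit RMSEs of roughly
#'   0.0035-0.018 nm).
#' @param drift Linear baseline drift, nm/s (default 0).
#' @param step_shift_sd SD of the Gaussian bulk-refractive offset injected
#'   at each step boundary, nm (default 0). Offsets accumulate: each
#'   boundary's shift is carried through the rest of the trace, mirroring
#'   how bulk artefacts appear in real traces.
#' @param seed RNG seed fixing the whole simulated stream (`NULL` draws from
#'   the session RNG).
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma = 0.005, drift = 0, step_shift_sd = 0,
                        seed = NULL) {
  if (!is_scalar_number(sigma) || sigma < 0)
    scbli_error("sigma must be >= 0", "validation")
  if (!is_scalar_number(drift))
    scbli_error("drift must be a finite number", "validation")
  if (!is_scalar_number(step_shift_sd) || step_shift_sd < 0)
    scbli_error("step_shift_sd must be >= 0", "validation")
  structure(list(sigma = sigma, drift = drift,
                 step_shift_sd = step_shift_sd, seed = seed),
            class = "noise_model")
}

#' Default single-cycle schedule for a concentration series
#'
#' Association dwell times taper linearly from 300 s (lowest concentration)
#' to 100 s (highest) -- exactly 300/250/200/150/100 s for a five-well
#' series -- because low-concentration wells approach steady state more
#' slowly. Wells are separated by 30 s mini-dissociations and the run ends
#' with a 600 s final dissociation (1200 s with `long_final = TRUE`, useful
#' for slow-dissociating binders).
#'
#' @param concentrations_M Strictly increasing analyte concentrations,
#'   molar.
#' @param long_final Use a 1200 s final dissociation instead of 600 s.
#' @return An [assay_schedule()].
#' @export
default_schedule <- function(concentrations_M, long_final = FALSE) {
  conc <- as.numeric(concentrations_M)
  if (length(conc) < 1 || anyNA(conc) || any(conc <= 0))
    scbli_error("concentrations must be positive", "validation")
  if (length(conc) > 1 && any(diff(conc) <= 0))
    scbli_error("concentrations must strictly increase (sensors move from lowest to highest wells)",
                "validation")
  n <- length(conc)
  dwell <- if (n == 1) 300 else seq(300, 100, length.out = n)
  steps <- list()
  for (i in seq_len(n)) {
    steps <- c(steps, list(assay_step("ASSOCIATION", dwell[i], conc[i],
                                      sprintf("well %d", i))))
    if (i < n)
      steps <- c(steps, list(assay_step("MINI_DISSOCIATION", 30)))
  }
  steps <- c(steps, list(assay_step("FINAL_DISSOCIATION",
                                    if (long_final) 1200 else 600)))
  assay_schedule(steps)
}

#' Simulate a noisy single-cycle sensorgram
#'
#' The noiseless piecewise trace ([predict_trace()]) plus, in order: linear
#' drift `drift * t`, cumulative Gaussian bulk shifts at every step
#' boundary, and iid Gaussian read noise. With all three artefact magnitudes
#' zero the output equals the analytic prediction exactly.
#'
#' @param schedule An [assay_schedule()].
#' @param params A [kinetic_params()] or [partial_params()].
#' @param noise A [noise_model()].
#' @param grid Sample spacing, seconds (default 0.5 s, a BLI-like cadence).
#' @return An aligned `sensorgram`.
#' @export
simulate_sensorgram <- function(schedule, params, noise = noise_model(),
                                grid = 0.5) {
  base <- predict_trace(schedule, params, grid = grid)
  with_seed(noise$seed, add_artefacts(base, schedule, noise))
}

# drift + cumulative step shifts + read noise, drawn from the current RNG
add_artefacts <- function(base, schedule, noise) {
  resp <- base$responses + noise$drift * base$times
  if (noise$step_shift_sd > 0) {
    st <- schedule$steps
    boundaries <- st$start_s[-1]
    shifts <- stats::rnorm(length(boundaries), 0, noise$step_shift_sd)
    offset <- cumsum(shifts)
    k <- findInterval(base$times, boundaries)
    resp <- resp + c(0, offset)[k + 1]
  }
  if (noise$sigma > 0)
    resp <- resp + stats::rnorm(length(resp), 0, noise$sigma)
  sensorgram(base$times, resp, step_index = base$step_index,
             schedule = schedule)
}

#' Simulate a sensor-loading trace
#'
#' Covalent, irreversible capture of the binder is pseudo-first-order in the
#' binder concentration: R(t) = R_sat (1 - exp(-k_capture C t)). The plateau
#' R_sat is set by the pre-loaded capture sites, so given enough time every
#' sensor attains the same density regardless of concentration; only the
#' approach rate reflects expression level.
#'
#' @param binder_concentration Binder concentration in the loading well,
#'   molar.
#' @param capture_rate_constant Capture rate constant, 1/(M s).
#' @param R_sat Saturating response, nm.
#' @param duration Loading dwell, seconds.
#' @param noise A [noise_model()].
#' @param grid Sample spacing, seconds.
#' @return A `sensorgram` with time measured from the start of loading.
#' @export
simulate_loading <- function(binder_concentration, capture_rate_constant,
                             R_sat, duration, noise = noise_model(),
                             grid = 0.5) {
  stopifnot_scalar_positive(binder_concentration, "binder_concentration")
  stopifnot_scalar_positive(capture_rate_constant, "capture_rate_constant")
  stopifnot_scalar_positive(R_sat, "R_sat")
  stopifnot_scalar_positive(duration, "duration")
  t <- seq(0, duration, by = grid)
  y <- R_sat * (1 - exp(-capture_rate_constant * binder_concentration * t))
  y <- y + noise$drift * t
  with_seed(noise$seed, {
    if (noise$sigma > 0) y <- y + stats::rnorm(length(y), 0, noise$sigma)
    sensorgram(t, y)
  })
}

#' Write a plate of simulated fixtures to disk
#'
#' Emits one tidy sensorgram CSV per entry, the shared schedule config, an
#' optional matched reference trace (drift plus noise around a zero
#' baseline, as produced by a matrix-only control sensor), and a manifest
#' JSON recording the generating parameters of every sensor.
#'
#' @param plate_spec A named list of entries, each a list with `params`
#'   (a [kinetic_params()]/[partial_params()]), `schedule` (an
#'   [assay_schedule()]; entries must share one schedule) and optional
#'   `noise` (a [noise_model()]) and `grid`.
#' @param dir Output directory (created if missing).
#' @param include_reference Also write `reference.csv`.
#' @return Invisibly, the paths written (named list with `sensorgrams`,
#'   `schedule`, `manifest`, and `reference` when requested).
#' @export
make_fixture_plate <- function(plate_spec, dir, include_reference = FALSE) {
  if (!is.list(plate_spec) || length(plate_spec) == 0)
    scbli_error("plate_spec must be a non-empty list", "validation")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    scbli_error(sprintf("cannot create output directory %s", dir), "config")
  ids <- names(plate_spec) %||% paste0("sensor", seq_along(plate_spec))
  ids[ids == ""] <- paste0("sensor", which(ids == ""))
  schedule <- plate_spec[[1]]$schedule
  paths <- character(0)
  manifest <- list()
  for (i in seq_along(plate_spec)) {
    e <- plate_spec[[i]]
    nm <- e$noise %||% noise_model()
    sg <- simulate_sensorgram(e$schedule %||% schedule, e$params, nm,
                              grid = e$grid %||% 0.5)
    p <- file.path(dir, paste0(ids[i], ".csv"))
    write_sensorgram_table(sg, p)
    paths <- c(paths, p)
    entry <- list(file = basename(p), k_on = e$params$k_on,
                  k_off = e$params$k_off, R_max = e$params$R_max,
                  K_D = dissociation_constant(e$params),
                  sigma = nm$sigma, drift = nm$drift,
                  step_shift_sd = nm$step_shift_sd, seed = nm$seed)
    if (inherits(e$params, "partial_params")) {
      entry$mode <- e$params$mode
      entry$phi <- e$params$phi
      entry$plateaus <- e$params$plateaus
    }
    manifest[[ids[i]]] <- entry
  }
  sched_path <- file.path(dir, "schedule.yaml")
  write_schedule(schedule, sched_path)
  out <- list(sensorgrams = paths, schedule = sched_path)
  if (include_reference) {
    nm <- plate_spec[[1]]$noise %||% noise_model()
    ref_seed <- if (!is.null(nm$seed)) nm$seed + 10000L else NULL
    grid <- plate_spec[[1]]$grid %||% 0.5
    t <- seq(min(schedule$steps$start_s), schedule_kinetic_end(schedule),
             by = grid)
    ref <- with_seed(ref_seed, {
      y <- nm$drift * t
      if (nm$sigma > 0) y <- y + stats::rnorm(length(t), 0, nm$sigma)
      sensorgram(t, y)
    })
    ref_path <- file.path(dir, "reference.csv")
    write_sensorgram_table(ref, ref_path)
    out$reference <- ref_path
    manifest[["reference"]] <- list(file = "reference.csv", null_ligand = TRUE,
                                    sigma = nm$sigma, drift = nm$drift)
  }
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out$manifest <- man_path
  invisible(out)
}
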