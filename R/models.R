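# Closed-form piecewise 1:1 Langmuir binding models for single-cycle traces.
#
# On the continuous assay clock, association in analyte well i follows
#   R(t) = R_eq,i + [R_0(t_i) - R_eq,i] * exp(-(k_on*C_i + k_off)*(t - t_i))
#   R_eq,i = R_max * k_on*C_i / (k_on*C_i + k_off)
# and every dissociation (mini or final) decays mono-exponentially from the
# value at the end of the previous step, either to zero (standard model) or
# towards a plateau R_inf (partial-dissociation model). The start value of
# each segment is forced to equal the end of the previous one, so predicted
# traces are continuous by construction; R_0(t = 0) = 0.

#' Kinetic parameters of a 1:1 interaction
#'
#' @param k_on Association rate constant, 1/(M s); > 0.
#' @param k_off Dissociation rate constant, 1/s; > 0.
#' @param R_max Maximal response at ligand saturation, nm; > 0.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_on, k_off, R_max) {
  stopifnot_scalar_positive(k_on, "k_on")
  stopifnot_scalar_positive(k_off, "k_off")
  stopifnot_scalar_positive(R_max, "R_max")
  structure(list(k_on = k_on, k_off = k_off, R_max = R_max),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("1:1 kinetics: k_on = %.4g 1/(M s), k_off = %.4g 1/s, R_max = %.4g nm, K_D = %.4g M\n",
              x$k_on, x$k_off, x$R_max, dissociation_constant(x)))
  invisible(x)
}

#' Partial-dissociation model parameters
#'
#' Extends [kinetic_params()] for interactions whose dissociation decays to a
#' non-zero plateau. Two parametrisations exist: a single mobile-fraction
#' parameter `phi` shared by all dissociation segments (each plateau is
#' `phi` times the response at the start of that decay: R_inf,i = phi * R0_i),
#' or one free plateau per dissociation segment (`local` mode). `phi = 0`
#' reduces to the standard model; `phi` is capped at 0.95 so that at least 5%
#' of the signal must eventually drop -- a trace flatter than that is better
#' explained as a very tight binder than as partial dissociation.
#'
#' @param base A [kinetic_params()].
#' @param mode `"global"` (mobile fraction, the default used throughout) or
#'   `"local"` (per-segment plateaus).
#' @param phi Plateau fraction in `[0, 0.95]` (global mode).
#' @param plateaus Numeric vector of plateau levels R_inf,i >= 0 nm, one per
#'   dissociation segment in schedule order (local mode). Clamped to the
#'   segment start value at evaluation time.
#' @return An object of class `partial_params` (inherits `kinetic_params`).
#' @export
partial_params <- function(base, mode = c("global", "local"), phi = NULL,
                           plateaus = NULL) {
  if (!inherits(base, "kinetic_params"))
    scbli_error("'base' must be a kinetic_params object", "validation")
  mode <- match.arg(mode)
  if (mode == "global") {
    if (!is_scalar_number(phi) || phi < 0 || phi > 0.95)
      scbli_error("phi must lie in [0, 0.95]", "validation")
    plateaus <- NULL
  } else {
    if (is.null(plateaus) || anyNA(plateaus) || any(plateaus < 0))
      scbli_error("local mode requires plateaus >= 0, one per dissociation segment",
                  "validation")
    phi <- NULL
  }
  structure(c(unclass(base),
              list(mode = mode, phi = phi, plateaus = as.numeric(plateaus))),
            class = c("partial_params", "kinetic_params"))
}

#' @export
print.partial_params <- function(x, ...) {
  cat(sprintf("1:1 partial-dissociation kinetics (%s): k_on = %.4g 1/(M s), k_off = %.4g 1/s, R_max = %.4g nm, K_D = %.4g M\n",
              x$mode, x$k_on, x$k_off, x$R_max, dissociation_constant(x)))
  if (x$mode == "global") cat(sprintf("  mobile-fraction parameter phi = %.3f\n", x$phi))
  else cat("  plateaus (nm):", paste(signif(x$plateaus, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Equilibrium dissociation constant
#'
#' @param params A [kinetic_params()].
#' @return K_D = k_off / k_on, in molar.
#' @export
dissociation_constant <- function(params) params$k_off / params$k_on

#' Equilibrium (steady-state) response at an analyte concentration
#'
#' R_eq = R_max * k_on C / (k_on C + k_off): zero without analyte, half of
#' R_max at C = K_D, approaching R_max at saturating concentrations.
#'
#' @param C Analyte concentration(s), molar; >= 0.
#' @param params A [kinetic_params()].
#' @return Equilibrium response(s), nm.
#' @export
equilibrium_response <- function(C, params) {
  if (anyNA(C) || any(C < 0))
    scbli_error("concentration must be >= 0", "domain")
  x <- params$k_on * C
  params$R_max * x / (x + params$k_off)
}

#' Segment state carried across step boundaries
#'
#' @param t_start Segment entry time on the assay clock, seconds.
#' @param R_start Response at entry, nm (the propagated R_0).
#' @return An object of class `segment_state`.
#' @export
segment_state <- function(t_start, R_start) {
  if (!is_scalar_number(t_start))
    scbli_error("t_start must be a finite number", "validation")
  if (!is_scalar_number(R_start) || R_start < -1e-9)
    scbli_error("R_start must be finite and non-negative", "validation")
  structure(list(t_start = t_start, R_start = R_start),
            class = "segment_state")
}

#' Association-phase response
#'
#' Exponential approach from the segment start value to the equilibrium
#' response, at observed rate k_on C + k_off.
#'
#' @param t Time(s) on the assay clock, seconds; `t >= state$t_start`.
#' @param state A [segment_state()].
#' @param C Analyte concentration in this well, molar; > 0.
#' @param params A [kinetic_params()].
#' @return Response(s), nm.
#' @export
response_association <- function(t, state, C, params) {
  if (any(t < state$t_start))
    scbli_error("t precedes the segment start", "domain")
  if (!is_scalar_number(C) || C <= 0)
    scbli_error("association requires C > 0", "domain")
  req <- equilibrium_response(C, params)
  req + (state$R_start - req) *
    exp(-(params$k_on * C + params$k_off) * (t - state$t_start))
}

#' Dissociation-phase response (standard model)
#'
#' Mono-exponential decay to zero from the segment start value.
#'
#' @param t Time(s), seconds; `t >= state$t_start`.
#' @param state A [segment_state()].
#' @param k_off Dissociation rate constant, 1/s.
#' @return Response(s), nm.
#' @export
response_dissociation <- function(t, state, k_off) {
  if (any(t < state$t_start))
    scbli_error("t precedes the segment start", "domain")
  state$R_start * exp(-k_off * (t - state$t_start))
}

#' Dissociation-phase response with a plateau (partial model)
#'
#' Mono-exponential decay from the segment start value towards a plateau
#' `R_inf`; with `R_inf = 0` this is exactly the standard dissociation.
#'
#' @param t Time(s), seconds; `t >= state$t_start`.
#' @param state A [segment_state()].
#' @param k_off Dissociation rate constant, 1/s.
#' @param R_inf Plateau response, nm; `0 <= R_inf <= state$R_start`.
#' @return Response(s), nm.
#' @export
response_dissociation_partial <- function(t, state, k_off, R_inf) {
  if (any(t < state$t_start))
    scbli_error("t precedes the segment start", "domain")
  if (R_inf < 0 || R_inf > state$R_start + 1e-12)
    scbli_error("plateau must satisfy 0 <= R_inf <= R_start (decay cannot rise to its plateau)",
                "domain")
  (state$R_start - R_inf) * exp(-k_off * (t - state$t_start)) + R_inf
}

# Vectorised piecewise evaluation at arbitrary clock times. Non-kinetic
# (pre-analyte) samples evaluate to 0: the models start at the first analyte
# well and alignment is assumed to have zeroed the baseline.
eval_trace <- function(times, schedule, params) {
  st <- schedule$steps
  idx <- step_index_for(times, schedule)
  resp <- numeric(length(times))
  R0 <- 0
  diss_counter <- 0L
  for (k in seq_len(nrow(st))) {
    if (!st$kinetic[k]) next
    sel <- which(!is.na(idx) & idx == k)
    state <- segment_state(st$start_s[k], R0)
    if (st$kind[k] == "ASSOCIATION") {
      if (length(sel))
        resp[sel] <- response_association(times[sel], state,
                                          st$concentration_M[k], params)
      R0 <- response_association(st$end_s[k], state,
                                 st$concentration_M[k], params)
    } else {
      diss_counter <- diss_counter + 1L
      R_inf <- 0
      if (inherits(params, "partial_params")) {
        R_inf <- if (params$mode == "global") params$phi * R0
                 else min(max(params$plateaus[diss_counter], 0), R0)
      }
      if (length(sel))
        resp[sel] <- response_dissociation_partial(times[sel], state,
                                                   params$k_off, R_inf)
      R0 <- response_dissociation_partial(st$end_s[k], state,
                                          params$k_off, R_inf)
    }
  }
  resp
}

#' Predict a noiseless single-cycle trace
#'
#' Evaluates the piecewise closed-form model over the whole schedule on the
#' continuous assay clock, chaining segments so the trace is exactly
#' continuous at every step boundary. In the global partial-dissociation
#' mode each dissociation plateau is `phi` times the response at the start of
#' that decay; association segments always use the standard form. Pre-analyte
#' steps (negative clock times) evaluate to a zero baseline.
#'
#' @param schedule An [assay_schedule()].
#' @param params A [kinetic_params()] or [partial_params()].
#' @param grid Sample spacing, seconds (default 1, a typical BLI cadence).
#' @param times Optional explicit sample times overriding `grid`.
#' @return An aligned `sensorgram` of the predicted response.
#' @export
predict_trace <- function(schedule, params, grid = 1, times = NULL) {
  if (!inherits(schedule, "assay_schedule"))
    scbli_error("'schedule' must be an assay_schedule", "validation")
  if (!any(schedule$steps$kind == "ASSOCIATION"))
    scbli_error("schedule has no association step to model", "model")
  if (is.null(times)) {
    if (!is_scalar_number(grid) || grid <= 0)
      scbli_error("grid spacing must be positive", "validation")
    times <- seq(min(schedule$steps$start_s), schedule_kinetic_end(schedule),
                 by = grid)
  }
  if (inherits(params, "partial_params") && params$mode == "local") {
    n_diss <- sum(schedule$steps$kind %in% DISSOCIATION_KINDS)
    if (length(params$plateaus) != n_diss)
      scbli_error(sprintf("local mode needs %d plateaus (one per dissociation segment), got %d",
                          n_diss, length(params$plateaus)), "validation")
  }
  sensorgram(times, eval_trace(times, schedule, params),
             step_index = step_index_for(times, schedule),
             schedule = schedule)
}
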