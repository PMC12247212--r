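# Global estimation of 1:1 binding kinetics from a single-cycle sensorgram.
#
# All kinetic segments (associations, mini-dissociations, final dissociation)
# are fitted jointly against the piecewise closed-form model; continuity
# across segments is enforced by construction, so the standard model has only
# three free parameters (k_on, k_off, R_max), the global partial model adds
# the mobile-fraction parameter phi, and the local partial model one plateau
# per dissociation segment. Optimisation is bounded Levenberg-Marquardt
# (minpack.lm) on log10-scaled rates with a small seeded multistart.

FIT_MODELS <- c("standard", "partial_global", "partial_local")

normalise_model <- function(model) {
  m <- gsub("-", "_", tolower(model[1]))
  m <- switch(m, "standard_1_1" = "standard", "global" = "partial_global",
              "local" = "partial_local", m)
  if (!m %in% FIT_MODELS)
    scbli_error(sprintf("unknown model '%s' (use standard, partial_global or partial_local)",
                        model), "validation")
  m
}

#' Fitting options
#'
#' @param k_on_bounds,k_off_bounds,R_max_bounds Box bounds on the rates
#'   (1/(M s), 1/s) and maximal response (nm). The defaults bracket the
#'   dynamic range of BLI (roughly 10 pM to 1 mM affinities).
#' @param phi_bounds Bounds on the mobile-fraction parameter.
#' @param n_starts Multistart size: the first start is the data-driven
#'   initial guess, the rest are jittered up to `jitter_factor` times above
#'   or below it.
#' @param jitter_factor Multiplicative jitter range for extra starts.
#' @param seed RNG seed for the multistart jitter (reproducibility).
#' @param ftol,ptol Levenberg-Marquardt stopping tolerances.
#' @param maxiter Maximum LM iterations per start.
#' @param segment_weights Optional per-kinetic-segment residual weights
#'   (default `NULL`: unweighted across all segments).
#' @return A list of options for [fit_single_cycle()].
#' @export
fit_options <- function(k_on_bounds = c(1e2, 1e8),
                        k_off_bounds = c(1e-7, 1),
                        R_max_bounds = c(1e-6, 10),
                        phi_bounds = c(0, 0.95),
                        n_starts = 5, jitter_factor = 10, seed = 1,
                        ftol = 1e-13, ptol = 1e-13, maxiter = 1024,
                        segment_weights = NULL) {
  list(k_on_bounds = k_on_bounds, k_off_bounds = k_off_bounds,
       R_max_bounds = R_max_bounds, phi_bounds = phi_bounds,
       n_starts = n_starts, jitter_factor = jitter_factor, seed = seed,
       ftol = ftol, ptol = ptol, maxiter = maxiter,
       segment_weights = segment_weights)
}

# Kinetic samples of an aligned sensorgram, with per-sample step kind.
kinetic_data <- function(sg, schedule) {
  if (is.null(sg$step_index))
    sg <- align_to_assay_clock(sg, schedule)
  st <- schedule$steps
  keep <- !is.na(sg$step_index) & st$kinetic[sg$step_index]
  list(t = sg$times[keep], y = sg$responses[keep],
       step = sg$step_index[keep], sg = sg)
}

# robust noise-floor estimate from first differences of the trace
noise_floor <- function(y) {
  if (length(y) < 3) return(0)
  stats::mad(diff(y)) / sqrt(2)
}

# Observed rate of a single exponential segment y ~ a + b exp(-k (t - t0)),
# by 1-D profiling over k with the linear part solved exactly.
segment_observed_rate <- function(t, y, k_range = c(1e-5, 10)) {
  tt <- t - t[1]
  sse <- function(lk) {
    X <- cbind(1, exp(-exp(lk) * tt))
    f <- stats::lm.fit(X, y)
    sum(f$residuals^2)
  }
  opt <- stats::optimize(sse, log(k_range), tol = 1e-8)
  exp(opt$minimum)
}

#' Data-driven starting values for a single-cycle fit
#'
#' `k_off` is guessed from a log-linear regression on the final dissociation;
#' per-well observed rates `k_obs,i` are profiled from each association
#' segment and regressed on concentration (slope = `k_on`); `R_max` is the
#' largest observed response divided by the occupancy those guesses imply at
#' the top concentration. All guesses are clamped to the optimizer bounds.
#'
#' @param sg An aligned `sensorgram` (or one alignable to `schedule`).
#' @param schedule The [assay_schedule()].
#' @param options A [fit_options()] list (for the bounds).
#' @return A [kinetic_params()] guess.
#' @export
initial_guess <- function(sg, schedule, options = fit_options()) {
  kd <- kinetic_data(sg, schedule)
  window <- diff(range(kd$y))
  floor <- noise_floor(kd$y)
  if (window <= 0 || window < 5 * floor)
    scbli_error(paste("response window is below the noise floor; check that",
                      "the sensor produced signal before fitting"), "guess")
  st <- schedule$steps
  clamp <- function(x, b) min(max(x, b[1]), b[2])

  # k_off from the final dissociation (log-linear decay)
  fin <- which(st$kind == "FINAL_DISSOCIATION")
  sel <- kd$step == fin
  tf <- kd$t[sel]; yf <- kd$y[sel]
  k_off <- 1e-3
  if (sum(sel) >= 3 && yf[1] > 0) {
    use <- yf > max(0.05 * yf[1], floor)
    if (sum(use) >= 3) {
      slope <- stats::coef(stats::lm(log(yf[use]) ~ tf[use]))[2]
      if (is.finite(slope) && slope < 0) k_off <- -slope
    }
  }
  k_off <- clamp(k_off, options$k_off_bounds)

  # k_on from regression of per-well observed rates on concentration
  assoc <- which(st$kind == "ASSOCIATION")
  k_obs <- conc <- numeric(0)
  for (a in assoc) {
    sel <- kd$step == a
    if (sum(sel) >= 5) {
      k_obs <- c(k_obs, segment_observed_rate(kd$t[sel], kd$y[sel]))
      conc <- c(conc, st$concentration_M[a])
    }
  }
  k_on <- NA_real_
  if (length(k_obs) >= 2) {
    slope <- stats::coef(stats::lm(k_obs ~ conc))[2]
    if (is.finite(slope) && slope > 0) k_on <- slope
  }
  if (!is.finite(k_on) && length(k_obs) >= 1)
    k_on <- max(k_obs[length(k_obs)] - k_off, 0) / conc[length(conc)]
  if (!is.finite(k_on) || k_on <= 0) k_on <- k_off / stats::median(conc)
  k_on <- clamp(k_on, options$k_on_bounds)

  # R_max from the peak response over the implied top-well occupancy
  c_top <- max(st$concentration_M[assoc])
  occupancy <- k_on * c_top / (k_on * c_top + k_off)
  R_max <- clamp(max(kd$y) / max(occupancy, 0.05), options$R_max_bounds)

  kinetic_params(k_on, k_off, R_max)
}

# pack/unpack between the optimizer vector and parameter objects
pack_theta <- function(params, model) {
  th <- log10(c(k_on = params$k_on, k_off = params$k_off,
                R_max = params$R_max))
  if (model == "partial_global") th <- c(th, phi = params$phi %||% 0.3)
  if (model == "partial_local") {
    pl <- params$plateaus
    names(pl) <- paste0("plateau", seq_along(pl))
    th <- c(th, pl)
  }
  th
}

unpack_theta <- function(theta, model, n_diss = 0) {
  base <- kinetic_params(10^theta[[1]], 10^theta[[2]], 10^theta[[3]])
  switch(model,
    standard = base,
    partial_global = partial_params(base, "global", phi = theta[[4]]),
    partial_local = partial_params(base, "local",
                                   plateaus = pmax(theta[3 + seq_len(n_diss)], 0)))
}

#' Global single-cycle kinetic fit
#'
#' Minimises the unweighted sum of squared residuals between an aligned
#' sensorgram and the piecewise binding model jointly over all kinetic
#' segments. The standard model has three free parameters; the global
#' partial-dissociation model adds `phi`; the local one adds one plateau per
#' dissociation segment. A small seeded multistart around the data-driven
#' initial guess protects against local minima.
#'
#' @param sg A `sensorgram` (aligned, or alignable to `schedule`).
#' @param schedule The [assay_schedule()].
#' @param model `"standard"`, `"partial_global"` or `"partial_local"`.
#' @param options A [fit_options()] list.
#' @return An object of class `scbli_fit`: fitted parameters, residuals,
#'   `N`, `p`, dof-corrected RMSE (and as a fraction of the response
#'   window), convergence info and evaluation counts.
#' @export
fit_single_cycle <- function(sg, schedule, model = "standard",
                             options = fit_options()) {
  model <- normalise_model(model)
  kd <- kinetic_data(sg, schedule)
  st <- schedule$steps
  n_diss <- sum(st$kind %in% DISSOCIATION_KINDS)
  p <- switch(model, standard = 3L, partial_global = 4L,
              partial_local = 3L + n_diss)
  N <- length(kd$y)
  if (N <= p)
    scbli_error(sprintf("need more samples (N = %d) than free parameters (p = %d)",
                        N, p), "dof")

  guess <- initial_guess(kd$sg, schedule, options)
  window <- diff(range(kd$y))

  # residual weights (per kinetic segment, default unweighted)
  wts <- rep(1, N)
  if (!is.null(options$segment_weights)) {
    kin_steps <- which(st$kinetic)
    if (length(options$segment_weights) != length(kin_steps))
      scbli_error("segment_weights must have one entry per kinetic segment",
                  "validation")
    wts <- sqrt(options$segment_weights[match(kd$step, kin_steps)])
  }

  n_eval <- 0L
  resid_fun <- function(theta) {
    n_eval <<- n_eval + 1L
    params <- unpack_theta(theta, model, n_diss)
    (kd$y - eval_trace(kd$t, schedule, params)) * wts
  }

  lb3 <- log10(c(options$k_on_bounds[1], options$k_off_bounds[1],
                 options$R_max_bounds[1]))
  ub3 <- log10(c(options$k_on_bounds[2], options$k_off_bounds[2],
                 options$R_max_bounds[2]))
  lower <- lb3; upper <- ub3
  if (model == "partial_global") {
    lower <- c(lower, options$phi_bounds[1])
    upper <- c(upper, options$phi_bounds[2])
  }
  if (model == "partial_local") {
    lower <- c(lower, rep(0, n_diss))
    upper <- c(upper, rep(options$R_max_bounds[2], n_diss))
  }

  # starting points: data-driven guess first, then seeded jitters
  phi0 <- estimate_phi0(kd, st)
  start_params <- guess
  if (model == "partial_global")
    start_params <- partial_params(guess, "global",
                                   phi = min(phi0, options$phi_bounds[2]))
  if (model == "partial_local")
    start_params <- partial_params(guess, "local",
                                   plateaus = rep(phi0 * window, n_diss))
  theta0 <- pack_theta(start_params, model)
  starts <- with_seed(options$seed, {
    c(list(theta0), lapply(seq_len(max(options$n_starts - 1, 0)), function(i) {
      th <- theta0
      th[1:3] <- th[1:3] + stats::runif(3, -log10(options$jitter_factor),
                                        log10(options$jitter_factor))
      if (model == "partial_global")
        th[4] <- stats::runif(1, 0.02, 0.9)
      if (model == "partial_local")
        th[-(1:3)] <- th[-(1:3)] * stats::runif(n_diss, 0.2, 1.5)
      pmin(pmax(th, lower), upper)
    }))
  })

  best <- NULL
  devs <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(starts[[i]], lower), upper), fn = resid_fun,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          ftol = options$ftol, ptol = options$ptol, gtol = 0,
          maxiter = options$maxiter, maxfev = 100000L)),
      error = function(e) NULL)
    if (is.null(res)) next
    devs[i] <- res$deviance
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    scbli_error("all optimisation starts failed", "convergence",
                start_deviances = devs)
  converged <- best$info %in% c(1:4, 6:8)
  if (!converged)
    scbli_warn(sprintf("fit did not meet convergence tolerances (info %d: %s)",
                       best$info, best$message), "convergence")

  params <- unpack_theta(best$par, model, n_diss)
  residuals <- kd$y - eval_trace(kd$t, schedule, params)
  rmse <- goodness_of_fit(residuals, p)
  structure(list(
    model = model, params = params, residuals = residuals,
    fitted = kd$y - residuals, times = kd$t, step = kd$step,
    N = N, p = p, rmse = rmse, window = window,
    rmse_fraction_of_window = rmse / window,
    converged = converged, info = best$info, message = best$message,
    n_evaluations = n_eval, deviance = best$deviance,
    start_deviances = devs, initial_guess = guess,
    standard_errors = NULL, schedule = schedule, options = options),
    class = "scbli_fit")
}

# crude plateau-fraction estimate from the final-dissociation tail
estimate_phi0 <- function(kd, st) {
  fin <- which(st$kind == "FINAL_DISSOCIATION")
  sel <- kd$step == fin
  y <- kd$y[sel]
  if (sum(sel) < 5 || y[1] <= 0) return(0.3)
  tail_lvl <- stats::median(y[max(1, length(y) - 9):length(y)])
  min(max(tail_lvl / y[1], 0.02), 0.9)
}

#' @export
print.scbli_fit <- function(x, ...) {
  cat(sprintf("Single-cycle fit (%s model)%s\n", x$model,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$params)
  cat(sprintf("  N = %d samples, p = %d free parameters\n", x$N, x$p))
  cat(sprintf("  RMSE = %.4g nm (%.2f%% of the %.4g nm response window)\n",
              x$rmse, 100 * x$rmse_fraction_of_window, x$window))
  if (!is.null(x$standard_errors)) {
    cat("  approximate standard errors:\n")
    print(x$standard_errors)
  }
  invisible(x)
}

#' Degrees-of-freedom-corrected root-mean-squared error
#'
#' RMSE = sqrt( sum (R_obs - R_fit)^2 / (N - p) ), where N is the number of
#' fitted data points and p the number of free parameters of the model.
#'
#' @param residuals Residuals (observed minus fitted), nm.
#' @param p Number of free fitting parameters.
#' @return RMSE in nm.
#' @export
goodness_of_fit <- function(residuals, p) {
  N <- length(residuals)
  if (N <= p)
    scbli_error(sprintf("RMSE needs N > p (N = %d, p = %d)", N, p), "dof")
  sqrt(sum(residuals^2) / (N - p))
}

#' Steady-state affinity from equilibrium plateaus
#'
#' Fits the binding isotherm R_eq(C) = R_max C / (C + K_D) to per-well
#' equilibrium responses -- the usual route for weak binders whose plateaus
#' are reached within each association dwell.
#'
#' @param C Analyte concentrations, molar (>= 3 distinct values).
#' @param Req Equilibrium responses, nm.
#' @return A list with `K_D` (molar), `R_max` (nm) and the `nls` fit object.
#' @export
fit_steady_state <- function(C, Req) {
  if (length(C) != length(Req))
    scbli_error("C and Req must have equal length", "validation")
  if (length(C) < 3)
    scbli_error("steady-state analysis needs at least 3 concentration points",
                "data")
  d <- data.frame(C = as.numeric(C), Req = as.numeric(Req))
  # no curvature = no K_D information: responses proportional to C mean all
  # points sit far below K_D and only R_max/K_D is identified
  lin <- stats::lm(Req ~ C, data = d)
  if (summary(lin)$r.squared > 0.999) {
    scbli_warn(paste("responses are essentially proportional to",
                     "concentration; K_D is unidentifiable from these",
                     "points"), "unidentifiable")
    scbli_error("steady-state K_D unidentifiable: isotherm shows no curvature",
                "data")
  }
  K0 <- stats::approx(d$Req / max(d$Req), d$C, xout = 0.5, rule = 2)$y
  fit <- tryCatch(
    minpack.lm::nlsLM(Req ~ R_max * C / (C + K_D), data = d,
                      start = list(R_max = 1.05 * max(d$Req), K_D = K0),
                      lower = c(R_max = 0, K_D = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      scbli_error(paste("steady-state fit failed:", conditionMessage(e)),
                  "convergence"))
  est <- stats::coef(fit)
  if (est[["K_D"]] > 100 * max(d$C)) {
    scbli_warn(paste("responses are proportional to concentration over the",
                     "sampled range; K_D is unidentifiable (all points far",
                     "below K_D)"), "unidentifiable")
    scbli_error("steady-state K_D unidentifiable from these points", "data")
  }
  if (!any(d$C > est[["K_D"]]) || !any(d$C < est[["K_D"]]))
    scbli_warn("concentration series does not bracket the fitted K_D; estimates may be poorly constrained",
               "design")
  list(K_D = unname(est["K_D"]), R_max = unname(est["R_max"]), fit = fit)
}

#' Asymptotic standard errors of a converged fit
#'
#' Errors are obtained from the Jacobian of the model at the optimum, scaled
#' by the residual variance (the usual local linearisation); they are
#' approximate and do not replace replicate experiments, whose spread should
#' be summarised as mean +/- SD across independent runs.
#'
#' @param fit A converged [fit_single_cycle()] result.
#' @param sg,schedule The data the fit was produced from (defaults to what
#'   is stored in the fit).
#' @return Named vector of standard errors on the natural parameter scale,
#'   with the Jacobian condition number as an attribute.
#' @export
parameter_uncertainty <- function(fit, sg = NULL, schedule = fit$schedule) {
  if (!inherits(fit, "scbli_fit"))
    scbli_error("'fit' must be an scbli_fit", "validation")
  if (!fit$converged)
    scbli_error("standard errors require a converged fit", "uncertainty")
  params <- fit$params
  x0 <- c(k_on = params$k_on, k_off = params$k_off, R_max = params$R_max)
  if (fit$model == "partial_global") x0 <- c(x0, phi = params$phi)
  if (fit$model == "partial_local") {
    pl <- params$plateaus
    names(pl) <- paste0("plateau", seq_along(pl))
    x0 <- c(x0, pl)
  }
  n_diss <- sum(schedule$steps$kind %in% DISSOCIATION_KINDS)
  predict_at <- function(x) {
    base <- kinetic_params(x[[1]], x[[2]], x[[3]])
    pr <- switch(fit$model,
      standard = base,
      partial_global = partial_params(base, "global",
                                      phi = min(max(x[[4]], 0), 0.95)),
      partial_local = partial_params(base, "local",
                                     plateaus = pmax(x[3 + seq_len(n_diss)], 0)))
    eval_trace(fit$times, schedule, pr)
  }
  J <- sapply(seq_along(x0), function(j) {
    h <- 1e-6 * abs(x0[j]) + 1e-12
    xp <- x0; xm <- x0
    xp[j] <- x0[j] + h; xm[j] <- max(x0[j] - h, 0)
    (predict_at(xp) - predict_at(xm)) / (xp[j] - xm[j])
  })
  sv <- svd(J, nu = 0, nv = 0)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (!is.finite(cond) || cond > 1e12)
    scbli_error(sprintf("Jacobian is ill-conditioned (condition number %.3g); standard errors are not reliable",
                        cond), "uncertainty", condition_number = cond)
  s2 <- sum(fit$residuals^2) / (fit$N - fit$p)
  covm <- tryCatch(solve(crossprod(J)) * s2, error = function(e)
    scbli_error("Jacobian cross-product is singular", "uncertainty",
                condition_number = cond))
  se <- sqrt(pmax(diag(covm), 0))
  names(se) <- names(x0)
  attr(se, "condition_number") <- cond
  attr(se, "approximate") <- TRUE
  se
}

#' Rank binders by expression level from loading traces
#'
#' Under pseudo-first-order covalent capture the loading response follows
#' R(t) = R_sat (1 - exp(-k_obs t)) with k_obs proportional to the binder
#' concentration in the well, while the plateau R_sat is set by the sensor's
#' capture capacity. Segments are therefore ranked by their fitted k_obs
#' (descending); traces having reached >= 95% of R_sat are flagged
#' saturated.
#'
#' @param loading_segments A (optionally named) list of `sensorgram`s, each
#'   covering one LOADING step with time measured from the start of loading.
#' @return A `data.frame` with one row per sensor, ordered by rank: fitted
#'   `k_obs` (1/s), `R_sat` (nm), `saturated` flag, `rank_score` (= k_obs)
#'   and `rank`.
#' @export
rank_expression <- function(loading_segments) {
  if (!is.list(loading_segments) || length(loading_segments) == 0)
    scbli_error("provide a non-empty list of loading-segment sensorgrams",
                "data")
  ids <- names(loading_segments) %||% paste0("sensor", seq_along(loading_segments))
  ids[ids == ""] <- paste0("sensor", which(ids == ""))
  rows <- lapply(seq_along(loading_segments), function(i) {
    sg <- loading_segments[[i]]
    t <- sg$times - sg$times[1]; y <- sg$responses
    floor <- noise_floor(y)
    if (diff(range(y)) <= 0 || diff(range(y)) < 5 * floor || max(y) <= 0) {
      scbli_warn(sprintf("loading trace '%s' is flat; k_obs cannot be fitted",
                         ids[i]), "quality")
      return(data.frame(sensor = ids[i], k_obs = NA_real_, R_sat = NA_real_,
                        saturated = FALSE, rank_score = NA_real_))
    }
    n <- length(y)
    if (stats::median(y[max(1, n - 4):n]) <
        stats::median(y[seq_len(min(5, n))]) - 5 * floor)
      scbli_warn(sprintf("loading trace '%s' decreases beyond noise; ranking it anyway",
                         ids[i]), "quality")
    # profile the capture rate, solving R_sat linearly at each candidate rate
    sse <- function(lk) {
      b <- 1 - exp(-exp(lk) * t)
      R <- sum(b * y) / sum(b * b)
      sum((y - R * b)^2)
    }
    opt <- stats::optimize(sse, log(c(1e-6, 10)), tol = 1e-10)
    k <- exp(opt$minimum)
    b <- 1 - exp(-k * t)
    R_sat <- sum(b * y) / sum(b * b)
    data.frame(sensor = ids[i], k_obs = k, R_sat = R_sat,
               saturated = max(y) >= 0.95 * R_sat, rank_score = k)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rank_score, na.last = TRUE), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Compare standard and partial-dissociation fits
#'
#' Parsimony rule: the partial model is preferred only when it reduces the
#' RMSE by at least `rmse_gain` (relative) and its fitted `phi` is at least
#' `phi_min` -- otherwise the simpler standard model is kept.
#'
#' @param standard_fit,partial_fit `scbli_fit`s of the two models on the
#'   same data.
#' @param rmse_gain Minimum relative RMSE reduction (default 0.05).
#' @param phi_min Minimum fitted phi (default 0.02).
#' @return The selected `scbli_fit`.
#' @export
select_model <- function(standard_fit, partial_fit, rmse_gain = 0.05,
                         phi_min = 0.02) {
  gain <- (standard_fit$rmse - partial_fit$rmse) / standard_fit$rmse
  phi <- partial_fit$params$phi %||%
    (max(partial_fit$params$plateaus) / max(partial_fit$fitted))
  if (is.finite(gain) && gain >= rmse_gain && phi >= phi_min) partial_fit
  else standard_fit
}
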