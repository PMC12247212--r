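# Independent numerical oracle for the standard 1:1 model: integrate the
# mass-action ODE dR/dt = k_on C (R_max - R) - k_off R segment by segment
# with deSolve, restarting at every step boundary so the integrator never
# smooths over the concentration discontinuities.
ode_trace <- function(times, schedule, params) {
  st <- schedule$steps
  st <- st[st$kinetic, , drop = FALSE]
  out <- rep(0, length(times))
  R0 <- 0
  for (k in seq_len(nrow(st))) {
    C <- if (st$kind[k] == "ASSOCIATION") st$concentration_M[k] else 0
    in_seg <- times >= st$start_s[k] & times < st$end_s[k]
    if (k == nrow(st)) in_seg <- in_seg | times == st$end_s[k]
    grid <- sort(unique(c(st$start_s[k], times[in_seg], st$end_s[k])))
    sol <- deSolve::lsoda(
      c(R = R0), grid,
      function(t, y, parms)
        list(params$k_on * C * (params$R_max - y) - params$k_off * y),
      rtol = 1e-12, atol = 1e-14)
    if (any(in_seg))
      out[in_seg] <- approx(sol[, 1], sol[, 2], xout = times[in_seg])$y
    R0 <- sol[nrow(sol), 2]
  }
  out
}

# log-uniform draw
runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))
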