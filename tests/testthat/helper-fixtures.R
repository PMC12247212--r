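# Shared synthetic-study conditions: a mid-nanomolar binder probed with the
# five-well default schedule (25-400 nM, 1:2 series), matching a typical
# nanobody single-cycle run.
nb_params <- function() kinetic_params(2.3e5, 1.12e-2, 0.14)
nb_schedule <- function() default_schedule(c(25, 50, 100, 200, 400) * 1e-9)

noiseless <- function() noise_model(sigma = 0, drift = 0, step_shift_sd = 0)

# K_D span mimicking a broad affinity panel (pM to high nM), with the
# concentration series scaled to each K_D (0.625x to 10x, 1:2 dilutions)
# and a long final dissociation for the slow-dissociating picomolar binders.
panel_sets <- function() list(
  list(kd = 3e-12,   k_on = 1.3e6),
  list(kd = 53e-12,  k_on = 1.6e6),
  list(kd = 143e-12, k_on = 2.3e6),
  list(kd = 0.67e-9, k_on = 1.7e6),
  list(kd = 6.7e-9,  k_on = 1.71e5),
  list(kd = 49.6e-9, k_on = 2.3e5),
  list(kd = 772e-9,  k_on = 3.2e5))

panel_schedule <- function(kd) {
  default_schedule(kd * c(0.625, 1.25, 2.5, 5, 10), long_final = kd < 1e-10)
}
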