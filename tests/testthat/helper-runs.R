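# Shared simulation cache: the expensive reference runs are computed once
# per test session and reused across test files.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

run_therapeutic <- function() cached_run("ther", simulate_protocol(
  oral_dose(1000, horizon = 96)))

run_22g <- function() cached_run("d22", simulate_protocol(
  oral_dose(22000, horizon = 96)))

run_22g_nac <- function(protocol_id, start_hr = 2) {
  key <- paste0("d22nac", protocol_id, "_", start_hr)
  cached_run(key, {
    ev <- rbind(oral_dose(22000, horizon = 96)$events,
                nac_protocol(protocol_id, start_hr))
    simulate_protocol(dosing_protocol(ev, horizon = 96))
  })
}

run_chronic <- function() cached_run("chronic", chronic_dosing_study())

run_boundary <- function() cached_run("boundary", survival_boundary(
  c(2, 12), thresholds = 0.30, dose_range_g = c(8, 120), horizon = 96))

run_boundary3 <- function() cached_run("boundary3", survival_boundary(
  8, thresholds = c(0.25, 0.30, 0.35), dose_range_g = c(8, 120),
  horizon = 96))

state_names_for_test <- function() apapsim:::state_names

# trajectory value at a time point (linear interpolation)
at_time <- function(traj, var, t) {
  stats::approx(traj$time, traj[[var]], xout = t, rule = 2)$y
}
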