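#' Convert an oral APAP dose to a gut concentration increment
#'
#' An oral dose is deposited in the gut compartment as a concentration jump:
#' `dose_mg * bioavailability / MW_APAP / vG` expressed in uM
#' (MW of acetaminophen 151.16 g/mol). With the defaults (75%
#' bioavailability, 1 L gut volume) a typical 20 mg/kg therapeutic dose for a
#' 60 kg adult (1200 mg) gives about 6000 uM.
#'
#' @param dose_mg oral dose in mg (vectorized, nonnegative).
#' @param params an [apap_parameters()] object.
#' @return concentration added to gut APAP, in uM.
#' @examples
#' dose_to_gut_concentration(1200, apap_parameters())  # ~ 5954 uM
#' @export
dose_to_gut_concentration <- function(dose_mg, params = apap_parameters()) {
  if (any(!is.finite(dose_mg)) || any(dose_mg < 0))
    stop("'dose_mg' must be finite and nonnegative")
  ## mg -> mmol -> umol, into vG liters -> uM
  dose_mg * params$bioavailability / params$mw_apap * 1000 / params$vG
}

#' Create a dosing protocol
#'
#' A dosing protocol is an ordered schedule of dose events over a simulation
#' horizon. Two kinds of event exist: instantaneous oral APAP boluses
#' (`kind = "oral_apap"`, amount in mg, duration 0) and constant-rate NAC
#' infusions (`kind = "nac_infusion"`, amount in mmol delivered over
#' `duration` hours into the plasma compartment).
#'
#' @param events data.frame with columns `time` (hr), `kind`, `amount`,
#'   `duration` (hr); may have zero rows.
#' @param horizon simulation horizon in hours (all event times must be
#'   strictly smaller).
#' @return object of class `dosing_protocol`.
#' @seealso [oral_dose()], [build_chronic_regimen()], [nac_protocol()]
#' @export
dosing_protocol <- function(events = NULL, horizon = 48) {
  if (is.null(events))
    events <- data.frame(time = numeric(), kind = character(),
                         amount = numeric(), duration = numeric())
  stopifnot(is.data.frame(events),
            all(c("time", "kind", "amount", "duration") %in% names(events)))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("'horizon' must be a single positive number of hours")
  if (nrow(events)) {
    if (any(events$time < 0)) stop("event times must be >= 0")
    if (any(events$amount < 0)) stop("event amounts must be >= 0")
    if (!all(events$kind %in% c("oral_apap", "nac_infusion")))
      stop("unknown event kind; use 'oral_apap' or 'nac_infusion'")
    bad_bolus <- events$kind == "oral_apap" & events$duration != 0
    if (any(bad_bolus)) stop("oral_apap events must have duration 0")
    bad_inf <- events$kind == "nac_infusion" & events$duration <= 0
    if (any(bad_inf)) stop("nac_infusion events must have duration > 0")
    if (any(events$time >= horizon))
      stop("all event times must be < horizon (", horizon, " hr)")
    events <- events[order(events$time, events$kind), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(events = events, horizon = horizon),
            class = "dosing_protocol")
}

#' @export
print.dosing_protocol <- function(x, ...) {
  cat("<dosing_protocol> horizon", x$horizon, "hr,",
      nrow(x$events), "event(s)\n")
  if (nrow(x$events)) print(utils::head(x$events, 10))
  invisible(x)
}

#' Single oral APAP bolus protocol
#'
#' @param dose_mg oral dose in mg.
#' @param time_hr dose time (hr), default 0.
#' @param horizon simulation horizon (hr).
#' @return a [dosing_protocol()].
#' @export
oral_dose <- function(dose_mg, time_hr = 0, horizon = 48) {
  dosing_protocol(data.frame(time = time_hr, kind = "oral_apap",
                             amount = dose_mg, duration = 0),
                  horizon = horizon)
}

#' Chronic oral dosing regimen
#'
#' Repeated oral boluses of `dose_mg` every `interval_hr` hours starting at
#' t = 0; the number of boluses is `floor(24 * days / interval_hr)`.
#'
#' @param dose_mg per-dose amount in mg.
#' @param interval_hr dosing interval in hours.
#' @param days length of the regimen in days.
#' @param extra_hr simulated time after the last scheduled dose window
#'   (default 0; the horizon is `24 * days + extra_hr`).
#' @return a [dosing_protocol()].
#' @examples
#' pr <- build_chronic_regimen(1000, 6, 10)  # 40 doses, 40 g total
#' nrow(pr$events)
#' @export
build_chronic_regimen <- function(dose_mg, interval_hr, days, extra_hr = 0) {
  if (dose_mg <= 0 || interval_hr <= 0 || days <= 0)
    stop("dose, interval and days must be positive")
  if (interval_hr > 24 * days)
    stop("interval_hr exceeds the regimen length")
  n <- floor(24 * days / interval_hr)
  dosing_protocol(
    data.frame(time = (seq_len(n) - 1) * interval_hr, kind = "oral_apap",
               amount = dose_mg, duration = 0),
    horizon = 24 * days + extra_hr)
}

#' NAC infusion protocols 1-3
#'
#' The three N-acetylcysteine rescue schedules studied with the model, each
#' delivering the same total amount:
#' \describe{
#'   \item{protocol 1}{the full amount infused over 1 hour;}
#'   \item{protocol 2}{the full amount at constant rate over 10 hours;}
#'   \item{protocol 3}{the clinical staged schedule: 1/2 of the amount over
#'     1 hour, then 1/6 over the next 4 hours, then 1/3 over a further
#'     16 hours (21 hours in all).}
#' }
#'
#' @param which protocol id, 1, 2 or 3.
#' @param start_hr infusion start time (hr after t = 0).
#' @param total_amount_mmol total NAC amount in mmol (default 36, the
#'   standard rescue amount; distributed into the plasma volume it
#'   corresponds to a 12 mM rise per hour during a 1-hour infusion).
#' @return data.frame of `nac_infusion` events (a protocol fragment to pass
#'   to [dosing_protocol()] or append to other events).
#' @examples
#' nac_protocol(3, start_hr = 2)   # three windows, amounts 18, 6, 12 mmol
#' @export
nac_protocol <- function(which, start_hr, total_amount_mmol = 36) {
  if (start_hr < 0) stop("'start_hr' must be >= 0")
  if (total_amount_mmol < 0) stop("'total_amount_mmol' must be >= 0")
  if (!length(which) == 1L || !which %in% 1:3)
    stop("unknown NAC protocol id: ", paste(which, collapse = ","),
         " (use 1, 2 or 3)")
  if (which == 1) {
    data.frame(time = start_hr, kind = "nac_infusion",
               amount = total_amount_mmol, duration = 1)
  } else if (which == 2) {
    data.frame(time = start_hr, kind = "nac_infusion",
               amount = total_amount_mmol, duration = 10)
  } else {
    data.frame(time = start_hr + c(0, 1, 5), kind = "nac_infusion",
               amount = total_amount_mmol * c(1 / 2, 1 / 6, 1 / 3),
               duration = c(1, 4, 16))
  }
}

## Piecewise-constant plasma NAC infusion rate (uM/hr) implied by a
## protocol's infusion events: amount (mmol) spread over the window and
## diluted into the plasma volume. Returns a function of time.
nac_rate_fun <- function(protocol, params) {
  ev <- protocol$events
  inf <- ev[ev$kind == "nac_infusion", , drop = FALSE]
  if (!nrow(inf)) return(function(t) 0)
  starts <- inf$time
  ends <- inf$time + inf$duration
  ## mmol -> umol, over vP liters and duration hours -> uM/hr
  rates <- inf$amount * 1000 / params$vP / inf$duration
  function(t) {
    active <- t >= starts & t < ends
    if (any(active)) sum(rates[active]) else 0
  }
}
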