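## Full right-hand side of the whole-body APAP ODE system.
##
## State layout (all concentrations uM within their own compartment;
## hepatocytes tracked as fractions of carrying capacity for numerical
## conditioning and converted to cell counts in trajectories):
##   gut:    gapap
##   plasma: papap, pas, pag, pnqgsh, pgsh, pnac
##   liver:  lapap, lpaps, las, lag, lnq, lcov, lnqgsh, lgsh, lcys, fh, fz
##   tissue: tapap, tpaps, tas, tag
##   urine:  uapap, uas, uag, unqgsh

state_names <- c("gapap",
                 "papap", "pas", "pag", "pnqgsh",
                 "lapap", "lpaps", "las", "lag", "lnq", "lcov", "lnqgsh",
                 "lgsh", "fh", "fz",
                 "tapap", "tpaps", "tas", "tag",
                 "uapap", "uas", "uag", "unqgsh",
                 "pgsh", "lcys", "pnac")

#' Drug-free baseline state of the model
#'
#' The pre-dose steady state: all APAP-pathway species zero, PAPS pools at
#' their synthesis/removal balance (`V/k`), liver GSH and cysteine at their
#' calibrated baselines, plasma GSH at its export/clearance balance,
#' functional hepatocytes at carrying capacity. This state is an exact
#' equilibrium of [apap_rhs()] by construction of the parameter sets.
#'
#' @param params an [apap_parameters()] object.
#' @param gsh_params a [gsh_parameters()] object.
#' @return named numeric state vector.
#' @export
baseline_state <- function(params = apap_parameters(),
                           gsh_params = gsh_parameters()) {
  s <- stats::setNames(numeric(length(state_names)), state_names)
  s["lpaps"] <- params$V_lpaps / params$k_lpaps
  s["tpaps"] <- params$V_tpaps / params$k_tpaps
  s["lgsh"] <- gsh_params$lgsh_baseline
  s["pgsh"] <- pgsh_baseline(params, gsh_params)
  s["lcys"] <- gsh_params$cys_baseline
  s["fh"] <- 1
  s["fz"] <- 0
  s
}

## Tolerance below which negative solver undershoot triggers a warning
## rather than silent clipping.
NEG_STATE_TOL <- 1e-6

#' Right-hand side of the whole-body APAP model
#'
#' Derivatives of all 26 state variables: linear inter-compartment transport
#' (with volume-ratio factors so transfers are expressed in the receiving
#' compartment's concentration units), hepatic and tissue metabolism through
#' the [v_cyp_total()], [v_ugt_total()], [v_sult()] and [v_gst()] rate laws,
#' reversible covalent binding of NAPQI, logistic hepatocyte
#' regeneration with covalent-binding-driven necrosis, and the glutathione
#' surrogate ([gsh_rhs_terms()]).
#'
#' Signature follows `deSolve` conventions and can be passed directly to
#' [deSolve::lsoda()].
#'
#' @param t time (hr).
#' @param state named numeric vector in the `state_names` layout
#'   (see [baseline_state()]).
#' @param parms list with elements `params` ([apap_parameters()]), `gsh`
#'   ([gsh_parameters()]) and optionally `nac_rate` (uM/hr into plasma,
#'   default 0, may be a function of time).
#' @return `list(derivatives)` per deSolve convention.
#' @export
apap_rhs <- function(t, state, parms) {
  if (any(!is.finite(state))) {
    bad <- names(state)[!is.finite(state)][1L]
    stop("non-finite state at t = ", signif(t, 6), " in variable '", bad, "'")
  }
  if (any(state < -NEG_STATE_TOL)) {
    bad <- names(state)[which.min(state)]
    warning("state undershoot below -", NEG_STATE_TOL, " clipped at t = ",
            signif(t, 6), " ('", bad, "' = ", signif(min(state), 4), ")")
  }
  p <- parms$params
  g <- parms$gsh
  nac_rate <- parms$nac_rate
  if (is.null(nac_rate)) nac_rate <- 0
  if (is.function(nac_rate)) nac_rate <- nac_rate(t)

  s <- pmax(state, 0)
  gapap <- s[["gapap"]]; papap <- s[["papap"]]; pas <- s[["pas"]]
  pag <- s[["pag"]]; pnqgsh <- s[["pnqgsh"]]
  lapap <- s[["lapap"]]; lpaps <- s[["lpaps"]]; las <- s[["las"]]
  lag <- s[["lag"]]; lnq <- s[["lnq"]]; lcov <- s[["lcov"]]
  lnqgsh <- s[["lnqgsh"]]; lgsh <- s[["lgsh"]]
  fh <- s[["fh"]]; fz <- s[["fz"]]
  tapap <- s[["tapap"]]; tpaps <- s[["tpaps"]]; tas <- s[["tas"]]
  tag <- s[["tag"]]
  uapap <- s[["uapap"]]; uas <- s[["uas"]]; uag <- s[["uag"]]
  unqgsh <- s[["unqgsh"]]
  pgsh <- s[["pgsh"]]; lcys <- s[["lcys"]]; pnac <- s[["pnac"]]

  ## metabolic velocities
  vcyp <- v_cyp_total(lapap, p)
  vlugt <- v_ugt_total(lapap, p, "liver")
  vlsult <- v_sult(lapap, lpaps, p, "liver")
  vtugt <- v_ugt_total(tapap, p, "tissue")
  vtsult <- v_sult(tapap, tpaps, p, "tissue")
  vgst_ <- v_gst(lnq, lgsh, p)

  ## glutathione surrogate
  vsyn <- gsh_synthesis(lcys, lgsh / g$lgsh_baseline, g, fh)
  vexp <- gsh_export_flux(lgsh, g)

  ## urine transfer factor for the NAPQI-GSH conjugate (see ?apap_parameters)
  u_nqg <- if (p$mass_consistent_urine_transfer) p$vP / p$vU else 1

  d <- numeric(length(state))
  names(d) <- state_names

  d["gapap"] <- -p$k_gl * gapap
  d["papap"] <- p$k_tp * (p$vT / p$vP) * tapap - p$k_pt * papap +
    p$k_lp * (p$vL / p$vP) * lapap - p$k_pl * papap - p$k_pu * papap
  d["pas"] <- p$k_slp * (p$vL / p$vP) * las +
    p$k_stp * (p$vT / p$vP) * tas - p$k_spu * pas
  d["pag"] <- p$k_glp * (p$vL / p$vP) * lag +
    p$k_gtp * (p$vT / p$vP) * tag - p$k_gpu * pag
  d["pnqgsh"] <- p$k_nqglp * (p$vL / p$vP) * lnqgsh - p$k_nqgpu * pnqgsh

  d["lapap"] <- p$k_gl * (p$vG / p$vL) * gapap +
    p$k_pl * (p$vP / p$vL) * papap - p$k_lp * lapap -
    vcyp - vlsult - vlugt
  d["lpaps"] <- p$V_lpaps - vlsult - p$k_lpaps * lpaps
  d["las"] <- vlsult - p$k_slp * las
  d["lag"] <- vlugt - p$k_glp * lag
  d["lnq"] <- vcyp - vgst_ + p$k_rev * lcov - p$k_bind * lnq
  d["lcov"] <- p$k_bind * lnq - p$k_rev * lcov
  d["lnqgsh"] <- vgst_ - p$k_nqglp * lnqgsh
  d["lgsh"] <- vsyn - vgst_ - g$k_gsh_deg * lgsh - vexp
  d["fh"] <- p$r_hep * fh * (1 - (fh + fz)) - p$eta * lcov * fh
  d["fz"] <- p$eta * lcov * fh - p$delta_z * fz

  d["tapap"] <- p$k_pt * (p$vP / p$vT) * papap - p$k_tp * tapap -
    vtsult - vtugt
  d["tpaps"] <- p$V_tpaps - vtsult - p$k_tpaps * tpaps
  d["tas"] <- vtsult - p$k_stp * tas
  d["tag"] <- vtugt - p$k_gtp * tag

  d["uapap"] <- p$k_pu * (p$vP / p$vU) * papap - p$k_u * uapap
  d["uas"] <- p$k_spu * (p$vP / p$vU) * pas - p$k_u * uas
  d["uag"] <- p$k_gpu * (p$vP / p$vU) * pag - p$k_u * uag
  d["unqgsh"] <- p$k_nqgpu * u_nqg * pnqgsh - p$k_u * unqgsh

  d["pgsh"] <- vexp * (p$vL / p$vP) - g$k_pgsh_clear * pgsh
  d["lcys"] <- g$J_cys - cys_catabolism(lcys, g) +
    g$k_nac_to_cys * pnac * (p$vP / p$vL) - vsyn
  d["pnac"] <- nac_rate - g$k_nac_clear * pnac - g$k_nac_to_cys * pnac

  list(d)
}

#' Volume-weighted APAP-moiety total (umol)
#'
#' Sums every species that carries the APAP moiety (parent drug, sulfate and
#' glucuronide conjugates, NAPQI, covalently bound NAPQI and the NAPQI-GSH
#' conjugate) weighted by its compartment volume. With urinary elimination
#' and PAPS turnover disabled and `mass_consistent_urine_transfer = TRUE`,
#' this total is conserved by the dynamics; used by the conservation tests.
#'
#' @param state named state vector.
#' @param params an [apap_parameters()] object.
#' @return total micromoles of APAP moiety in the body.
#' @export
apap_moiety_umol <- function(state, params) {
  p <- params
  s <- state
  p$vG * s[["gapap"]] +
    p$vP * (s[["papap"]] + s[["pas"]] + s[["pag"]] + s[["pnqgsh"]]) +
    p$vL * (s[["lapap"]] + s[["las"]] + s[["lag"]] + s[["lnq"]] +
              s[["lcov"]] + s[["lnqgsh"]]) +
    p$vT * (s[["tapap"]] + s[["tas"]] + s[["tag"]]) +
    p$vU * (s[["uapap"]] + s[["uas"]] + s[["uag"]] + s[["unqgsh"]])
}
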