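#' Parameters of the hepatic glutathione surrogate submodel
#'
#' The whole-body APAP model consumes liver glutathione (GSH) through GST
#' conjugation of NAPQI. GSH supply is represented here by a compact
#' four-state surrogate of hepatic glutathione turnover (liver GSH, plasma
#' GSH, liver cysteine, plasma NAC) rather than a full glutathione-metabolism
#' network: synthesis from cysteine with saturable kinetics and strong
#' product feedback, basal degradation, saturable sinusoidal export to
#' plasma, and stimulation of synthesis by infused N-acetylcysteine (NAC)
#' acting as a cysteine source.
#'
#' Structure:
#' \describe{
#' \item{synthesis}{`V_syn = V_syn_max * lcys/(Km_cys + lcys) *
#'   1/(1 + feedback_strength * (lgsh/lgsh_baseline)^feedback_hill)`.
#'   The Hill-shaped feedback makes net resupply very small near baseline
#'   (GSH takes days to regain its last few percent) yet strong once GSH has
#'   fallen by a third or more.}
#' \item{liver GSH}{`d(lgsh)/dt = V_syn - V_GST - k_gsh_deg*lgsh -
#'   V_gsh_export*lgsh/(Km_gsh_export + lgsh)`. Export is saturable, so
#'   plasma GSH falls proportionally less than liver GSH under chronic
#'   load.}
#' \item{plasma GSH}{`d(pgsh)/dt = export*(vL/vP) - k_pgsh_clear*pgsh`.}
#' \item{liver cysteine}{`d(lcys)/dt = J_cys -
#'   k_cys_clear*lcys*(1 + lcys/Km_cys_catab) + k_nac_to_cys*pnac*(vP/vL) -
#'   V_syn`; the constant supply `J_cys` is derived so that `cys_baseline`
#'   is the no-drug steady state. The finite supply caps sustained GSH
#'   synthesis during deep depletion, and the substrate-induced (superlinear)
#'   catabolism disposes of bolus cysteine loads disproportionately, which
#'   is why slow NAC infusions outperform a one-hour bolus.}
#' \item{plasma NAC}{`d(pnac)/dt = infusion_rate(t) - k_nac_clear*pnac -
#'   k_nac_to_cys*pnac`.}
#' }
#'
#' With `hep_scale_synthesis = TRUE` (default) the synthesis capacity is
#' multiplied by the functional-hepatocyte fraction (necrotic liver cannot
#' synthesize GSH); `hep_scale_floor` sets a residual capacity fraction.
#'
#' `V_syn_max` and `J_cys` are derived in the constructor from the
#' steady-state identities at `lgsh = lgsh_baseline`, `lcys = cys_baseline`,
#' so the drug-free baseline is an exact equilibrium by construction.
#'
#' The shipped defaults are the result of calibrating the integrated model
#' against its target behaviours (see [gsh_calibration_report()]): about 10%
#' liver-GSH depletion after a therapeutic 1 g dose with slow (>48 h)
#' recovery, near-complete depletion between 2 and 10 h after 15 g, GSH
#' recovery onset near 40 h after 20 g, and chronic-dosing steady states of
#' about 70% (liver) and 88% (plasma) of baseline.
#'
#' @param ... named overrides of any default value.
#' @return An object of class `gsh_parameters` (named list, validated, with
#'   derived members `V_syn_max` and `J_cys` unless explicitly overridden).
#' @seealso [gsh_rhs_terms()], [gsh_calibrate()], [apap_parameters()]
#' @export
gsh_parameters <- function(...) {
  g <- list(
    lgsh_baseline = 7000,    # uM, hepatic GSH steady state
    k_gsh_deg = 3.1837e-4,   # 1/hr basal degradation (2.23 uM/hr at baseline)
    V_gsh_export = 5.5334,   # uM/hr max sinusoidal export (3.77 at baseline)
    Km_gsh_export = 3270,    # uM
    k_pgsh_clear = 0.2,      # 1/hr plasma GSH clearance
    feedback_strength = 60,  # product inhibition of synthesis by GSH
    feedback_hill = 12,      # its Hill exponent
    Km_cys = 4000,           # uM
    cys_baseline = 850,      # uM hepatic cysteine/precursor steady state
    k_cys_clear = 0.169412,  # 1/hr basal cysteine catabolism
    Km_cys_catab = 1700,     # uM; catabolism doubles at this level (CDO induction)
    k_nac_to_cys = 2,        # 1/hr plasma NAC -> liver cysteine
    k_nac_clear = 1,         # 1/hr plasma NAC elimination
    hep_scale_synthesis = TRUE,  # scale synthesis by functional liver mass
    hep_scale_floor = 0,     # residual capacity fraction at complete necrosis
    V_syn_max = NULL,        # uM/hr, derived if NULL
    J_cys = NULL             # uM/hr, derived if NULL
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), names(g))
    if (length(unknown))
      stop("unknown GSH parameter(s): ", paste(unknown, collapse = ", "))
    g[names(dots)] <- dots
  }
  ## baseline turnover of liver GSH (uM/hr): degradation + export at baseline
  turnover <- g$k_gsh_deg * g$lgsh_baseline +
    g$V_gsh_export * g$lgsh_baseline / (g$Km_gsh_export + g$lgsh_baseline)
  if (is.null(g$V_syn_max)) {
    ## synthesis at baseline must equal turnover:
    ## V_syn_max * sat(cys_b) / (1 + fb) = turnover
    g$V_syn_max <- turnover * (1 + g$feedback_strength) *
      (g$Km_cys + g$cys_baseline) / g$cys_baseline
  }
  if (is.null(g$J_cys)) {
    ## cysteine supply balances clearance + baseline synthesis consumption
    g$J_cys <- cys_catabolism(g$cys_baseline, g) + turnover
  }
  g <- structure(g, class = "gsh_parameters")
  validate_gsh_parameters(g)
  g
}

validate_gsh_parameters <- function(g) {
  pos <- c("lgsh_baseline", "k_gsh_deg", "V_gsh_export", "Km_gsh_export",
           "k_pgsh_clear", "feedback_strength", "feedback_hill", "Km_cys",
           "cys_baseline", "k_cys_clear", "k_nac_to_cys", "k_nac_clear",
           "Km_cys_catab", "V_syn_max", "J_cys")
  if (!is.numeric(g$hep_scale_floor) || length(g$hep_scale_floor) != 1L ||
      g$hep_scale_floor < 0 || g$hep_scale_floor >= 1)
    stop("hep_scale_floor must be in [0, 1)")
  for (nm in pos) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("GSH parameter '", nm, "' must be a single strictly positive number")
  }
  if (!is.logical(g$hep_scale_synthesis) || length(g$hep_scale_synthesis) != 1L)
    stop("hep_scale_synthesis must be TRUE or FALSE")
  invisible(g)
}

#' @export
print.gsh_parameters <- function(x, ...) {
  cat("<gsh_parameters> hepatic glutathione surrogate submodel\n")
  cat(sprintf("  baseline: liver GSH %g uM, cysteine %g uM\n",
              x$lgsh_baseline, x$cys_baseline))
  cat(sprintf("  synthesis: V_syn_max %.4g uM/hr, Km_cys %g uM, feedback %g (Hill %g)\n",
              x$V_syn_max, x$Km_cys, x$feedback_strength, x$feedback_hill))
  cat(sprintf("  turnover: k_deg %.3g /hr, export %.3g uM/hr (Km %g uM)\n",
              x$k_gsh_deg, x$V_gsh_export, x$Km_gsh_export))
  invisible(x)
}

## GSH synthesis velocity (uM/hr) at given precursor level and GSH
## fraction x = lgsh/baseline (steep Hill-shaped product feedback). When
## hep_scale_synthesis is on, capacity scales with the functional
## hepatocyte fraction fh (necrotic liver cannot synthesize GSH), with an
## optional residual floor.
gsh_synthesis <- function(lcys, x, g, fh = 1) {
  cap <- if (isTRUE(g$hep_scale_synthesis))
    g$hep_scale_floor + (1 - g$hep_scale_floor) * min(fh, 1) else 1
  cap * g$V_syn_max * (lcys / (g$Km_cys + lcys)) /
    (1 + g$feedback_strength * max(x, 0)^g$feedback_hill)
}

## Saturable liver -> plasma GSH export flux (uM/hr in liver units).
gsh_export_flux <- function(lgsh, g) {
  g$V_gsh_export * lgsh / (g$Km_gsh_export + lgsh)
}

## Cysteine catabolism flux (uM/hr): first-order at baseline levels but
## superlinear at excess (cysteine dioxygenase is substrate-induced), so
## bolus cysteine loads are disposed of disproportionately.
cys_catabolism <- function(lcys, g) {
  g$k_cys_clear * lcys * (1 + lcys / g$Km_cys_catab)
}

#' Glutathione submodel derivative contributions
#'
#' Computes the four derivative contributions of the glutathione surrogate:
#' `d(lgsh)/dt` (including the conjugation loss `-V_GST` against liver
#' NAPQI), `d(pgsh)/dt`, `d(lcys)/dt` and `d(pnac)/dt`. Used by [apap_rhs()]
#' and directly testable at the drug-free baseline, where all four
#' contributions are zero.
#'
#' @param state named numeric vector containing at least `lgsh`, `pgsh`,
#'   `lcys`, `pnac` and `lnq` (all uM).
#' @param params an [apap_parameters()] object (for GST kinetics and the
#'   plasma/liver volume ratio).
#' @param gsh_params a [gsh_parameters()] object.
#' @param nac_rate NAC infusion rate into plasma, uM/hr (default 0).
#' @return named list with elements `dlgsh`, `dpgsh`, `dlcys`, `dpnac`
#'   (uM/hr) and the fluxes `v_syn`, `v_gst`, `v_export`.
#' @export
gsh_rhs_terms <- function(state, params, gsh_params, nac_rate = 0) {
  req <- c("lgsh", "pgsh", "lcys", "pnac", "lnq")
  if (!all(req %in% names(state)))
    stop("state must contain: ", paste(req, collapse = ", "))
  fh <- if ("fh" %in% names(state)) max(state[["fh"]], 0) else 1
  s <- pmax(state[req], 0)
  g <- gsh_params
  vsyn <- gsh_synthesis(s[["lcys"]], s[["lgsh"]] / g$lgsh_baseline, g, fh)
  vgst <- v_gst(s[["lnq"]], s[["lgsh"]], params)
  vexp <- gsh_export_flux(s[["lgsh"]], g)
  list(
    dlgsh = vsyn - vgst - g$k_gsh_deg * s[["lgsh"]] - vexp,
    dpgsh = vexp * (params$vL / params$vP) - g$k_pgsh_clear * s[["pgsh"]],
    dlcys = g$J_cys - cys_catabolism(s[["lcys"]], g) +
      g$k_nac_to_cys * s[["pnac"]] * (params$vP / params$vL) - vsyn,
    dpnac = nac_rate - g$k_nac_clear * s[["pnac"]] -
      g$k_nac_to_cys * s[["pnac"]],
    v_syn = vsyn, v_gst = vgst, v_export = vexp
  )
}

## Plasma GSH baseline implied by the submodel (needs volume ratio).
pgsh_baseline <- function(params, gsh_params) {
  gsh_export_flux(gsh_params$lgsh_baseline, gsh_params) *
    (params$vL / params$vP) / gsh_params$k_pgsh_clear
}
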