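## Kinetic rate laws of hepatic APAP metabolism. All take concentrations in
## uM and return velocities in uM/hr. Exposed individually so dose-sweep
## studies and tests can interrogate each pathway in isolation.

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("'", what, "' must be finite and nonnegative")
  invisible(x)
}

#' Total cytochrome P450 oxidation velocity (APAP to NAPQI)
#'
#' Sum of three Michaelis-Menten isoform terms (CYP1A2, CYP2E1, CYP3A4)
#' multiplied by a substrate-activation Hill factor
#' `1 + p * S^n / (d^n + S^n)`. Without substrate activation the P450 flux
#' cannot supply enough NAPQI at large overdoses; the Hill multiplier raises
#' the velocity up to `(1 + p)`-fold at saturating APAP. The whole flux is
#' scaled by `cyp_fold` (enzyme-induction studies).
#'
#' @param lapap liver APAP concentration (uM), vectorized.
#' @param params an [apap_parameters()] object.
#' @return velocity in uM/hr; monotone nondecreasing in `lapap` and bounded
#'   by `cyp_fold * (sum of Vmax) * (1 + p)`.
#' @examples
#' p <- apap_parameters()
#' v_cyp_total(677, p)   # CYP2E1 at half-saturation dominates
#' @export
v_cyp_total <- function(lapap, params) {
  check_nonneg(lapap, "lapap")
  p <- params
  mm <- p$Vmax_cyp1a2 * lapap / (p$Km_cyp1a2 + lapap) +
        p$Vmax_cyp2e1 * lapap / (p$Km_cyp2e1 + lapap) +
        p$Vmax_cyp3a4 * lapap / (p$Km_cyp3a4 + lapap)
  sn <- lapap^p$cyp_act_n
  act <- 1 + p$cyp_act_p * sn / (p$cyp_act_d^p$cyp_act_n + sn)
  p$cyp_fold * mm * act
}

#' Total UGT glucuronidation velocity
#'
#' Sum of the four UGT isoform velocities: UGT1 has Hill kinetics
#' (n = 3.2), UGT3 is Michaelis-Menten, and UGT2 and UGT4 show substrate
#' inhibition (`V S / (Km + S (1 + S/Ki))`), so their contributions rise to an
#' interior maximum at `S = sqrt(Km * Ki)` and then fall toward zero. Liver
#' and tissue differ only in the Vmax vector (tissue = 20% of liver). All four
#' Vmax are scaled by `ugt_fold` (polymorphism studies).
#'
#' @param apap APAP concentration (uM), vectorized.
#' @param params an [apap_parameters()] object.
#' @param compartment `"liver"` or `"tissue"`.
#' @return velocity in uM/hr.
#' @export
v_ugt_total <- function(apap, params, compartment = c("liver", "tissue")) {
  check_nonneg(apap, "apap")
  compartment <- match.arg(compartment)
  p <- params
  vmax <- p$ugt_fold *
    if (compartment == "liver") p$Vmax_ugt_liver else p$Vmax_ugt_tissue
  sn <- apap^p$n_ugt1
  v1 <- vmax[1] * sn / (p$Km_ugt1^p$n_ugt1 + sn)
  v2 <- vmax[2] * apap / (p$Km_ugt2 + apap * (1 + apap / p$Ki_ugt2))
  v3 <- vmax[3] * apap / (p$Km_ugt3 + apap)
  v4 <- vmax[4] * apap / (p$Km_ugt4 + apap * (1 + apap / p$Ki_ugt4))
  v1 + v2 + v3 + v4
}

#' Sulfation velocity (bi-bi kinetics in APAP and PAPS)
#'
#' Standard two-substrate saturable form
#' `Vmax * apap * paps / ((Km_apap + apap) (Km_paps + paps))`. In practice the
#' reaction is limited by the small PAPS pool and its slow resynthesis, which
#' is why sulfation saturates at modest APAP doses.
#'
#' @param apap APAP concentration (uM).
#' @param paps PAPS concentration (uM).
#' @param params an [apap_parameters()] object.
#' @param compartment `"liver"` or `"tissue"` (selects Vmax).
#' @return velocity in uM/hr, bounded by the compartment Vmax.
#' @export
v_sult <- function(apap, paps, params, compartment = c("liver", "tissue")) {
  check_nonneg(apap, "apap"); check_nonneg(paps, "paps")
  compartment <- match.arg(compartment)
  p <- params
  vmax <- if (compartment == "liver") p$Vmax_sult_liver else p$Vmax_sult_tissue
  vmax * apap * paps / ((p$Km_sult_apap + apap) * (p$Km_sult_paps + paps))
}

#' GST conjugation velocity (NAPQI + GSH)
#'
#' Two-substrate saturable form
#' `Vmax * lnq * lgsh / ((Km_napqi + lnq) (Km_gsh + lgsh))`. The Km for GSH
#' (5200 uM) is of the same order as the hepatic GSH pool, so conjugation
#' capacity falls as GSH is depleted.
#'
#' @param lnq liver NAPQI concentration (uM).
#' @param lgsh liver GSH concentration (uM).
#' @param params an [apap_parameters()] object.
#' @return velocity in uM/hr.
#' @export
v_gst <- function(lnq, lgsh, params) {
  check_nonneg(lnq, "lnq"); check_nonneg(lgsh, "lgsh")
  p <- params
  p$Vmax_gst * lnq * lgsh / ((p$Km_gst_napqi + lnq) * (p$Km_gst_gsh + lgsh))
}
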