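#' Model parameters for the whole-body acetaminophen model
#'
#' Builds the full parameter set of the five-compartment APAP
#' transport/metabolism model: compartment volumes, first-order transport
#' rate constants, kinetic constants of the CYP, UGT, SULT and GST reactions,
#' PAPS turnover, covalent-binding rates, and hepatocyte population dynamics.
#' Defaults are the literature-derived values the model was built around;
#' any subset can be overridden by name.
#'
#' Units: concentrations in micromolar (uM), rates in uM/hr, first-order rate
#' constants in 1/hr, volumes in liters, times in hours.
#'
#' @param ... named overrides of any default value, e.g. `cyp_fold = 2`.
#'
#' @details
#' The scaling knobs `cyp_fold` and `ugt_fold` multiply the whole P450 flux
#' and all four UGT Vmax values respectively, and are used by the
#' enzyme-induction and polymorphism studies. Tissue SULT and UGT Vmax values
#' default to exactly 20% of the liver values.
#'
#' `mass_consistent_urine_transfer` controls the plasma-to-urine transfer of
#' the NAPQI-GSH conjugate. The default (`FALSE`) follows the model equations
#' verbatim, where that single transfer lacks the `vP/vU` volume ratio carried
#' by the other plasma-to-urine terms; setting it to `TRUE` applies `vP/vU`
#' uniformly, which makes the transfer mole-consistent and is used by the
#' mole-conservation tests.
#'
#' @return An object of class `apap_parameters`: a named list of numeric
#'   parameters (validated).
#' @seealso [gsh_parameters()], [apap_rhs()], [simulate_protocol()]
#' @examples
#' p <- apap_parameters()
#' p$k_gl                      # gut-to-liver absorption, 1/hr
#' p2 <- apap_parameters(cyp_fold = 2)
#' @export
apap_parameters <- function(...) {
  p <- list(
    ## compartment volumes (L)
    vG = 1, vP = 3, vL = 1.5, vT = 30, vU = 1.5,
    ## transport rate constants (1/hr)
    k_gl = 4,        # APAP gut -> liver
    k_pt = 0.39,     # APAP plasma -> tissue
    k_tp = 0.78,     # APAP tissue -> plasma
    k_pl = 0.0225,   # APAP plasma -> liver
    k_lp = 0.2025,   # APAP liver -> plasma
    k_slp = 0.24,    # sulfate conjugate liver -> plasma
    k_stp = 0.0913,  # sulfate conjugate tissue -> plasma
    k_glp = 0.3024,  # glucuronide liver -> plasma
    k_gtp = 0.5171,  # glucuronide tissue -> plasma
    k_nqglp = 0.3,   # NAPQI-GSH liver -> plasma
    k_pu = 0.06,     # APAP plasma -> urine
    k_spu = 4,       # sulfate plasma -> urine
    k_gpu = 3.8,     # glucuronide plasma -> urine
    k_nqgpu = 0.4,   # NAPQI-GSH plasma -> urine
    k_u = 1.54,      # urine elimination
    ## P450 substrate activation (Hill multiplier)
    cyp_act_p = 20, cyp_act_d = 18000, cyp_act_n = 2,
    ## P450 isoforms (Km uM, Vmax uM/hr)
    Km_cyp1a2 = 3430, Vmax_cyp1a2 = 0.55,
    Km_cyp2e1 = 677,  Vmax_cyp2e1 = 345,
    Km_cyp3a4 = 276,  Vmax_cyp3a4 = 0.99,
    ## sulfotransferase (bi-bi)
    Km_sult_apap = 97, Km_sult_paps = 5.6,
    Vmax_sult_liver = 1785, Vmax_sult_tissue = 357,
    ## PAPS synthesis / removal
    V_lpaps = 0.1,  k_lpaps = 0.0033,
    V_tpaps = 0.01, k_tpaps = 0.00033,
    ## glutathione S-transferase
    Km_gst_gsh = 5200, Km_gst_napqi = 15, Vmax_gst = 72000,
    ## covalent binding of NAPQI (linear, reversible)
    k_bind = 1000, k_rev = 0.25,
    ## UGT isoforms 1..4
    Km_ugt1 = 5500,  n_ugt1 = 3.2,
    Km_ugt2 = 4000,  Ki_ugt2 = 23000,
    Km_ugt3 = 9200,
    Km_ugt4 = 23000, Ki_ugt4 = 5300,
    Vmax_ugt_liver  = c(6370, 490, 4900, 7350),
    Vmax_ugt_tissue = c(1274, 98, 980, 1470),
    ## hepatocyte dynamics
    r_hep = 0.0417,            # logistic regeneration, 1/hr
    h_max = 1.6e11,            # hepatocyte carrying capacity, cells
    eta = 0.213 * 10^-4.2,     # death rate per uM covalent binding, 1/hr/uM
    delta_z = 0.2083,          # clearance of damaged cells, 1/hr
    ## scaling knobs and dosing constants
    cyp_fold = 1, ugt_fold = 1,
    body_mass_kg = 60, bioavailability = 0.75,
    mw_apap = 151.16,          # g/mol
    mass_consistent_urine_transfer = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "apap_parameters")
  validate_apap_parameters(p)
  p
}

validate_apap_parameters <- function(p) {
  pos <- c("vG", "vP", "vL", "vT", "vU",
           "cyp_act_p", "cyp_act_d",
           "Km_cyp1a2", "Vmax_cyp1a2", "Km_cyp2e1", "Vmax_cyp2e1",
           "Km_cyp3a4", "Vmax_cyp3a4",
           "Km_sult_apap", "Km_sult_paps", "Vmax_sult_liver", "Vmax_sult_tissue",
           "V_lpaps", "k_lpaps", "V_tpaps", "k_tpaps",
           "Km_gst_gsh", "Km_gst_napqi", "Vmax_gst",
           "k_bind", "k_rev",
           "Km_ugt1", "Km_ugt2", "Ki_ugt2", "Km_ugt3", "Km_ugt4", "Ki_ugt4",
           "r_hep", "h_max", "eta", "delta_z", "body_mass_kg", "mw_apap")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single strictly positive number")
  }
  ## transport rate constants may be zero (pathway knockouts, conservation
  ## experiments) but not negative
  nonneg <- c("k_gl", "k_pt", "k_tp", "k_pl", "k_lp", "k_slp", "k_stp",
              "k_glp", "k_gtp", "k_nqglp", "k_pu", "k_spu", "k_gpu",
              "k_nqgpu", "k_u")
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a single nonnegative number")
  }
  for (nm in c("Vmax_ugt_liver", "Vmax_ugt_tissue")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 4L || any(!is.finite(v)) || any(v <= 0))
      stop("parameter '", nm, "' must be four strictly positive Vmax values")
  }
  if (p$cyp_act_n < 1 || p$n_ugt1 < 1)
    stop("Hill exponents must be >= 1")
  if (p$bioavailability <= 0 || p$bioavailability > 1)
    stop("bioavailability must be in (0, 1]")
  if (p$cyp_fold < 0 || p$ugt_fold < 0)
    stop("fold factors must be >= 0")
  if (!is.logical(p$mass_consistent_urine_transfer) ||
      length(p$mass_consistent_urine_transfer) != 1L)
    stop("mass_consistent_urine_transfer must be TRUE or FALSE")
  invisible(p)
}

#' @export
print.apap_parameters <- function(x, ...) {
  cat("<apap_parameters> whole-body APAP model parameter set\n")
  cat(sprintf("  volumes (L): gut %g, plasma %g, liver %g, tissue %g, urine %g\n",
              x$vG, x$vP, x$vL, x$vT, x$vU))
  cat(sprintf("  scaling: cyp_fold %g, ugt_fold %g; body mass %g kg; F %g\n",
              x$cyp_fold, x$ugt_fold, x$body_mass_kg, x$bioavailability))
  cat(sprintf("  hepatocytes: r %g /hr, h_max %.3g cells, eta %.4g /hr/uM\n",
              x$r_hep, x$h_max, x$eta))
  cat("  (", length(unlist(x)), "values; see ?apap_parameters )\n")
  invisible(x)
}
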