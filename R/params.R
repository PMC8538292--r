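#' Population PK-PD parameters
#'
#' Returns the final-model population parameters of the quasi-equilibrium
#' TMDD + indirect-response model: fixed effects for drug and target
#' disposition, binding constants, the fecal-calprotectin (FC) turnover
#' parameters, covariate coefficients, inter-individual variability (IIV)
#' magnitudes and residual-error magnitudes, together with the covariate
#' centering constants and the drug molecular weight.
#'
#' Units: rate constants in 1/day, volumes in L, clearances in L/day,
#' concentrations in nmol/L, FC in mg/kg, `mw` in g/mol. `emax` is the
#' dimensionless maximum stimulation factor of FC production by the free
#' target (the published 219\% reads as 2.19). IIV magnitudes are CV
#' fractions for exponentially distributed parameters and a logit-scale SD
#' for the absorbed fraction F.
#'
#' @param ... named overrides of individual defaults.
#' @return an object of class `pop_params` (a validated named list).
#' @examples
#' p <- pop_params()
#' p$cl_typ      # 0.277 L/day
#' pop_params(kd = 0.2)$kd
#' @export
pop_params <- function(...) {
  p <- list(
    # drug PK
    ka         = 0.381,   # SC absorption rate (1/day)
    cl_typ     = 0.277,   # linear clearance (L/day)
    th_ffm_cl  = 0.598,   # power of FFM/45 on CL
    th_alb_cl  = -0.0165, # per g/L albumin (linear, centred at 43)
    th_bio_cl  = -0.227,  # proportional shift if bio-naive
    vc_typ     = 3.57,    # central volume, drug (L)
    th_ffm_vc  = 0.590,
    q          = 1.89,    # intercompartmental clearance, drug (L/day)
    vp_typ     = 3.30,    # peripheral volume, drug (L)
    th_ffm_vp  = 0.586,
    f_vv       = 0.888,   # absorbed fraction, FCGR3A-158 V/V
    f_other    = 0.710,   # absorbed fraction, V/F and F/F
    # target PK
    ksyn_typ   = 9.86e-9, # target synthesis (nmol/L/day)
    th_crp_ksyn = 0.0846, # per mg/L CRP (linear, centred at 3)
    kdeg       = 9.26e-10,# target degradation (1/day)
    vc_t       = 2.44,    # central volume, target (L)
    q_t        = 0.493,   # intercompartmental clearance, target (L/day)
    vp_t       = 11.0,    # peripheral volume, target (L)
    # binding
    kint       = 2.83e-6, # complex internalization (1/day)
    kd         = 0.168,   # equilibrium dissociation constant (nmol/L)
    # FC turnover
    kout       = 0.0581,  # FC degradation (1/day)
    fc0_ulcer  = 213,     # baseline FC, endoscopically active (mg/kg)
    fc0_noulcer = 102,    # baseline FC, no ulcers (mg/kg)
    emax       = 2.19,    # max stimulation of FC production (dimensionless)
    c50        = 2.46,    # free target conc at half-max stimulation (nmol/L)
    # inter-individual variability
    omega_cl   = 0.180,
    omega_vc   = 0.0979,
    omega_vp   = 0.241,
    omega_f    = 0.173,   # SD on the logit scale
    omega_ksyn = 0.992,
    omega_fc0  = 0.990,
    # residual error
    sigma_add  = 4.55,    # additive, drug (nmol/L)
    sigma_prop = 0.0777,  # proportional, drug
    sigma_fc   = 0.573,   # proportional, FC
    # constants
    mw         = 149000,  # g/mol
    ffm_ref    = 45,      # kg
    alb_ref    = 43,      # g/L
    crp_ref    = 3        # mg/L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown population parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  validate_pop_params(structure(p, class = "pop_params"))
}

#' Validate population parameters
#'
#' Checks positivity of rates, volumes and error magnitudes, and that the
#' absorbed fractions lie in (0, 1].
#'
#' @param p a `pop_params` object.
#' @return `p`, invisibly usable (returned unchanged) if valid; errors
#'   otherwise.
#' @export
validate_pop_params <- function(p) {
  stopifnot(inherits(p, "pop_params"))
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("non-numeric or non-finite population parameter(s): ",
         paste(names(p)[!num], collapse = ", "))
  }
  pos <- c("ka", "cl_typ", "vc_typ", "q", "vp_typ", "ksyn_typ", "kdeg",
           "vc_t", "q_t", "vp_t", "kint", "kd", "kout", "fc0_ulcer",
           "fc0_noulcer", "emax", "c50", "mw", "ffm_ref", "alb_ref",
           "crp_ref")
  badp <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(badp)) {
    stop("population parameter(s) must be strictly positive: ",
         paste(badp, collapse = ", "))
  }
  sds <- c("omega_cl", "omega_vc", "omega_vp", "omega_f", "omega_ksyn",
           "omega_fc0", "sigma_add", "sigma_prop", "sigma_fc")
  bads <- sds[vapply(sds, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bads)) {
    stop("variability magnitude(s) must be non-negative: ",
         paste(bads, collapse = ", "))
  }
  for (nm in c("f_vv", "f_other")) {
    if (p[[nm]] <= 0 || p[[nm]] > 1) {
      stop(nm, " must lie in (0, 1]")
    }
  }
  p
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population PK-PD parameters (QE-TMDD + indirect response)\n")
  cat(sprintf("  drug:    ka %.3g/d, CL %.3g L/d, Vc %.3g L, Q %.3g L/d, Vp %.3g L\n",
              x$ka, x$cl_typ, x$vc_typ, x$q, x$vp_typ))
  cat(sprintf("  target:  Ksyn %.3g nmol/L/d, Kdeg %.3g/d (R0 %.3g nmol/L), Vc %.3g L, Q %.3g L/d, Vp %.3g L\n",
              x$ksyn_typ, x$kdeg, x$ksyn_typ / x$kdeg, x$vc_t, x$q_t, x$vp_t))
  cat(sprintf("  binding: Kd %.3g nmol/L, Kint %.3g/d\n", x$kd, x$kint))
  cat(sprintf("  FC:      Kout %.4g/d, FC0 %g/%g mg/kg (ulcer/no ulcer), Emax %.3g, C50 %.3g nmol/L\n",
              x$kout, x$fc0_ulcer, x$fc0_noulcer, x$emax, x$c50))
  invisible(x)
}
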