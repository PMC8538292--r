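#' Unit conversions at the drug molecular weight
#'
#' The model operates on molar drug amounts and concentrations; doses are
#' prescribed in mg and serum concentrations are reported in ug/mL. Both
#' conversions use the antibody molecular weight (149 kDa by default).
#'
#' `mg_to_nmol()` converts a dose in mg to nmol; `nmoll_to_ugml()` converts a
#' concentration in nmol/L to ug/mL (1 nmol/L = 0.149 ug/mL at 149 kDa).
#' `convert_units()` is a dispatcher over the two directions.
#'
#' @param x numeric vector, non-negative.
#' @param mw molecular weight in g/mol.
#' @param direction one of `"mg_to_nmol"`, `"nmoll_to_ugml"`.
#' @return converted numeric vector.
#' @examples
#' mg_to_nmol(90)             # 604.03 nmol
#' nmoll_to_ugml(10)          # 1.49 ug/mL
#' convert_units(390, "mg_to_nmol")
#' @export
mg_to_nmol <- function(x, mw = 149000) {
  check_nonneg(x, "amount (mg)")
  x * 1e6 / mw
}

#' @rdname mg_to_nmol
#' @export
nmoll_to_ugml <- function(x, mw = 149000) {
  check_nonneg(x, "concentration (nmol/L)")
  x * mw / 1e6
}

#' @rdname mg_to_nmol
#' @export
convert_units <- function(x, direction = c("mg_to_nmol", "nmoll_to_ugml"),
                          mw = 149000) {
  direction <- match.arg(direction)
  switch(direction,
         mg_to_nmol = mg_to_nmol(x, mw),
         nmoll_to_ugml = nmoll_to_ugml(x, mw))
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(what, " must be finite and numeric")
  }
  if (any(x < 0)) stop(what, " must be non-negative")
  invisible(x)
}
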