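#' Free concentrations under the quasi-equilibrium binding approximation
#'
#' Given total (free + complex) drug and target concentrations in the central
#' compartment and the equilibrium dissociation constant Kd, solves the
#' binding equilibrium for the free concentrations. Free drug is the positive
#' root of the quadratic
#' \deqn{C = \tfrac12\left[(C_{tot} - R_{tot} - K_d) +
#'   \sqrt{(C_{tot} - R_{tot} - K_d)^2 + 4 K_d C_{tot}}\right],}
#' the complex is \eqn{C_{tot} - C} and free target is \eqn{R_{tot} -}
#' complex. The root is evaluated in a cancellation-free form so that the
#' equilibrium identity \eqn{K_d \cdot complex = C \cdot R} holds to near
#' machine precision over the whole concentration range.
#'
#' @param ctot total drug concentration (nmol/L), vector allowed.
#' @param rtot total target concentration (nmol/L).
#' @param kd dissociation constant (nmol/L), scalar or vector.
#' @return a list with components `c_free`, `r_free`, `complex` (nmol/L).
#' @examples
#' qe_free_concentrations(10, 10.65, 0.168)
#' @export
qe_free_concentrations <- function(ctot, rtot, kd) {
  if (!is.numeric(ctot) || !is.numeric(rtot) || !is.numeric(kd) ||
      anyNA(ctot) || anyNA(rtot) || anyNA(kd) ||
      any(!is.finite(ctot)) || any(!is.finite(rtot)) || any(!is.finite(kd))) {
    stop("qe_free_concentrations: inputs must be finite numerics")
  }
  if (any(ctot < 0) || any(rtot < 0)) {
    stop("qe_free_concentrations: total concentrations must be non-negative")
  }
  if (any(kd <= 0)) stop("qe_free_concentrations: kd must be positive")
  out <- qe_free(ctot, rtot, kd)
  list(c_free = out$c_free, r_free = out$r_free, complex = out$complex)
}

# Internal, check-free vectorised solver used inside the ODE right-hand side.
# b = Rtot + Kd - Ctot; when b >= 0 the naive root subtracts nearly equal
# numbers, so the conjugate form 2*Kd*Ctot / (b + disc) is used instead.
qe_free <- function(ctot, rtot, kd) {
  b <- rtot + kd - ctot
  disc <- sqrt(b * b + 4 * kd * ctot)
  c_free <- ifelse(b >= 0, 2 * kd * ctot / (b + disc), (disc - b) / 2)
  c_free[ctot == 0] <- 0
  c_free <- pmin(c_free, ctot)
  # free target from its own stable quadratic (roles of C and R swapped)
  b2 <- ctot + kd - rtot
  disc2 <- sqrt(b2 * b2 + 4 * kd * rtot)
  r_free <- ifelse(b2 >= 0, 2 * kd * rtot / (b2 + disc2), (disc2 - b2) / 2)
  r_free[rtot == 0] <- 0
  r_free <- pmin(r_free, rtot)
  # complex = min(totals) minus the corresponding free species: avoids
  # cancellation when one total dwarfs the other
  cpx <- ifelse(ctot <= rtot, ctot - c_free, rtot - r_free)
  list(c_free = c_free, r_free = r_free, complex = cpx)
}
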