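#' Add residual (observation-level) error to a simulated series
#'
#' Applies the published residual-error models to export synthetic
#' observations. Drug concentrations (nmol/L) receive combined error,
#' `y = C*(1 + e1) + e2` with `e1 ~ N(0, sigma_prop^2)` and
#' `e2 ~ N(0, sigma_add^2)`; fecal calprotectin receives proportional error,
#' `y = FC*(1 + e)` with `e ~ N(0, sigma_fc^2)`. Negative draws are floored
#' at 0. Remission classification in the study runner uses the model-predicted
#' FC, never these perturbed observations.
#'
#' @param x numeric series (nmol/L for `kind = "drug"`, mg/kg for
#'   `kind = "fc"`).
#' @param kind `"drug"` or `"fc"`.
#' @param pop population parameters supplying the error magnitudes.
#' @param seed optional integer; when given, draws are reproducible.
#' @return numeric series with residual error, same length as `x`.
#' @examples
#' add_residual_error(c(10, 50, 100), "drug", pop_params(), seed = 7)
#' @export
add_residual_error <- function(x, kind = c("drug", "fc"), pop = pop_params(),
                               seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("add_residual_error: series must be finite numeric")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  y <- if (kind == "drug") {
    x * (1 + stats::rnorm(n, 0, pop$sigma_prop)) +
      stats::rnorm(n, 0, pop$sigma_add)
  } else {
    x * (1 + stats::rnorm(n, 0, pop$sigma_fc))
  }
  pmax(y, 0)
}
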