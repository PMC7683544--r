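#' Convert pH to hydrogen-ion concentration
#'
#' Rumen acid status is recorded as pH (Sorensen scale) but all model fitting
#' in this package is done on the hydrogen-ion concentration \eqn{[H^+]}
#' (moles per litre), because the pH scale is logarithmic and distorts
#' arithmetic on the underlying chemistry: \eqn{pH = -\log_{10}[H^+]}.
#'
#' @param ph Numeric vector of pH values.
#' @return Numeric vector of \eqn{[H^+]} in moles per litre.
#' @seealso [h_to_ph()]
#' @examples
#' ph_to_h(6)      # 1e-6
#' ph_to_h(5.5)    # ~3.16e-6
#' @export
ph_to_h <- function(ph) {
  if (!is.numeric(ph) || any(!is.finite(ph))) {
    stop("`ph` must be finite numeric", call. = FALSE)
  }
  10^(-ph)
}

#' Convert hydrogen-ion concentration to pH
#'
#' Inverse of [ph_to_h()]: \eqn{pH = -\log_{10}[H^+]}.
#'
#' @param h Numeric vector of \eqn{[H^+]} in moles per litre; must be > 0.
#' @return Numeric vector of pH values.
#' @export
h_to_ph <- function(h) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h <= 0)) {
    stop("`h` must be finite and strictly positive", call. = FALSE)
  }
  -log10(h)
}
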