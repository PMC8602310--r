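#' Convert pressure from mmHg to kPa
#'
#' Lengths in this package are mm and moduli kPa; clinically reported
#' intraluminal pressures are mmHg and are converted on input
#' (1 mmHg = 0.133322 kPa).
#'
#' @param p pressure in mmHg.
#' @return pressure in kPa.
#' @examples
#' mmhg_to_kpa(60) # 7.99932
#' @export
mmhg_to_kpa <- function(p) {
  stopifnot(is.numeric(p))
  p * 0.133322
}
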