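# ADC mapping from two-b-value, three-direction DWI.

#' Apparent diffusion coefficient map container
#' @param adc 3-D map, mm^2/s; NaN outside the validity mask.
#' @param valid logical validity mask.
#' @export
adc_map <- function(adc, valid) {
  stopifnot(identical(dim(adc), dim(valid)))
  structure(list(adc = adc, valid = valid), class = "adc_map")
}

#' Compute the ADC map from b = 0 and three diffusion-weighted volumes
#'
#' Combines the three direction volumes into a trace-weighted signal by
#' geometric mean, then inverts the mono-exponential signal decay:
#' adc = ln(b0 / S_trace) / b. The geometric-mean formulation is
#' algebraically identical to averaging the three per-direction ADCs.
#' Voxels with non-positive b0 or trace signal are invalid; negative ADC
#' values (noise pushing S_trace above b0) are clamped to 0 and counted
#' in attribute `n_clamped`.
#'
#' @param b0 3-D volume at b = 0.
#' @param dwi_dirs list of three 3-D volumes at the diffusion b-value.
#' @param b diffusion weighting, s/mm^2 (> 0).
#' @param min_b0 optional noise floor on b0 (voxels below are invalid;
#'   default 0 = off).
#' @return An [adc_map()].
#' @export
compute_adc <- function(b0, dwi_dirs, b = 1000, min_b0 = 0) {
  stopifnot(b > 0, length(dwi_dirs) == 3L)
  for (v in dwi_dirs) stopifnot(identical(dim(v), dim(b0)))
  s_trace <- (dwi_dirs[[1]] * dwi_dirs[[2]] * dwi_dirs[[3]])^(1 / 3)
  valid <- b0 > max(0, min_b0) & s_trace > 0 & is.finite(b0) &
    is.finite(s_trace)
  adc <- array(NaN, dim = dim(b0))
  adc[valid] <- log(b0[valid] / s_trace[valid]) / b
  n_clamped <- sum(adc[valid] < 0)
  adc[valid] <- pmax(adc[valid], 0)
  out <- adc_map(adc, valid)
  attr(out, "n_clamped") <- n_clamped
  out
}
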