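# Delay-insensitive deconvolution of the tissue convolution model
# C_t = F R (x) C_a by truncated SVD of a block-circulant system, and
# derivation of the CBF / CBV / MTT / Tmax parameter maps.

#' Deconvolution configuration
#'
#' @param truncation_threshold singular values below this fraction of the
#'   largest singular value are zeroed in the pseudo-inverse (default 0.2,
#'   the standard fixed relative threshold).
#' @param pad_factor zero-padding factor for the circulant embedding
#'   (fixed at 2: curves of length N live on a circle of length 2N).
#' @param rho brain density, g/ml, used for absolute-unit scaling.
#' @param k_h hematocrit correction factor (large vessel vs capillary).
#' @export
deconv_config <- function(truncation_threshold = 0.2, pad_factor = 2L,
                          rho = 1.04, k_h = 0.73) {
  stopifnot(truncation_threshold > 0, truncation_threshold < 1,
            pad_factor == 2L, rho > 0, k_h > 0)
  structure(list(truncation_threshold = truncation_threshold,
                 pad_factor = 2L, rho = rho, k_h = k_h),
            class = "deconv_config")
}

#' Build the block-circulant AIF convolution matrix
#'
#' Zero-pads the arterial curve to length L = 2N and forms the L x L
#' circulant matrix whose column j is the padded AIF circularly shifted
#' by j, scaled by dt. Circular convolution with this matrix equals the
#' rectangle-rule discrete convolution for curves whose support fits in
#' the padding, which makes the inversion insensitive to bolus delay.
#'
#' @param aif an `aif` object (or list with `curve` and `dt`).
#' @param n_frames number of frames N of the tissue curves.
#' @return L x L numeric matrix.
#' @export
build_circulant_system <- function(aif, n_frames = length(aif$curve)) {
  a <- aif$curve
  stopifnot(length(a) == n_frames, aif$dt > 0)
  if (all(a == 0)) stop("all-zero AIF: singular system")
  L <- 2L * n_frames
  a_pad <- c(a, numeric(L - n_frames))
  idx <- (outer(seq_len(L), seq_len(L), "-")) %% L + 1L
  matrix(aif$dt * a_pad[idx], L, L)
}

# truncated pseudo-inverse from an SVD, relative threshold
truncated_pinv <- function(sv, threshold) {
  keep <- sv$d >= threshold * max(sv$d)
  inv_d <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (inv_d * t(sv$u))
}

#' Residue-function estimate container
#' @param k_curve scaled residue function F*R(t) samples (length 2N), 1/s.
#' @param dt frame spacing, s.
#' @export
residue_estimate <- function(k_curve, dt) {
  stopifnot(all(is.finite(k_curve)), dt > 0)
  structure(list(k_curve = k_curve, dt = dt), class = "residue_estimate")
}

#' Deconvolve one tissue curve by truncated SVD
#'
#' @param tissue_curve concentration curve, length N or 2N (zero-padded).
#' @param system the circulant matrix from [build_circulant_system()], or
#'   a precomputed `svd()` of it.
#' @param config [deconv_config()].
#' @param dt frame spacing, s.
#' @return A [residue_estimate()].
#' @export
osvd_deconvolve <- function(tissue_curve, system, config = deconv_config(),
                            dt) {
  sv <- if (is.matrix(system)) svd(system) else system
  L <- nrow(sv$u)
  if (!all(is.finite(tissue_curve))) stop("non-finite tissue curve")
  c_pad <- c(tissue_curve, numeric(L - length(tissue_curve)))
  keep <- sv$d >= config$truncation_threshold * max(sv$d)
  inv_d <- ifelse(keep, 1 / sv$d, 0)
  k <- as.numeric(sv$v %*% (inv_d * (t(sv$u) %*% c_pad)))
  residue_estimate(k, dt)
}

#' Perfusion parameters from a residue estimate
#'
#' CBF is the maximum of the deconvolved residue curve, Tmax the time of
#' that maximum (earliest frame on ties), CBV the rectangle-rule area,
#' and MTT = CBV/CBF (central volume theorem). The first N samples of the
#' padded curve are used. Absolute units use
#' cbf = cbf_raw * 6000 k_h / rho [ml/100g/min] and
#' cbv = cbv_raw * 100 k_h / rho [ml/100g].
#'
#' @param est a [residue_estimate()].
#' @param config [deconv_config()].
#' @return list(cbf, cbv, mtt, tmax, valid).
#' @export
residue_to_parameters <- function(est, config = deconv_config()) {
  L <- length(est$k_curve)
  k <- est$k_curve[seq_len(L %/% 2L)]
  cbf_raw <- max(k)
  if (!is.finite(cbf_raw) || cbf_raw <= 0)
    return(list(cbf = NA_real_, cbv = NA_real_, mtt = NA_real_,
                tmax = NA_real_, valid = FALSE))
  imax <- which.max(k)                     # earliest maximum
  cbv_raw <- sum(k) * est$dt
  s_cbf <- 60 * 100 * config$k_h / config$rho
  s_cbv <- 100 * config$k_h / config$rho
  list(cbf = cbf_raw * s_cbf, cbv = cbv_raw * s_cbv,
       mtt = cbv_raw / cbf_raw, tmax = (imax - 1) * est$dt, valid = TRUE)
}

#' Perfusion parameter maps container
#' @param cbf,cbv,mtt,tmax 3-D maps (ml/100g/min, ml/100g, s, s).
#' @param valid logical validity mask; maps are NaN outside it.
#' @export
perfusion_maps <- function(cbf, cbv, mtt, tmax, valid) {
  stopifnot(identical(dim(cbf), dim(cbv)), identical(dim(cbf), dim(mtt)),
            identical(dim(cbf), dim(tmax)), identical(dim(cbf), dim(valid)))
  structure(list(cbf = cbf, cbv = cbv, mtt = mtt, tmax = tmax,
                 valid = valid), class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  d <- dim(x$cbf)
  cat(sprintf("<perfusion_maps> grid %dx%dx%d, %d valid voxels\n",
              d[1], d[2], d[3], sum(x$valid)))
  invisible(x)
}

#' Compute CBF/CBV/MTT/Tmax maps from a concentration series
#'
#' Applies the block-circulant truncated-SVD deconvolution voxel-wise
#' inside the brain mask. The SVD of the AIF system is computed once and
#' applied to all voxels. Voxels with a non-positive residue maximum are
#' marked invalid (NaN in all maps); their count is in attribute
#' `n_invalid`.
#'
#' @param conc_series `dynamic_series` of kind `"concentration"`.
#' @param aif an `aif` with the same dt and frame count.
#' @param config [deconv_config()].
#' @param brain_mask logical 3-D mask (`NULL` = all voxels).
#' @return A [perfusion_maps()] object; MTT satisfies
#'   mtt = 60 cbv / cbf exactly wherever defined.
#' @export
compute_perfusion_maps <- function(conc_series, aif,
                                   config = deconv_config(),
                                   brain_mask = NULL) {
  stopifnot(conc_series$kind == "concentration")
  d <- dim(conc_series$data)
  n <- d[4]
  stopifnot(length(aif$curve) == n, isTRUE(all.equal(aif$dt, conc_series$dt)))
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = d[1:3])
  if (!any(brain_mask)) stop("empty brain mask")
  m <- series_matrix(conc_series)
  vox <- which(as.vector(brain_mask) & rowSums(!is.finite(m)) == 0L)
  if (!length(vox)) stop("no valid voxels inside the brain mask")
  A <- build_circulant_system(aif, n)
  sv <- svd(A)
  keep <- sv$d >= config$truncation_threshold * max(sv$d)
  P <- sv$v %*% (ifelse(keep, 1 / sv$d, 0) * t(sv$u))
  L <- 2L * n
  Cpad <- rbind(t(m[vox, , drop = FALSE]), matrix(0, L - n, length(vox)))
  K <- P %*% Cpad                      # L x nvox residue curves
  Kn <- K[seq_len(n), , drop = FALSE]
  cbf_raw <- apply(Kn, 2, max)
  imax <- apply(Kn, 2, which.max)
  cbv_raw <- colSums(Kn) * conc_series$dt
  ok <- is.finite(cbf_raw) & cbf_raw > 0
  s_cbf <- 60 * 100 * config$k_h / config$rho
  s_cbv <- 100 * config$k_h / config$rho
  blank <- function() array(NaN, dim = d[1:3])
  cbf <- blank(); cbv <- blank(); mtt <- blank(); tmax <- blank()
  cbf[vox[ok]] <- cbf_raw[ok] * s_cbf
  cbv[vox[ok]] <- cbv_raw[ok] * s_cbv
  mtt[vox[ok]] <- cbv_raw[ok] / cbf_raw[ok]
  tmax[vox[ok]] <- (imax[ok] - 1) * conc_series$dt
  valid <- array(FALSE, dim = d[1:3]); valid[vox[ok]] <- TRUE
  maps <- perfusion_maps(cbf, cbv, mtt, tmax, valid)
  attr(maps, "n_invalid") <- sum(brain_mask) - sum(ok)
  maps
}
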