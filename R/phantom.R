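# Synthetic DSC-PWI / DWI phantom with known per-class ground truth.
# Forward model: C_t(t) = F * R(t - delay) (x) C_a(t); signal via
# S(t) = S0 exp(-TE dR2*(t)) with tissue (linear) or large-vessel
# (quadratic) relaxivity; DWI via S_b = S0 exp(-b ADC).

# Unit constants shared by the forward model and quantification so they
# cancel exactly in recovery tests: brain density rho [g/ml], hematocrit
# correction k_H (large-vessel to capillary).
.RHO_BRAIN <- 1.04
.K_HEMATOCRIT <- 0.73

#' Tissue class with ground-truth perfusion and diffusion parameters
#'
#' @param label one of `"normal_wm"`, `"normal_gm"`, `"core"`, `"penumbra"`,
#'   `"vessel"`.
#' @param cbf_true cerebral blood flow, ml/100g/min (>= 0).
#' @param cbv_true cerebral blood volume, ml/100g (>= 0).
#' @param delay_true bolus arrival delay relative to the AIF, s.
#' @param adc_true apparent diffusion coefficient, mm^2/s, in [0, 4e-3].
#' @param residue_model `"exponential"` (R(t) = exp(-t/MTT)) or `"boxcar"`
#'   (R(t) = 1 for t < MTT).
#' @return A `tissue_class` object; `mtt_true` (s) is derived as
#'   60 * cbv_true / cbf_true.
#' @export
tissue_class <- function(label, cbf_true, cbv_true, delay_true, adc_true,
                         residue_model = c("exponential", "boxcar")) {
  label <- match.arg(label,
    c("normal_wm", "normal_gm", "core", "penumbra", "vessel"))
  residue_model <- match.arg(residue_model)
  stopifnot(cbf_true >= 0, cbv_true >= 0, delay_true >= 0,
            adc_true >= 0, adc_true <= 4e-3)
  mtt_true <- if (cbf_true > 0) 60 * cbv_true / cbf_true else NA_real_
  structure(list(label = label, cbf_true = cbf_true, cbv_true = cbv_true,
                 mtt_true = mtt_true, delay_true = delay_true,
                 adc_true = adc_true, residue_model = residue_model),
            class = "tissue_class")
}

#' Default tissue classes for the stroke phantom
#'
#' Normal white/gray matter, a diffusion-restricted infarct core, a
#' hypoperfused penumbra (delayed, true Tmax > 6 s) and a large-vessel
#' class that carries the arterial input function.
#'
#' @return Named list of [tissue_class()] objects; names are the labels and
#'   the list order defines the integer codes used in class maps.
#' @export
default_tissue_classes <- function() {
  list(
    normal_wm = tissue_class("normal_wm", cbf_true = 22, cbv_true = 1.5,
                             delay_true = 0, adc_true = 800e-6),
    normal_gm = tissue_class("normal_gm", cbf_true = 60, cbv_true = 4.0,
                             delay_true = 0, adc_true = 900e-6),
    core      = tissue_class("core", cbf_true = 8, cbv_true = 1.0,
                             delay_true = 8, adc_true = 400e-6),
    penumbra  = tissue_class("penumbra", cbf_true = 15, cbv_true = 2.0,
                             delay_true = 8, adc_true = 750e-6),
    vessel    = tissue_class("vessel", cbf_true = 100, cbv_true = 4.0,
                             delay_true = 0, adc_true = 3000e-6)
  )
}

#' Gamma-variate bolus parameters
#'
#' Standard model for the arterial concentration curve:
#' C_a(t) = A ((t-t0)/(alpha beta))^alpha exp(alpha - (t-t0)/beta) for
#' t > t0 and 0 before; the peak value is A, at t = t0 + alpha*beta.
#'
#' @param amplitude peak concentration, mM (> 0).
#' @param t0 bolus arrival time, s.
#' @param alpha shape (dimensionless, > 0).
#' @param beta time scale, s (> 0).
#' @export
gamma_variate_params <- function(amplitude = 5, t0 = 20, alpha = 2, beta = 1) {
  stopifnot(amplitude > 0, alpha > 0, beta > 0, t0 >= 0)
  structure(list(amplitude = amplitude, t0 = t0, alpha = alpha, beta = beta),
            class = "gamma_variate_params")
}

#' Evaluate a gamma-variate arterial input function
#'
#' @param params a [gamma_variate_params()] object.
#' @param time_grid strictly increasing, uniformly spaced times, s.
#' @return Concentration curve in mM, zero before `t0`, unimodal.
#' @export
gamma_variate_aif <- function(params, time_grid) {
  stopifnot(inherits(params, "gamma_variate_params"))
  d <- diff(time_grid)
  if (length(time_grid) < 2L || any(d <= 0) ||
      any(abs(d - d[1]) > 1e-9 * d[1]))
    stop("time_grid must be strictly increasing with uniform spacing")
  s <- (time_grid - params$t0) / (params$alpha * params$beta)
  curve <- ifelse(s <= 0, 0,
    params$amplitude * s^params$alpha *
      exp(params$alpha * (1 - s)))
  curve
}

#' Phantom acquisition and geometry specification
#'
#' Defaults emulate a 1.5 T gradient-echo DSC acquisition (TR = 2 s,
#' TE = 45 ms, 90 s coverage) and isotropic two-b-value DWI
#' (b = 0 / 1000 s/mm^2, three directions) on a desk-scale grid.
#'
#' @param grid_shape integer triple (nx, ny, nz).
#' @param voxel_size mm triple; default 0.94 x 0.94 x 5 mm.
#' @param n_frames number of dynamic frames.
#' @param tr repetition time, s (frame spacing).
#' @param te echo time, ms.
#' @param b_values DWI b-values, s/mm^2; must contain 0 and one positive b.
#' @param aif_params [gamma_variate_params()] for the injected bolus.
#' @param s0 baseline signal, arbitrary units.
#' @param noise_sigma Gaussian signal noise SD (same units as `s0`).
#' @param rng_seed integer seed; fixed seed gives bit-identical datasets.
#' @param class_map 3-D integer array of class codes (indices into
#'   `classes`), same shape as `grid_shape`; `NULL` uses
#'   [default_class_map()].
#' @param classes named list of [tissue_class()]; default
#'   [default_tissue_classes()].
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 4L),
                         voxel_size = c(0.94, 0.94, 5),
                         n_frames = 45L, tr = 2, te = 45,
                         b_values = c(0, 1000),
                         aif_params = gamma_variate_params(),
                         s0 = 1000, noise_sigma = 10,
                         rng_seed = 1L,
                         class_map = NULL,
                         classes = default_tissue_classes()) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            all(voxel_size > 0), n_frames >= 2L, tr > 0, te > 0,
            noise_sigma >= 0, s0 > 0, length(b_values) >= 2L,
            any(b_values == 0), any(b_values > 0))
  if (is.null(class_map))
    class_map <- default_class_map(grid_shape, classes)
  stopifnot(all(dim(class_map) == grid_shape),
            all(class_map %in% seq_along(classes)))
  # the dynamic window must cover the bolus: require >= 8 pre-bolus frames
  # and arrival well inside the acquisition
  if (aif_params$t0 < 8 * tr)
    stop("aif_params$t0 leaves fewer than 8 pre-bolus baseline frames")
  if (aif_params$t0 + aif_params$alpha * aif_params$beta >= n_frames * tr)
    stop("bolus peak falls outside the acquisition window")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, n_frames = as.integer(n_frames),
                 tr = tr, te = te, b_values = b_values,
                 aif_params = aif_params, s0 = s0,
                 noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed),
                 class_map = class_map, classes = classes),
            class = "phantom_spec")
}

#' Default lesion geometry: core sphere inside a penumbra shell
#'
#' Background is white matter with a gray-matter rim, a spherical
#' diffusion core at the grid centre surrounded by a connected penumbra
#' shell, and a single large-vessel voxel away from the lesion.
#'
#' @param grid_shape integer triple.
#' @param classes class list (order defines codes).
#' @param core_radius,penumbra_radius radii in voxels (in-plane).
#' @return 3-D integer array of class codes.
#' @export
default_class_map <- function(grid_shape, classes = default_tissue_classes(),
                              core_radius = 4, penumbra_radius = 8) {
  code <- stats::setNames(seq_along(classes), names(classes))
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  m <- array(code[["normal_wm"]], dim = grid_shape)
  # gray-matter rim: outermost in-plane shell
  m[1, , ] <- code[["normal_gm"]]; m[nx, , ] <- code[["normal_gm"]]
  m[, 1, ] <- code[["normal_gm"]]; m[, ny, ] <- code[["normal_gm"]]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  for (k in seq_len(nz)) {
    dz2 <- ((k - cz) * 2)^2  # slices are thick; stretch z distance
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      r2 <- (i - cx)^2 + (j - cy)^2 + dz2
      if (r2 <= core_radius^2) m[i, j, k] <- code[["core"]]
      else if (r2 <= penumbra_radius^2 && m[i, j, k] == code[["normal_wm"]])
        m[i, j, k] <- code[["penumbra"]]
    }
  }
  m[3, 3, max(1L, as.integer(cz))] <- code[["vessel"]]
  m
}

#' Vessel voxel coordinate of a phantom
#' @param spec a [phantom_spec()].
#' @return 1-based (i, j, k) of the first vessel voxel.
#' @export
phantom_vessel_voxel <- function(spec) {
  code <- which(names(spec$classes) == "vessel")
  idx <- which(spec$class_map == code)[1]
  if (is.na(idx)) stop("phantom has no vessel voxel")
  as.integer(arrayInd(idx, dim(spec$class_map)))
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

# flow scale F [1/s] from CBF [ml/100g/min]: the dimensionless
# blood-volume fraction seen by the tracer is cbv * rho / (100 k_H),
# and F = fraction / MTT.
.flow_scale <- function(cbf_true) cbf_true * .RHO_BRAIN / (100 * 60 * .K_HEMATOCRIT)

#' Blood-volume fraction implied by a CBV in ml/100g
#' @param cbv_true ml/100g
#' @return dimensionless fraction (equals the area ratio of tissue to
#'   arterial concentration curves in the forward model).
#' @export
cbv_fraction <- function(cbv_true) cbv_true * .RHO_BRAIN / (100 * .K_HEMATOCRIT)

# Sampled, delayed residue function R(t - delay) on t = (0:(n-1))*dt.
# The exponential residue is discretised as the geometric sequence
# R[i] = (1 - dt/MTT)^(t/dt): its maximum is 1 and its rectangle-rule
# area is exactly MTT, so the discrete forward model satisfies the
# central volume theorem at any dt (it converges to exp(-t/MTT) as
# dt -> 0). Requires MTT > dt.
sample_residue <- function(tissue, n, dt) {
  t <- (seq_len(n) - 1) * dt - tissue$delay_true
  if (is.na(tissue$mtt_true)) return(numeric(n))
  switch(tissue$residue_model,
    exponential = {
      if (tissue$mtt_true <= dt)
        stop("exponential residue requires mtt_true > dt (use boxcar ",
             "for transit times below the frame spacing)")
      a <- 1 - dt / tissue$mtt_true
      ifelse(t < 0, 0, a^(t / dt))
    },
    boxcar = as.numeric(t >= 0 & t < tissue$mtt_true))
}

#' Forward tissue concentration curve (convolution model)
#'
#' Discretises C_t = F R(t - delay) (x) C_a with rectangle-rule step `dt`,
#' the same convention the deconvolution inverts. The curve areas satisfy
#' integral(C_t)/integral(C_a) = [cbv_fraction(cbv_true)] up to truncation
#' of the tail by the acquisition window.
#'
#' @param aif_curve arterial concentration per frame, mM.
#' @param tissue a [tissue_class()].
#' @param dt frame spacing, s.
#' @return Tissue concentration per frame, mM.
#' @export
tissue_concentration <- function(aif_curve, tissue, dt) {
  stopifnot(inherits(tissue, "tissue_class"), dt > 0)
  n <- length(aif_curve)
  if (tissue$cbf_true == 0) return(numeric(n))
  fr <- .flow_scale(tissue$cbf_true) * sample_residue(tissue, n, dt)
  # linear discrete convolution, first n samples
  full <- convolve(aif_curve, rev(fr), type = "open")
  dt * full[seq_len(n)]
}

#' Render the dynamic PWI signal series of a phantom
#'
#' Tissue voxels follow the linear tissue relaxivity, vessel voxels the
#' quadratic large-vessel relaxivity; signal is S0 exp(-TE dR2*) plus
#' Gaussian noise. Also returns the ground-truth perfusion maps.
#'
#' @param spec a [phantom_spec()].
#' @param params [conversion_params()] holding the relaxivities used in
#'   the forward direction (defaults are the 1.5 T values).
#' @return list with `series` (a `dynamic_series` of kind `"signal"`),
#'   `truth` (a `perfusion_maps` of the injected values, Tmax = delay),
#'   `aif_true` (the injected arterial curve) and `class_map`.
#' @export
render_pwi <- function(spec, params = conversion_params(te = spec$te)) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_frames
  tgrid <- (seq_len(n) - 1) * spec$tr
  aif <- gamma_variate_aif(spec$aif_params, tgrid)
  nclass <- length(spec$classes)
  curves <- matrix(0, nrow = nclass, ncol = n)  # dR2* per class, ms^-1
  for (ci in seq_len(nclass)) {
    cls <- spec$classes[[ci]]
    if (cls$label == "vessel") {
      curves[ci, ] <- params$r_vessel * aif + params$q_vessel * aif^2
    } else {
      conc <- tissue_concentration(aif, cls, spec$tr)
      curves[ci, ] <- params$r_tissue * conc
    }
  }
  if (max(curves) * spec$te > 50)
    stop("concentration too high: rendered signal would underflow to zero")
  nvox <- prod(spec$grid_shape)
  lab <- as.integer(spec$class_map)
  sig <- spec$s0 * exp(-spec$te * curves[lab, , drop = FALSE])  # nvox x n
  if (spec$noise_sigma > 0)
    sig <- sig + with_seed(spec$rng_seed,
      matrix(rnorm(nvox * n, sd = spec$noise_sigma), nvox, n))
  data <- array(sig, dim = c(spec$grid_shape, n))
  truth_map <- function(field) {
    v <- vapply(spec$classes, function(cl) {
      x <- cl[[field]]; if (is.null(x) || is.na(x)) NA_real_ else x
    }, numeric(1))
    array(v[lab], dim = spec$grid_shape)
  }
  truth <- perfusion_maps(cbf = truth_map("cbf_true"),
                          cbv = truth_map("cbv_true"),
                          mtt = truth_map("mtt_true"),
                          tmax = truth_map("delay_true"),
                          valid = array(TRUE, dim = spec$grid_shape))
  list(series = dynamic_series(data, dt = spec$tr, kind = "signal",
                               te = spec$te),
       truth = truth, aif_true = aif, class_map = spec$class_map)
}

#' Render the DWI volumes of a phantom (isotropic Stejskal-Tanner decay)
#'
#' @param spec a [phantom_spec()].
#' @return list with `b0` volume, `dwi` (list of three direction volumes,
#'   identical up to noise), `b` (the positive b-value, s/mm^2) and
#'   `truth` (an `adc_map` of the injected ADC values).
#' @export
render_dwi <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  b <- max(spec$b_values)
  lab <- as.integer(spec$class_map)
  adc <- vapply(spec$classes, function(cl) cl$adc_true, numeric(1))[lab]
  adc_vol <- array(adc, dim = spec$grid_shape)
  nvox <- prod(spec$grid_shape)
  noise <- function(k) matrix(rnorm(nvox * k, sd = spec$noise_sigma), nvox, k)
  vols <- with_seed(spec$rng_seed + 1L, {
    b0 <- spec$s0 + if (spec$noise_sigma > 0) noise(1)[, 1] else 0
    dirs <- lapply(1:3, function(d) {
      s <- spec$s0 * exp(-b * adc)
      if (spec$noise_sigma > 0) s <- s + noise(1)[, 1]
      array(s, dim = spec$grid_shape)
    })
    list(b0 = array(b0, dim = spec$grid_shape), dirs = dirs)
  })
  list(b0 = vols$b0, dwi = vols$dirs, b = b,
       truth = adc_map(adc_vol, valid = array(TRUE, dim = spec$grid_shape)))
}

#' Write a phantom dataset to disk (NIfTI + JSON sidecar)
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
write_phantom <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pwi <- render_pwi(spec)
  dwi <- render_dwi(spec)
  paths <- c(
    pwi = write_nifti_vol(pwi$series$data, file.path(dir, "pwi.nii.gz"),
                          spec$voxel_size, tr = spec$tr),
    b0 = write_nifti_vol(dwi$b0, file.path(dir, "dwi_b0.nii.gz"),
                         spec$voxel_size),
    class_map = write_nifti_vol(spec$class_map * 1.0,
                                file.path(dir, "class_map.nii.gz"),
                                spec$voxel_size))
  for (d in 1:3)
    paths[paste0("dwi_dir", d)] <- write_nifti_vol(
      dwi$dwi[[d]], file.path(dir, sprintf("dwi_b1000_dir%d.nii.gz", d)),
      spec$voxel_size)
  for (f in c("cbf", "cbv", "mtt", "tmax"))
    paths[paste0("truth_", f)] <- write_nifti_vol(
      pwi$truth[[f]], file.path(dir, sprintf("truth_%s.nii.gz", f)),
      spec$voxel_size)
  paths["truth_adc"] <- write_nifti_vol(dwi$truth$adc,
    file.path(dir, "truth_adc.nii.gz"), spec$voxel_size)
  side <- list(
    grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
    n_frames = spec$n_frames, tr_s = spec$tr, te_ms = spec$te,
    b_values = spec$b_values, s0 = spec$s0, noise_sigma = spec$noise_sigma,
    rng_seed = spec$rng_seed,
    aif_params = unclass(spec$aif_params),
    vessel_voxel_0based = if ("vessel" %in% names(spec$classes) &&
                               any(spec$class_map ==
                                     which(names(spec$classes) == "vessel")))
      phantom_vessel_voxel(spec) - 1L else NULL,
    classes = lapply(spec$classes, unclass))
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["sidecar"] <- file.path(dir, "phantom.json")
  invisible(paths)
}
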