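# Signal -> dR2* -> concentration conversion for DSC-PWI, including the
# quadratic large-vessel correction of the arterial input function.

#' Conversion parameters for DSC signal-to-concentration mapping
#'
#' The defaults are the 1.5 T literature values: tissue relaxivity
#' r_tissue = 0.044 ms^-1 mM^-1 and large-vessel coefficients
#' r = 7.6e-3 ms^-1 mM^-1, q = 574e-6 ms^-1 mM^-2. TE and the
#' relaxivities are kept in ms / ms^-1 so these constants apply verbatim;
#' curve time axes are in seconds.
#'
#' @param k proportionality constant of the signal equation (default 1).
#' @param te echo time, ms.
#' @param r_tissue tissue relaxivity, ms^-1 mM^-1.
#' @param r_vessel large-vessel linear coefficient, ms^-1 mM^-1.
#' @param q_vessel large-vessel quadratic coefficient, ms^-1 mM^-2.
#' @param n_baseline number of pre-bolus frames averaged for S0.
#' @export
conversion_params <- function(k = 1, te = 45, r_tissue = 0.044,
                              r_vessel = 7.6e-3, q_vessel = 574e-6,
                              n_baseline = 8L) {
  stopifnot(te > 0, r_tissue > 0, r_vessel > 0, q_vessel > 0,
            n_baseline >= 1L)
  structure(list(k = k, te = te, r_tissue = r_tissue, r_vessel = r_vessel,
                 q_vessel = q_vessel, n_baseline = as.integer(n_baseline)),
            class = "conversion_params")
}

#' 4-D dynamic series container
#'
#' @param data 4-D array (x, y, z, frame) of signal, dR2* (ms^-1) or
#'   concentration (mM).
#' @param dt frame spacing, s.
#' @param kind `"signal"`, `"delta_r2star"` or `"concentration"`.
#' @param te echo time, ms (metadata).
#' @export
dynamic_series <- function(data, dt, kind = c("signal", "delta_r2star",
                                              "concentration"), te = NA) {
  kind <- match.arg(kind)
  stopifnot(length(dim(data)) == 4L, dt > 0)
  structure(list(data = data, dt = dt, kind = kind, te = te),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %s, grid %dx%dx%d, %d frames, dt = %g s\n",
              x$kind, d[1], d[2], d[3], d[4], x$dt))
  invisible(x)
}

# flatten a 4-D series to an (nvox x nframes) matrix
series_matrix <- function(series) {
  d <- dim(series$data)
  matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
}

#' Per-voxel baseline signal S0
#'
#' Mean of the first `n_baseline` pre-bolus frames per voxel. Voxels with
#' non-positive S0 are flagged invalid and excluded downstream.
#'
#' @param series a `dynamic_series` of kind `"signal"`.
#' @param n_baseline number of leading frames to average.
#' @return list with `s0` (3-D volume) and `valid` (logical volume).
#' @export
estimate_baseline <- function(series, n_baseline = 8L) {
  stopifnot(inherits(series, "dynamic_series"), series$kind == "signal")
  d <- dim(series$data)
  if (n_baseline > d[4])
    stop("n_baseline exceeds the number of frames")
  m <- series_matrix(series)
  s0 <- rowMeans(m[, seq_len(n_baseline), drop = FALSE])
  list(s0 = array(s0, dim = d[1:3]),
       valid = array(s0 > 0, dim = d[1:3]))
}

# clamp rule for non-physical samples: frames with S <= 0 or S > 10 S0 are
# linearly interpolated from valid neighbours (constant extrapolation at
# the ends); returns the repaired matrix and the flagged-voxel count
repair_signal <- function(m, s0) {
  bad <- m <= 0 | m > 10 * s0
  nbad_vox <- 0L
  for (v in which(rowSums(bad) > 0L)) {
    ok <- !bad[v, ]
    if (!any(ok)) next  # fully invalid voxel: left as-is, S0 mask handles it
    m[v, ] <- approx(which(ok), m[v, ok], xout = seq_len(ncol(m)),
                     rule = 2)$y
    nbad_vox <- nbad_vox + 1L
  }
  list(m = m, n_repaired = nbad_vox)
}

#' Convert signal to relative transverse relaxivity change
#'
#' dR2*(t) = -(k/TE) ln(S(t)/S0), in ms^-1 for TE in ms. Samples with
#' S <= 0 or S > 10 S0 are repaired by linear interpolation across frames
#' before conversion and counted in attribute `n_repaired`.
#'
#' @param series `dynamic_series` of kind `"signal"`.
#' @param baseline result of [estimate_baseline()].
#' @param params [conversion_params()].
#' @return `dynamic_series` of kind `"delta_r2star"`.
#' @export
signal_to_delta_r2star <- function(series, baseline, params) {
  stopifnot(series$kind == "signal")
  d <- dim(series$data)
  m <- series_matrix(series)
  s0 <- as.vector(baseline$s0)
  ok <- as.vector(baseline$valid)
  rep <- repair_signal(m[ok, , drop = FALSE], s0[ok])
  dr <- matrix(NA_real_, nrow = nrow(m), ncol = ncol(m))
  dr[ok, ] <- -(params$k / params$te) * log(rep$m / s0[ok])
  out <- dynamic_series(array(dr, dim = d), dt = series$dt,
                        kind = "delta_r2star", te = params$te)
  attr(out, "n_repaired") <- rep$n_repaired
  out
}

#' Convert tissue dR2* to contrast concentration
#'
#' C(t) = dR2*(t) / r_tissue, in mM. Negative values (noise) are retained
#' so curve integrals stay unbiased.
#'
#' @param series `dynamic_series` of kind `"delta_r2star"`.
#' @param params [conversion_params()].
#' @return `dynamic_series` of kind `"concentration"`.
#' @export
delta_r2star_to_concentration <- function(series, params) {
  stopifnot(series$kind == "delta_r2star")
  dynamic_series(series$data / params$r_tissue, dt = series$dt,
                 kind = "concentration", te = series$te)
}

#' Invert the quadratic large-vessel relaxivity for the AIF
#'
#' Solves dR2* = r C + q C^2 for the non-negative root
#' C = (-r + sqrt(r^2 + 4 q dR2*)) / (2 q) per frame. Negative dR2*
#' samples (noise below baseline) map to C = 0; their count is returned
#' in attribute `n_negative`.
#'
#' @param delta_r2star numeric vector, ms^-1.
#' @param params [conversion_params()].
#' @return Concentration curve, mM.
#' @export
correct_aif <- function(delta_r2star, params) {
  r <- params$r_vessel; q <- params$q_vessel
  neg <- delta_r2star < 0
  d <- pmax(delta_r2star, 0)
  conc <- (-r + sqrt(r^2 + 4 * q * d)) / (2 * q)
  attr(conc, "n_negative") <- sum(neg)
  conc
}

#' Extract and convert the arterial input function
#'
#' Manual mode extracts the configured voxel's signal curve, estimates its
#' baseline, converts to dR2* and applies the large-vessel correction.
#' Automatic mode scores every voxel by peak dR2* divided by curve width
#' (area/peak) and arrival time, favouring early, tall, narrow bolus
#' curves, and returns the best-scoring voxel.
#'
#' @param series `dynamic_series` of kind `"signal"`.
#' @param coordinate 1-based (i, j, k) voxel index, or `"auto"`.
#' @param params [conversion_params()].
#' @param min_peak minimum peak dR2* (ms^-1) below which a curve is
#'   rejected as having no bolus.
#' @return An `aif` object: `voxel`, `curve` (mM), `delta_r2star`, `dt`.
#' @export
select_aif <- function(series, coordinate, params = conversion_params(),
                       min_peak = 0.01) {
  stopifnot(series$kind == "signal")
  d <- dim(series$data)
  voxel_dr2s <- function(v) {
    s <- series$data[v[1], v[2], v[3], ]
    s0 <- mean(s[seq_len(min(params$n_baseline, length(s)))])
    if (s0 <= 0) return(NULL)
    s <- pmin(pmax(s, 1e-12), 10 * s0)
    -(params$k / params$te) * log(s / s0)
  }
  if (identical(coordinate, "auto")) {
    m <- series_matrix(series)
    s0 <- rowMeans(m[, seq_len(params$n_baseline), drop = FALSE])
    ok <- s0 > 0
    dr <- -(params$k / params$te) *
      log(pmin(pmax(sweep(m, 1, s0, "/"), 1e-12), 10))
    peak <- apply(dr, 1, max)
    cand <- which(ok & peak >= pmax(min_peak, 0.5 * max(peak[ok])))
    if (!length(cand)) stop("no bolus-bearing voxel found in auto mode")
    score <- vapply(cand, function(v) {
      crv <- pmax(dr[v, ], 0)
      p <- max(crv); tp <- which.max(crv)
      width <- sum(crv) * series$dt / p          # equivalent width, s
      p / (width * (tp * series$dt))             # tall, narrow, early
    }, numeric(1))
    coordinate <- as.integer(arrayInd(cand[which.max(score)], d[1:3]))
  }
  v <- as.integer(coordinate)
  stopifnot(length(v) == 3L, all(v >= 1L), all(v <= d[1:3]))
  dr2s <- voxel_dr2s(v)
  if (is.null(dr2s) || max(dr2s) < min_peak)
    stop("no bolus at the selected AIF voxel (peak dR2* below threshold); ",
         "reselect the AIF coordinate")
  conc <- correct_aif(dr2s, params)
  structure(list(voxel = v, curve = as.numeric(conc),
                 delta_r2star = dr2s, dt = series$dt,
                 n_negative = attr(conc, "n_negative")),
            class = "aif")
}

#' Full signal-to-concentration preprocessing of a PWI series
#'
#' Convenience wrapper: baseline, dR2* conversion and tissue
#' concentration in one step.
#'
#' @param series `dynamic_series` of kind `"signal"`.
#' @param params [conversion_params()].
#' @return list with `concentration` (`dynamic_series`), `s0`, `valid`.
#' @export
preprocess_pwi <- function(series, params = conversion_params()) {
  bl <- estimate_baseline(series, params$n_baseline)
  dr <- signal_to_delta_r2star(series, bl, params)
  conc <- delta_r2star_to_concentration(dr, params)
  list(concentration = conc, s0 = bl$s0, valid = bl$valid,
       n_repaired = attr(dr, "n_repaired"))
}
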