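# Seeded volume-growing segmentation of the diffusion lesion and the
# hypoperfused region, and the tissue-at-risk (mismatch) mask.

#' Volume-growing configuration
#'
#' @param adc_threshold upper ADC bound for the diffusion lesion, mm^2/s
#'   (default 550e-6, the standard acute-stroke core threshold; the
#'   predicate is strict: adc < threshold).
#' @param tmax_threshold lower Tmax bound for hypoperfusion, s (default
#'   6; strict: tmax > threshold).
#' @param connectivity 6 (faces) or 26 (faces+edges+corners) neighbours.
#' @export
grow_config <- function(adc_threshold = 550e-6, tmax_threshold = 6,
                        connectivity = 26L) {
  stopifnot(adc_threshold > 0, tmax_threshold > 0,
            connectivity %in% c(6L, 26L))
  structure(list(adc_threshold = adc_threshold,
                 tmax_threshold = tmax_threshold,
                 connectivity = as.integer(connectivity)),
            class = "grow_config")
}

# neighbour offset table for the given connectivity
neighbour_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L)
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1L, ]
  as.matrix(g)
}

#' Seeded region growing on a 3-D map
#'
#' Breadth-first growth from the seed voxels through the set of voxels
#' satisfying the predicate, under the chosen connectivity. Seeds that
#' fail the predicate contribute nothing. NA / NaN map values never
#' satisfy the predicate.
#'
#' @param map 3-D numeric array.
#' @param seeds n x 3 matrix (or length-3 vector) of 1-based voxel
#'   indices.
#' @param predicate function mapping the array to a logical array (e.g.
#'   `function(x) x < 550e-6`).
#' @param connectivity 6 or 26.
#' @return Logical mask of the grown region.
#' @export
region_grow <- function(map, seeds, predicate, connectivity = 26L) {
  d <- dim(map)
  stopifnot(length(d) == 3L)
  if (is.null(seeds) || length(seeds) == 0L) stop("empty seed set")
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  if (any(seeds < 1L) || any(seeds > matrix(d, nrow(seeds), 3, byrow = TRUE)))
    stop("seed outside the grid")
  pass <- predicate(map)
  pass[!is.finite(map)] <- FALSE
  pass <- array(as.logical(pass), dim = d)
  off <- neighbour_offsets(as.integer(connectivity))
  visited <- array(FALSE, dim = d)
  queue <- seeds[pass[seeds], , drop = FALSE]
  if (nrow(queue)) visited[queue] <- TRUE
  while (nrow(queue) > 0L) {
    nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(o)
      sweep(queue, 2L, off[o, ], "+")))
    inside <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
      nb[, 2] >= 1L & nb[, 2] <= d[2] & nb[, 3] >= 1L & nb[, 3] <= d[3]
    nb <- nb[inside, , drop = FALSE]
    if (!nrow(nb)) break
    keep <- pass[nb] & !visited[nb]
    nb <- unique(nb[keep, , drop = FALSE])
    if (!nrow(nb)) break
    visited[nb] <- TRUE
    queue <- nb
  }
  visited
}

#' Segment the acute diffusion lesion by ADC-thresholded growing
#'
#' Grows from the seed points through voxels with ADC strictly below the
#' configured upper threshold.
#'
#' @param adc an [adc_map()] (or bare 3-D array).
#' @param seeds n x 3 matrix of 1-based seed voxels.
#' @param config [grow_config()].
#' @return Logical lesion mask; empty (with a warning) if no seed lies
#'   below the threshold.
#' @export
segment_dwi_lesion <- function(adc, seeds, config = grow_config()) {
  vol <- if (inherits(adc, "adc_map")) adc$adc else adc
  mask <- region_grow(vol, seeds, function(x) x < config$adc_threshold,
                      config$connectivity)
  if (!any(mask))
    warning("no seed below the ADC threshold: empty DWI lesion")
  mask
}

#' Segment hypoperfused tissue growing from the diffusion lesion
#'
#' Uses every DWI-lesion voxel as a seed and grows through voxels with
#' Tmax strictly above the threshold.
#'
#' @param tmax 3-D Tmax map, s.
#' @param dwi_lesion logical lesion mask (non-empty).
#' @param config [grow_config()].
#' @return Logical hypoperfusion mask.
#' @export
segment_hypoperfusion <- function(tmax, dwi_lesion, config = grow_config()) {
  stopifnot(identical(dim(tmax), dim(dwi_lesion)))
  if (!any(dwi_lesion)) stop("empty DWI lesion: no seeds for hypoperfusion")
  seeds <- which(dwi_lesion, arr.ind = TRUE)
  region_grow(tmax, seeds, function(x) x > config$tmax_threshold,
              config$connectivity)
}

#' Tissue-at-risk mask (perfusion-diffusion mismatch)
#'
#' Set difference: hypoperfused voxels outside the diffusion lesion; by
#' construction disjoint from the lesion.
#'
#' @param hypoperfusion,dwi_lesion logical masks on one grid.
#' @return Logical mask.
#' @export
tissue_at_risk <- function(hypoperfusion, dwi_lesion) {
  stopifnot(identical(dim(hypoperfusion), dim(dwi_lesion)))
  hypoperfusion & !dwi_lesion
}

#' Lesion masks container
#' @param dwi_lesion,hypoperfusion logical masks; `tar` is derived.
#' @param voxel_size mm triple.
#' @export
lesion_masks <- function(dwi_lesion, hypoperfusion, voxel_size) {
  tar <- tissue_at_risk(hypoperfusion, dwi_lesion)
  structure(list(dwi_lesion = dwi_lesion, hypoperfusion = hypoperfusion,
                 tar = tar, voxel_size = voxel_size),
            class = "lesion_masks")
}

#' Mask volume in millilitres
#' @param mask logical mask.
#' @param voxel_size mm triple.
#' @export
mask_volume_ml <- function(mask, voxel_size) {
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  sum(mask) * prod(voxel_size) / 1000
}
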