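# Per-subject VOI summaries: median parameter values and volumes for the
# DWI lesion and the tissue-at-risk, and the cohort table feeding the
# statistics stage.

#' Median of a map inside a mask
#'
#' Sample median (midpoint of the central order statistics for even
#' counts) over the valid, finite voxels of the mask. Invariant to voxel
#' order and to NaN padding outside the mask.
#'
#' @param map 3-D numeric array.
#' @param mask logical mask.
#' @return Scalar median, or `NA` (with a warning) if no valid voxel
#'   remains.
#' @export
median_in_mask <- function(map, mask) {
  stopifnot(identical(dim(map), dim(mask)))
  vals <- map[mask & is.finite(map)]
  if (!length(vals)) {
    warning("no valid voxels in mask: median is NA")
    return(NA_real_)
  }
  median(vals)
}

# one cohort row for one VOI of one subject
voi_row <- function(subject_id, group, voi, mask, maps, adc, voxel_size) {
  data.frame(
    subject_id = subject_id, group = group, voi = voi,
    volume_ml = mask_volume_ml(mask, voxel_size),
    adc_median = median_in_mask(adc$adc, mask),
    tmax_median = median_in_mask(maps$tmax, mask),
    cbf_median = median_in_mask(maps$cbf, mask),
    cbv_median = median_in_mask(maps$cbv, mask),
    mtt_median = median_in_mask(maps$mtt, mask),
    stringsAsFactors = FALSE)
}

#' Build the cohort table of per-subject, per-VOI medians
#'
#' Two rows per subject (VOIs `dwi_lesion` and `tar`) with the median
#' ADC, Tmax, CBF, CBV and MTT and the VOI volume. Subjects with an
#' empty tissue-at-risk contribute only their lesion row (with a
#' warning).
#'
#' @param subjects list of per-subject lists with fields `subject_id`,
#'   `group`, `maps` ([perfusion_maps()]), `adc` ([adc_map()]), `masks`
#'   ([lesion_masks()]).
#' @return data.frame with columns subject_id, group, voi, volume_ml,
#'   adc_median, tmax_median, cbf_median, cbv_median, mtt_median.
#' @export
build_cohort_table <- function(subjects) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject_id: ",
                               ids[duplicated(ids)][1])
  rows <- lapply(subjects, function(s) {
    vs <- s$masks$voxel_size
    out <- voi_row(s$subject_id, s$group, "dwi_lesion",
                   s$masks$dwi_lesion, s$maps, s$adc, vs)
    if (any(s$masks$tar)) {
      out <- rbind(out, voi_row(s$subject_id, s$group, "tar",
                                s$masks$tar, s$maps, s$adc, vs))
    } else {
      warning("subject ", s$subject_id, ": empty tissue-at-risk, ",
              "only the lesion row emitted")
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-level median and interquartile-range summary of a cohort table
#'
#' Quartiles use the linear-interpolation convention (`quantile`
#' type 7).
#'
#' @param cohort a cohort table from [build_cohort_table()].
#' @param parameters columns to summarise.
#' @return data.frame with one row per group x voi x parameter and
#'   columns median, q1, q3, n.
#' @export
cohort_summary <- function(cohort,
                           parameters = c("volume_ml", "adc_median",
                                          "tmax_median", "cbf_median",
                                          "cbv_median", "mtt_median")) {
  combos <- expand.grid(group = unique(cohort$group),
                        voi = unique(cohort$voi),
                        parameter = parameters,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- cohort$group == combos$group[i] & cohort$voi == combos$voi[i]
    x <- cohort[[combos$parameter[i]]][sel]
    x <- x[is.finite(x)]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(combos[i, ], median = q[2], q1 = q[1], q3 = q[3],
               n = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
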