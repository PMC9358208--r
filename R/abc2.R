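#' ABC/2 measurement record
#'
#' Rater-style measurement for the bedside ellipsoid approximation: on the
#' axial slice with the largest lesion, `a` is the longest in-slice length
#' and `b` the width orthogonal to it, both in cm; `n_slices` counts the
#' eligible slices and `slice_thickness` their thickness in cm (0.5 cm for
#' the acquiring protocol). The craniocaudal extent C is
#' `n_slices * slice_thickness`, a length, so the /2 in ABC/2 is purely the
#' ellipsoid factor.
#'
#' @param a,b in-slice length and orthogonal width, cm (> 0).
#' @param n_slices number of eligible slices (>= 1).
#' @param slice_thickness slice thickness, cm.
#' @return an `abc_measurement` object.
#' @export
abc_measurement <- function(a, b, n_slices, slice_thickness = 0.5) {
  if (a <= 0 || b <= 0) stop_ich("a and b must be positive lengths (cm)", "ich_domain_error")
  if (n_slices < 1) stop_ich("n_slices must be >= 1", "ich_domain_error")
  if (slice_thickness <= 0) stop_ich("slice_thickness must be positive", "ich_domain_error")
  structure(list(a = a, b = b, n_slices = n_slices,
                 slice_thickness = slice_thickness), class = "abc_measurement")
}

#' ABC/2 ellipsoid volume estimate
#'
#' `a * b * (n_slices * slice_thickness) / 2`, in ml (= cc). For a true
#' ellipsoid with axes A, B, C the exact volume is pi*A*B*C/6, so ABC/2
#' overestimates by the factor 3/pi (about 4.7%).
#'
#' @param m an [abc_measurement()].
#' @return volume in ml.
#' @export
abc2_volume <- function(m) {
  stopifnot(inherits(m, "abc_measurement"))
  m$a * m$b * (m$n_slices * m$slice_thickness) / 2
}

#' Count eligible slices for the C term
#'
#' The reference slice is the one with the largest in-slice lesion area
#' (ties broken toward the lowest slice index); a slice is eligible when its
#' lesion area is at least `min_fraction` of the reference slice's area
#' (slices with less than 25% lesion are not counted, by default).
#'
#' @param hemorrhage_mask logical 3D mask, axis order (slice, row, column).
#' @param min_fraction eligibility threshold relative to the reference
#'   slice's area.
#' @return list with `n_slices` and `reference_slice` (index).
#' @export
eligible_slices <- function(hemorrhage_mask, min_fraction = 0.25) {
  if (!any(hemorrhage_mask)) stop_ich("empty lesion mask", "ich_no_lesion_error")
  areas <- apply(hemorrhage_mask, 1, sum)
  ref <- which.max(areas)
  list(n_slices = sum(areas > 0 & areas >= min_fraction * areas[ref]),
       reference_slice = ref)
}

#' Rater-style ABC/2 measurement from a lesion mask
#'
#' Emulates the manual procedure on a segmented lesion: pick the reference
#' slice by [eligible_slices()], read A and B as the in-plane bounding-box
#' extents of the lesion on that slice (cm), and count eligible slices for C.
#'
#' @param mask logical 3D lesion mask, axis order (slice, row, column).
#' @param voxel_size voxel edges (dz, dy, dx) in mm.
#' @param min_fraction slice eligibility threshold.
#' @return an [abc_measurement()].
#' @export
abc_from_mask <- function(mask, voxel_size, min_fraction = 0.25) {
  el <- eligible_slices(mask, min_fraction)
  sl <- mask[el$reference_slice, , , drop = TRUE]
  rows <- which(apply(sl, 1, any))
  cols <- which(apply(sl, 2, any))
  ext_y <- (max(rows) - min(rows) + 1) * voxel_size[2] / 10  # mm -> cm
  ext_x <- (max(cols) - min(cols) + 1) * voxel_size[3] / 10
  abc_measurement(a = max(ext_y, ext_x), b = min(ext_y, ext_x),
                  n_slices = el$n_slices,
                  slice_thickness = voxel_size[1] / 10)
}

#' Perihematomal edema volume by ABC/2 subtraction
#'
#' The edema outline is measured with the same ABC/2 procedure (the
#' hypodense boundary instead of the hemorrhage boundary) and the hematoma
#' volume is subtracted. A negative difference is clamped to zero and
#' flagged via the `"clamped"` attribute.
#'
#' @param edema_measurement an [abc_measurement()] of the edema outline
#'   (hematoma plus surrounding edema).
#' @param hematoma_volume hematoma ABC/2 volume, ml (>= 0).
#' @return edema volume in ml.
#' @export
abc2_phe <- function(edema_measurement, hematoma_volume) {
  if (hematoma_volume < 0) stop_ich("hematoma_volume must be >= 0", "ich_domain_error")
  v <- abc2_volume(edema_measurement) - hematoma_volume
  out <- max(0, v)
  attr(out, "clamped") <- v < 0
  out
}
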