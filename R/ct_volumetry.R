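#' CT volume container
#'
#' A 3D grid of Hounsfield units with voxel geometry. Axis order is
#' (slice, row, column); indices are 0.5 cm axial slices only by convention
#' of the acquiring protocol, not a requirement.
#'
#' @param values numeric 3D array of Hounsfield units, in \[-1024, 3071\].
#' @param voxel_size numeric length-3, voxel edge lengths (dz, dy, dx) in mm.
#' @return a `ct_volume` object.
#' @export
ct_volume <- function(values, voxel_size) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop_ich("voxel dimensions must be three positive lengths (mm)", "ich_domain_error")
  rng <- range(values)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop_ich("HU values outside [-1024, 3071]", "ich_domain_error")
  structure(list(values = values, voxel_size = as.numeric(voxel_size)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume>", paste(dim(x$values), collapse = " x "),
      "voxels,", paste(x$voxel_size, collapse = " x "), "mm\n")
  invisible(x)
}

#' Read / write a CT volume as NIfTI
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return `read_ct_volume`: a [ct_volume()]; `write_ct_volume`: `path`,
#'   invisibly.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  ct_volume(array(as.numeric(img), dim = dim(img)), vox)
}

#' @rdname read_ct_volume
#' @param vol a [ct_volume()] or a logical/integer mask array.
#' @param voxel_size voxel edges in mm (taken from `vol` if a `ct_volume`).
#' @export
write_ct_volume <- function(vol, path, voxel_size = NULL) {
  if (inherits(vol, "ct_volume")) {
    arr <- vol$values
    voxel_size <- vol$voxel_size
  } else {
    arr <- vol + 0  # masks as 0/1
    if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  }
  img <- RNifti::asNifti(arr, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Dual-clustering segmentation parameters
#'
#' The dual-clustering rule retains a voxel when (i) its HU falls inside
#' `hu_window` and (ii) at least `neighbor_fraction` of its neighbors within
#' `neighborhood_radius` are also in-window; retained voxels are grouped into
#' connected components, and components smaller than `min_cluster_voxels` or
#' with mean HU not exceeding `intensity_floor` are discarded. The windows
#' are user parameters (acute blood roughly 45-90 HU, edema 5-23 HU, soft
#' tissue 0-80 HU); defaults are declared here, not inferred from any scan.
#'
#' @param hu_window length-2 numeric, inclusive HU window \[lo, hi\].
#' @param neighborhood_radius neighborhood half-width in voxels.
#' @param neighbor_fraction required in-window fraction of the neighborhood.
#' @param min_cluster_voxels minimum component size kept.
#' @param connectivity 6 (faces) or 26 (faces+edges+corners).
#' @param intensity_floor components must have mean HU above this to be kept.
#' @return a `dual_cluster_params` list.
#' @export
dual_cluster_params <- function(hu_window, neighborhood_radius = 1L,
                                neighbor_fraction = 0.5,
                                min_cluster_voxels = 1L,
                                connectivity = 26L,
                                intensity_floor = -1024) {
  if (length(hu_window) != 2 || hu_window[1] >= hu_window[2])
    stop_ich("hu_window must be [lo, hi] with lo < hi", "ich_domain_error")
  if (hu_window[1] < -1024 || hu_window[2] > 3071)
    stop_ich("hu_window outside the HU range [-1024, 3071]", "ich_domain_error")
  if (neighbor_fraction < 0 || neighbor_fraction > 1)
    stop_ich("neighbor_fraction must be in [0, 1]", "ich_domain_error")
  stopifnot(connectivity %in% c(6, 26))
  structure(list(hu_window = as.numeric(hu_window),
                 neighborhood_radius = as.integer(neighborhood_radius),
                 neighbor_fraction = neighbor_fraction,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 connectivity = as.integer(connectivity),
                 intensity_floor = intensity_floor),
            class = "dual_cluster_params")
}

#' Dual-clustering segmentation of a CT volume
#'
#' @param vol a [ct_volume()].
#' @param params a [dual_cluster_params()].
#' @param within optional logical mask; the segmentation is restricted to it
#'   before component analysis.
#' @return logical mask array.
#' @export
dual_cluster_segment <- function(vol, params, within = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(params, "dual_cluster_params"))
  v <- vol$values
  inw <- v >= params$hu_window[1] & v <= params$hu_window[2]
  r <- params$neighborhood_radius
  inw_num <- array(as.numeric(inw), dim(v))
  cube <- box_sum3d(inw_num, r)
  ntot <- box_sum3d(array(1, dim(v)), r) - 1  # neighbors actually on the grid
  nin <- cube - inw_num
  keep <- inw & (nin >= params$neighbor_fraction * ntot)
  if (!is.null(within)) {
    stopifnot(identical(dim(within), dim(v)))
    keep <- keep & within
  }
  lab <- label_components(keep, params$connectivity)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    means <- vapply(seq_along(sizes), function(i) mean(v[lab == i]), 0)
    ok <- sizes >= params$min_cluster_voxels & means > params$intensity_floor
    keep <- array(lab > 0 & ok[pmax(lab, 1L)], dim(v))
  }
  keep
}

#' Extract the brain from a head CT
#'
#' Dual-clustering with a soft-tissue window (excluding bone and air),
#' keeping the single largest connected component.
#'
#' @inheritParams dual_cluster_segment
#' @param params soft-tissue [dual_cluster_params()]; default window 0-80 HU.
#' @return logical brain mask.
#' @export
extract_brain <- function(vol, params = dual_cluster_params(c(0, 80),
                                                            min_cluster_voxels = 50L)) {
  m <- dual_cluster_segment(vol, params)
  lab <- label_components(m, params$connectivity)
  if (max(lab) == 0)
    stop_ich("no brain component found in the soft-tissue window", "ich_no_brain_error")
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Segment perihematomal edema around a hemorrhage mask
#'
#' Candidate voxels are the ring obtained by successive 3D binary dilation of
#' the hemorrhage (6-connected structuring element) up to `dilation_limit`
#' iterations, minus the hemorrhage itself, restricted to brain; the ring is
#' then refined by a further dual-clustering pass with edema-specific HU.
#'
#' @inheritParams dual_cluster_segment
#' @param hemorrhage logical hemorrhage mask, subset of `brain`.
#' @param brain logical brain mask.
#' @param dilation_limit dilation iterations (>= 1), default 10.
#' @param edema_params edema-window [dual_cluster_params()]; default 5-23 HU.
#' @return logical edema mask, disjoint from `hemorrhage` by construction.
#' @export
segment_edema <- function(vol, hemorrhage, brain, dilation_limit = 10L,
                          edema_params = dual_cluster_params(c(5, 23),
                                                             min_cluster_voxels = 10L)) {
  if (!any(hemorrhage)) stop_ich("empty hemorrhage mask", "ich_no_lesion_error")
  if (any(hemorrhage & !brain))
    stop_ich("hemorrhage mask extends outside the brain mask", "ich_domain_error")
  if (dilation_limit < 1) stop_ich("dilation_limit must be >= 1", "ich_domain_error")
  ring <- dilate_mask(hemorrhage, dilation_limit) & !hemorrhage & brain
  dual_cluster_segment(vol, edema_params, within = ring)
}

#' Volume of a binary mask
#'
#' @param mask logical mask array.
#' @param voxel_size voxel edges in mm.
#' @return volume in ml (= cc): voxel count times voxel volume / 1000.
#' @export
mask_volume <- function(mask, voxel_size) {
  sum(mask) * prod(voxel_size) / 1000
}

#' Bundle of segmentation masks with invariant checks
#'
#' @param brain,hemorrhage,edema aligned logical masks; hemorrhage and edema
#'   must lie inside the brain and be mutually disjoint.
#' @param provenance parameter set used (any list), stored as-is.
#' @return a `segmentation_masks` object.
#' @export
segmentation_masks <- function(brain, hemorrhage, edema, provenance = list()) {
  stopifnot(identical(dim(brain), dim(hemorrhage)),
            identical(dim(brain), dim(edema)))
  if (any(hemorrhage & !brain)) stop_ich("hemorrhage not contained in brain", "ich_invariant_error")
  if (any(edema & !brain)) stop_ich("edema not contained in brain", "ich_invariant_error")
  if (any(hemorrhage & edema)) stop_ich("hemorrhage and edema overlap", "ich_invariant_error")
  structure(list(brain = brain, hemorrhage = hemorrhage, edema = edema,
                 provenance = provenance), class = "segmentation_masks")
}

#' Full semiautomated volumetry of a head CT
#'
#' Brain extraction, hemorrhage dual-clustering, edema ring refinement, and
#' voxel-count volumes, in one call.
#'
#' @inheritParams segment_edema
#' @param brain_params,hemorrhage_params,edema_params per-compartment
#'   [dual_cluster_params()].
#' @return list with `masks` (a [segmentation_masks()]) and `volumes_ml`
#'   (named: brain, iph, phe).
#' @export
ct_volumetry <- function(vol,
                         brain_params = dual_cluster_params(c(0, 80), min_cluster_voxels = 50L),
                         hemorrhage_params = dual_cluster_params(c(45, 90), min_cluster_voxels = 20L),
                         edema_params = dual_cluster_params(c(5, 23), min_cluster_voxels = 10L),
                         dilation_limit = 10L) {
  brain <- extract_brain(vol, brain_params)
  hem <- dual_cluster_segment(vol, hemorrhage_params, within = brain)
  if (!any(hem)) stop_ich("no hemorrhage found", "ich_no_lesion_error")
  ede <- segment_edema(vol, hem, brain, dilation_limit, edema_params)
  masks <- segmentation_masks(brain, hem, ede,
                              provenance = list(brain = brain_params,
                                                hemorrhage = hemorrhage_params,
                                                edema = edema_params,
                                                dilation_limit = dilation_limit))
  list(masks = masks,
       volumes_ml = c(brain = mask_volume(brain, vol$voxel_size),
                      iph = mask_volume(hem, vol$voxel_size),
                      phe = mask_volume(ede, vol$voxel_size)))
}
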