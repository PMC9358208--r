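#' Three-channel blood-smear image
#'
#' @param dapi,cd11b,despr nonnegative intensity matrices of identical
#'   shape: DAPI marks DNA, CD11b activated myeloid cells, DEspR the "rogue"
#'   subset.
#' @param pixel_size pixel edge in micrometers.
#' @param field_id label for the imaging position.
#' @return a `smear_image` object.
#' @export
smear_image <- function(dapi, cd11b, despr, pixel_size = 1, field_id = "field") {
  stopifnot(is.matrix(dapi), identical(dim(dapi), dim(cd11b)),
            identical(dim(dapi), dim(despr)))
  if (min(dapi) < 0 || min(cd11b) < 0 || min(despr) < 0)
    stop_ich("channel intensities must be nonnegative", "ich_domain_error")
  if (pixel_size <= 0) stop_ich("pixel_size must be positive", "ich_domain_error")
  structure(list(channels = list(dapi = dapi, cd11b = cd11b, despr = despr),
                 pixel_size = pixel_size, field_id = field_id),
            class = "smear_image")
}

#' Read / write a smear field as multi-channel TIFF
#'
#' Channel order in the file is DAPI, CD11b, DEspR (one directory each).
#'
#' @param path TIFF file path.
#' @param pixel_size,field_id see [smear_image()].
#' @return `read_smear_tiff`: a [smear_image()].
#' @export
read_smear_tiff <- function(path, pixel_size = 1, field_id = basename(path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3) stop_ich("expected a 3-channel TIFF", "ich_io_error")
  smear_image(pages[[1]], pages[[2]], pages[[3]],
              pixel_size = pixel_size, field_id = field_id)
}

#' @rdname read_smear_tiff
#' @param img a [smear_image()]; intensities are rescaled to the unit range
#'   of the file format.
#' @export
write_smear_tiff <- function(img, path) {
  mx <- max(1, unlist(lapply(img$channels, max)))
  tiff::writeTIFF(lapply(img$channels, function(ch) ch / mx), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Segment nuclei on the DAPI channel
#'
#' Connected components (8-connectivity) of the thresholded DAPI signal
#' after hole filling; components smaller than `min_area` are dropped. Each
#' object carries its pixel set, area, Crofton-traced perimeter, and the
#' area of its minimum enclosing circle — the shape quantities the
#' circularity index is built from.
#'
#' @param img a [smear_image()].
#' @param min_area minimum object area in square micrometers.
#' @param threshold `"otsu"` (per-field Otsu threshold) or a numeric
#'   intensity cutoff.
#' @return list of `nucleus_object`s (possibly empty).
#' @export
segment_nuclei <- function(img, min_area = 20, threshold = "otsu") {
  stopifnot(inherits(img, "smear_image"))
  dapi <- img$channels$dapi
  mx <- max(dapi)
  if (mx == 0) return(list())
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(dapi / mx)) * mx
  } else as.numeric(threshold)
  mask <- dapi > thr
  if (!any(mask)) return(list())
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0
  lab <- label_components(mask, connectivity = 26)
  px2 <- img$pixel_size^2
  min_px <- min_area / px2
  out <- list()
  for (i in seq_len(max(lab))) {
    pix <- which(lab == i, arr.ind = TRUE)
    if (nrow(pix) < min_px) next
    m <- lab == i
    perim <- crofton_perimeter(m) * img$pixel_size
    # enclose the pixel squares, not just their centers, so the enclosing
    # circle always covers the object area
    corners <- rbind(cbind(pix[, 1] - 0.5, pix[, 2] - 0.5),
                     cbind(pix[, 1] - 0.5, pix[, 2] + 0.5),
                     cbind(pix[, 1] + 0.5, pix[, 2] - 0.5),
                     cbind(pix[, 1] + 0.5, pix[, 2] + 0.5))
    mec <- min_enclosing_circle(corners)
    out[[length(out) + 1L]] <- structure(list(
      label = length(out) + 1L,
      field_id = img$field_id,
      pixel_set = pix,
      object_area = nrow(pix) * px2,
      traced_perimeter = perim,
      mec_area = pi * (mec$radius * img$pixel_size)^2,
      mec_center = mec$center,
      mec_radius = mec$radius * img$pixel_size), class = "nucleus_object")
  }
  out
}

#' Circularity index of a nucleus
#'
#' `4 * pi * mec_area / traced_perimeter^2`, where `mec_area` is the area of
#' the minimum circle enclosing the whole nucleus (including any DNA
#' extrusions) and `traced_perimeter` the traced outline length of the
#' DAPI-stained DNA with all extrusions. A perfect disk scores 1; DNA
#' extrusions lengthen the outline and drive the index down. Because the
#' enclosing-circle area is at least the object area, rough near-disks can
#' score slightly above 1; such values are clamped to 1 and flagged via the
#' `"clamped"` attribute.
#'
#' @param obj a `nucleus_object` from [segment_nuclei()].
#' @return circularity in (0, 1].
#' @export
circularity_index <- function(obj) {
  if (nrow(obj$pixel_set) < 2 || obj$traced_perimeter <= 0)
    stop_ich("degenerate object: circularity undefined", "ich_domain_error")
  circ <- 4 * pi * obj$mec_area / obj$traced_perimeter^2
  out <- min(1, circ)
  attr(out, "clamped") <- circ > 1
  out
}

#' NET classification by circularity
#'
#' NET-positive below 0.8; the 0.8 to 1.0 band is NET-negative, so exactly
#' 0.8 classifies negative.
#'
#' @param circ circularity index (> 0).
#' @return logical: NET-forming.
#' @export
classify_net <- function(circ) {
  if (any(circ <= 0)) stop_ich("circularity must be positive", "ich_domain_error")
  circ < 0.8
}

#' Background thresholds for marker positivity
#'
#' Mean + 3 sd of each marker channel over a cell-free region (all pixels
#' outside the given nucleus mask, or the whole field if no mask).
#'
#' @param img a [smear_image()].
#' @param nucleus_mask optional logical matrix of nucleus pixels to exclude.
#' @return named list with `cd11b` and `despr` thresholds.
#' @export
background_thresholds <- function(img, nucleus_mask = NULL) {
  sel <- if (is.null(nucleus_mask)) TRUE else !nucleus_mask
  list(cd11b = mean(img$channels$cd11b[sel]) + 3 * stats::sd(img$channels$cd11b[sel]),
       despr = mean(img$channels$despr[sel]) + 3 * stats::sd(img$channels$despr[sel]))
}

#' Co-localized marker intensity and positivity
#'
#' Mean CD11b and DEspR intensity over the nucleus pixel set;
#' double-positive when both means exceed their background thresholds.
#'
#' @param obj a `nucleus_object`.
#' @param img the [smear_image()] it came from.
#' @param bg named list of background thresholds (`cd11b`, `despr`).
#' @return list with `mean_cd11b`, `mean_despr`, `despr_cd11b_positive`.
#' @export
marker_positivity <- function(obj, img, bg) {
  if (is.null(bg$cd11b) || is.null(bg$despr))
    stop_ich("background thresholds for cd11b and despr are required", "ich_config_error")
  mc <- mean(img$channels$cd11b[obj$pixel_set])
  md <- mean(img$channels$despr[obj$pixel_set])
  list(mean_cd11b = mc, mean_despr = md,
       despr_cd11b_positive = mc > bg$cd11b && md > bg$despr)
}

#' Score a whole slide scan
#'
#' Processes every imaged field (the acquisition protocol tiles 100 evenly
#' spaced positions per slide): segments nuclei, computes circularity, NET
#' and marker calls, and aggregates. The NET-positive fraction is computed
#' over DEspR+CD11b+ nuclei; the double-positive fraction over all nuclei.
#' An absolute NET+ concentration is reported only when an external anchor
#' neutrophil concentration (cells/uL, e.g. from the same-day CBC) is
#' supplied — the conversion is never inferred from the images.
#'
#' @param fields list of [smear_image()]s.
#' @param min_area,threshold passed to [segment_nuclei()].
#' @param bg background thresholds; `NULL` estimates them per field via
#'   [background_thresholds()].
#' @param anchor_per_ul optional neutrophil concentration anchor, cells/uL.
#' @return a `slide_scan_result`: `n_fields`, `nuclei` (data frame),
#'   `net_fraction`, `dp_fraction`, `net_count_per_ul` (or `NA`).
#' @export
scan_slide <- function(fields, min_area = 20, threshold = "otsu", bg = NULL,
                       anchor_per_ul = NULL) {
  if (length(fields) == 0) stop_ich("empty field list", "ich_domain_error")
  rows <- list()
  for (img in fields) {
    objs <- segment_nuclei(img, min_area = min_area, threshold = threshold)
    if (length(objs) == 0) next
    nmask <- matrix(FALSE, nrow(img$channels$dapi), ncol(img$channels$dapi))
    for (o in objs) nmask[o$pixel_set] <- TRUE
    bgi <- if (is.null(bg)) background_thresholds(img, nmask) else bg
    for (o in objs) {
      circ <- circularity_index(o)
      mk <- marker_positivity(o, img, bgi)
      rows[[length(rows) + 1L]] <- data.frame(
        field_id = img$field_id, label = o$label,
        object_area = o$object_area, traced_perimeter = o$traced_perimeter,
        mec_area = o$mec_area, circularity = as.numeric(circ),
        net_positive = classify_net(as.numeric(circ)),
        mean_cd11b = mk$mean_cd11b, mean_despr = mk$mean_despr,
        despr_cd11b_positive = mk$despr_cd11b_positive,
        stringsAsFactors = FALSE)
    }
  }
  nuclei <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field_id = character(), label = integer(), object_area = numeric(),
               traced_perimeter = numeric(), mec_area = numeric(),
               circularity = numeric(), net_positive = logical(),
               mean_cd11b = numeric(), mean_despr = numeric(),
               despr_cd11b_positive = logical())
  dp <- nuclei$despr_cd11b_positive
  net_fraction <- if (any(dp)) mean(nuclei$net_positive[dp]) else 0
  dp_fraction <- if (nrow(nuclei)) mean(dp) else 0
  structure(list(
    n_fields = length(fields), nuclei = nuclei,
    net_fraction = net_fraction, dp_fraction = dp_fraction,
    net_count_per_ul = if (is.null(anchor_per_ul)) NA_real_
                       else net_fraction * anchor_per_ul),
    class = "slide_scan_result")
}
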