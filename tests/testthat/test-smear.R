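test_that("nucleus segmentation counts disjoint disks and filters small objects", {
  expect_length(segment_nuclei(disks_image(5, rad = 6)), 5)
  # a disk below min_area (pi * 2^2 ~ 12.6 um^2 < 20 um^2) is dropped
  expect_length(segment_nuclei(disks_image(1, rad = 2)), 0)
  blank <- smear_image(matrix(0, 40, 40), matrix(0, 40, 40), matrix(0, 40, 40))
  expect_length(segment_nuclei(blank), 0)
})

test_that("segmented objects overlap generator truth at Jaccard >= 0.9", {
  # a mixed slide yields one object per generated nucleus (round or NET-like)
  mixed <- generate_smear(smear_spec(n_fields = 2, cells_per_field = 6,
                                     net_fraction = 0.5, seed = 4))
  for (f in 1:2)
    expect_length(segment_nuclei(mixed$fields[[f]]),
                  sum(mixed$truth$field == f))
  # per-object pixel overlap scored on round nuclei, whose truth masks are
  # exact disks
  sp <- smear_spec(n_fields = 2, cells_per_field = 6, net_fraction = 0, seed = 4)
  sm <- generate_smear(sp)
  for (f in 1:2) {
    img <- sm$fields[[f]]
    objs <- segment_nuclei(img)
    tr <- sm$truth[sm$truth$field == f, ]
    expect_length(objs, nrow(tr))
    for (o in objs) {
      d <- (tr$row - o$mec_center[1])^2 + (tr$col - o$mec_center[2])^2
      cell <- tr[which.min(d), ]
      truth_mask <- raster_disk(nrow(img$channels$dapi), c(cell$row, cell$col),
                                sp$nucleus_radius / sp$pixel_size)
      obj_mask <- matrix(FALSE, nrow(img$channels$dapi), ncol(img$channels$dapi))
      obj_mask[o$pixel_set] <- TRUE
      expect_gte(jaccard(obj_mask, truth_mask), 0.9)
    }
  }
})

test_that("circularity of a rasterized disk is 1.0 within 0.05", {
  objs <- segment_nuclei(disks_image(1, rad = 20, side = 60, gap = 60))
  expect_length(objs, 1)
  circ <- circularity_index(objs[[1]])
  expect_equal(as.numeric(circ), 1.0, tolerance = 0.05)
  expect_gte(objs[[1]]$mec_area, objs[[1]]$object_area)
})

test_that("circularity matches the closed form on a star polygon", {
  verts <- star_polygon(c(90, 90), R = 60, r = 24, k = 7)
  mask <- raster_polygon(180, verts)
  img <- smear_image(mask * 100, matrix(0, 180, 180), matrix(0, 180, 180))
  objs <- segment_nuclei(img, threshold = 50)
  expect_length(objs, 1)
  analytic <- 4 * pi * (pi * 60^2) / star_perimeter(60, 24, 7)^2
  expect_equal(as.numeric(circularity_index(objs[[1]])), analytic,
               tolerance = 0.08)
})

test_that("circularity is scale-invariant to within 0.03", {
  circ_at <- function(R, k) {
    verts <- star_polygon(c(3 * R, 3 * R), R = R, r = 0.45 * R, k = k)
    mask <- raster_polygon(6 * R, verts)
    img <- smear_image(mask * 100, matrix(0, 6 * R, 6 * R), matrix(0, 6 * R, 6 * R))
    as.numeric(circularity_index(segment_nuclei(img, threshold = 50)[[1]]))
  }
  expect_lt(abs(circ_at(30, 6) - circ_at(60, 6)), 0.03)
})

test_that("mec_area >= object_area across generated nuclei", {
  sm <- generate_smear(smear_spec(n_fields = 3, cells_per_field = 6,
                                  net_fraction = 0.4, seed = 9))
  for (img in sm$fields)
    for (o in segment_nuclei(img))
      expect_gte(o$mec_area, o$object_area - 1e-9)
})

test_that("the NET cutoff at 0.8 is closed below", {
  expect_true(classify_net(0.79))
  expect_false(classify_net(0.80))   # the 0.8-1.0 band is NET-negative
  expect_false(classify_net(1.0))
  expect_error(classify_net(0), class = "ich_domain_error")
  expect_error(classify_net(-0.2), class = "ich_domain_error")
})

test_that("lengthening extrusions at fixed enclosing circle lowers circularity", {
  circ_for <- function(tau) {
    sp <- smear_spec(n_fields = 1, cells_per_field = 4, net_fraction = 1,
                     n_extrusions = 4, extrusion_len = 5, tortuosity = tau,
                     seed = 5)
    mean(scan_slide(generate_smear(sp)$fields)$nuclei$circularity)
  }
  cs <- vapply(c(1.2, 1.5, 1.8, 2.2), circ_for, 0)
  expect_true(all(diff(cs) < 0))
})

test_that("the moderate-extrusion morphology class scores near 0.6", {
  sp <- smear_spec(n_fields = 2, cells_per_field = 4, net_fraction = 1,
                   n_extrusions = 4, extrusion_len = 5, tortuosity = 1.33,
                   seed = 2)
  res <- scan_slide(generate_smear(sp)$fields)
  expect_equal(mean(res$nuclei$circularity), 0.6, tolerance = 0.1)
  expect_true(all(res$nuclei$net_positive))
})

test_that("marker positivity is a conjunction over background thresholds", {
  img <- disks_image(1, rad = 8)
  obj <- segment_nuclei(img)[[1]]
  bg <- list(cd11b = 10, despr = 10)
  mk <- marker_positivity(obj, img, bg)
  expect_equal(mk$mean_cd11b, 0)
  expect_false(mk$despr_cd11b_positive)
  # paint cd11b only: conjunction stays false
  img2 <- img; img2$channels$cd11b[] <- 50
  expect_false(marker_positivity(obj, img2, bg)$despr_cd11b_positive)
  img3 <- img2; img3$channels$despr[] <- 50
  expect_true(marker_positivity(obj, img3, bg)$despr_cd11b_positive)
  expect_error(marker_positivity(obj, img, list(cd11b = 10)),
               class = "ich_config_error")
})

test_that("slide scoring recovers the planted NET fraction and applies anchors", {
  sp <- smear_spec(n_fields = 25, cells_per_field = 6, net_fraction = 0.2,
                   seed = 13)
  sm <- generate_smear(sp)
  res <- scan_slide(sm$fields, anchor_per_ul = 3000)
  expect_equal(res$n_fields, 25)
  truth_frac <- mean(sm$truth$net)
  expect_equal(res$net_fraction, truth_frac, tolerance = 1e-9)
  # binomial 95% bound around the requested rate at n = 150 cells
  expect_lt(abs(res$net_fraction - 0.2), 2 * sqrt(0.2 * 0.8 / nrow(sm$truth)) + 0.01)
  expect_equal(res$net_count_per_ul, res$net_fraction * 3000)
  # all-round slide scores zero
  allround <- generate_smear(smear_spec(n_fields = 2, cells_per_field = 4,
                                        net_fraction = 0, seed = 1))
  expect_equal(scan_slide(allround$fields)$net_fraction, 0)
  expect_error(scan_slide(list()), class = "ich_domain_error")
})

test_that("smear fields round-trip through multi-channel TIFF", {
  sm <- generate_smear(smear_spec(n_fields = 1, cells_per_field = 4, seed = 2))
  img <- sm$fields[[1]]
  p <- tempfile(fileext = ".tif")
  write_smear_tiff(img, p)
  back <- read_smear_tiff(p, pixel_size = img$pixel_size)
  mx <- max(unlist(lapply(img$channels, max)))
  expect_equal(back$channels$dapi * mx, img$channels$dapi, tolerance = 1e-3)
  expect_equal(back$channels$despr * mx, img$channels$despr, tolerance = 1e-3)
})
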