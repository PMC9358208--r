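test_that("dual-clustering keeps a uniform in-window volume and drops specks", {
  v <- ct_volume(array(60, c(8, 8, 8)), c(1, 1, 1))
  p <- dual_cluster_params(c(45, 90))
  expect_true(all(dual_cluster_segment(v, p)))
  # restricted to `within` it returns exactly that mask
  w <- array(FALSE, c(8, 8, 8)); w[3:5, 3:5, 3:5] <- TRUE
  expect_equal(dual_cluster_segment(v, p, within = w), w)
  # a single isolated in-window voxel dies under min_cluster_voxels = 2
  a <- array(0, c(8, 8, 8)); a[4, 4, 4] <- 60
  v2 <- ct_volume(a, c(1, 1, 1))
  p2 <- dual_cluster_params(c(45, 90), neighbor_fraction = 0, min_cluster_voxels = 2L)
  expect_false(any(dual_cluster_segment(v2, p2)))
  expect_error(dual_cluster_params(c(90, 45)), class = "ich_domain_error")
  expect_error(dual_cluster_params(c(45, 5000)), class = "ich_domain_error")
})

test_that("widening the HU window never shrinks the retained voxel set", {
  ph <- generate_ct_phantom(phantom_spec(noise_sd = 5, seed = 42))
  loose <- function(w) dual_cluster_params(w, neighbor_fraction = 0.5,
                                           min_cluster_voxels = 1L,
                                           intensity_floor = -1024)
  narrow <- dual_cluster_segment(ph$volume, loose(c(50, 70)))
  wide <- dual_cluster_segment(ph$volume, loose(c(45, 90)))
  expect_true(all(wide[narrow]))
})

test_that("phantom hematoma segmentation hits Dice >= 0.95 and 10% volume error", {
  ph <- generate_ct_phantom(phantom_spec(noise_sd = 3, seed = 1))
  res <- ct_volumetry(ph$volume)
  expect_gte(dice_coef(res$masks$hemorrhage, ph$truth$hematoma), 0.95)
  expect_lt(abs(res$volumes_ml[["iph"]] - ph$analytic_ml[["hematoma"]]) /
              ph$analytic_ml[["hematoma"]], 0.10)
  expect_lt(abs(res$volumes_ml[["phe"]] - ph$analytic_ml[["edema"]]) /
              ph$analytic_ml[["edema"]], 0.10)
  # pipeline outputs satisfy the mask invariants (asserted by constructor)
  expect_s3_class(res$masks, "segmentation_masks")
})

test_that("brain extraction excludes the skull and recovers brain volume", {
  ph <- generate_ct_phantom(phantom_spec(noise_sd = 3, seed = 2))
  brain <- extract_brain(ph$volume)
  expect_false(any(brain & ph$truth$skull))
  vol <- mask_volume(brain, ph$volume$voxel_size)
  expect_lt(abs(vol - ph$analytic_ml[["brain"]]) / ph$analytic_ml[["brain"]], 0.05)
  # an all-air scan has no brain
  air <- ct_volume(array(-1000, c(6, 6, 6)), c(1, 1, 1))
  expect_error(extract_brain(air), class = "ich_no_brain_error")
})

test_that("edema ring segmentation respects masks and recovers the shell", {
  ph <- generate_ct_phantom(phantom_spec(noise_sd = 3, seed = 3))
  res <- ct_volumetry(ph$volume)
  hem <- res$masks$hemorrhage; brain <- res$masks$brain; ede <- res$masks$edema
  expect_false(any(ede & hem))   # disjoint by construction
  expect_true(all(brain[ede]))   # contained in brain
  expect_lt(abs(mask_volume(ede, ph$volume$voxel_size) - ph$analytic_ml[["edema"]]) /
              ph$analytic_ml[["edema"]], 0.10)
  expect_error(segment_edema(ph$volume, array(FALSE, dim(hem)), brain),
               class = "ich_no_lesion_error")
  # ring saturation: uniform edema-HU volume returns the ring itself
  v <- ct_volume(array(15, c(10, 10, 10)), c(1, 1, 1))
  core <- array(FALSE, c(10, 10, 10)); core[5:6, 5:6, 5:6] <- TRUE
  all_brain <- array(TRUE, c(10, 10, 10))
  ring <- ichneutro:::dilate_mask(core, 2) & !core
  got <- segment_edema(v, core, all_brain, dilation_limit = 2,
                       edema_params = dual_cluster_params(c(5, 23),
                                                          min_cluster_voxels = 1L))
  expect_equal(got, ring)
})

test_that("mask volumes convert voxel counts exactly and match analytic truth", {
  m <- array(FALSE, c(10, 10, 10)); m[seq_len(1000)] <- TRUE
  expect_equal(mask_volume(m, c(1, 1, 1)), 1.0)
  expect_equal(mask_volume(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), 0)
  expect_equal(mask_volume(m, c(0.5, 0.5, 2)), 0.5)
  # voxelized truth mask within one voxel shell of the closed form
  ph <- generate_ct_phantom(phantom_spec(hematoma_semiaxes = c(10, 10, 10),
                                         noise_sd = 0))
  vol <- mask_volume(ph$truth$hematoma, ph$volume$voxel_size)
  shell <- 4 * pi * 10^2 * 1 / 1000  # surface area x voxel edge, ml
  expect_lt(abs(vol - 4.18879), shell)
  expect_equal(ph$analytic_ml[["hematoma"]], 4 / 3 * pi * 10^3 / 1000)
})

test_that("segmentation mask invariants are enforced", {
  d <- c(4, 4, 4)
  brain <- array(TRUE, d)
  hem <- array(FALSE, d); hem[2, 2, 2] <- TRUE
  ede <- array(FALSE, d); ede[3, 3, 3] <- TRUE
  expect_s3_class(segmentation_masks(brain, hem, ede), "segmentation_masks")
  expect_error(segmentation_masks(!brain, hem, ede), class = "ich_invariant_error")
  expect_error(segmentation_masks(brain, hem, hem), class = "ich_invariant_error")
})

test_that("CT volumes and masks round-trip through NIfTI", {
  ph <- generate_ct_phantom(phantom_spec(shape = c(20, 24, 24), noise_sd = 0,
                                         brain_semiaxes = c(8, 10, 10),
                                         hematoma_semiaxes = c(3, 3, 3),
                                         edema_thickness = 2))
  p <- tempfile(fileext = ".nii.gz")
  write_ct_volume(ph$volume, p)
  back <- read_ct_volume(p)
  expect_equal(back$values, ph$volume$values, tolerance = 1e-6)
  expect_equal(back$voxel_size, ph$volume$voxel_size)
})
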