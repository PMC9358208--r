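#' CT phantom specification
#'
#' An ellipsoidal brain inside a skull shell, with an ellipsoidal hyperdense
#' hematoma and a hypodense perihematomal edema shell, all with analytic
#' (closed-form) volumes. Default HU means follow the usual radiodensity
#' scale: air -1000, brain parenchyma 30, acute blood 60, edema 15,
#' skull 1000.
#'
#' @param shape grid dimensions (slice, row, column).
#' @param voxel_size voxel edges (dz, dy, dx) in mm.
#' @param brain_semiaxes,hematoma_semiaxes ellipsoid semi-axes in mm.
#' @param hematoma_center offset of the hematoma center from the brain
#'   center, mm.
#' @param edema_thickness edema shell thickness in mm (added to each
#'   hematoma semi-axis).
#' @param hu named HU means (air, brain, hematoma, edema, skull).
#' @param skull_thickness skull shell thickness, mm.
#' @param noise_sd Gaussian HU noise sd.
#' @param seed RNG seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(60, 72, 72), voxel_size = c(1, 1, 1),
                         brain_semiaxes = c(26, 32, 32),
                         hematoma_semiaxes = c(10, 10, 10),
                         hematoma_center = c(0, 0, 0),
                         edema_thickness = 3,
                         hu = c(air = -1000, brain = 30, hematoma = 60,
                                edema = 15, skull = 1000),
                         skull_thickness = 2, noise_sd = 3, seed = 1L) {
  outer <- hematoma_semiaxes + edema_thickness
  if (any(abs(hematoma_center) + outer >= brain_semiaxes))
    stop_ich("hematoma plus edema shell must lie strictly inside the brain",
             "ich_spec_error")
  structure(list(shape = shape, voxel_size = voxel_size,
                 brain_semiaxes = brain_semiaxes,
                 hematoma_semiaxes = hematoma_semiaxes,
                 hematoma_center = hematoma_center,
                 edema_thickness = edema_thickness, hu = hu,
                 skull_thickness = skull_thickness,
                 noise_sd = noise_sd, seed = seed), class = "phantom_spec")
}

ellipsoid_mask <- function(shape, voxel_size, center_mm, semiaxes_mm) {
  ax <- lapply(1:3, function(i) ((seq_len(shape[i]) - 0.5) * voxel_size[i] - center_mm[i]) / semiaxes_mm[i])
  g1 <- array(ax[[1]]^2, shape)
  g2 <- array(rep(ax[[2]]^2, each = shape[1]), shape)
  g3 <- array(rep(ax[[3]]^2, each = shape[1] * shape[2]), shape)
  (g1 + g2 + g3) <= 1
}

#' Generate a CT head phantom with ground truth
#'
#' Deterministic given the spec's seed. Analytic volumes use the ellipsoid
#' closed form `(4/3) * pi * a * b * c`; the edema analytic volume is the
#' outer shell minus the hematoma.
#'
#' @param spec a [phantom_spec()].
#' @return list: `volume` (a [ct_volume()]), `truth` (logical masks brain,
#'   hematoma, edema, skull), `analytic_ml` (named closed-form volumes).
#' @export
generate_ct_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape; vx <- spec$voxel_size
  center <- sh * vx / 2
  hcenter <- center + spec$hematoma_center
  brain <- ellipsoid_mask(sh, vx, center, spec$brain_semiaxes)
  skull_outer <- ellipsoid_mask(sh, vx, center, spec$brain_semiaxes + spec$skull_thickness)
  skull <- skull_outer & !brain
  hema <- ellipsoid_mask(sh, vx, hcenter, spec$hematoma_semiaxes)
  outer <- ellipsoid_mask(sh, vx, hcenter, spec$hematoma_semiaxes + spec$edema_thickness)
  edema <- outer & !hema
  v <- array(spec$hu[["air"]], sh)
  v[brain] <- spec$hu[["brain"]]
  v[skull] <- spec$hu[["skull"]]
  v[edema] <- spec$hu[["edema"]]
  v[hema] <- spec$hu[["hematoma"]]
  if (spec$noise_sd > 0)
    v <- v + with_seed(spec$seed, array(stats::rnorm(prod(sh), sd = spec$noise_sd), sh))
  v <- pmin(pmax(v, -1024), 3071)
  ell_ml <- function(s) 4 / 3 * pi * prod(s) / 1000
  list(volume = ct_volume(v, vx),
       truth = list(brain = brain, hematoma = hema, edema = edema, skull = skull),
       analytic_ml = c(brain = ell_ml(spec$brain_semiaxes),
                       hematoma = ell_ml(spec$hematoma_semiaxes),
                       edema = ell_ml(spec$hematoma_semiaxes + spec$edema_thickness) -
                         ell_ml(spec$hematoma_semiaxes)))
}

#' Blood-smear specification
#'
#' Round nuclei are disks; NET-like nuclei are disks with sinuous DNA
#' extrusions whose analytic outline length and enclosing-circle radius are
#' recorded, giving each cell a known target circularity. A fraction of
#' cells is painted positive on both marker channels.
#'
#' @param n_fields number of imaging positions (the slide protocol uses
#'   100).
#' @param cells_per_field nuclei per field.
#' @param net_fraction fraction of double-positive cells that are NET-like.
#' @param double_positive_fraction fraction of cells CD11b+DEspR+.
#' @param field_px square field side, pixels.
#' @param pixel_size micrometers per pixel.
#' @param nucleus_radius nucleus radius, micrometers.
#' @param n_extrusions extrusion arms per NET-like nucleus.
#' @param extrusion_len radial extent of each arm, micrometers.
#' @param tortuosity arc length of an arm relative to its extent (>= 1).
#' @param intensity named means for nucleus DAPI signal and for positive
#'   marker signal.
#' @param background_sd additive channel noise sd.
#' @param seed RNG seed.
#' @return a `smear_spec` list.
#' @export
smear_spec <- function(n_fields = 10, cells_per_field = 8, net_fraction = 0.2,
                       double_positive_fraction = 1, field_px = 240,
                       pixel_size = 0.5, nucleus_radius = 4,
                       n_extrusions = 4, extrusion_len = 5, tortuosity = 1.6,
                       intensity = c(dapi = 200, marker = 150),
                       background_sd = 4, seed = 1L) {
  if (net_fraction < 0 || net_fraction > 1 ||
      double_positive_fraction < 0 || double_positive_fraction > 1)
    stop_ich("fractions must lie in [0, 1]", "ich_spec_error")
  # crude packing bound: cells sit on a jittered grid, one per tile
  tile <- floor(field_px / ceiling(sqrt(cells_per_field)))
  need <- 2 * (nucleus_radius + extrusion_len) / pixel_size
  if (tile < need)
    stop_ich("cells_per_field exceeds the non-overlapping packing limit",
             "ich_spec_error")
  structure(as.list(environment()), class = "smear_spec")
}

# analytic target circularity of a NET-like cell under a smear_spec
net_target_circularity <- function(spec) {
  r <- spec$nucleus_radius
  mec_r <- r + spec$extrusion_len
  perim <- 2 * pi * r + 2 * spec$n_extrusions * spec$tortuosity * spec$extrusion_len
  4 * pi * (pi * mec_r^2) / perim^2
}

# pixels within w/2 of the polyline given by pts (n x 2, pixel coords)
rasterize_path <- function(shape, pts, width) {
  acc <- matrix(FALSE, shape[1], shape[2])
  half <- width / 2
  for (i in seq_len(nrow(pts) - 1)) {
    p <- pts[i, ]; q <- pts[i + 1, ]
    lo <- floor(pmin(p, q) - half - 1); hi <- ceiling(pmax(p, q) + half + 1)
    rs <- max(1, lo[1]):min(shape[1], hi[1])
    cs <- max(1, lo[2]):min(shape[2], hi[2])
    if (length(rs) == 0 || length(cs) == 0) next
    gr <- matrix(rs, length(rs), length(cs))
    gc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
    d <- q - p
    l2 <- sum(d^2)
    t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((gr - p[1]) * d[1] + (gc - p[2]) * d[2]) / l2))
    dist2 <- (gr - (p[1] + t * d[1]))^2 + (gc - (p[2] + t * d[2]))^2
    acc[rs, cs] <- acc[rs, cs] | (dist2 <= half^2)
  }
  acc
}

disk_mask <- function(shape, center, radius) {
  gr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  gc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (gr - center[1])^2 + (gc - center[2])^2 <= radius^2
}

# one sinuous extrusion arm: radial direction theta, extent L, arc ~ tau*L
extrusion_path <- function(center, theta, extent_px, tortuosity, n_seg = 24) {
  s <- seq(0, 1, length.out = n_seg)
  # sine wiggle orthogonal to the arm; amplitude chosen so that the arc
  # length is close to tortuosity * extent
  amp <- extent_px / (2 * pi) * sqrt(max(0, 2 * (tortuosity^2 - 1)))
  along <- s * extent_px
  across <- amp * sin(2 * pi * s)
  dir <- c(cos(theta), sin(theta)); orth <- c(-sin(theta), cos(theta))
  cbind(center[1] + along * dir[1] + across * orth[1],
        center[2] + along * dir[2] + across * orth[2])
}

#' Generate synthetic blood-smear fields with truth labels
#'
#' @param spec a [smear_spec()].
#' @return list: `fields` (list of [smear_image()]) and `truth` (data frame
#'   with per-cell field, center, NET / double-positive labels, analytic
#'   perimeter, enclosing-circle radius and target circularity).
#' @export
generate_smear <- function(spec = smear_spec()) {
  stopifnot(inherits(spec, "smear_spec"))
  with_seed(spec$seed, {
    px <- spec$pixel_size
    r_px <- spec$nucleus_radius / px
    ext_px <- spec$extrusion_len / px
    ncell <- spec$cells_per_field
    grid_n <- ceiling(sqrt(ncell))
    tile <- floor(spec$field_px / grid_n)
    fields <- vector("list", spec$n_fields)
    truth <- list()
    for (f in seq_len(spec$n_fields)) {
      dapi <- matrix(0, spec$field_px, spec$field_px)
      cd11b <- matrix(0, spec$field_px, spec$field_px)
      despr <- matrix(0, spec$field_px, spec$field_px)
      slots <- utils::head(as.matrix(expand.grid(seq_len(grid_n), seq_len(grid_n))), ncell)
      for (ci in seq_len(ncell)) {
        margin <- r_px + ext_px + 2
        lo <- (slots[ci, ] - 1) * tile + margin
        hi <- slots[ci, ] * tile - margin
        center <- c(stats::runif(1, lo[1], max(lo[1], hi[1])),
                    stats::runif(1, lo[2], max(lo[2], hi[2])))
        dp <- stats::runif(1) < spec$double_positive_fraction
        is_net <- dp && stats::runif(1) < spec$net_fraction
        m <- disk_mask(dim(dapi), center, r_px)
        if (is_net) {
          theta0 <- stats::runif(1, 0, 2 * pi)
          for (e in seq_len(spec$n_extrusions)) {
            th <- theta0 + (e - 1) * 2 * pi / spec$n_extrusions
            start <- center + r_px * 0.9 * c(cos(th), sin(th))
            pts <- extrusion_path(start, th, ext_px, spec$tortuosity)
            m <- m | rasterize_path(dim(dapi), pts, width = 2)
          }
        }
        dapi[m] <- spec$intensity[["dapi"]]
        if (dp) {
          mm <- disk_mask(dim(dapi), center, r_px + 2)
          cd11b[mm] <- spec$intensity[["marker"]]
          despr[mm] <- spec$intensity[["marker"]]
        }
        truth[[length(truth) + 1L]] <- data.frame(
          field = f, cell = ci, row = center[1], col = center[2],
          net = is_net, double_positive = dp,
          analytic_perimeter = if (is_net)
            px * (2 * pi * r_px + 2 * spec$n_extrusions * spec$tortuosity * ext_px)
            else px * 2 * pi * r_px,
          mec_radius = if (is_net) px * (0.9 * r_px + ext_px) else px * r_px,
          target_circularity = if (is_net) {
            pr <- 2 * pi * r_px + 2 * spec$n_extrusions * spec$tortuosity * ext_px
            min(1, 4 * pi * pi * (0.9 * r_px + ext_px)^2 / pr^2)
          } else 1)
      }
      noise <- function(x) {
        x <- x + matrix(stats::rnorm(length(x), sd = spec$background_sd), nrow(x))
        x[x < 0] <- 0
        x
      }
      fields[[f]] <- smear_image(noise(dapi), noise(cd11b), noise(despr),
                                 pixel_size = px, field_id = sprintf("f%03d", f))
    }
    list(fields = fields, truth = do.call(rbind, truth))
  })
}

#' Flow-cytometry mixture specification
#'
#' Three scatter clouds (lymphocytes, monocytes, neutrophils) as bivariate
#' Gaussians in FSC x SSC, log-normal fluorescence, a planted
#' double-positive fraction among neutrophils, and a log-normal isotype
#' background distribution.
#'
#' @param n_events stained-tube events.
#' @param n_isotype isotype-control events.
#' @param q2_fraction double-positive fraction among neutrophils.
#' @param proportions mixture weights (neutrophil, monocyte, lymphocyte).
#' @param scatter list of per-population c(fsc_mean, fsc_sd, ssc_mean,
#'   ssc_sd).
#' @param fl_neg,fl_pos log-normal (meanlog, sdlog) for negative and
#'   positive fluorescence.
#' @param seed RNG seed.
#' @return a `flow_spec` list.
#' @export
flow_spec <- function(n_events = 50000, n_isotype = 20000, q2_fraction = 0.10,
                      proportions = c(neutrophil = 0.55, monocyte = 0.10,
                                      lymphocyte = 0.35),
                      scatter = list(neutrophil = c(600, 60, 600, 70),
                                     monocyte = c(450, 50, 300, 40),
                                     lymphocyte = c(250, 40, 150, 30)),
                      fl_neg = c(meanlog = log(50), sdlog = 0.4),
                      fl_pos = c(meanlog = log(500), sdlog = 0.3),
                      seed = 1L) {
  if (q2_fraction < 0 || q2_fraction > 1)
    stop_ich("q2_fraction must lie in [0, 1]", "ich_spec_error")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop_ich("population proportions must be nonnegative and sum to 1", "ich_spec_error")
  if (any(c(scatter$neutrophil[c(2, 4)], scatter$monocyte[c(2, 4)],
            scatter$lymphocyte[c(2, 4)]) <= 0))
    stop_ich("scatter sds must be positive", "ich_spec_error")
  structure(as.list(environment()), class = "flow_spec")
}

#' Generate a synthetic flow-cytometry event table
#'
#' Monocytes are CD11b-positive but DEspR-negative; lymphocytes are double
#' negative; among neutrophils the planted `q2_fraction` is double
#' positive. Truth population labels and the double-positive flag travel in
#' the `truth_population` / `truth_q2` columns. Channels are generated
#' pre-compensated.
#'
#' @param spec a [flow_spec()].
#' @return an [event_table()] with truth columns, stained events followed
#'   by isotype-control events.
#' @export
generate_flow_events <- function(spec = flow_spec()) {
  stopifnot(inherits(spec, "flow_spec"))
  with_seed(spec$seed, {
    n <- spec$n_events
    pop <- sample(names(spec$proportions), n, replace = TRUE, prob = spec$proportions)
    sc <- do.call(rbind, lapply(pop, function(p) spec$scatter[[p]]))
    fsc <- stats::rnorm(n, sc[, 1], sc[, 2])
    ssc <- stats::rnorm(n, sc[, 3], sc[, 4])
    rln <- function(n, par) stats::rlnorm(n, par[["meanlog"]], par[["sdlog"]])
    q2 <- pop == "neutrophil" & stats::runif(n) < spec$q2_fraction
    fl_despr <- ifelse(q2, rln(n, spec$fl_pos), rln(n, spec$fl_neg))
    cd11b_pos <- q2 | pop == "monocyte"
    fl_cd11b <- ifelse(cd11b_pos, rln(n, spec$fl_pos), rln(n, spec$fl_neg))
    ev <- event_table(fsc, ssc, fl_despr, fl_cd11b, sample_id = "synthetic",
                      is_control = "stain")
    ev$truth_population <- pop
    ev$truth_q2 <- q2
    ni <- spec$n_isotype
    iso <- event_table(stats::rnorm(ni, spec$scatter$neutrophil[1], spec$scatter$neutrophil[2]),
                       stats::rnorm(ni, spec$scatter$neutrophil[3], spec$scatter$neutrophil[4]),
                       rln(ni, spec$fl_neg), rln(ni, spec$fl_neg),
                       sample_id = "synthetic", is_control = "isotype")
    iso$truth_population <- "neutrophil"
    iso$truth_q2 <- FALSE
    out <- rbind(ev, iso)
    class(out) <- c("event_table", "data.frame")
    out
  })
}

#' Copula cohort specification
#'
#' A Gaussian copula imposes a target Spearman correlation structure on
#' arbitrary marginals: the target is given directly on the Spearman scale
#' and converted internally to the latent Pearson scale via the exact sine
#' relation `rho_pearson = 2 * sin(pi * rho_spearman / 6)` (so callers and
#' tests must not convert again).
#'
#' @param n number of patients.
#' @param target_spearman symmetric target matrix with unit diagonal.
#' @param marginals named list of quantile functions (one per column),
#'   each taking a vector of probabilities.
#' @param seed RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n = 13,
                        target_spearman = diag(4),
                        marginals = list(
                          iph_vol = function(p) stats::qlnorm(p, log(5), 1),
                          phe_vol = function(p) stats::qlnorm(p, log(8), 1),
                          rogue_n_count = function(p) stats::qlnorm(p, log(2000), 0.8),
                          nlr = function(p) stats::qlnorm(p, log(4), 0.7)),
                        seed = 1L) {
  k <- length(marginals)
  if (!isTRUE(all.equal(dim(target_spearman), c(k, k))) ||
      any(abs(diag(target_spearman) - 1) > 1e-12) ||
      any(abs(target_spearman - t(target_spearman)) > 1e-12))
    stop_ich("target_spearman must be symmetric with unit diagonal, one row per marginal",
             "ich_spec_error")
  latent <- 2 * sin(pi * target_spearman / 6)
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_ich("target correlation matrix is not positive semidefinite on the latent scale",
             "ich_spec_error")
  structure(list(n = n, target_spearman = target_spearman, latent = latent,
                 marginals = marginals, seed = seed), class = "cohort_spec")
}

#' Generate a synthetic cohort with target rank-correlation structure
#'
#' Gaussian-copula draw: latent multivariate normal with the sine-converted
#' Pearson matrix, probability-transformed through each marginal's quantile
#' function. With continuous marginals the empirical Spearman matrix
#' converges to the target as n grows.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with one column per marginal and an `id` column.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    k <- length(spec$marginals)
    L <- chol(spec$latent + diag(1e-10, k))
    z <- matrix(stats::rnorm(spec$n * k), spec$n, k) %*% L
    u <- stats::pnorm(z)
    out <- as.data.frame(lapply(seq_len(k), function(j) spec$marginals[[j]](u[, j])))
    names(out) <- names(spec$marginals)
    cbind(id = seq_len(spec$n), out)
  })
}
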