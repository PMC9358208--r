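# shared scoring helpers and small geometric fixtures built in code

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# rasterized disk as a logical matrix (pixel-center inclusion)
raster_disk <- function(side, center, radius) {
  gr <- matrix(seq_len(side), side, side)
  gc <- matrix(seq_len(side), side, side, byrow = TRUE)
  (gr - center[1])^2 + (gc - center[2])^2 <= radius^2
}

# rasterized simple polygon (vertices in pixel coordinates, n x 2)
raster_polygon <- function(side, verts) {
  gr <- matrix(seq_len(side), side, side)
  gc <- matrix(seq_len(side), side, side, byrow = TRUE)
  ins <- pracma::inpolygon(as.vector(gr), as.vector(gc),
                           verts[, 1], verts[, 2], boundary = TRUE)
  matrix(ins, side, side)
}

# star polygon: 2k vertices alternating between outer radius R and inner r
star_polygon <- function(center, R, r, k = 5) {
  ang <- seq(0, 2 * pi, length.out = 2 * k + 1)[-(2 * k + 1)]
  rad <- rep(c(R, r), k)
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}

# analytic perimeter of that star polygon
star_perimeter <- function(R, r, k = 5) {
  step <- pi / k
  2 * k * sqrt(R^2 + r^2 - 2 * R * r * cos(step))
}

# a smear image with nd disjoint disks of radius rad on a blank background
disks_image <- function(nd, rad = 6, side = 120, gap = 24, value = 100) {
  dapi <- matrix(0, side, side)
  centers <- cbind(gap * seq_len(nd) - gap / 2, gap * seq_len(nd) - gap / 2)
  for (i in seq_len(nd)) dapi[raster_disk(side, centers[i, ], rad)] <- value
  smear_image(dapi, matrix(0, side, side), matrix(0, side, side),
              pixel_size = 1, field_id = "disks")
}

# cohort fixture written to a temp file with one cell overridden
cohort_csv_with <- function(row, col, value) {
  src <- system.file("extdata", "table1_cohort.csv", package = "ichneutro")
  df <- utils::read.csv(src, colClasses = "character", check.names = FALSE)
  df[row, col] <- as.character(value)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  path
}
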