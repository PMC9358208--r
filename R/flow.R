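#' Flow-cytometry event table
#'
#' Per-event forward scatter (size), side scatter (granularity) and the two
#' fluorescence channels (anti-DEspR, anti-CD11b), plus the control class of
#' the tube each event came from.
#'
#' @param fsc,ssc,fl_despr,fl_cd11b numeric event channels (finite).
#' @param sample_id sample label.
#' @param is_control one of `"stain"`, `"isotype"`, `"fmo_despr"`,
#'   `"fmo_cd11b"` (recycled).
#' @return an `event_table` data frame.
#' @export
event_table <- function(fsc, ssc, fl_despr, fl_cd11b, sample_id = "s1",
                        is_control = "stain") {
  df <- data.frame(fsc = fsc, ssc = ssc, fl_despr = fl_despr,
                   fl_cd11b = fl_cd11b, sample_id = sample_id,
                   is_control = is_control, stringsAsFactors = FALSE)
  validate_events(df)
  class(df) <- c("event_table", "data.frame")
  df
}

validate_events <- function(df) {
  chans <- c("fsc", "ssc", "fl_despr", "fl_cd11b")
  for (ch in chans)
    if (!all(is.finite(df[[ch]])))
      stop_ich(paste0("non-finite values in channel ", ch), "ich_validation_error")
  bad <- !df$is_control %in% c("stain", "isotype", "fmo_despr", "fmo_cd11b")
  if (any(bad)) stop_ich("unknown control class in is_control", "ich_validation_error")
  invisible(df)
}

#' Read / write events as CSV
#'
#' Events travel as plain CSV (columns fsc, ssc, fl_despr, fl_cd11b,
#' sample_id, is_control) rather than binary FCS.
#'
#' @param path CSV file path.
#' @return `read_events`: an [event_table()].
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_table(df$fsc, df$ssc, df$fl_despr, df$fl_cd11b,
              sample_id = if (is.null(df$sample_id)) "s1" else df$sample_id,
              is_control = if (is.null(df$is_control)) "stain" else df$is_control)
}

#' @rdname read_events
#' @param events an [event_table()].
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# TRUE when the closed polygon has two non-adjacent properly intersecting edges
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  ccw <- function(a, b, c) (c[2] - a[2]) * (b[1] - a[1]) - (b[2] - a[2]) * (c[1] - a[1])
  inter <- function(s1, s2) {
    d1 <- ccw(s2[1, ], s2[2, ], s1[1, ]); d2 <- ccw(s2[1, ], s2[2, ], s1[2, ])
    d3 <- ccw(s1[1, ], s1[2, ], s2[1, ]); d4 <- ccw(s1[1, ], s1[2, ], s2[2, ])
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent around the wrap
      if (inter(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

#' Gate the neutrophil cloud on scatter
#'
#' Keeps events inside a simple polygon drawn in FSC x SSC space (the
#' encircled neutrophil cloud on the dot plot); the polygon boundary counts
#' as inside.
#'
#' @param events an [event_table()].
#' @param gate two-column matrix of polygon vertices (fsc, ssc).
#' @return the gated [event_table()].
#' @export
gate_neutrophils <- function(events, gate = default_neutrophil_gate()) {
  stopifnot(is.matrix(gate), ncol(gate) == 2)
  if (nrow(gate) < 3) stop_ich("gate polygon needs at least 3 vertices", "ich_geometry_error")
  if (polygon_self_intersects(gate))
    stop_ich("gate polygon is self-intersecting", "ich_geometry_error")
  inside <- pracma::inpolygon(events$fsc, events$ssc, gate[, 1], gate[, 2],
                              boundary = TRUE)
  out <- events[inside, , drop = FALSE]
  class(out) <- c("event_table", "data.frame")
  out
}

#' Default neutrophil scatter gate
#'
#' A generous polygon around the high-FSC / high-SSC neutrophil cloud of the
#' synthetic mixtures produced by [generate_flow_events()]; documented so
#' recall against truth labels is reproducible.
#'
#' @return two-column vertex matrix (fsc, ssc).
#' @export
default_neutrophil_gate <- function() {
  cbind(fsc = c(420, 950, 950, 420), ssc = c(380, 380, 950, 950))
}

#' Quadrant thresholds from control tubes
#'
#' Each fluorescence threshold is the given quantile (default 0.999) of the
#' matching control distribution: the isotype tube by default, or the
#' channel-matched FMO tubes.
#'
#' @param controls an [event_table()] containing the control events.
#' @param quantile quantile of the control distribution.
#' @param control `"isotype"` (one tube for both channels) or `"fmo"`
#'   (per-channel fmo_despr / fmo_cd11b tubes).
#' @return named numeric: `t_despr`, `t_cd11b`.
#' @export
quadrant_thresholds <- function(controls, quantile = 0.999, control = c("isotype", "fmo")) {
  control <- match.arg(control)
  if (control == "isotype") {
    iso <- controls[controls$is_control == "isotype", , drop = FALSE]
    if (nrow(iso) == 0) stop_ich("no isotype control events", "ich_config_error")
    c(t_despr = unname(stats::quantile(iso$fl_despr, quantile)),
      t_cd11b = unname(stats::quantile(iso$fl_cd11b, quantile)))
  } else {
    fd <- controls[controls$is_control == "fmo_despr", , drop = FALSE]
    fc <- controls[controls$is_control == "fmo_cd11b", , drop = FALSE]
    if (nrow(fd) == 0 || nrow(fc) == 0)
      stop_ich("missing FMO control events", "ich_config_error")
    c(t_despr = unname(stats::quantile(fd$fl_despr, quantile)),
      t_cd11b = unname(stats::quantile(fc$fl_cd11b, quantile)))
  }
}

#' Quadrant counts and the Q2 double-positive fraction
#'
#' Positivity is strictly above threshold (conventions vary across analysis
#' software; this one is fixed and documented). Quadrants: Q1 DEspR+ only,
#' Q2 DEspR+CD11b+ (the "rogue" subset), Q3 double-negative, Q4 CD11b+
#' only. Fractions are over the gated events; a Q2 absolute concentration
#' is reported only when an external anchor neutrophil concentration is
#' supplied.
#'
#' @param gated gated [event_table()] (nonempty).
#' @param thresholds named numeric from [quadrant_thresholds()].
#' @param anchor_per_ul optional neutrophil concentration, cells/uL.
#' @return a `quadrant_result` list: `thresholds`, `counts`, `fractions`,
#'   `q2_fraction`, `q2_concentration`.
#' @export
quadrant_counts <- function(gated, thresholds, anchor_per_ul = NULL) {
  n <- nrow(gated)
  if (n == 0) stop_ich("empty gated table: fractions undefined", "ich_domain_error")
  dp <- gated$fl_despr > thresholds[["t_despr"]]
  cp <- gated$fl_cd11b > thresholds[["t_cd11b"]]
  counts <- c(q1 = sum(dp & !cp), q2 = sum(dp & cp),
              q3 = sum(!dp & !cp), q4 = sum(!dp & cp))
  fractions <- counts / n
  structure(list(thresholds = thresholds, counts = counts,
                 fractions = fractions, q2_fraction = unname(fractions["q2"]),
                 q2_concentration = if (is.null(anchor_per_ul)) NA_real_
                                    else unname(fractions["q2"]) * anchor_per_ul),
            class = "quadrant_result")
}
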