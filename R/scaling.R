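#' Regional carbon sink from a per-area rate
#'
#' Scales a per-hectare carbon accumulation rate to a regional total:
#' Mg C ha-1 yr-1 times Mha gives Tg C yr-1.
#'
#' @param rate_c Carbon accumulation rate, Mg C/ha/yr.
#' @param area_mha Forest area, millions of hectares.
#' @return Regional sink, Tg C/yr.
#' @export
regional_sink <- function(rate_c, area_mha) {
  if (any(area_mha < 0)) stop("area must be non-negative", call. = FALSE)
  rate_c * area_mha
}

#' Minimum square fragment sustaining a carbon sink
#'
#' A square fragment of side L with an edge band of depth d accumulates
#' carbon at `interior_rate` over its core (L - 2d)^2 and at `edge_rate`
#' (typically negative) over the band L^2 - (L - 2d)^2. The minimum side
#' solves interior_rate (L - 2d)^2 + edge_rate (L^2 - (L - 2d)^2) = 0 for
#' L > 2d, giving L = 2d / (1 - sqrt(-edge_rate / (interior_rate -
#' edge_rate))).
#'
#' @param interior_rate Net AGB (or carbon) change of interior forest,
#'   Mg/ha/yr (> 0).
#' @param edge_rate Net change of the edge band, same units (<= 0 for a
#'   non-trivial solution; a positive value makes any fragment a sink and
#'   the boundary side 2d is returned with a note).
#' @param edge_depth Edge-effect penetration depth d, m.
#' @return Object of class `fragment_geometry`: the rates and depth,
#'   `min_side_m`, exact `min_area_ha`, and the paper-style rounded values
#'   `min_area_ha_rounded` (truncated to integer ha) and `min_side_km_rounded`
#'   (0.1 km); `note` marks the degenerate cases.
#' @export
min_fragment_square <- function(interior_rate, edge_rate, edge_depth) {
  if (interior_rate <= 0) stop("interior_rate must be positive", call. = FALSE)
  if (edge_depth <= 0) stop("edge_depth must be positive", call. = FALSE)
  note <- NA_character_
  if (edge_rate > 0) {
    side <- 2 * edge_depth
    note <- "edge rate positive: any fragment is a sink; boundary side 2d returned"
  } else {
    ratio <- -edge_rate / (interior_rate - edge_rate)
    side <- 2 * edge_depth / (1 - sqrt(ratio))
    if (edge_rate == 0) note <- "edge rate zero: boundary case, side = 2d"
  }
  area_ha <- side^2 / 1e4
  structure(list(interior_rate = interior_rate, edge_rate = edge_rate,
                 edge_depth = edge_depth, min_side_m = side,
                 min_area_ha = area_ha,
                 min_area_ha_rounded = floor(area_ha),
                 min_side_km_rounded = round(side / 1000, 1),
                 note = note), class = "fragment_geometry")
}

#' @export
print.fragment_geometry <- function(x, ...) {
  cat("<fragment_geometry> edge depth ", x$edge_depth, " m, rates ",
      signif(x$interior_rate, 3), " / ", signif(x$edge_rate, 3),
      " Mg/ha/yr\n  minimum square: ", round(x$min_area_ha, 1), " ha (",
      x$min_area_ha_rounded, " ha, ", x$min_side_km_rounded, " x ",
      x$min_side_km_rounded, " km)\n", sep = "")
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}
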