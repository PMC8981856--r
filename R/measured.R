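#' Colour difference between two L*a*b* colours
#'
#' The default method is the plain Euclidean distance in L*a*b* space,
#' \eqn{\Delta E = \sqrt{(L_2-L_1)^2 + (a_2-a_1)^2 + (b_2-b_1)^2}} (the
#' CIE76 form). `"ciede2000"` computes the CIEDE2000 formula, which weights
#' the lightness, chroma and hue terms perceptually; note CIEDE2000 is not a
#' metric (it can violate the triangle inequality).
#'
#' @param c1,c2 Numeric length-3 vectors `c(L, a, b)`.
#' @param method `"euclidean"` (default) or `"ciede2000"`.
#' @return Non-negative colour difference.
#' @export
#' @examples
#' delta_e(c(50, 10, 10), c(53, 14, 10))  # 5
delta_e <- function(c1, c2, method = c("euclidean", "ciede2000")) {
  method <- match.arg(method)
  stopifnot(length(c1) == 3, length(c2) == 3, is.finite(c1), is.finite(c2))
  if (method == "euclidean") {
    sqrt(sum((c2 - c1)^2))
  } else {
    delta_e_ciede2000(c1, c2)
  }
}

# CIEDE2000 (kL = kC = kH = 1), following the standard published
# formulation with hue arithmetic in degrees.
delta_e_ciede2000 <- function(c1, c2) {
  L1 <- c1[1]; a1 <- c1[2]; b1 <- c1[3]
  L2 <- c2[1]; a2 <- c2[2]; b2 <- c2[3]
  rad <- pi / 180
  Cbar <- (sqrt(a1^2 + b1^2) + sqrt(a2^2 + b2^2)) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  hp <- function(b, ap) {
    if (b == 0 && ap == 0) return(0)
    h <- atan2(b, ap) / rad
    if (h < 0) h + 360 else h
  }
  h1p <- hp(b1, a1p); h2p <- hp(b2, a2p)
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- if (C1p * C2p == 0) 0 else {
    d <- h2p - h1p
    if (abs(d) <= 180) d else if (d > 180) d - 360 else d + 360
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * rad / 2)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hbp <- if (C1p * C2p == 0) h1p + h2p else {
    s <- h1p + h2p
    if (abs(h1p - h2p) <= 180) s / 2 else if (s < 360) (s + 360) / 2 else (s - 360) / 2
  }
  Tt <- 1 - 0.17 * cos((hbp - 30) * rad) + 0.24 * cos(2 * hbp * rad) +
    0.32 * cos((3 * hbp + 6) * rad) - 0.20 * cos((4 * hbp - 63) * rad)
  dTheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dTheta * rad) * RC
  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}

#' Distance in years between two time periods
#'
#' Each period spans integer years `[start, end]` and is summarised by its
#' midpoint \eqn{S + (E - S)/2}; the distance is the floored absolute gap
#' between the two midpoints. Open-ended labels (for instance "before 1700")
#' must already be resolved to explicit bounds in the period lookup table.
#'
#' @param p1,p2 Numeric length-2 vectors `c(start, end)` with
#'   `start <= end`.
#' @return Integer number of years.
#' @export
#' @examples
#' period_distance(c(1840, 1849), c(1850, 1859))  # 10
period_distance <- function(p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2, is.finite(p1), is.finite(p2))
  if (p1[1] > p1[2] || p2[1] > p2[2]) abort("period start must not exceed its end")
  mid <- function(p) p[1] + (p[2] - p[1]) / 2
  unname(floor(abs(mid(p1) - mid(p2))))
}

#' Great-circle distance between two geographic points
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param g1,g2 Numeric length-2 vectors `c(lat, lon)` in degrees.
#' @return Distance in kilometres.
#' @export
#' @examples
#' geo_distance(c(0, 0), c(0, 1))  # ~111.19 km
geo_distance <- function(g1, g2) {
  check_geo(g1); check_geo(g2)
  # geosphere expects (lon, lat) ordering and returns metres
  geosphere::distHaversine(c(g1[2], g1[1]), c(g2[2], g2[1]), r = 6371000) / 1000
}

check_geo <- function(g) {
  stopifnot(length(g) == 2, is.finite(g))
  if (g[1] < -90 || g[1] > 90) abort("latitude must lie in [-90, 90]")
  if (g[2] <= -180 || g[2] > 180) abort("longitude must lie in (-180, 180]")
  invisible(g)
}

#' Location of a composite region
#'
#' A region with no single reference point (for instance a quadrant of a
#' country) is located at the arithmetic mean latitude and mean longitude of
#' its named sub-areas. Longitudes are averaged arithmetically, with no
#' wrap-around handling: composite regions straddling the antimeridian are a
#' documented limitation.
#'
#' @param points Data frame or matrix with columns `lat`, `lon` (one row per
#'   sub-area), or a list of `c(lat, lon)` vectors.
#' @return Numeric `c(lat, lon)`.
#' @export
composite_region_location <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, points)
    colnames(points) <- c("lat", "lon")
  }
  points <- as.data.frame(points)
  if (!nrow(points)) abort("composite region needs at least one sub-area")
  c(lat = mean(points$lat), lon = mean(points$lon))
}

#' Read an offline lookup table
#'
#' Lookup tables replace online ontology services with local CSVs mapping
#' each modality label to a measurable object:
#' \describe{
#'   \item{colour}{header `label,L,a,b` (L*a*b* coordinates)}
#'   \item{geo}{header `label,lat,lon` and optionally `areas`; a row whose
#'     `areas` cell lists semicolon-separated sub-area labels is located at
#'     their mean coordinates via [composite_region_location()]}
#'   \item{period}{header `label,start,end` (integer years)}
#' }
#'
#' @param path CSV path.
#' @param kind `"colour"`, `"geo"` or `"period"`.
#' @return A tibble keyed by `label`; geo composites are already resolved.
#' @export
read_lookup_table <- function(path, kind = c("colour", "geo", "period")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("lookup table not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- switch(kind, colour = c("label", "L", "a", "b"),
                 geo = c("label", "lat", "lon"),
                 period = c("label", "start", "end"))
  if (!all(need %in% names(df))) {
    abort(sprintf("%s table must have header columns %s",
                  kind, paste(need, collapse = ",")))
  }
  if (anyDuplicated(df$label)) abort("duplicated labels in lookup table")
  to_num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(v)
    if (any(bad)) abort(sprintf("malformed numeric '%s' in column '%s'",
                                x[which(bad)[1]], col))
    v
  }
  if (kind == "colour") {
    out <- tibble(label = df$label, L = to_num(df$L, "L"),
                  a = to_num(df$a, "a"), b = to_num(df$b, "b"))
    if (anyNA(out[-1])) abort("colour table has missing coordinates")
    return(out)
  }
  if (kind == "period") {
    out <- tibble(label = df$label, start = to_num(df$start, "start"),
                  end = to_num(df$end, "end"))
    if (anyNA(out[-1])) abort("period table has missing bounds")
    if (any(out$start > out$end)) abort("period start must not exceed its end")
    return(out)
  }
  # geo: resolve composite rows against plain rows
  lat <- to_num(df$lat, "lat"); lon <- to_num(df$lon, "lon")
  areas <- if ("areas" %in% names(df)) df$areas else rep(NA_character_, nrow(df))
  plain <- !is.na(lat) & !is.na(lon)
  out <- tibble(label = df$label, lat = lat, lon = lon)
  for (i in which(!plain)) {
    if (is.na(areas[i]) || !nzchar(areas[i])) {
      abort(sprintf("geo row '%s' has neither coordinates nor sub-areas", df$label[i]))
    }
    subs <- trimws(strsplit(areas[i], ";")[[1]])
    idx <- match(subs, out$label[plain])
    if (anyNA(idx)) {
      abort(sprintf("unresolvable sub-area '%s' for composite region '%s'",
                    subs[which(is.na(idx))[1]], df$label[i]))
    }
    loc <- composite_region_location(out[plain, ][idx, c("lat", "lon")])
    out$lat[i] <- loc[["lat"]]; out$lon[i] <- loc[["lon"]]
  }
  for (i in seq_len(nrow(out))) check_geo(c(out$lat[i], out$lon[i]))
  out
}
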