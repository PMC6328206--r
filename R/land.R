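#' Test whether points lie strictly inside land
#'
#' Even-odd point-in-polygon test against every polygon of the landmask;
#' points on a polygon boundary count as ocean.
#'
#' @param point numeric length-2 vector (lon, lat) or an n x 2 matrix.
#' @param landmask a `landmask` object ([make_synthetic_coastline()] or
#'   [read_landmask()]).
#' @return logical (vector): `TRUE` where the point is on land.
#' @export
is_on_land <- function(point, landmask) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 2)
  stopifnot(ncol(point) == 2, inherits(landmask, "landmask"))
  land <- rep(FALSE, nrow(point))
  for (poly in landmask) {
    ro <- poly$outer
    if (nrow(ro) < 4) stop("invalid geometry: ring with fewer than 3 vertices")
    inside <- pracma::inpolygon(point[, 1], point[, 2], ro[, 1], ro[, 2],
                                boundary = FALSE)
    for (hole in poly$holes) {
      in_hole <- pracma::inpolygon(point[, 1], point[, 2], hole[, 1], hole[, 2],
                                   boundary = TRUE)
      inside <- inside & !in_hole
    }
    land <- land | inside
  }
  land
}

#' Polygonal approximation of a credible ellipse
#'
#' Axis-aligned ellipse in degree space: the longitude semi-axis is the 95%
#' credible half-width in longitude, the latitude semi-axis the half-width in
#' latitude.
#'
#' @param center numeric length 2 (lon, lat).
#' @param a semi-axis along longitude (degrees), > 0.
#' @param b semi-axis along latitude (degrees), > 0.
#' @param n_vertices number of polygon vertices.
#' @return closed (n+1) x 2 matrix of lon/lat vertices.
#' @export
ellipse_polygon <- function(center, a, b, n_vertices = 720) {
  if (a <= 0 || b <= 0) stop("ellipse semi-axes must be positive")
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)
  cbind(center[1] + a * cos(ang), center[2] + b * sin(ang))
}

# planar projection about a reference point: lon scaled by cos(lat0)
to_planar <- function(xy, center) {
  f <- cos(center[2] * pi / 180)
  cbind((xy[, 1] - center[1]) * f, xy[, 2] - center[2])
}
from_planar <- function(xy, center) {
  f <- cos(center[2] * pi / 180)
  c(center[1] + xy[1] / f, center[2] + xy[2])
}

# union of land x-intervals cut by the horizontal line at y (planar coords);
# rings of one polygon combine even-odd, polygons union
land_intervals_at <- function(y, polys_planar) {
  out <- NULL
  for (rings in polys_planar) {
    xs <- numeric(0)
    for (r in rings) {
      y1 <- r[-nrow(r), 2]; y2 <- r[-1, 2]
      x1 <- r[-nrow(r), 1]; x2 <- r[-1, 1]
      cross <- (y1 <= y) != (y2 <= y)
      if (any(cross))
        xs <- c(xs, x1[cross] + (y - y1[cross]) * (x2[cross] - x1[cross]) /
                  (y2[cross] - y1[cross]))
    }
    if (length(xs) >= 2) {
      xs <- sort(xs)
      out <- rbind(out, matrix(xs[seq_len(2 * floor(length(xs) / 2))],
                               ncol = 2, byrow = TRUE))
    }
  }
  if (is.null(out) || nrow(out) == 0) return(matrix(numeric(0), ncol = 2))
  out <- out[order(out[, 1]), , drop = FALSE]
  merged <- out[1, , drop = FALSE]
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      if (out[i, 1] <= merged[nrow(merged), 2]) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], out[i, 2])
      } else {
        merged <- rbind(merged, out[i, ])
      }
    }
  }
  merged
}

# subtract land intervals from [-w, w]; returns matrix of ocean intervals
ocean_intervals <- function(w, land) {
  if (nrow(land) == 0) return(matrix(c(-w, w), ncol = 2))
  res <- NULL
  cur <- -w
  for (i in seq_len(nrow(land))) {
    lo <- max(land[i, 1], -w); hi <- min(land[i, 2], w)
    if (hi <= cur) next
    if (lo > cur) res <- rbind(res, c(cur, min(lo, w)))
    cur <- max(cur, hi)
    if (cur >= w) break
  }
  if (cur < w) res <- rbind(res, c(cur, w))
  if (is.null(res)) matrix(numeric(0), ncol = 2) else res
}

# slab integration of the ocean part of an axis-aligned ellipse (planar);
# returns area, centroid and the per-slab ocean intervals
ellipse_ocean_integrate <- function(ap, bp, polys_planar, n_slabs) {
  h <- 2 * bp / n_slabs
  ys <- -bp + (seq_len(n_slabs) - 0.5) * h
  area <- 0; sx <- 0; sy <- 0
  slabs <- vector("list", n_slabs)
  for (i in seq_along(ys)) {
    y <- ys[i]
    w <- ap * sqrt(max(0, 1 - (y / bp)^2))
    if (w <= 0) { slabs[[i]] <- matrix(numeric(0), ncol = 2); next }
    oc <- ocean_intervals(w, land_intervals_at(y, polys_planar))
    slabs[[i]] <- oc
    if (nrow(oc) > 0) {
      len <- oc[, 2] - oc[, 1]
      mid <- (oc[, 1] + oc[, 2]) / 2
      area <- area + sum(len) * h
      sx <- sx + sum(mid * len) * h
      sy <- sy + y * sum(len) * h
    }
  }
  list(area = area, cx = if (area > 0) sx / area else NA_real_,
       cy = if (area > 0) sy / area else NA_real_,
       ys = ys, slabs = slabs)
}

nearest_in_slabs <- function(intg, target) {
  # nearest point of the ocean remainder to a planar target point
  best <- NULL; bd <- Inf
  for (i in seq_along(intg$ys)) {
    oc <- intg$slabs[[i]]
    if (nrow(oc) == 0) next
    for (k in seq_len(nrow(oc))) {
      px <- min(max(target[1], oc[k, 1]), oc[k, 2])
      d2 <- (px - target[1])^2 + (intg$ys[i] - target[2])^2
      if (d2 < bd) { bd <- d2; best <- c(px, intg$ys[i]) }
    }
  }
  best
}

#' Centroid of the ocean portion of a credible ellipse
#'
#' Implements the land-correction geometry: the axis-aligned 95% credible
#' ellipse around a daily estimate is clipped against the landmask and the
#' area centroid of the remaining ocean region is returned. Geometry is
#' computed in a local planar projection about the ellipse centre (longitude
#' scaled by cos(latitude)) using slab integration with an exact ellipse
#' width per slab. If the whole ellipse is on land, both axes are inflated by
#' `inflate` up to `max_inflate` times; if still empty, the nearest ocean
#' point to the centre (expanding radial search) is returned. If the
#' computed centroid itself falls on land (possible for crescent-shaped
#' remainders) it is replaced by the nearest point of the ocean remainder.
#'
#' @param center numeric length 2 (lon, lat), the daily estimate.
#' @param a,b ellipse semi-axes: 95% credible half-widths in longitude and
#'   latitude (degrees).
#' @param landmask a `landmask` object.
#' @param n_slabs number of integration slabs.
#' @param inflate axis inflation factor of the empty-ocean fallback.
#' @param max_inflate maximum number of inflations.
#' @param max_search_deg radius limit (planar degrees) of the last-resort
#'   nearest-ocean search.
#' @return numeric length 2: corrected (lon, lat), never on land.
#' @export
ocean_centroid <- function(center, a, b, landmask, n_slabs = 720,
                           inflate = 1.5, max_inflate = 3,
                           max_search_deg = 10) {
  if (a <= 0 || b <= 0) stop("ellipse semi-axes must be positive")
  stopifnot(inherits(landmask, "landmask"))
  f <- cos(center[2] * pi / 180)
  polys_planar <- lapply(landmask, function(p) {
    lapply(c(list(p$outer), p$holes), to_planar, center = center)
  })
  for (attempt in 0:max_inflate) {
    ap <- a * f * inflate^attempt
    bp <- b * inflate^attempt
    intg <- ellipse_ocean_integrate(ap, bp, polys_planar, n_slabs)
    if (is.finite(intg$area) && intg$area > 1e-12 * pi * ap * bp) {
      pt <- c(intg$cx, intg$cy)
      ll <- from_planar(pt, center)
      if (is_on_land(ll, landmask)) {
        pt <- nearest_in_slabs(intg, pt)
        ll <- from_planar(pt, center)
      }
      return(ll)
    }
  }
  # last resort: expanding radial search for the nearest ocean point
  ang <- seq(0, 2 * pi, length.out = 361)[-361]
  radii <- seq(max(a * f, b) * 0.5, max_search_deg, length.out = 200)
  for (r in radii) {
    cand_pl <- cbind(r * cos(ang), r * sin(ang))
    cand <- cbind(center[1] + cand_pl[, 1] / f, center[2] + cand_pl[, 2])
    ok <- !is_on_land(cand, landmask)
    if (any(ok)) return(cand[which(ok)[1], ])
  }
  stop("ocean_centroid: no ocean found within ", max_search_deg,
       " degrees of (", center[1], ", ", center[2], ")")
}

#' Relocate on-land daily estimates to ocean
#'
#' Applies [ocean_centroid()] to every day of a fitted track whose posterior
#' mean position lies on land. Only on-land days are modified; dates and the
#' behavioural mode mean `b_mean` are untouched. The output keeps the
#' pre-correction coordinates and a per-day `corrected` flag. Correcting an
#' already-corrected track changes nothing.
#'
#' @param track a `posterior_track` data frame (needs `lon`, `lat`,
#'   `lon_hw95`, `lat_hw95`).
#' @param landmask a `landmask` object.
#' @param min_axis floor (degrees) applied to degenerate credible half-widths
#'   so the ellipse is always two-dimensional.
#' @param ... passed to [ocean_centroid()].
#' @return the track with corrected coordinates plus columns `corrected`,
#'   `lon_pre`, `lat_pre`.
#' @export
correct_track <- function(track, landmask, min_axis = 0.01, ...) {
  stopifnot(all(c("lon", "lat", "lon_hw95", "lat_hw95") %in% names(track)))
  on_land <- is_on_land(cbind(track$lon, track$lat), landmask)
  out <- track
  if (is.null(track$corrected)) {
    out$corrected <- on_land
    out$lon_pre <- track$lon
    out$lat_pre <- track$lat
  } else {
    out$corrected <- track$corrected | on_land
  }
  for (i in which(on_land)) {
    p <- ocean_centroid(c(track$lon[i], track$lat[i]),
                        a = max(track$lon_hw95[i], min_axis),
                        b = max(track$lat_hw95[i], min_axis),
                        landmask, ...)
    out$lon[i] <- p[1]
    out$lat[i] <- p[2]
  }
  out
}
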