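# Surface dose extraction and developable unfolding.
#
# The 3D contact surface is sampled per CT slice (z index). Within a slice
# the contour is an ordered chain of grid-adjacent voxel centres; the chain
# anchor is one end of the contour (lateral edge by default). Unfolding maps
# each point to 2D coordinates (u, v):
#   u = cumulative 3D arc length along the slice chain from the anchor,
#   v = cumulative 3D distance along the anchor polyline across slices,
#       starting at the most superior slice (v grows toward inferior).
# For developable surfaces (plane, cylinder sector, tilted cradle plane)
# this preserves all consecutive-point distances exactly.

#' Extract and order surface dose samples
#'
#' Samples the dose grid at each surface voxel centre (trilinear, exact for
#' linear fields) and establishes a per-slice contour ordering by greedy
#' nearest-neighbour chaining from a configurable anchor.
#'
#' @param dose a [dose_grid()]; must cover every surface voxel.
#' @param surface the surface-voxel contour, a [structure_mask()].
#' @param anchor which contour end starts each chain: `"min_x"` (lateral
#'   edge, default), `"max_x"`, `"min_y"` or `"max_y"`.
#' @return A `surface_sample`: data.frame with columns `slice`, `ord`,
#'   `x`, `y`, `z` (cm) and `dose` (percent of prescription), ordered by
#'   slice then chain position; attributes carry the lattice diagonal and
#'   prescription.
#' @export
extract_surface_dose <- function(dose, surface,
                                 anchor = c("min_x", "max_x",
                                            "min_y", "max_y")) {
  stopifnot(inherits(dose, "dose_grid"), inherits(surface, "structure_mask"))
  anchor <- match.arg(anchor)
  idx <- which(surface$mask)
  if (length(idx) == 0) stop("empty surface mask")
  d <- dim(surface$mask)
  pts <- voxel_centres(idx, d, surface$spacing, surface$origin)
  dd <- trilinear_sample(dose$dose, dose$spacing, dose$origin, pts,
                         outside = "error")
  pct <- 100 * dd / dose$prescription
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L # z slice index
  diag_len <- sqrt(sum(surface$spacing^2))
  out <- vector("list", length(unique(k)))
  slices <- sort(unique(k))
  for (si in seq_along(slices)) {
    sel <- which(k == slices[si])
    p <- pts[sel, , drop = FALSE]
    ord <- chain_order(p, anchor, diag_len)
    out[[si]] <- data.frame(slice = slices[si], ord = seq_along(ord),
                            x = p[ord, 1], y = p[ord, 2], z = p[ord, 3],
                            dose = pct[sel][ord])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "diag") <- diag_len
  attr(res, "prescription") <- dose$prescription
  class(res) <- c("surface_sample", "data.frame")
  res
}

# Greedy nearest-neighbour chain through in-slice points starting at the
# anchor end; errors on gaps larger than one voxel diagonal.
chain_order <- function(p, anchor, diag_len) {
  n <- nrow(p)
  if (n == 1) return(1L)
  start <- switch(anchor,
                  min_x = which.min(p[, 1] + 1e-6 * p[, 2]),
                  max_x = which.max(p[, 1] - 1e-6 * p[, 2]),
                  min_y = which.min(p[, 2] + 1e-6 * p[, 1]),
                  max_y = which.max(p[, 2] - 1e-6 * p[, 1]))
  ord <- integer(n)
  used <- logical(n)
  ord[1] <- start
  used[start] <- TRUE
  for (i in seq_len(n - 1)) {
    cur <- p[ord[i], ]
    cand <- which(!used)
    d2 <- (p[cand, 1] - cur[1])^2 + (p[cand, 2] - cur[2])^2 +
      (p[cand, 3] - cur[3])^2
    nxt <- cand[which.min(d2)]
    if (sqrt(min(d2)) > diag_len * 1.001)
      stop("non-contiguous surface contour: gap of ",
           signif(sqrt(min(d2)), 4), " cm exceeds the voxel diagonal")
    ord[i + 1] <- nxt
    used[nxt] <- TRUE
  }
  ord
}

#' Unfold an ordered surface sample into the plane
#'
#' Maps each surface point to 2D coordinates preserving consecutive
#' point-to-point 3D vector magnitudes: along-contour positions are
#' cumulative arc lengths from the slice anchor, across-slice positions are
#' cumulative anchor-to-anchor distances starting from the most superior
#' slice. Dose values are carried unchanged. Non-developable input is not
#' rejected: a distortion summary (discrepancy between 2D and 3D distances
#' of across-slice neighbours beyond the anchors) is attached instead.
#'
#' @param sample a `surface_sample` from [extract_surface_dose()].
#' @param flip_u reverse the along-contour direction (left-right flip of the
#'   resulting maps, for matching a film scanning convention).
#' @return An `unfolded_surface`: list with `points` (data.frame `u`, `v`,
#'   `dose`, `slice`, `ord`, `x`, `y`, `z`), `slice_v` (anchor positions),
#'   and `distortion` (mean/max across-slice metric discrepancy in cm).
#' @export
unfold_surface <- function(sample, flip_u = FALSE) {
  stopifnot(inherits(sample, "surface_sample"))
  sl <- split(sample, sample$slice)
  # superior (largest z anchor) first; v grows toward the inferior end
  anchors <- t(vapply(sl, function(s) c(s$x[1], s$y[1], s$z[1]),
                      numeric(3)))
  ord_sl <- order(anchors[, 3], decreasing = TRUE)
  sl <- sl[ord_sl]
  anchors <- anchors[ord_sl, , drop = FALSE]
  nv <- length(sl)
  v <- c(0, cumsum(unname(sqrt(rowSums(
    (anchors[-1, , drop = FALSE] - anchors[-nv, , drop = FALSE])^2)))))
  pts <- vector("list", nv)
  diag_len <- attr(sample, "diag")
  for (i in seq_len(nv)) {
    s <- sl[[i]]
    seg <- sqrt(diff(s$x)^2 + diff(s$y)^2 + diff(s$z)^2)
    if (!is.null(diag_len) && length(seg) &&
        max(seg) > diag_len * 1.001)
      stop("non-contiguous surface contour in slice ", s$slice[1],
           ": gap of ", signif(max(seg), 4), " cm exceeds the voxel ",
           "diagonal")
    u <- c(0, cumsum(seg))
    if (flip_u) u <- max(u) - u
    pts[[i]] <- data.frame(u = u, v = v[i], dose = s$dose,
                           slice = s$slice, ord = s$ord,
                           x = s$x, y = s$y, z = s$z)
  }
  points <- do.call(rbind, pts)
  rownames(points) <- NULL
  # distortion: compare 2D vs 3D distance between same-rank points of
  # neighbouring slices (exact zero on developable surfaces)
  disc <- numeric(0)
  for (i in seq_len(nv - 1)) {
    a <- pts[[i]]; b <- pts[[i + 1]]
    m <- min(nrow(a), nrow(b))
    if (m < 1) next
    d3 <- sqrt((a$x[1:m] - b$x[1:m])^2 + (a$y[1:m] - b$y[1:m])^2 +
                 (a$z[1:m] - b$z[1:m])^2)
    d2 <- sqrt((a$u[1:m] - b$u[1:m])^2 + (a$v[1:m] - b$v[1:m])^2)
    disc <- c(disc, abs(d2 - d3))
  }
  structure(list(points = points, slice_v = v,
                 distortion = list(mean = if (length(disc)) mean(disc) else 0,
                                   max = if (length(disc)) max(disc) else 0)),
            class = "unfolded_surface")
}

#' Rasterize an unfolded surface onto the film lattice
#'
#' Linear interpolation of the sparse unfolded samples onto a regular grid
#' at film resolution: first along the contour within each slice, then
#' across slices at each raster column. Exact for fields linear in (u, v).
#' Pixels outside the sampled region of support are invalidated.
#'
#' @param unfolded an `unfolded_surface` from [unfold_surface()].
#' @param target_spacing raster pitch in cm; default 2.54/72 (72 DPI film).
#' @param prescription carried through for provenance only.
#' @return A [film_dose_map()]; row 1 is the superior edge. The unfolded
#'   source points are attached as attribute `"source_points"` so each
#'   pixel's 3D provenance can be recovered with [map_provenance()].
#' @export
rasterize_to_film_grid <- function(unfolded, target_spacing = 2.54 / 72,
                                   prescription = NULL) {
  stopifnot(inherits(unfolded, "unfolded_surface"))
  p <- unfolded$points
  v_sl <- unfolded$slice_v
  if (length(v_sl) < 2 || diff(range(p$u)) <= 0)
    stop("degenerate unfolded point set: spans no area")
  ug <- seq(0, max(p$u), by = target_spacing)
  vg <- seq(0, max(v_sl), by = target_spacing)
  sl <- split(p, p$slice)
  # order slices by their v coordinate
  sl_v <- vapply(sl, function(s) s$v[1], numeric(1))
  o <- order(sl_v)
  sl <- sl[o]; sl_v <- sl_v[o]
  rows <- matrix(NA_real_, length(sl), length(ug))
  for (i in seq_along(sl)) {
    s <- sl[[i]]
    if (nrow(s) >= 2) {
      rows[i, ] <- approx(s$u, s$dose, xout = ug, rule = 1,
                          ties = "ordered")$y
    } else {
      hit <- abs(ug - s$u[1]) <= target_spacing / 2
      rows[i, hit] <- s$dose[1]
    }
  }
  dose <- matrix(NA_real_, length(vg), length(ug))
  for (j in seq_along(ug)) {
    col <- rows[, j]
    ok <- !is.na(col)
    if (sum(ok) >= 2) {
      dose[, j] <- approx(sl_v[ok], col[ok], xout = vg, rule = 1,
                          ties = "ordered")$y
    } else if (sum(ok) == 1) {
      hit <- abs(vg - sl_v[ok]) <= target_spacing / 2
      dose[hit, j] <- col[ok]
    }
  }
  map <- film_dose_map(dose, target_spacing, provenance = "unfolded_tps")
  attr(map, "source_points") <- p
  attr(map, "slice_v") <- sl_v
  map
}

#' Recover the 3D source point of raster pixels
#'
#' Uses the provenance attached by [rasterize_to_film_grid()]: for each
#' queried pixel, the nearest slice by the across-slice coordinate, then the
#' nearest sample along the contour.
#'
#' @param map a raster produced by [rasterize_to_film_grid()].
#' @param rows,cols pixel indices (vectors of equal length).
#' @return data.frame with the pixel indices and source `x`, `y`, `z`.
#' @export
map_provenance <- function(map, rows, cols) {
  p <- attr(map, "source_points")
  if (is.null(p)) stop("map carries no source provenance")
  stopifnot(length(rows) == length(cols))
  s <- map$pixel_spacing
  vq <- (rows - 1) * s
  uq <- (cols - 1) * s
  sl <- split(p, p$slice)
  sl_v <- vapply(sl, function(x) x$v[1], numeric(1))
  o <- order(sl_v)
  sl <- sl[o]; sl_v <- sl_v[o]
  out <- data.frame(row = rows, col = cols, x = NA_real_, y = NA_real_,
                    z = NA_real_)
  for (i in seq_along(rows)) {
    si <- which.min(abs(sl_v - vq[i]))
    s_i <- sl[[si]]
    pi <- which.min(abs(s_i$u - uq[i]))
    out$x[i] <- s_i$x[pi]; out$y[i] <- s_i$y[pi]; out$z[i] <- s_i$z[pi]
  }
  out
}

#' Segment a film-resolution map into lateral and inferior regions
#'
#' Rows whose across-slice coordinate lies in the upper `lateral_extent` cm
#' are lateral; the remainder are inferior. The boundary row belongs to the
#' lateral band.
#'
#' @param map a [film_dose_map()].
#' @param lateral_extent,inferior_extent segment lengths in cm.
#' @return character matrix (same shape as the map) with entries
#'   `"lateral"` / `"inferior"`.
#' @export
segment_lat_inf <- function(map, lateral_extent = 11, inferior_extent = 14) {
  stopifnot(inherits(map, "film_dose_map"))
  nr <- nrow(map$dose)
  height <- (nr - 1) * map$pixel_spacing
  if (height < lateral_extent)
    stop("map height (", signif(height, 4),
         " cm) is shorter than the lateral extent")
  v <- (seq_len(nr) - 1) * map$pixel_spacing
  lab <- if (lateral_extent > 0) {
    ifelse(v <= lateral_extent + 1e-9, "lateral", "inferior")
  } else rep("inferior", nr)
  matrix(lab, nr, ncol(map$dose))
}
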