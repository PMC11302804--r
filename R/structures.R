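# TPS structure generation: HU thresholding, contour expansion, the
# body-cradle contact surface, and interior skin rinds.

#' Threshold a CT grid into a structure mask
#'
#' Voxels with `hu_lo <= HU <= hu_hi` (inclusive at both ends, for
#' deterministic behaviour at band edges). Optionally keep only the largest
#' 26-connected component, as one would when segmenting the patient body
#' out of a couch/cradle scene.
#'
#' @param ct a [voxel_grid()] of HU values.
#' @param hu_lo,hu_hi band limits in HU, `hu_lo <= hu_hi`.
#' @param keep_largest keep only the largest connected component.
#' @param label label for the resulting mask.
#' @return A [structure_mask()].
#' @export
threshold_structure <- function(ct, hu_lo, hu_hi, keep_largest = FALSE,
                                label = "threshold") {
  stopifnot(inherits(ct, "voxel_grid"))
  if (hu_lo > hu_hi) stop("hu_lo must be <= hu_hi")
  m <- ct$values >= hu_lo & ct$values <= hu_hi
  if (keep_largest) {
    if (!any(m)) stop("empty threshold result; no component to keep")
    m <- array(.largest_component_cpp(m, dim(m)), dim(m))
  }
  structure_mask(m, ct$spacing, ct$origin, label)
}

#' Expand a contour outward by a physical distance
#'
#' All voxels whose centre lies within `distance` cm (Euclidean, honouring
#' anisotropic spacing) of a voxel centre of the input mask. Used for the
#' 2.0 cm extended body contour that helps surface dose calculation.
#'
#' @param mask a [structure_mask()].
#' @param distance expansion distance in cm (>= 0); 0 is the identity.
#' @return A [structure_mask()].
#' @export
expand_contour <- function(mask, distance) {
  stopifnot(inherits(mask, "structure_mask"))
  if (distance < 0) stop("distance must be >= 0")
  if (distance == 0) return(mask)
  d <- edt_distance(mask$mask, mask$spacing)
  structure_mask(d <= distance + 1e-9, mask$spacing, mask$origin,
                 paste0(mask$label, "+", distance, "cm"))
}

#' Body-cradle contact surface contour
#'
#' The single layer of body voxels in contact with the cradle: body voxels
#' face-adjacent (6-connectivity by default) to a cradle voxel. Because body
#' and cradle masks are disjoint, a literal voxelwise AND would be empty;
#' the adjacency construction realises the intended "region of the breast in
#' contact with the cradle". Face adjacency keeps the contour one voxel
#' thick along the local surface normal; 26-connectivity is available for
#' masks that only touch diagonally.
#'
#' @param body,cradle [structure_mask()]s on the same lattice.
#' @param connectivity 6 (faces) or 26 (faces, edges and corners).
#' @return A [structure_mask()] labelled `"contact_surface"`.
#' @export
contact_surface <- function(body, cradle, connectivity = 6) {
  stopifnot(inherits(body, "structure_mask"),
            inherits(cradle, "structure_mask"))
  if (!all(dim(body$mask) == dim(cradle$mask)))
    stop("body and cradle masks must share a lattice")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  dil <- dilate_mask(cradle$mask, connectivity)
  m <- body$mask & dil
  if (!any(m))
    stop("empty contact surface: body and cradle are not adjacent ",
         "(no film region)")
  structure_mask(m, body$spacing, body$origin, "contact_surface")
}

# binary dilation by one voxel with 6- or 26-connectivity
dilate_mask <- function(m, connectivity = 6) {
  d <- dim(m)
  out <- m
  shifts <- if (connectivity == 6) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
         c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
    g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
    lapply(seq_len(nrow(g)), function(r) as.numeric(g[r, ]))
  }
  for (s in shifts) out <- out | shift_array(m, s)
  out
}

# shift a 3D logical array by integer offsets, padding with FALSE
shift_array <- function(m, s) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (s[a] >= 0) {
      dst[[a]] <- seq_len(d[a] - s[a]) + s[a]
      src[[a]] <- seq_len(d[a] - s[a])
    } else {
      dst[[a]] <- seq_len(d[a] + s[a])
      src[[a]] <- seq_len(d[a] + s[a]) - s[a]
    }
    if (length(dst[[a]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Interior skin rind from a surface contour
#'
#' Body voxels whose centre lies within `thickness` cm (anisotropic
#' Euclidean distance) of the surface-voxel contour, unioned with the
#' surface layer itself. Built on the distance transform rather than
#' morphological erosion because slice spacing is typically coarser than
#' in-plane spacing. With `thickness = 0` the rind is the surface layer.
#'
#' @param surface the surface-voxel contour, a subset of `body`.
#' @param body the body [structure_mask()].
#' @param thickness rind thickness in cm (>= 0).
#' @return A [structure_mask()].
#' @export
make_rind <- function(surface, body, thickness) {
  stopifnot(inherits(surface, "structure_mask"),
            inherits(body, "structure_mask"))
  if (!all(dim(surface$mask) == dim(body$mask)))
    stop("surface and body masks must share a lattice")
  if (any(surface$mask & !body$mask))
    stop("surface must be a subset of body")
  if (thickness < 0) stop("thickness must be >= 0")
  m <- surface$mask
  if (thickness > 0) {
    d <- edt_distance(surface$mask, surface$spacing)
    m <- m | (body$mask & d <= thickness + 1e-9)
  }
  structure_mask(m, body$spacing, body$origin,
                 sprintf("rind_%.1fcm", thickness))
}

#' Restrict a rind to the contact-region footprint
#'
#' Keeps only voxels whose projection onto the cradle plane falls in a bin
#' occupied by the surface contour, preventing a rind from spilling
#' sideways past the edge of the contact region.
#'
#' @param rind,surface [structure_mask()]s on the same lattice.
#' @param spec the [phantom_spec()] supplying the plane orientation.
#' @return A [structure_mask()].
#' @export
restrict_to_footprint <- function(rind, surface, spec) {
  stopifnot(inherits(rind, "structure_mask"),
            inherits(surface, "structure_mask"))
  d <- dim(rind$mask)
  bin <- c(rind$spacing[1], max(rind$spacing))
  proj_bins <- function(mask) {
    idx <- which(mask)
    pts <- voxel_centres(idx, d, rind$spacing, rind$origin)
    pc <- plane_coords(spec, pts)
    paste(round(pc$x / bin[1]), round(pc$w / bin[2]))
  }
  surf_bins <- unique(proj_bins(surface$mask))
  idx <- which(rind$mask)
  keep <- proj_bins(rind$mask) %in% surf_bins
  m <- array(FALSE, d)
  m[idx[keep]] <- TRUE
  m <- m | surface$mask
  structure_mask(m, rind$spacing, rind$origin, rind$label)
}
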