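# Shared containers and low-level numerics.
#
# Conventions used throughout:
#  * 3D arrays are indexed [x, y, z] with x = right-left, y = vertical
#    (posterior cradle below, anterior tissue above), z = superior-inferior.
#    Voxel-centre convention: the centre of voxel (i, j, k) (1-based) sits at
#    origin + (c(i, j, k) - 1) * spacing.
#  * 2D film-resolution maps are matrices indexed [row, col]; row 1 is the
#    superior edge, the across-slice coordinate v grows downward (inferior),
#    the along-contour coordinate u grows with the column index.

#' Construct a voxel grid
#'
#' A scalar field on a regular anisotropic voxel lattice (e.g. a CT volume in
#' Hounsfield units).
#'
#' @param values 3D numeric array, indexed `[x, y, z]`.
#' @param spacing numeric length-3, voxel spacing in cm (dx, dy, dz).
#' @param origin numeric length-3, physical position (cm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3, length(spacing) == 3,
            length(origin) == 3)
  if (any(spacing <= 0)) stop("voxel spacing components must be > 0")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " cm\n", sep = "")
  invisible(x)
}

#' Construct a structure mask
#'
#' Binary voxel mask aligned to a grid (body, cradle, surface contour, rind).
#'
#' @param mask 3D logical array.
#' @param spacing,origin lattice geometry, as in [voxel_grid()].
#' @param label character label for reporting.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(mask, spacing, origin = c(0, 0, 0),
                           label = "structure") {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  if (any(spacing <= 0)) stop("voxel spacing components must be > 0")
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), label = label),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat("<structure_mask> '", x$label, "': ", sum(x$mask), " of ",
      length(x$mask), " voxels\n", sep = "")
  invisible(x)
}

#' Construct a dose grid
#'
#' 3D absorbed dose (Gy) on a voxel lattice, with the prescription dose
#' carried as metadata so doses can be expressed as percent of prescription.
#'
#' @param dose 3D numeric array of dose in Gy (non-negative).
#' @param spacing,origin lattice geometry, as in [voxel_grid()].
#' @param prescription prescription dose in Gy (> 0).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(dose, spacing, origin = c(0, 0, 0), prescription) {
  stopifnot(length(dim(dose)) == 3)
  if (any(spacing <= 0)) stop("voxel spacing components must be > 0")
  if (prescription <= 0) stop("prescription must be > 0")
  if (any(dose < 0)) stop("dose must be non-negative")
  structure(list(dose = dose, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 prescription = as.numeric(prescription)),
            class = "dose_grid")
}

#' Construct a 2D film-resolution dose map
#'
#' Shared container for measured film dose and unfolded TPS dose: a 2D dose
#' image in percent of the prescription dose, with a validity mask.
#'
#' @param dose numeric matrix, percent of prescription. Entries outside
#'   `valid` may be `NA`.
#' @param pixel_spacing pixel pitch in cm (2.54/dpi for scanned film).
#' @param valid logical matrix, same shape as `dose`.
#' @param provenance short label recording where the map came from.
#' @return An object of class `film_dose_map`.
#' @export
film_dose_map <- function(dose, pixel_spacing, valid = NULL,
                          provenance = "unknown") {
  stopifnot(is.matrix(dose))
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  if (is.null(valid)) valid <- !is.na(dose)
  stopifnot(is.logical(valid), all(dim(valid) == dim(dose)))
  if (any(is.na(dose[valid])))
    stop("dose must be defined wherever valid_mask is TRUE")
  structure(list(dose = dose, pixel_spacing = as.numeric(pixel_spacing),
                 valid = valid, provenance = provenance),
            class = "film_dose_map")
}

#' @export
print.film_dose_map <- function(x, ...) {
  cat("<film_dose_map> ", nrow(x$dose), " x ", ncol(x$dose), " px @ ",
      signif(x$pixel_spacing, 4), " cm, ", sum(x$valid), " valid [",
      x$provenance, "]\n", sep = "")
  invisible(x)
}

# physical voxel-centre coordinates along each axis
grid_axis <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

# voxel-centre coordinates (n x 3 matrix) for linear indices of a 3D array
voxel_centres <- function(idx, dim, spacing, origin) {
  idx <- idx - 1L
  i <- idx %% dim[1]
  j <- (idx %/% dim[1]) %% dim[2]
  k <- idx %/% (dim[1] * dim[2])
  cbind(origin[1] + i * spacing[1],
        origin[2] + j * spacing[2],
        origin[3] + k * spacing[3])
}

#' Trilinear interpolation of a 3D grid at arbitrary points
#'
#' Exact for fields linear in the coordinates; used to sample dose grids at
#' structure voxel centres when the dose and CT lattices differ.
#'
#' @param values 3D numeric array.
#' @param spacing,origin lattice geometry.
#' @param pts n x 3 matrix of physical coordinates (cm).
#' @param outside `"error"` to fail on points outside the grid extent,
#'   `"na"` to return `NA` there.
#' @return numeric vector of length `nrow(pts)`.
#' @export
trilinear_sample <- function(values, spacing, origin, pts,
                             outside = c("error", "na")) {
  outside <- match.arg(outside)
  d <- dim(values)
  g <- sweep(sweep(pts, 2, origin), 2, spacing, "/") + 1 # fractional index
  out_of_range <- g[, 1] < 1 - 1e-9 | g[, 1] > d[1] + 1e-9 |
    g[, 2] < 1 - 1e-9 | g[, 2] > d[2] + 1e-9 |
    g[, 3] < 1 - 1e-9 | g[, 3] > d[3] + 1e-9
  if (any(out_of_range)) {
    if (outside == "error")
      stop("sample point outside grid extent")
  }
  gi <- pmin(pmax(g[, 1], 1), d[1])
  gj <- pmin(pmax(g[, 2], 1), d[2])
  gk <- pmin(pmax(g[, 3], 1), d[3])
  i0 <- pmin(floor(gi), d[1] - 1); fi <- gi - i0
  j0 <- pmin(floor(gj), d[2] - 1); fj <- gj - j0
  k0 <- pmin(floor(gk), d[3] - 1); fk <- gk - k0
  if (d[1] == 1) { i0 <- rep(1, length(gi)); fi <- rep(0, length(gi)) }
  if (d[2] == 1) { j0 <- rep(1, length(gj)); fj <- rep(0, length(gj)) }
  if (d[3] == 1) { k0 <- rep(1, length(gk)); fk <- rep(0, length(gk)) }
  at <- function(di, dj, dk) {
    ii <- pmin(i0 + di, d[1]); jj <- pmin(j0 + dj, d[2])
    kk <- pmin(k0 + dk, d[3])
    values[cbind(ii, jj, kk)]
  }
  v <- at(0, 0, 0) * (1 - fi) * (1 - fj) * (1 - fk) +
    at(1, 0, 0) * fi * (1 - fj) * (1 - fk) +
    at(0, 1, 0) * (1 - fi) * fj * (1 - fk) +
    at(0, 0, 1) * (1 - fi) * (1 - fj) * fk +
    at(1, 1, 0) * fi * fj * (1 - fk) +
    at(1, 0, 1) * fi * (1 - fj) * fk +
    at(0, 1, 1) * (1 - fi) * fj * fk +
    at(1, 1, 1) * fi * fj * fk
  if (outside == "na") v[out_of_range] <- NA_real_
  v
}

# Bilinear interpolation of a matrix at fractional (row, col) indices
# (1-based). Out-of-extent queries return NA. `valid` (optional) marks source
# pixels; a query is NA unless every contributing pixel is valid.
bilinear_at <- function(x, ri, ci, valid = NULL) {
  nr <- nrow(x); nc <- ncol(x)
  ok <- ri >= 1 - 1e-9 & ri <= nr + 1e-9 & ci >= 1 - 1e-9 & ci <= nc + 1e-9
  ri <- pmin(pmax(ri, 1), nr); ci <- pmin(pmax(ci, 1), nc)
  i0 <- pmin(floor(ri), max(nr - 1, 1)); fi <- ri - i0
  j0 <- pmin(floor(ci), max(nc - 1, 1)); fj <- ci - j0
  if (nr == 1) { i0 <- rep(1, length(ri)); fi <- rep(0, length(ri)) }
  if (nc == 1) { j0 <- rep(1, length(ci)); fj <- rep(0, length(ci)) }
  i1 <- pmin(i0 + 1, nr); j1 <- pmin(j0 + 1, nc)
  v <- x[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    x[cbind(i1, j0)] * fi * (1 - fj) +
    x[cbind(i0, j1)] * (1 - fi) * fj +
    x[cbind(i1, j1)] * fi * fj
  if (!is.null(valid)) {
    w <- valid[cbind(i0, j0)] & valid[cbind(i1, j0)] &
      valid[cbind(i0, j1)] & valid[cbind(i1, j1)]
    ok <- ok & w
  }
  v[!ok] <- NA_real_
  v
}

# Summed-area-table box sums over (2*half+1)^2 windows, clipped at borders.
box_sum <- function(x, half) {
  nr <- nrow(x); nc <- ncol(x)
  sat <- matrix(0, nr + 1, nc + 1)
  cs <- apply(x, 2, cumsum)
  if (nr == 1) cs <- matrix(cs, nrow = 1)
  rc <- t(apply(cs, 1, cumsum))
  if (nc == 1) rc <- matrix(cs, ncol = 1)
  sat[-1, -1] <- rc
  lo_r <- pmax(seq_len(nr) - half, 1); hi_r <- pmin(seq_len(nr) + half, nr)
  lo_c <- pmax(seq_len(nc) - half, 1); hi_c <- pmin(seq_len(nc) + half, nc)
  sat[hi_r + 1, hi_c + 1, drop = FALSE] -
    sat[lo_r, hi_c + 1, drop = FALSE] -
    sat[hi_r + 1, lo_c, drop = FALSE] +
    sat[lo_r, lo_c, drop = FALSE]
}

# number of in-bounds cells in each clipped window
box_count <- function(nr, nc, half) {
  rr <- pmin(seq_len(nr) + half, nr) - pmax(seq_len(nr) - half, 1) + 1
  cc <- pmin(seq_len(nc) + half, nc) - pmax(seq_len(nc) - half, 1) + 1
  outer(rr, cc)
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Euclidean distance (cm) from every voxel to the nearest TRUE voxel of
# `feature`, honouring anisotropic spacing. Returns a 3D array.
edt_distance <- function(feature, spacing) {
  d2 <- .edt_sq_cpp(as.logical(feature), dim(feature), as.numeric(spacing))
  array(sqrt(d2), dim = dim(feature))
}
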