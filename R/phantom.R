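# Synthetic phantom and dose generator.
#
# The phantom is a generic water-equivalent half-cylinder ("breast") resting
# flat-face down on a thin carbon-fibre-like shell ("cradle") whose plane is
# tilted by `cradle_tilt` degrees about the right-left (x) axis. In the
# tilted plane frame:
#   h = height above the cradle plane   (h = y cos(t) - z sin(t))
#   w = position along the plane        (w = y sin(t) + z cos(t))
# Body:   x^2 + h^2 <= r^2, h >= 0, 0 <= w <= breast_length
# Cradle: -thickness <= h < 0, |x| <= r + overhang, -overhang <= w <= L + overhang
# w = 0 is the inferior end of the contact region, w = breast_length the
# superior end. The flat contact face (|x| <= r, h = 0) unrolls to a
# breast_length x 2r rectangle, the region the film stencil covers.

CRADLE_OVERHANG <- 0.5 # cm the cradle shell extends beyond the body footprint

#' Phantom specification
#'
#' Geometry and acquisition constants of the synthetic breast-on-cradle
#' phantom. Defaults reproduce the study conditions: a 12 degree cradle tilt,
#' a ~170 cm^2 contact region split into an upper 11 cm lateral band and a
#' lower 14 cm inferior band, CT voxels of 0.12 x 0.12 x 0.25 cm, a 0.1 cm
#' dose calculation lattice, and a 42.5 Gy prescription.
#'
#' @param breast_radius half-cylinder radius (cm); the contact width is
#'   `2 * breast_radius`.
#' @param breast_length superior-inferior extent (cm) measured along the
#'   tilted cradle plane; must equal `lateral_extent + inferior_extent`
#'   (the unfolded contact-region length).
#' @param cradle_tilt tilt of the cradle plane, degrees in `[0, 90)`.
#' @param cradle_thickness shell thickness (cm).
#' @param ct_spacing CT voxel spacing `(dx, dy, dz)` in cm.
#' @param dose_grid_spacing isotropic dose lattice spacing in cm.
#' @param prescription prescription dose in Gy.
#' @param n_fractions number of treatment fractions the prescription is
#'   delivered in (film measures single fractions).
#' @param contact_area_target nominal contact area in cm^2 (informational;
#'   the realised area is `2 * breast_radius * breast_length`).
#' @param lateral_extent,inferior_extent lengths (cm) of the lateral (upper)
#'   and inferior (lower) segments of the unfolded contact region.
#' @param margin air margin (cm) around the phantom in the CT volume.
#' @param voxel_budget refuse to build CT grids larger than this many voxels.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(breast_radius = 3.4,
                         breast_length = 25,
                         cradle_tilt = 12,
                         cradle_thickness = 0.3,
                         ct_spacing = c(0.12, 0.12, 0.25),
                         dose_grid_spacing = 0.1,
                         prescription = 42.5,
                         n_fractions = 16L,
                         contact_area_target = 170,
                         lateral_extent = 11,
                         inferior_extent = 14,
                         margin = 2.5,
                         voxel_budget = 2.5e7) {
  lens <- c(breast_radius = breast_radius, breast_length = breast_length,
            cradle_thickness = cradle_thickness,
            dose_grid_spacing = dose_grid_spacing,
            prescription = prescription,
            lateral_extent = lateral_extent,
            inferior_extent = inferior_extent, margin = margin)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths must be finite and > 0: degenerate phantom rejected")
  if (any(ct_spacing <= 0)) stop("ct_spacing components must be > 0")
  if (cradle_tilt < 0 || cradle_tilt >= 90)
    stop("cradle_tilt must be in [0, 90) degrees")
  if (abs(lateral_extent + inferior_extent - breast_length) > 1e-6)
    stop("lateral_extent + inferior_extent must equal breast_length ",
         "(the unfolded contact-region length)")
  structure(list(breast_radius = breast_radius,
                 breast_length = breast_length,
                 cradle_tilt = cradle_tilt,
                 cradle_thickness = cradle_thickness,
                 ct_spacing = as.numeric(ct_spacing),
                 dose_grid_spacing = dose_grid_spacing,
                 prescription = prescription,
                 n_fractions = as.integer(n_fractions),
                 contact_area_target = contact_area_target,
                 lateral_extent = lateral_extent,
                 inferior_extent = inferior_extent,
                 margin = margin, voxel_budget = voxel_budget),
            class = "phantom_spec")
}

#' Tilted-plane coordinates of physical points
#'
#' Maps patient coordinates to the cradle plane frame: `h` is the height
#' above the plane (cm) and `w` the position along the plane from the
#' inferior end of the contact region.
#'
#' @param spec a [phantom_spec()].
#' @param pts n x 3 matrix of `(x, y, z)` coordinates in cm.
#' @return data.frame with columns `x`, `h`, `w`.
#' @export
plane_coords <- function(spec, pts) {
  t <- spec$cradle_tilt * pi / 180
  data.frame(x = pts[, 1],
             h = pts[, 2] * cos(t) - pts[, 3] * sin(t),
             w = pts[, 2] * sin(t) + pts[, 3] * cos(t))
}

# inverse of plane_coords: (x, h, w) -> (x, y, z)
plane_to_xyz <- function(spec, x, h, w) {
  t <- spec$cradle_tilt * pi / 180
  cbind(x, h * cos(t) + w * sin(t), -h * sin(t) + w * cos(t))
}

# CT lattice covering phantom + margin
ct_lattice <- function(spec, spacing = spec$ct_spacing,
                       margin = spec$margin) {
  r <- spec$breast_radius; L <- spec$breast_length
  th <- spec$cradle_thickness; ov <- CRADLE_OVERHANG
  t <- spec$cradle_tilt * pi / 180
  xr <- c(-(r + ov), r + ov)
  # y/z extremes over body (h in [0, r], w in [0, L]) and cradle
  hs <- c(-th, 0, r); ws <- c(-ov, 0, L, L + ov)
  corners <- expand.grid(h = hs, w = ws)
  ys <- corners$h * cos(t) + corners$w * sin(t)
  zs <- -corners$h * sin(t) + corners$w * cos(t)
  lo <- c(xr[1], min(ys), min(zs)) - margin
  hi <- c(xr[2], max(ys), max(zs)) + margin
  n <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(origin = lo, n = n, spacing = spacing)
}

# Analytic membership of lattice voxels in body / cradle, evaluated without
# materialising full coordinate arrays (h and w depend only on y and z).
phantom_membership <- function(spec, lat) {
  r <- spec$breast_radius; L <- spec$breast_length
  th <- spec$cradle_thickness; ov <- CRADLE_OVERHANG
  t <- spec$cradle_tilt * pi / 180
  xs <- grid_axis(lat$n[1], lat$spacing[1], lat$origin[1])
  ys <- grid_axis(lat$n[2], lat$spacing[2], lat$origin[2])
  zs <- grid_axis(lat$n[3], lat$spacing[3], lat$origin[3])
  h <- outer(ys * cos(t), zs * sin(t), "-")      # ny x nz
  w <- outer(ys * sin(t), zs * cos(t), "+")
  in_w_body <- w >= 0 & w <= L
  lim2 <- r^2 - h^2
  body_lim <- sqrt(pmax(lim2, 0))
  body_lim[!(h >= 0 & in_w_body & lim2 >= 0)] <- -1
  cradle_yz <- h >= -th & h < 0 & w >= -ov & w <= L + ov
  xabs <- abs(xs)
  body <- array(FALSE, lat$n); cradle <- array(FALSE, lat$n)
  for (i in seq_along(xs)) {
    body[i, , ] <- xabs[i] <= body_lim
    cradle[i, , ] <- cradle_yz & xabs[i] <= r + ov
  }
  list(body = body, cradle = cradle)
}

#' Generate a phantom CT volume with ground-truth masks
#'
#' Builds the Hounsfield-unit CT grid of the half-cylinder breast phantom on
#' its tilted cradle: air at -1000 HU, water-equivalent tissue at 0 HU, and
#' the cradle shell at -700 HU (inside the -800..-600 HU thresholding band
#' used for cradle segmentation). Ground-truth body/cradle/air masks are
#' returned alongside and are mutually disjoint, tiling the grid.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `ct` ([voxel_grid()]), `body`, `cradle`, `air`
#'   ([structure_mask()]s) and `spec`.
#' @export
generate_phantom_ct <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lat <- ct_lattice(spec)
  if (prod(lat$n) > spec$voxel_budget)
    stop("CT grid of ", paste(lat$n, collapse = "x"),
         " voxels exceeds the voxel budget (", spec$voxel_budget, ")")
  mem <- phantom_membership(spec, lat)
  if (!any(mem$body)) stop("degenerate phantom: empty body")
  hu <- array(-1000, lat$n)
  hu[mem$cradle] <- -700
  hu[mem$body] <- 0
  air <- !(mem$body | mem$cradle)
  list(ct = voxel_grid(hu, lat$spacing, lat$origin),
       body = structure_mask(mem$body, lat$spacing, lat$origin, "body"),
       cradle = structure_mask(mem$cradle, lat$spacing, lat$origin, "cradle"),
       air = structure_mask(air, lat$spacing, lat$origin, "air"),
       spec = spec)
}

#' Dose-algorithm profile
#'
#' Parametric stand-in for a TPS photon dose engine near the surface. The
#' depth dose below an entrance/contact surface is modelled as
#' `D(d) = Rx * (S + (1 - S) * (1 - exp(-d / lambda)))`, optionally reduced
#' on scatter (inferior exit) surfaces by a deficit that decays over the
#' same buildup length, plus a signed bias applied in the first voxel layer:
#' `D(d) = Rx * (S + (1-S)(1-exp(-d/lambda))) * (1 - sc * delta * exp(-d/lambda))
#'         + Rx * bias/100 * [d <= first layer]`
#' with `S = surface_dose_fraction`, `lambda = buildup_length`,
#' `delta = lateral_scatter_deficit / 100` and `sc` the scatter-surface
#' indicator.
#'
#' @param name profile label (e.g. `"truth"`, `"aaa_like"`, `"axb_like"`).
#' @param surface_dose_fraction fraction of prescription at zero depth, in
#'   `[0, 1]`.
#' @param buildup_length exponential buildup length in cm (> 0).
#' @param surface_bias signed percent of prescription added in the first
#'   voxel layer.
#' @param lateral_scatter_deficit signed percent reduction applied on the
#'   scatter (inferior) surface, decaying with depth.
#' @return An object of class `algorithm_profile`.
#' @export
algorithm_profile <- function(name, surface_dose_fraction, buildup_length,
                              surface_bias = 0, lateral_scatter_deficit = 0) {
  if (surface_dose_fraction < 0 || surface_dose_fraction > 1)
    stop("surface_dose_fraction must be in [0, 1]")
  if (buildup_length <= 0) stop("buildup_length must be > 0")
  structure(list(name = name,
                 surface_dose_fraction = surface_dose_fraction,
                 buildup_length = buildup_length,
                 surface_bias = surface_bias,
                 lateral_scatter_deficit = lateral_scatter_deficit),
            class = "algorithm_profile")
}

#' Default algorithm profiles
#'
#' Three profiles sharing one buildup length: `truth` (what the film
#' measures), an `aaa_like` profile that underestimates surface dose with a
#' larger deficit on the scatter (inferior) surface, and an `axb_like`
#' profile with a small overestimate. Offsets are expressed relative to the
#' truth surface dose fraction so per-case anatomical variation moves all
#' three together.
#'
#' @param truth_surface_fraction surface dose fraction of the ground truth.
#' @param buildup_length shared buildup length, cm.
#' @param aaa_offset,axb_offset signed additive offsets on the surface dose
#'   fraction for the two algorithm-like profiles.
#' @param aaa_deficit,axb_deficit scatter-surface deficits, percent.
#' @return named list of [algorithm_profile()]s.
#' @export
default_profiles <- function(truth_surface_fraction = 0.80,
                             buildup_length = 0.4,
                             aaa_offset = -0.04, aaa_deficit = 4,
                             axb_offset = +0.03, axb_deficit = 2.3) {
  list(
    truth = algorithm_profile("truth", truth_surface_fraction,
                              buildup_length),
    aaa_like = algorithm_profile("aaa_like",
                                 truth_surface_fraction + aaa_offset,
                                 buildup_length,
                                 lateral_scatter_deficit = aaa_deficit),
    axb_like = algorithm_profile("axb_like",
                                 truth_surface_fraction + axb_offset,
                                 buildup_length,
                                 lateral_scatter_deficit = axb_deficit))
}

#' Generate a TPS-like dose grid for a phantom
#'
#' Evaluates the parametric buildup model of an [algorithm_profile()] on the
#' dose-calculation lattice. Depth below the body surface is the anisotropic
#' Euclidean distance transform to the nearest non-body voxel; points
#' outside the body carry the surface dose (depth clamped to zero) so that
#' trilinear sampling near the surface is not diluted by zeros. The scatter
#' deficit applies to voxels whose along-plane coordinate lies in the
#' inferior segment (`w < inferior_extent`).
#'
#' @param spec a [phantom_spec()].
#' @param profile an [algorithm_profile()].
#' @param spacing dose lattice spacing in cm (default from `spec`).
#' @param return_depth attach the depth array as element `depth`.
#' @return list with `grid` (a [dose_grid()]), and optionally `depth`.
#' @export
generate_dose_grid <- function(spec, profile,
                               spacing = spec$dose_grid_spacing,
                               return_depth = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!inherits(profile, "algorithm_profile"))
    stop("unknown profile: supply an algorithm_profile")
  lat <- ct_lattice(spec, spacing = rep(spacing, 3), margin = 1.0)
  if (prod(lat$n) > spec$voxel_budget)
    stop("dose grid exceeds the voxel budget")
  mem <- phantom_membership(spec, lat)
  depth <- edt_distance(!mem$body, lat$spacing) # 0 outside body
  dose <- buildup_dose(spec, profile, lat, depth, mem$body)
  out <- list(grid = dose_grid(dose, lat$spacing, lat$origin,
                               spec$prescription))
  if (return_depth) out$depth <- depth
  out
}

# closed-form buildup dose (Gy) given depth array on a lattice
buildup_dose <- function(spec, profile, lat, depth, body) {
  rx <- spec$prescription
  s <- profile$surface_dose_fraction
  lam <- profile$buildup_length
  delta <- profile$lateral_scatter_deficit / 100
  t <- spec$cradle_tilt * pi / 180
  ys <- grid_axis(lat$n[2], lat$spacing[2], lat$origin[2])
  zs <- grid_axis(lat$n[3], lat$spacing[3], lat$origin[3])
  w_yz <- outer(ys * sin(t), zs * cos(t), "+")
  scatter_yz <- w_yz < spec$inferior_extent
  scatter <- aperm(array(scatter_yz, c(lat$n[2], lat$n[3], lat$n[1])),
                   c(3, 1, 2))
  decay <- exp(-depth / lam)
  dose <- rx * (s + (1 - s) * (1 - decay)) * (1 - scatter * delta * decay)
  if (profile$surface_bias != 0) {
    first <- body & depth <= lat$spacing[1] + 1e-9
    dose[first] <- dose[first] + rx * profile$surface_bias / 100
  }
  pmax(dose, 0)
}

#' Film noise model
#'
#' Stochastic components of a synthetic film measurement: a systematic dose
#' offset, i.i.d. Gaussian pixel noise, and an optional periodic ridge
#' artefact emulating the reconstruction artefacts seen in the inferior
#' region of unfolded dose maps.
#'
#' @param systematic_offset percent of prescription added everywhere.
#' @param noise_sd per-pixel Gaussian noise SD, percent of prescription
#'   (>= 0).
#' @param ridge_amplitude ridge artefact amplitude, percent of prescription.
#' @param ridge_period ridge period along the across-slice coordinate, cm
#'   (> 0 whenever the amplitude is nonzero).
#' @param misalign_translation_sd per-fraction random rigid shift SD, pixels.
#' @param misalign_rotation_sd per-fraction random rotation SD, degrees.
#' @param seed RNG seed for reproducible film realisations.
#' @return An object of class `film_noise_model`.
#' @export
film_noise_model <- function(systematic_offset = 0, noise_sd = 7.5,
                             ridge_amplitude = 2, ridge_period = 0.5,
                             misalign_translation_sd = 1.5,
                             misalign_rotation_sd = 0.75,
                             seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (ridge_amplitude != 0 && ridge_period <= 0)
    stop("ridge_period must be > 0 when ridge_amplitude is nonzero")
  structure(list(systematic_offset = systematic_offset,
                 noise_sd = noise_sd,
                 ridge_amplitude = ridge_amplitude,
                 ridge_period = ridge_period,
                 misalign_translation_sd = misalign_translation_sd,
                 misalign_rotation_sd = misalign_rotation_sd,
                 seed = as.integer(seed)),
            class = "film_noise_model")
}

#' Simulate per-fraction film measurements
#'
#' Each simulated fraction is the true surface dose plus the systematic
#' offset, the ridge artefact, and i.i.d. Gaussian noise, optionally viewed
#' through a small random rigid misalignment (to exercise registration
#' downstream). Identical seeds give bit-identical output.
#'
#' @param true_surface a [film_dose_map()] of the true surface dose
#'   (percent of prescription).
#' @param noise a [film_noise_model()].
#' @param n_fractions number of measured fractions (default 3).
#' @param ridge_mask optional logical matrix restricting the ridge artefact
#'   (e.g. to the inferior region); `NULL` applies it everywhere.
#' @return list of [film_dose_map()]s; the injected rigid transforms are
#'   attached as attribute `"misalignments"`.
#' @export
generate_film_measurement <- function(true_surface, noise, n_fractions = 3L,
                                      ridge_mask = NULL) {
  stopifnot(inherits(true_surface, "film_dose_map"),
            inherits(noise, "film_noise_model"))
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  nr <- nrow(true_surface$dose); nc <- ncol(true_surface$dose)
  v <- (seq_len(nr) - 1) * true_surface$pixel_spacing
  ridge <- matrix(0, nr, nc)
  if (noise$ridge_amplitude != 0) {
    ridge <- matrix(noise$ridge_amplitude *
                      sin(2 * pi * v / noise$ridge_period), nr, nc)
    if (!is.null(ridge_mask)) ridge[!ridge_mask] <- 0
  }
  base <- true_surface$dose + noise$systematic_offset + ridge
  maps <- vector("list", n_fractions)
  transforms <- vector("list", n_fractions)
  with_local_seed(noise$seed, {
    for (f in seq_len(n_fractions)) {
      tr <- list(rotation = 0, translation = c(0, 0))
      dose_f <- base
      valid_f <- true_surface$valid
      if (noise$misalign_translation_sd > 0 ||
          noise$misalign_rotation_sd > 0) {
        tr$rotation <- rnorm(1, 0, noise$misalign_rotation_sd)
        tr$translation <- rnorm(2, 0, noise$misalign_translation_sd) *
          true_surface$pixel_spacing
        warped <- apply_rigid_transform(
          film_dose_map(base, true_surface$pixel_spacing,
                        true_surface$valid, true_surface$provenance),
          rotation = tr$rotation, translation = tr$translation)
        dose_f <- warped$dose
        valid_f <- warped$valid
      }
      if (noise$noise_sd > 0)
        dose_f <- dose_f + matrix(rnorm(nr * nc, 0, noise$noise_sd), nr, nc)
      dose_f[!valid_f] <- NA_real_
      maps[[f]] <- film_dose_map(dose_f, true_surface$pixel_spacing,
                                 valid_f,
                                 provenance = paste0("film_fx", f))
      transforms[[f]] <- tr
    }
  })
  attr(maps, "misalignments") <- transforms
  maps
}
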