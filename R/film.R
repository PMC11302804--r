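# Film dosimetry processing: calibration, trimming, filtering, rigid
# registration and fraction averaging.

#' Film scan image container
#'
#' An RGB scanner image of a radiochromic film, with resolution metadata.
#'
#' @param pixels numeric array `h x w x 3` of channel values.
#' @param dpi scan resolution in dots per inch (> 0; film protocol uses 72).
#' @param bit_depth bits per channel (metadata only).
#' @return An object of class `film_scan_image`.
#' @export
film_scan_image <- function(pixels, dpi = 72, bit_depth = 16) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] >= 3)
  if (dpi <= 0) stop("dpi must be > 0")
  if (any(dim(pixels)[1:2] == 0)) stop("image must be non-empty")
  structure(list(pixels = pixels, dpi = dpi, bit_depth = bit_depth),
            class = "film_scan_image")
}

# rational calibration response: X(D) = (a + b D) / (c + D)
cal_response <- function(curve, dose) {
  (curve$a + curve$b * dose) / (curve$c + dose)
}

# inverse: D(X) = (a - c X) / (X - b)
cal_inverse <- function(curve, x) {
  (curve$a - curve$c * x) / (x - curve$b)
}

#' Fit a rational film calibration curve
#'
#' Least-squares fit of the one-scan-protocol rational form
#' `X(D) = (a + b D) / (c + D)` mapping dose to green-channel response.
#' The model is first solved through its linearisation
#' `X D = a + b D - c X` (exact for noiseless data), then refined by
#' nonlinear least squares in response space.
#'
#' @param doses delivered doses in Gy (>= 3 distinct levels).
#' @param responses mean green-channel values at those doses; must be
#'   strictly monotone in dose.
#' @return An object of class `calibration_curve` with coefficients `a`,
#'   `b`, `c`, the `valid_dose_range`, the fitted `response_range` and the
#'   per-point `residuals`.
#' @export
fit_calibration <- function(doses, responses) {
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length")
  o <- order(doses)
  doses <- doses[o]; responses <- responses[o]
  if (length(unique(doses)) < 3)
    stop("calibration requires at least 3 distinct dose levels")
  dr <- diff(responses)
  if (any(dr == 0) || !(all(dr > 0) || all(dr < 0)))
    stop("calibration error: responses are not strictly monotone in dose")
  fit0 <- lm(I(responses * doses) ~ doses + responses)
  a <- unname(coef(fit0)[1]); b <- unname(coef(fit0)[2])
  cc <- -unname(coef(fit0)[3])
  if (length(doses) > 3) {
    nl <- tryCatch(
      minpack.lm::nlsLM(responses ~ (a + b * doses) / (cc + doses),
                        start = list(a = a, b = b, cc = cc),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      p <- coef(nl)
      a <- unname(p["a"]); b <- unname(p["b"]); cc <- unname(p["cc"])
    }
  }
  curve <- structure(list(a = a, b = b, c = cc,
                          valid_dose_range = range(doses)),
                     class = "calibration_curve")
  if (any(abs(curve$c + doses) < 1e-9))
    stop("calibration error: pole inside the calibrated dose range")
  fitted <- cal_response(curve, doses)
  curve$residuals <- responses - fitted
  curve$response_range <- range(cal_response(curve, curve$valid_dose_range))
  curve
}

#' Convert a film scan to a dose map
#'
#' Inverts the calibration on the green channel and expresses dose as
#' percent of the prescription. Responses outside the calibrated response
#' range are flagged invalid rather than clipped, so no dose is fabricated
#' outside the measured range.
#'
#' @param scan a [film_scan_image()].
#' @param curve a [calibration_curve][fit_calibration()].
#' @param prescription prescription dose in Gy for the percent scale (for
#'   per-fraction film measurements, the per-fraction prescription).
#' @return A [film_dose_map()] with `pixel_spacing = 2.54 / dpi`.
#' @export
apply_calibration <- function(scan, curve, prescription) {
  stopifnot(inherits(scan, "film_scan_image"),
            inherits(curve, "calibration_curve"))
  if (prescription <= 0) stop("prescription must be > 0")
  x <- scan$pixels[, , 2] # green channel
  rng <- curve$response_range
  tol <- 1e-6 * max(abs(rng), 1)
  valid <- x >= rng[1] - tol & x <= rng[2] + tol
  dose <- cal_inverse(curve, x)
  dose[!valid] <- NA_real_
  film_dose_map(100 * dose / prescription, 2.54 / scan$dpi, valid,
                provenance = "film_calibrated")
}

#' Render a dose map into a synthetic film scan
#'
#' Forward model used by the synthetic pipeline and in round-trip tests:
#' dose (percent of prescription) is pushed through the calibration curve
#' into a green-channel image; red and blue carry a flat background.
#' Invalid pixels are rendered at the zero-dose response.
#'
#' @inheritParams apply_calibration
#' @param map a [film_dose_map()].
#' @return A [film_scan_image()].
#' @export
render_film_scan <- function(map, curve, prescription) {
  stopifnot(inherits(map, "film_dose_map"),
            inherits(curve, "calibration_curve"))
  dose_gy <- map$dose * prescription / 100
  dose_gy[!map$valid] <- 0
  g <- cal_response(curve, dose_gy)
  px <- array(0, c(dim(g), 3))
  px[, , 1] <- cal_response(curve, 0)
  px[, , 2] <- g
  px[, , 3] <- cal_response(curve, 0)
  film_scan_image(px, dpi = 2.54 / map$pixel_spacing)
}

#' Trim the outer pixels of a film dose map
#'
#' Erodes the validity mask inward by `n_pixels` along the mask boundary
#' (Chebyshev distance, so corners are respected), removing potential film
#' cutting artefacts at the edge. The image borders count as boundary.
#'
#' @param map a [film_dose_map()].
#' @param n_pixels number of boundary pixels to remove (default 2).
#' @return A [film_dose_map()] with the eroded mask.
#' @export
trim_edges <- function(map, n_pixels = 2) {
  stopifnot(inherits(map, "film_dose_map"))
  if (n_pixels < 0) stop("n_pixels must be >= 0")
  if (n_pixels == 0) return(map)
  d <- dim(map$dose)
  if (any(d <= 2 * n_pixels))
    stop("map too small to trim ", n_pixels, " pixels per side")
  inv <- 1 - map$valid
  cnt_inv <- box_sum(inv, n_pixels)
  cells <- box_count(d[1], d[2], n_pixels)
  area <- (2 * n_pixels + 1)^2
  # virtual pixels beyond the border are invalid
  new_valid <- map$valid & (cnt_inv + (area - cells) == 0)
  dose <- map$dose
  dose[!new_valid] <- NA_real_
  film_dose_map(dose, map$pixel_spacing, new_valid, map$provenance)
}

#' Noise-suppress a film dose map
#'
#' Two-stage filtering within the validity mask: a 5x5 adaptive
#' local-mean/variance (Wiener-type) filter followed by a 5x5 median filter
#' (order configurable). Constant regions are fixed points of both stages;
#' invalid pixels neither contribute to nor receive filtered values.
#'
#' @param map a [film_dose_map()].
#' @param size odd window size (default 5).
#' @param order `"wiener_median"` (default) or `"median_wiener"`.
#' @return A filtered [film_dose_map()].
#' @export
denoise <- function(map, size = 5,
                    order = c("wiener_median", "median_wiener")) {
  stopifnot(inherits(map, "film_dose_map"))
  order <- match.arg(order)
  if (size %% 2 != 1 || size < 3) stop("size must be an odd integer >= 3")
  if (sum(map$valid) < size^2) {
    warning("valid region smaller than the filter window; map passed through")
    return(map)
  }
  stages <- strsplit(order, "_")[[1]]
  out <- map
  for (s in stages) {
    out <- if (s == "wiener") wiener_masked(out, size) else
      median_masked(out, size)
  }
  out
}

# adaptive local-mean/variance filter (wiener2-style) within the mask
wiener_masked <- function(map, size = 5) {
  half <- (size - 1) %/% 2
  x <- map$dose
  x[!map$valid] <- 0
  v <- map$valid * 1
  cnt <- box_sum(v, half)
  s1 <- box_sum(x * v, half)
  s2 <- box_sum(x^2 * v, half)
  cnt_safe <- pmax(cnt, 1)
  mu <- s1 / cnt_safe
  varr <- pmax(s2 / cnt_safe - mu^2, 0)
  noise <- mean(varr[map$valid])
  gain <- ifelse(varr > noise, (varr - noise) / varr, 0)
  out <- mu + gain * (map$dose - mu)
  out[!map$valid] <- NA_real_
  film_dose_map(out, map$pixel_spacing, map$valid, map$provenance)
}

# masked median filter (compiled kernel)
median_masked <- function(map, size = 5) {
  half <- (size - 1) %/% 2
  x <- map$dose
  x[!map$valid] <- 0
  out <- .median_filter_masked_cpp(x, map$valid, half)
  out[!map$valid] <- NA_real_
  film_dose_map(out, map$pixel_spacing, map$valid, map$provenance)
}

# Resample a map through a rigid transform: the returned map, on the same
# lattice, shows the input as if it had been moved by `rotation` (degrees,
# about the map centre) and then `translation` (cm). Used both to inject
# misalignments and to apply recovered registrations.
apply_rigid_transform <- function(map, rotation = 0, translation = c(0, 0)) {
  s <- map$pixel_spacing
  x <- map$dose
  x[!map$valid] <- 0
  dose <- .rigid_resample_cpp(x, map$valid, rotation,
                              translation[1] / s, translation[2] / s)
  valid <- !is.nan(dose)
  dose[!valid] <- NA_real_
  film_dose_map(dose, s, valid, map$provenance)
}

#' Rigidly register one film dose map to another
#'
#' Estimates the rotation + translation aligning `moving` with `fixed` by
#' maximising normalised cross-correlation (NCC) over the overlapping valid
#' region, using a multi-resolution pyramid: an exhaustive coarse search
#' over integer shifts and a rotation fan, then Nelder-Mead refinement at
#' each pyramid level.
#'
#' @param moving,fixed [film_dose_map()]s with equal pixel spacing.
#' @param max_shift largest translation searched, cm.
#' @param max_rotation largest rotation searched, degrees.
#' @param pyramid integer downsampling factors, coarse to fine.
#' @return list with `transform` (list `rotation` degrees, `translation` cm
#'   — the motion that takes `moving` onto `fixed`), `registered` (the
#'   resampled moving map on the fixed lattice) and `ncc` (final metric).
#' @export
register_rigid <- function(moving, fixed, max_shift = 1.2,
                           max_rotation = 6, pyramid = c(4, 2, 1)) {
  stopifnot(inherits(moving, "film_dose_map"),
            inherits(fixed, "film_dose_map"))
  if (abs(moving$pixel_spacing - fixed$pixel_spacing) >
      1e-9 * fixed$pixel_spacing)
    stop("maps must share pixel spacing")
  if (!all(dim(moving$dose) == dim(fixed$dose)))
    stop("maps must share a lattice")

  # maps passed here carry zero-filled invalid pixels
  ncc_at <- function(mov, fix, rot, tr_cm) {
    s <- mov$pixel_spacing
    .rigid_ncc_cpp(mov$dose, mov$valid, fix$dose, fix$valid, rot,
                   tr_cm[1] / s, tr_cm[2] / s)[1]
  }

  par <- c(0, 0, 0) # rotation deg, tx cm, ty cm
  for (li in seq_along(pyramid)) {
    f <- pyramid[li]
    mov0 <- downsample_map(moving, f)
    fix0 <- downsample_map(fixed, f)
    mov <- list(dose = {x <- mov0$dose; x[!mov0$valid] <- 0; x},
                valid = mov0$valid, pixel_spacing = mov0$pixel_spacing)
    fix <- list(dose = {x <- fix0$dose; x[!fix0$valid] <- 0; x},
                valid = fix0$valid, pixel_spacing = fix0$pixel_spacing)
    if (li == 1) {
      # exhaustive coarse initialisation
      s <- fix$pixel_spacing
      shift_px <- ceiling(max_shift / s)
      rots <- unique(c(seq(-max_rotation, max_rotation, by = 2), 0))
      shifts <- unique(c(seq(-shift_px, shift_px, by = 2), 0))
      best <- c(-Inf, 0, 0, 0)
      for (r in rots) {
        for (di in shifts) {
          for (dj in shifts) {
            val <- ncc_at(mov, fix, r, c(di * s, dj * s))
            if (val > best[1]) best <- c(val, r, di * s, dj * s)
          }
        }
      }
      par <- best[2:4]
    }
    obj <- function(p) -ncc_at(mov, fix, p[1], p[2:3])
    sc <- c(0.5, fix$pixel_spacing, fix$pixel_spacing)
    opt <- optim(par, obj, method = "Nelder-Mead",
                 control = list(maxit = if (f == 1) 200 else 400,
                                reltol = 1e-12, parscale = sc))
    par <- opt$par
  }
  final_ncc <- ncc_at(moving, fixed, par[1], par[2:3])
  if (!is.finite(final_ncc))
    stop("registration failed to converge: no usable overlap between maps ",
         "(rotation ", signif(par[1], 3), " deg, translation ",
         paste(signif(par[2:3], 3), collapse = "/"), " cm)")
  registered <- apply_rigid_transform(moving, par[1], par[2:3])
  list(transform = list(rotation = par[1], translation = par[2:3]),
       registered = registered, ncc = final_ncc)
}

# block-average downsampling preserving the valid mask (a block is valid if
# any constituent pixel is valid; its value is the mean of valid pixels)
downsample_map <- function(map, f) {
  if (f == 1) return(map)
  nr <- nrow(map$dose); nc <- ncol(map$dose)
  nrb <- nr %/% f; ncb <- nc %/% f
  if (nrb < 4 || ncb < 4) return(map)
  x <- map$dose[seq_len(nrb * f), seq_len(ncb * f), drop = FALSE]
  v <- map$valid[seq_len(nrb * f), seq_len(ncb * f), drop = FALSE]
  x[!v] <- 0
  dim(x) <- c(f, nrb, f, ncb)
  dim(v) <- c(f, nrb, f, ncb)
  sums <- apply(x, c(2, 4), sum)
  cnts <- apply(v, c(2, 4), sum)
  dose <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  film_dose_map(dose, map$pixel_spacing * f, cnts > 0, map$provenance)
}

#' Average co-registered fraction dose maps
#'
#' Pixel-wise arithmetic mean over maps; a pixel of the mean map is valid
#' only where every fraction is valid (the validity intersection), so the
#' mask never grows.
#'
#' @param maps non-empty list of co-registered [film_dose_map()]s on one
#'   lattice.
#' @return A [film_dose_map()] of the mean measured dose distribution.
#' @export
average_fractions <- function(maps) {
  if (length(maps) == 0) stop("empty list of fraction maps")
  stopifnot(all(vapply(maps, inherits, logical(1), "film_dose_map")))
  d <- dim(maps[[1]]$dose)
  sp <- maps[[1]]$pixel_spacing
  for (m in maps) {
    if (!all(dim(m$dose) == d) ||
        abs(m$pixel_spacing - sp) > 1e-9 * sp)
      stop("fraction maps must share a lattice")
  }
  valid <- Reduce(`&`, lapply(maps, function(m) m$valid))
  acc <- matrix(0, d[1], d[2])
  for (m in maps) {
    x <- m$dose
    x[!m$valid] <- 0
    acc <- acc + x
  }
  dose <- acc / length(maps)
  dose[!valid] <- NA_real_
  film_dose_map(dose, sp, valid, provenance = "film_mean")
}
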