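# Shared fixtures and independent reference implementations (oracles).
# Oracles are deliberately written as direct loops / first-principles
# formulas, independent of the package's vectorised or compiled paths.

# A small phantom that keeps unit tests fast while preserving all study
# geometry features (tilt, lateral/inferior split, anisotropic CT voxels).
small_spec <- function(...) {
  phantom_spec(breast_radius = 1.2, breast_length = 6,
               lateral_extent = 2.5, inferior_extent = 3.5,
               cradle_tilt = 12, dose_grid_spacing = 0.15,
               margin = 1.0, ...)
}

# run_config scaled to the small phantom
small_config <- function(...) {
  run_config(phantom = list(breast_radius = 1.2, breast_length = 6,
                            lateral_extent = 2.5, inferior_extent = 3.5,
                            dose_grid_spacing = 0.15),
             extended_body_cm = 0.5,
             registration = list(max_shift = 0.3, max_rotation = 3),
             ...)
}

# smooth synthetic film map with texture suitable for registration tests
smooth_test_map <- function(nr = 120, nc = 120, spacing = 0.05) {
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dose <- 80 + 10 * sin(ii / 9) * cos(jj / 7) +
    6 * exp(-((ii - nr / 3)^2 + (jj - nc / 2)^2) / 220) +
    0.05 * ii - 0.03 * jj
  film_dose_map(dose, spacing, provenance = "test")
}

# --- independent reference filters -----------------------------------------

ref_median_filter <- function(x, valid, half = 2) {
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!valid[i, j]) next
      vals <- c()
      for (di in -half:half) {
        for (dj in -half:half) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              valid[ii, jj])
            vals <- c(vals, x[ii, jj])
        }
      }
      out[i, j] <- median(vals)
    }
  }
  out
}

ref_wiener_filter <- function(x, valid, half = 2) {
  nr <- nrow(x); nc <- ncol(x)
  mu <- matrix(NA_real_, nr, nc)
  vr <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (di in -half:half) {
        for (dj in -half:half) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              valid[ii, jj])
            vals <- c(vals, x[ii, jj])
        }
      }
      if (length(vals) > 0) {
        mu[i, j] <- mean(vals)
        vr[i, j] <- mean(vals^2) - mean(vals)^2
      }
    }
  }
  noise <- mean(vr[valid])
  out <- x
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!valid[i, j]) next
      g <- if (vr[i, j] > noise) (vr[i, j] - noise) / vr[i, j] else 0
      out[i, j] <- mu[i, j] + g * (x[i, j] - mu[i, j])
    }
  }
  out
}

# --- independent gamma oracle ----------------------------------------------

# Exhaustive brute-force gamma: fine-lattice bilinear upsampling computed
# point by point from the four surrounding coarse pixels, then a full scan
# over every fine node within the search radius (no early termination).
gamma_oracle <- function(reference, evaluated, criteria) {
  m <- criteria$upsample
  sp <- reference$pixel_spacing
  nr <- nrow(reference$dose); nc <- ncol(reference$dose)
  fr <- (nr - 1) * m + 1; fc <- (nc - 1) * m + 1
  fine <- matrix(NA_real_, fr, fc)
  fine_ok <- matrix(FALSE, fr, fc)
  for (fi in seq_len(fr)) {
    ri <- (fi - 1) / m + 1
    i0 <- min(floor(ri), nr - 1); wi <- ri - i0
    for (fj in seq_len(fc)) {
      ci <- (fj - 1) / m + 1
      j0 <- min(floor(ci), nc - 1); wj <- ci - j0
      on_node_i <- abs(wi) < 1e-12 || abs(wi - 1) < 1e-12
      on_node_j <- abs(wj) < 1e-12 || abs(wj - 1) < 1e-12
      ii <- if (abs(wi - 1) < 1e-12) i0 + 1 else i0
      jj <- if (abs(wj - 1) < 1e-12) j0 + 1 else j0
      need_i <- if (on_node_i) ii else c(i0, i0 + 1)
      need_j <- if (on_node_j) jj else c(j0, j0 + 1)
      if (all(evaluated$valid[need_i, need_j])) {
        v <- evaluated$dose[i0, j0] * (1 - wi) * (1 - wj) +
          evaluated$dose[i0 + 1, j0] * wi * (1 - wj) +
          evaluated$dose[i0, j0 + 1] * (1 - wi) * wj +
          evaluated$dose[i0 + 1, j0 + 1] * wi * wj
        fine[fi, fj] <- v
        fine_ok[fi, fj] <- TRUE
      }
    }
  }
  fine_sp <- sp / m
  radius <- criteria$search_radius_factor * criteria$dta
  g <- matrix(NA_real_, nr, nc)
  fidx <- which(fine_ok, arr.ind = TRUE)
  fvals <- fine[fine_ok]
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!reference$valid[i, j]) next
      ci <- (i - 1) * m + 1; cj <- (j - 1) * m + 1
      d2 <- ((fidx[, 1] - ci) * fine_sp)^2 + ((fidx[, 2] - cj) * fine_sp)^2
      sel <- d2 <= radius^2 + 1e-12
      if (!any(sel)) next
      gg <- d2[sel] / criteria$dta^2 +
        (fvals[sel] - reference$dose[i, j])^2 / criteria$dose_tol^2
      g[i, j] <- sqrt(min(gg))
    }
  }
  g
}

# evaluated$dose must be finite where invalid for the oracle's blind
# bilinear reads; callers pass maps with zeros outside the mask
zero_fill <- function(map) {
  d <- map$dose
  d[!map$valid] <- 0
  film_dose_map(d, map$pixel_spacing, map$valid, map$provenance)
}

# random co-registered 32 x 32 map pair used for gamma oracle checks
random_map_pair <- function(seed, n = 32, spacing = 0.1) {
  set.seed(seed)
  base <- matrix(90 + 8 * rnorm(n * n), n, n)
  ref <- film_dose_map(base, spacing, provenance = "ref")
  ev <- film_dose_map(base + matrix(rnorm(n * n, 0, 5), n, n), spacing,
                      provenance = "eval")
  list(ref = ref, ev = ev)
}

# --- independent trilinear oracle ------------------------------------------

ref_trilinear <- function(values, spacing, origin, p) {
  g <- (p - origin) / spacing + 1
  i0 <- min(max(floor(g[1]), 1), dim(values)[1] - 1)
  j0 <- min(max(floor(g[2]), 1), dim(values)[2] - 1)
  k0 <- min(max(floor(g[3]), 1), dim(values)[3] - 1)
  fx <- g[1] - i0; fy <- g[2] - j0; fz <- g[3] - k0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    acc <- acc + w * values[i0 + dx, j0 + dy, k0 + dz]
  }
  acc
}

# small phantom with fully built structures, memoised per session
small_case_structures <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- small_spec()
    ph <- generate_phantom_ct(spec)
    body <- threshold_structure(ph$ct, -300, 3071, keep_largest = TRUE,
                                label = "body")
    cradle <- threshold_structure(ph$ct, -800, -600, label = "cradle")
    contact <- contact_surface(body, cradle)
    cache <<- list(spec = spec, ph = ph, body = body, cradle = cradle,
                   contact = contact)
    cache
  }
})
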