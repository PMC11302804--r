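# 2D gamma-index analysis of film versus unfolded TPS dose maps.

#' Gamma criteria
#'
#' Acceptance criteria for the gamma index: distance to agreement (DTA) and
#' dose tolerance, with global normalisation (doses are already percent of
#' prescription, so the tolerance is a plain percent).
#'
#' @param dta distance to agreement in cm (> 0, default 0.5).
#' @param dose_tol dose tolerance, percent of prescription (> 0; 7 or 10 in
#'   the standard analysis).
#' @param normalization only `"global"` is implemented; `"local"` errors.
#' @param low_dose_threshold reference pixels below this dose (percent) are
#'   excluded (default 0: no threshold).
#' @param search_radius_factor search truncation radius in units of DTA.
#' @param upsample evaluated-map upsampling factor (bilinear) controlling
#'   discretisation of the spatial search.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dta = 0.5, dose_tol = 7,
                           normalization = "global",
                           low_dose_threshold = 0,
                           search_radius_factor = 3, upsample = 3L) {
  if (dta <= 0) stop("dta must be > 0")
  if (dose_tol <= 0) stop("dose_tol must be > 0")
  if (!identical(normalization, "global"))
    stop("only global normalization is implemented")
  if (search_radius_factor <= 0) stop("search_radius_factor must be > 0")
  structure(list(dta = dta, dose_tol = dose_tol,
                 normalization = normalization,
                 low_dose_threshold = low_dose_threshold,
                 search_radius_factor = search_radius_factor,
                 upsample = as.integer(upsample)),
            class = "gamma_criteria")
}

# bilinear upsampling of a map onto the fine lattice with factor m:
# coarse pixel (i, j) lands on fine node ((i-1)*m + 1, (j-1)*m + 1).
upsample_fine <- function(dose, valid, m) {
  x <- dose
  x[!valid] <- 0
  up1 <- function(x, valid, m) { # upsample along rows (dim 1)
    n <- nrow(x)
    if (m == 1 || n == 1)
      return(list(x = x, v = valid))
    fn <- (n - 1) * m + 1
    xf <- matrix(0, fn, ncol(x))
    vf <- matrix(FALSE, fn, ncol(x))
    xf[seq(1, fn, by = m), ] <- x
    vf[seq(1, fn, by = m), ] <- valid
    lo <- seq_len(n - 1)
    vpair <- valid[lo, , drop = FALSE] & valid[lo + 1, , drop = FALSE]
    for (t in seq_len(m - 1)) {
      w <- t / m
      pos <- (lo - 1) * m + 1 + t
      xf[pos, ] <- (1 - w) * x[lo, , drop = FALSE] +
        w * x[lo + 1, , drop = FALSE]
      vf[pos, ] <- vpair
    }
    list(x = xf, v = vf)
  }
  a <- up1(x, valid, m)
  b <- up1(t(a$x), t(a$v), m)
  fine <- t(b$x)
  fine_valid <- t(b$v)
  fine[!fine_valid] <- 0
  list(dose = fine, valid = fine_valid)
}

#' Gamma index of an evaluated map against a reference
#'
#' For each valid reference pixel, the gamma index is the minimum over
#' evaluated positions within `search_radius_factor * dta` of
#' `sqrt(||e - r||^2 / dta^2 + (D_eval(e) - D_ref(r))^2 / dose_tol^2)`,
#' with the evaluated distribution bilinearly upsampled to control
#' discretisation. Reference pixels whose entire search neighbourhood is
#' invalid receive `NA` and are excluded from pass rates.
#'
#' @param reference,evaluated co-registered [film_dose_map()]s on the same
#'   lattice (doses in percent of prescription).
#' @param criteria a [gamma_criteria()].
#' @return An object of class `gamma_map`: list with the `gamma` matrix,
#'   the overall `pass_rate` (percent of evaluated pixels with gamma <= 1),
#'   `n_evaluated`, and the criteria.
#' @export
gamma_index <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "film_dose_map"),
            inherits(evaluated, "film_dose_map"),
            inherits(criteria, "gamma_criteria"))
  if (!all(dim(reference$dose) == dim(evaluated$dose)))
    stop("lattice mismatch between reference and evaluated maps")
  if (abs(reference$pixel_spacing - evaluated$pixel_spacing) >
      1e-9 * reference$pixel_spacing)
    stop("lattice mismatch: pixel spacings differ")
  m <- criteria$upsample
  fine <- upsample_fine(evaluated$dose, evaluated$valid, m)
  fine_spacing <- reference$pixel_spacing / m
  ref_ok <- reference$valid
  if (criteria$low_dose_threshold > 0)
    ref_ok <- ref_ok & reference$dose >= criteria$low_dose_threshold
  ref_dose <- reference$dose
  ref_dose[!ref_ok] <- 0
  g <- .gamma_index_cpp(ref_dose, ref_ok, fine$dose, fine$valid,
                        m, fine_spacing, criteria$dta, criteria$dose_tol,
                        criteria$search_radius_factor * criteria$dta)
  evaluated_px <- sum(!is.na(g))
  pass <- if (evaluated_px > 0)
    100 * sum(g <= 1 + 1e-12, na.rm = TRUE) / evaluated_px else NA_real_
  structure(list(gamma = g, pass_rate = pass, n_evaluated = evaluated_px,
                 criteria = criteria),
            class = "gamma_map")
}

#' @export
print.gamma_map <- function(x, ...) {
  cat(sprintf("<gamma_map> %.1f%%/%.2fcm: pass rate %.1f%% over %d px\n",
              x$criteria$dose_tol, x$criteria$dta, x$pass_rate,
              x$n_evaluated))
  invisible(x)
}

#' Per-region gamma pass rates
#'
#' @param gm a [gamma_map()][gamma_index()].
#' @param regions character matrix of region labels (from
#'   [segment_lat_inf()]), same shape as the gamma matrix.
#' @return data.frame with columns `region` (`full`, then each label) and
#'   `pass_rate` (percent), plus `n` evaluated pixels.
#' @export
gamma_pass_rates <- function(gm, regions) {
  stopifnot(inherits(gm, "gamma_map"))
  g <- gm$gamma
  stopifnot(all(dim(regions) == dim(g)))
  rate <- function(sel) {
    n <- sum(!is.na(g[sel]))
    r <- if (n > 0) 100 * sum(g[sel] <= 1 + 1e-12, na.rm = TRUE) / n
    else NA_real_
    c(r, n)
  }
  labs <- c("full", sort(unique(as.vector(regions))))
  out <- lapply(labs, function(l) {
    sel <- if (l == "full") rep(TRUE, length(g)) else regions == l
    v <- rate(sel)
    data.frame(region = l, pass_rate = v[1], n = v[2])
  })
  do.call(rbind, out)
}

#' Summarise gamma pass rates across cases
#'
#' Builds the gamma report table: mean and SD of pass rates per criteria
#' row and algorithm x region column, in the shape of the standard gamma
#' summary table.
#'
#' @param rates data.frame with columns `case`, `algorithm`, `dose_tol`,
#'   `dta`, `region`, `pass_rate` (one row per case/cell).
#' @return data.frame: one row per (dta, dose_tol), columns
#'   `<algorithm>_<region>_mean` and `..._sd`.
#' @export
gamma_report <- function(rates) {
  need <- c("case", "algorithm", "dose_tol", "dta", "region", "pass_rate")
  if (!all(need %in% names(rates)))
    stop("rates must have columns: ", paste(need, collapse = ", "))
  combos <- unique(rates[, c("dta", "dose_tol")])
  combos <- combos[order(combos$dose_tol), , drop = FALSE]
  algs <- unique(rates$algorithm)
  regs <- intersect(c("full", "lateral", "inferior"),
                    unique(rates$region))
  out <- list()
  for (r in seq_len(nrow(combos))) {
    sel <- rates$dta == combos$dta[r] & rates$dose_tol == combos$dose_tol[r]
    row <- list(dta = combos$dta[r], dose_tol = combos$dose_tol[r])
    for (a in algs) {
      for (g in regs) {
        v <- rates$pass_rate[sel & rates$algorithm == a & rates$region == g]
        row[[paste0(a, "_", g, "_mean")]] <- mean(v)
        row[[paste0(a, "_", g, "_sd")]] <- if (length(v) > 1) sd(v) else 0
      }
    }
    out[[r]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}
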