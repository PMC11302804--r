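# Pixel-wise calculated-minus-measured dose differences, pooled histograms,
# Gaussian fits and the between-algorithm t-test.

#' Mask a film map to the contact region
#'
#' Intersects the film validity mask with the region of contact defined by
#' the unfolded TPS map (only pixels where the skin actually touched the
#' film/cradle are comparable).
#'
#' @param film a [film_dose_map()].
#' @param contact a [film_dose_map()] (its validity mask defines the
#'   contact outline) or a logical matrix.
#' @return The film map with the intersected mask.
#' @export
mask_to_contact <- function(film, contact) {
  stopifnot(inherits(film, "film_dose_map"))
  cmask <- if (inherits(contact, "film_dose_map")) contact$valid else contact
  stopifnot(is.logical(cmask), all(dim(cmask) == dim(film$dose)))
  valid <- film$valid & cmask
  if (!any(valid))
    stop("empty intersection between film and contact region")
  dose <- film$dose
  dose[!valid] <- NA_real_
  film_dose_map(dose, film$pixel_spacing, valid, film$provenance)
}

#' Pixel-by-pixel dose difference (calculated minus measured)
#'
#' @param calculated,measured co-registered [film_dose_map()]s on the same
#'   lattice; by the sign convention the result is TPS minus film.
#' @return An object of class `dose_difference_map`: `diff` matrix
#'   (percent of prescription), `valid` (both inputs valid),
#'   `pixel_spacing`.
#' @export
dose_difference <- function(calculated, measured) {
  stopifnot(inherits(calculated, "film_dose_map"),
            inherits(measured, "film_dose_map"))
  if (!all(dim(calculated$dose) == dim(measured$dose)))
    stop("lattice mismatch between calculated and measured maps")
  if (abs(calculated$pixel_spacing - measured$pixel_spacing) >
      1e-9 * measured$pixel_spacing)
    stop("lattice mismatch: pixel spacings differ")
  valid <- calculated$valid & measured$valid
  dif <- calculated$dose - measured$dose
  dif[!valid] <- NA_real_
  structure(list(diff = dif, valid = valid,
                 pixel_spacing = calculated$pixel_spacing),
            class = "dose_difference_map")
}

#' Pooled dose-difference histogram
#'
#' Histogram over all valid pixels of all supplied difference maps within a
#' region, with bins of `bin_width` percent centred on multiples of the bin
#' width (integers for the default 1% bins).
#'
#' @param diffs list of [dose_difference_map()][dose_difference()]s.
#' @param region `"full"`, `"lateral"` or `"inferior"`.
#' @param region_maps list of label matrices (from [segment_lat_inf()]),
#'   parallel to `diffs`; required unless `region = "full"`.
#' @param bin_width bin width in percent (default 1).
#' @return list with `mids` (bin centres), `edges`, `counts` and `n`
#'   (total pixel count).
#' @export
pooled_histogram <- function(diffs, region = "full", region_maps = NULL,
                             bin_width = 1) {
  if (length(diffs) == 0) stop("no difference maps supplied")
  vals <- pooled_pixels(diffs, region, region_maps)
  if (length(vals) == 0) stop("no valid pixels in region '", region, "'")
  lo <- floor(min(vals) / bin_width) - 1
  hi <- ceiling(max(vals) / bin_width) + 1
  mids <- seq(lo, hi) * bin_width
  edges <- c(mids - bin_width / 2, mids[length(mids)] + bin_width / 2)
  counts <- tabulate(
    findInterval(vals, edges, rightmost.closed = TRUE),
    nbins = length(mids))
  list(mids = mids, edges = edges, counts = counts, n = length(vals),
       bin_width = bin_width, region = region)
}

# gather valid pixel values of a region across difference maps
pooled_pixels <- function(diffs, region = "full", region_maps = NULL) {
  if (region != "full" && is.null(region_maps))
    stop("region_maps required for region '", region, "'")
  out <- vector("list", length(diffs))
  for (i in seq_along(diffs)) {
    d <- diffs[[i]]
    stopifnot(inherits(d, "dose_difference_map"))
    sel <- d$valid
    if (region != "full") sel <- sel & (region_maps[[i]] == region)
    out[[i]] <- d$diff[sel]
  }
  unlist(out)
}

#' Fit a Gaussian to a histogram
#'
#' Nonlinear least squares of `A * exp(-(x - mu)^2 / (2 * sigma^2))` to the
#' bin counts at the bin centres, initialised from the count-weighted
#' moments. Reports the coefficient standard errors and the coefficient of
#' determination against the counts.
#'
#' @param histogram result of [pooled_histogram()].
#' @return An object of class `gaussian_fit`: `mean`, `sd`, `amplitude`
#'   (all in histogram units), `r_squared`, `se_mean`, `se_sd`,
#'   `coefficient_uncertainty` (the larger of the two standard errors).
#' @export
fit_gaussian <- function(histogram) {
  x <- histogram$mids
  y <- histogram$counts
  if (sum(y > 0) < 5)
    stop("need at least 5 non-empty bins for a Gaussian fit")
  n <- sum(y)
  mu0 <- sum(x * y) / n
  sd0 <- sqrt(max(sum(y * (x - mu0)^2) / n, histogram$bin_width^2 / 12))
  a0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(A = a0, mu = mu0, sigma = sd0),
      lower = c(0, -Inf, 1e-6),
      fn = function(p) y - p$A * exp(-(x - p$mu)^2 / (2 * p$sigma^2)),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e)
      stop("Gaussian fit failed (start A=", signif(a0, 4),
           ", mu=", signif(mu0, 4), ", sigma=", signif(sd0, 4), "): ",
           conditionMessage(e)))
  if (fit$info == 0 || fit$info == 5)
    stop("Gaussian fit did not converge (start A=", signif(a0, 4),
         ", mu=", signif(mu0, 4), ", sigma=", signif(sd0, 4), "): ",
         fit$message)
  p <- unlist(fit$par)
  se <- tryCatch(coef(summary(fit))[, "Std. Error"], error = function(e)
    c(NA_real_, NA_real_, NA_real_))
  res <- fit$fvec
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(mean = unname(p["mu"]), sd = abs(unname(p["sigma"])),
                 amplitude = unname(p["A"]), r_squared = r2,
                 se_mean = unname(se[2]), se_sd = unname(se[3]),
                 coefficient_uncertainty = max(se[2:3])),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mean %.2f%%, sd %.2f%% (R^2 = %.4f)\n",
              x$mean, x$sd, x$r_squared))
  invisible(x)
}

#' Compare two algorithms' dose-difference distributions
#'
#' Tests whether the calculated-minus-measured distributions of two dose
#' algorithms differ. Two variants: a Welch two-sample t-test on the pooled
#' pixels (the literal pixel-pool reading; spatially autocorrelated pixels
#' inflate its n), and a paired t-test on per-case mean differences (the
#' conservative default).
#'
#' @param diffs_a,diffs_b lists of [dose_difference()] maps, one per case;
#'   the paired variant requires the lists to be parallel (same cases in
#'   the same order).
#' @param variant `"per_case_paired"` (default) or `"pooled_welch"`.
#' @param region,region_maps optional region restriction, as in
#'   [pooled_histogram()].
#' @return An object of class `t_test_result`: `statistic`, `p_value`,
#'   `df`, `variant`.
#' @export
compare_algorithms <- function(diffs_a, diffs_b,
                               variant = c("per_case_paired",
                                           "pooled_welch"),
                               region = "full", region_maps = NULL) {
  variant <- match.arg(variant)
  if (length(diffs_a) == 0 || length(diffs_b) == 0)
    stop("both pixel pools must be non-empty")
  if (variant == "pooled_welch") {
    a <- pooled_pixels(diffs_a, region, region_maps)
    b <- pooled_pixels(diffs_b, region, region_maps)
    if (identical(a, b))
      return(structure(list(statistic = 0, p_value = 1,
                            df = 2 * length(a) - 2, variant = variant),
                       class = "t_test_result"))
    tt <- t.test(a, b, var.equal = FALSE)
  } else {
    if (length(diffs_a) != length(diffs_b))
      stop("per-case paired variant requires matched cases")
    mean_of <- function(d, rm) {
      sel <- d$valid
      if (region != "full") sel <- sel & (rm == region)
      mean(d$diff[sel])
    }
    rms <- if (is.null(region_maps)) vector("list", length(diffs_a)) else
      region_maps
    a <- mapply(mean_of, diffs_a, rms)
    b <- mapply(mean_of, diffs_b, rms)
    if (length(a) < 2)
      stop("per-case paired variant requires at least 2 cases")
    if (all(abs(a - b) < 1e-15))
      return(structure(list(statistic = 0, p_value = 1,
                            df = length(a) - 1, variant = variant),
                       class = "t_test_result"))
    tt <- t.test(a, b, paired = TRUE)
  }
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 variant = variant),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> %s: t = %.3f, df = %.1f, p = %.3g\n",
              x$variant, x$statistic, x$df, x$p_value))
  invisible(x)
}
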