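# Cumulative dose-volume histograms and Dx% extraction for skin structures.

#' Cumulative DVH of a structure
#'
#' Doses are sampled at the structure's voxel centres by trilinear
#' interpolation (the dose lattice usually differs from the CT lattice),
#' expressed as percent of prescription, and binned with equal voxel
#' weighting: the curve value at a dose edge is the fraction of voxels
#' receiving at least that dose.
#'
#' @param dose a [dose_grid()].
#' @param mask a non-empty [structure_mask()] covered by the dose grid.
#' @param bin_width DVH bin width, percent of prescription (default 0.5).
#' @return An object of class `dvh_curve`: `dose_edges` (percent),
#'   `cum_vol_fraction` (1 at 0 dose, monotone non-increasing, 0 above the
#'   maximum), `voxel_count`, `structure_label`, `bin_width`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.5) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  idx <- which(mask$mask)
  if (length(idx) == 0) stop("empty structure mask")
  pts <- voxel_centres(idx, dim(mask$mask), mask$spacing, mask$origin)
  d_gy <- trilinear_sample(dose$dose, dose$spacing, dose$origin, pts,
                           outside = "error")
  pct <- 100 * d_gy / dose$prescription
  dvh_from_doses(pct, bin_width, mask$label)
}

# cumulative DVH from a vector of per-voxel doses (percent)
dvh_from_doses <- function(pct, bin_width = 0.5, label = "structure") {
  edges <- seq(0, ceiling(max(pct) / bin_width) * bin_width + bin_width,
               by = bin_width)
  n <- length(pct)
  # fraction receiving >= edge, via one sort
  srt <- sort(pct)
  cum <- (n - findInterval(edges - 1e-12, srt)) / n
  structure(list(dose_edges = edges, cum_vol_fraction = cum,
                 voxel_count = n, structure_label = label,
                 bin_width = bin_width),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat("<dvh_curve> '", x$structure_label, "': ", x$voxel_count,
      " voxels, D50% = ", signif(dose_at_volume(x, 50), 4), "%\n", sep = "")
  invisible(x)
}

#' Dose received by the hottest fraction of a structure
#'
#' Dx% under the hottest-x% convention: the largest dose edge at which the
#' cumulative volume fraction is still at least `volume_pct / 100` (the
#' minimum dose received by the hottest x% of the volume, resolved at the
#' DVH bin width). For a uniform dose the result is exact; generally it
#' agrees with the order-statistic quantile to within one bin width.
#'
#' @param curve a [compute_dvh()] result.
#' @param volume_pct volume percentage in (0, 100]; 50 gives the median
#'   structure dose D50%.
#' @return dose in percent of prescription.
#' @export
dose_at_volume <- function(curve, volume_pct) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (volume_pct <= 0 || volume_pct > 100)
    stop("volume_pct must be in (0, 100]")
  target <- volume_pct / 100
  ok <- which(curve$cum_vol_fraction >= target - 1e-12)
  if (length(ok) == 0) return(curve$dose_edges[1])
  curve$dose_edges[max(ok)]
}

#' Summarise D50% across cases, structures and algorithms
#'
#' Builds the median-structure-dose summary table (one column per
#' algorithm x structure, rows mean and SD across cases).
#'
#' @param d50 data.frame with columns `case`, `algorithm`, `structure`,
#'   `d50` (percent of prescription).
#' @return data.frame with columns `statistic` (`mean`, `sd`) and one
#'   column per `<algorithm>_<structure>`.
#' @export
summarize_structures <- function(d50) {
  need <- c("case", "algorithm", "structure", "d50")
  if (!all(need %in% names(d50)))
    stop("d50 must have columns: ", paste(need, collapse = ", "))
  algs <- unique(d50$algorithm)
  strs <- unique(d50$structure)
  cases <- unique(d50$case)
  for (a in algs) for (s in strs) {
    got <- d50$case[d50$algorithm == a & d50$structure == s]
    if (!setequal(got, cases) || anyDuplicated(got))
      stop("inconsistent case sets across algorithm/structure cells")
  }
  out <- data.frame(statistic = c("mean", "sd"))
  for (a in algs) {
    for (s in strs) {
      v <- d50$d50[d50$algorithm == a & d50$structure == s]
      out[[paste0(a, "_", s)]] <- c(mean(v), if (length(v) > 1) sd(v) else 0)
    }
  }
  out
}
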