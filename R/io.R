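# Plain-text and TIFF readers/writers for dose maps, scans, calibration
# sets and run configurations.

#' Write a film-resolution dose map as CSV
#'
#' Matrix CSV with a small commented header carrying the pixel spacing and
#' provenance; invalid pixels are written as `NA`. Round-trips through
#' [read_dose_map_csv()].
#'
#' @param map a [film_dose_map()].
#' @param path output file path.
#' @export
write_dose_map_csv <- function(map, path) {
  stopifnot(inherits(map, "film_dose_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pixel_spacing_cm: %.10g", map$pixel_spacing),
               sprintf("# provenance: %s", map$provenance)), con)
  dose <- map$dose
  dose[!map$valid] <- NA_real_
  write.table(format(dose, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
}

#' Read a film-resolution dose map written by [write_dose_map_csv()]
#'
#' @param path input file path.
#' @return A [film_dose_map()].
#' @export
read_dose_map_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  spacing <- as.numeric(sub("# pixel_spacing_cm: ", "", hdr[1]))
  prov <- sub("# provenance: ", "", hdr[2])
  m <- as.matrix(read.csv(path, header = FALSE, comment.char = "#"))
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  film_dose_map(m, spacing, !is.na(m), prov)
}

#' Write a dose map as 32-bit TIFF
#'
#' Visualisation export: dose is scaled by `full_scale` into the `[0, 1]`
#' sample range TIFF stores, and invalid pixels are written as zero. The
#' CSV writer ([write_dose_map_csv()]) is the lossless format.
#'
#' @param map a [film_dose_map()].
#' @param path output file path.
#' @param full_scale dose (percent of prescription) mapped to 1.0.
#' @export
write_dose_map_tiff <- function(map, path, full_scale = 200) {
  stopifnot(inherits(map, "film_dose_map"))
  x <- map$dose / full_scale
  x[!map$valid] <- 0
  x <- pmin(pmax(x, 0), 1)
  tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write a synthetic film scan as 16-bit RGB TIFF
#'
#' Channels are scaled from native units to `[0, 1]` by `scale_max` (the
#' scanner's full-scale value) as TIFF stores normalised samples; the DPI
#' is recorded in the resolution tags.
#'
#' @param scan a [film_scan_image()].
#' @param path output file path.
#' @param scale_max full-scale channel value (default `2^16 - 1`).
#' @export
write_film_scan_tiff <- function(scan, path, scale_max = 65535) {
  stopifnot(inherits(scan, "film_scan_image"))
  px <- pmin(pmax(scan$pixels / scale_max, 0), 1)
  tiff::writeTIFF(px, path, bits.per.sample = 16L,
                  reduce = FALSE)
  invisible(path)
}

#' Read an RGB TIFF film scan
#'
#' Accepts 8- or 16-bit RGB TIFFs; values are rescaled back to native
#' units with `scale_max`. DPI is taken from the file's resolution tags
#' when present, else from `default_dpi`.
#'
#' @param path TIFF file path.
#' @param scale_max full-scale channel value (default `2^16 - 1`).
#' @param default_dpi fallback resolution.
#' @return A [film_scan_image()].
#' @export
read_film_scan_tiff <- function(path, scale_max = 65535,
                                default_dpi = 72) {
  px <- tiff::readTIFF(path, info = TRUE)
  info <- attributes(px)
  dpi <- default_dpi
  if (!is.null(info$x.resolution) && is.finite(info$x.resolution) &&
      info$x.resolution > 0)
    dpi <- info$x.resolution
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  film_scan_image(px * scale_max, dpi = dpi)
}

#' Read a calibration set from CSV
#'
#' Expects columns `dose_Gy` and `mean_green_response`.
#'
#' @param path CSV file path.
#' @return data.frame with the two columns, sorted by dose.
#' @export
read_calibration_csv <- function(path) {
  d <- read.csv(path)
  need <- c("dose_Gy", "mean_green_response")
  if (!all(need %in% names(d)))
    stop("calibration CSV must have columns: ",
         paste(need, collapse = ", "))
  d[order(d$dose_Gy), need]
}

#' Default synthetic calibration curve
#'
#' The rational green-channel response used by the synthetic pipeline:
#' darkening film, 16-bit scanner scale, calibrated over 0-4 Gy. A matching
#' calibration set ships in `inst/extdata/synthetic_calibration.csv`.
#'
#' @return A `calibration_curve`.
#' @export
default_calibration_curve <- function() {
  curve <- structure(list(a = 100000, b = 12000, c = 2.5,
                          valid_dose_range = c(0, 4)),
                     class = "calibration_curve")
  curve$residuals <- numeric(0)
  curve$response_range <- range(cal_response(curve,
                                             curve$valid_dose_range))
  curve
}

#' Write a 3D grid as a self-describing text container
#'
#' Gzipped text: a JSON header line (dims, spacing, origin, kind) followed
#' by the flattened values, one per line. Intended for persisting synthetic
#' CT/dose volumes without a DICOM dependency.
#'
#' @param values 3D array.
#' @param spacing,origin lattice geometry.
#' @param path output path (`.txt.gz` recommended).
#' @param kind free-text content label.
#' @export
write_grid_container <- function(values, spacing, origin, path,
                                 kind = "grid") {
  con <- gzfile(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(dim = dim(values), spacing = spacing,
                               origin = origin, kind = kind),
                          auto_unbox = FALSE, digits = NA)
  writeLines(as.character(hdr), con)
  writeLines(format(as.vector(values), digits = 10, trim = TRUE,
                    scientific = TRUE), con)
}

#' Read a grid container written by [write_grid_container()]
#'
#' @param path input path.
#' @return list with `values` (3D array), `spacing`, `origin`, `kind`.
#' @export
read_grid_container <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1))
  vals <- as.numeric(readLines(con))
  list(values = array(vals, hdr$dim), spacing = hdr$spacing,
       origin = hdr$origin, kind = hdr$kind)
}
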