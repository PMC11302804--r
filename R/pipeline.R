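# End-to-end orchestration: synthetic cohort generation through report
# tables.
#
# A "case" plays the role of one patient: a jittered phantom, three dose
# grids (ground truth and the two algorithm-like profiles), skin
# structures and DVHs, and — when the film stage is enabled — simulated
# film fractions processed to a mean measured map, registered and compared
# to the unfolded TPS maps by dose difference and gamma analysis.

#' Build a run configuration
#'
#' All knobs of the synthetic end-to-end pipeline with study-condition
#' defaults: an 18-case cohort, CT at 0.12 x 0.12 x 0.25 cm, 0.1 cm dose
#' lattice, 42.5 Gy in 16 fractions, 0.2/0.5 cm rinds, gamma at 0.5 cm DTA
#' with 7% and 10% tolerances, film noise SD 7.5% with inferior ridge
#' artefacts, and three measured fractions per case.
#'
#' @param ... named overrides of the defaults (nested lists are merged
#'   shallowly per top-level name).
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    mode = "synthetic",
    seed = 1L,
    n_cases = 18L,
    phantom = list(breast_radius = 3.4, breast_length = 25,
                   cradle_tilt = 12, cradle_thickness = 0.3,
                   ct_spacing = c(0.12, 0.12, 0.25),
                   dose_grid_spacing = 0.1, prescription = 42.5,
                   n_fractions = 16L, lateral_extent = 11,
                   inferior_extent = 14),
    profiles = list(truth_surface_fraction = 0.80, buildup_length = 0.4,
                    aaa_offset = -0.04, aaa_deficit = 4,
                    axb_offset = +0.03, axb_deficit = 2.3),
    case_jitter = list(radius_rel_sd = 0.05, surface_fraction_sd = 0.05,
                       buildup_rel_sd = 0.05),
    noise = list(systematic_offset = 0, noise_sd = 7.5,
                 ridge_amplitude = 2, ridge_period = 0.5,
                 misalign_translation_sd = 1.5,
                 misalign_rotation_sd = 0.75),
    film_fractions = 3L,
    trim_pixels = 2L,
    denoise_order = "wiener_median",
    body_hu_band = c(-300, 3071),
    cradle_hu_band = c(-800, -600),
    extended_body_cm = 2.0,
    rind_thicknesses = c(0.2, 0.5),
    restrict_rind_to_footprint = TRUE,
    dvh_bin_width = 0.5,
    gamma_criteria = list(list(dta = 0.5, dose_tol = 7),
                          list(dta = 0.5, dose_tol = 10)),
    registration = list(max_shift = 0.5, max_rotation = 4),
    with_film = TRUE,
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Reports problems without stopping: `error` findings make
#' [run_pipeline()] refuse to start, `warning` findings are informational
#' (for instance a body HU band that covers only air — a sign of an
#' inverted threshold — or a suspiciously small dose tolerance).
#'
#' @param config a [run_config()].
#' @return data.frame with columns `level`, `field`, `message`; zero rows
#'   when the configuration is clean.
#' @export
validate_config <- function(config) {
  f <- list()
  add <- function(level, field, message)
    f[[length(f) + 1]] <<- data.frame(level = level, field = field,
                                      message = message)
  if (!config$mode %in% c("synthetic", "real"))
    add("error", "mode", "mode must be 'synthetic' or 'real'")
  if (config$n_cases < 1) add("error", "n_cases", "n_cases must be >= 1")
  if (any(config$rind_thicknesses < 0))
    add("error", "rind_thicknesses", "rind thicknesses must be >= 0")
  ph <- config$phantom
  if (any(unlist(ph[c("breast_radius", "breast_length",
                      "dose_grid_spacing", "prescription")]) <= 0))
    add("error", "phantom", "phantom lengths and prescription must be > 0")
  if (abs(ph$lateral_extent + ph$inferior_extent - ph$breast_length) >
      1e-6)
    add("error", "phantom",
        "lateral_extent + inferior_extent must equal breast_length")
  band <- config$body_hu_band
  if (band[1] > band[2])
    add("error", "body_hu_band", "body HU band is inverted (lo > hi)")
  else if (band[2] <= -950)
    add("warning", "body_hu_band",
        paste("body HU band lies entirely in the air range (<= -950 HU);",
              "published threshold bands are sometimes quoted with",
              "inverted signs - the body segmentation would select air"))
  if (config$film_fractions < 1)
    add("error", "film_fractions", "film_fractions must be >= 1")
  for (gc in config$gamma_criteria) {
    if (gc$dta <= 0 || gc$dose_tol <= 0)
      add("error", "gamma_criteria", "dta and dose_tol must be > 0")
  }
  if (config$noise$noise_sd < 0)
    add("error", "noise", "noise_sd must be >= 0")
  if (length(f) == 0)
    return(data.frame(level = character(), field = character(),
                      message = character()))
  do.call(rbind, f)
}

# per-case jittered phantom spec + profiles, drawn from the case RNG
case_parameters <- function(config, case_id) {
  j <- config$case_jitter
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  radius <- config$phantom$breast_radius *
    clamp(1 + rnorm(1, 0, j$radius_rel_sd), 0.85, 1.15)
  s_truth <- clamp(config$profiles$truth_surface_fraction +
                     rnorm(1, 0, j$surface_fraction_sd), 0.55, 0.95)
  lambda <- config$profiles$buildup_length *
    clamp(1 + rnorm(1, 0, j$buildup_rel_sd), 0.8, 1.2)
  spec <- do.call(phantom_spec,
                  modifyList(config$phantom,
                             list(breast_radius = radius)))
  profiles <- default_profiles(
    truth_surface_fraction = s_truth,
    buildup_length = lambda,
    aaa_offset = config$profiles$aaa_offset,
    aaa_deficit = config$profiles$aaa_deficit,
    axb_offset = config$profiles$axb_offset,
    axb_deficit = config$profiles$axb_deficit)
  list(spec = spec, profiles = profiles,
       meta = data.frame(case = case_id, radius = radius,
                         s_truth = s_truth, buildup = lambda))
}

#' Run a single synthetic case
#'
#' Generates the phantom, builds the skin structures, computes the DVH
#' D50% table rows, and (unless `config$with_film` is `FALSE`) simulates
#' and processes the film measurement and compares it against the
#' unfolded algorithm-like dose maps.
#'
#' @param config a [run_config()].
#' @param case_id integer case index (1-based).
#' @return list with `d50` (data.frame rows), `gamma_rates` (data.frame),
#'   `diffs` (named list of [dose_difference()] maps), `regions` (label
#'   matrix), `meta`.
#' @export
run_case <- function(config, case_id) {
  seed_case <- as.integer(config$seed) + 7919L * as.integer(case_id)
  pars <- with_local_seed(seed_case, case_parameters(config, case_id))
  spec <- pars$spec
  profiles <- pars$profiles

  ph <- generate_phantom_ct(spec)
  body <- threshold_structure(ph$ct, config$body_hu_band[1],
                              config$body_hu_band[2],
                              keep_largest = TRUE, label = "body")
  cradle <- threshold_structure(ph$ct, config$cradle_hu_band[1],
                                config$cradle_hu_band[2], label = "cradle")
  extended <- expand_contour(body, config$extended_body_cm)
  contact <- contact_surface(body, cradle)
  rinds <- list(surface = contact)
  for (th in config$rind_thicknesses) {
    r <- make_rind(contact, body, th)
    if (config$restrict_rind_to_footprint)
      r <- restrict_to_footprint(r, contact, spec)
    rinds[[sprintf("rind%02.0f", th * 10)]] <- r
  }

  # dose grids: shared lattice/depth, per-profile closed-form buildup
  lat <- ct_lattice(spec, spacing = rep(spec$dose_grid_spacing, 3),
                    margin = 1.0)
  mem <- phantom_membership(spec, lat)
  depth <- edt_distance(!mem$body, lat$spacing)
  grids <- lapply(profiles, function(p)
    dose_grid(buildup_dose(spec, p, lat, depth, mem$body), lat$spacing,
              lat$origin, spec$prescription))

  d50 <- list()
  for (alg in c("aaa_like", "axb_like")) {
    for (sn in names(rinds)) {
      curve <- compute_dvh(grids[[alg]], rinds[[sn]],
                           bin_width = config$dvh_bin_width)
      d50[[length(d50) + 1]] <-
        data.frame(case = case_id, algorithm = alg, structure = sn,
                   d50 = dose_at_volume(curve, 50))
    }
  }
  d50 <- do.call(rbind, d50)
  out <- list(d50 = d50, meta = pars$meta, case = case_id)
  if (!isTRUE(config$with_film)) return(out)

  # unfold the three dose grids over the shared contact contour
  maps <- lapply(grids, function(g)
    rasterize_to_film_grid(unfold_surface(
      extract_surface_dose(g, contact))))
  regions <- segment_lat_inf(maps$truth, spec$lateral_extent,
                             spec$inferior_extent)

  # simulate and process the film measurement
  noise <- do.call(film_noise_model,
                   c(config$noise, list(seed = seed_case + 17L)))
  fractions <- generate_film_measurement(maps$truth, noise,
                                         config$film_fractions,
                                         ridge_mask = regions == "inferior")
  cal <- default_calibration_curve()
  rx_fx <- spec$prescription / spec$n_fractions
  processed <- lapply(fractions, function(fx) {
    scan <- render_film_scan(fx, cal, rx_fx)
    m <- apply_calibration(scan, cal, rx_fx)
    m <- trim_edges(m, config$trim_pixels)
    denoise(m, order = config$denoise_order)
  })
  if (length(processed) > 1) {
    fixedm <- processed[[1]]
    for (i in seq_along(processed)[-1]) {
      processed[[i]] <- register_rigid(
        processed[[i]], fixedm,
        max_shift = config$registration$max_shift,
        max_rotation = config$registration$max_rotation)$registered
    }
  }
  film_mean <- average_fractions(processed)

  # bring the measurement into the TPS frame and compare
  reg <- register_rigid(film_mean, maps$aaa_like,
                        max_shift = config$registration$max_shift,
                        max_rotation = config$registration$max_rotation)
  film_reg <- mask_to_contact(reg$registered, maps$aaa_like)

  diffs <- list()
  rates <- list()
  for (alg in c("aaa_like", "axb_like")) {
    diffs[[alg]] <- dose_difference(maps[[alg]], film_reg)
    for (gc in config$gamma_criteria) {
      gm <- gamma_index(film_reg, maps[[alg]],
                        gamma_criteria(dta = gc$dta,
                                       dose_tol = gc$dose_tol))
      pr <- gamma_pass_rates(gm, regions)
      pr$case <- case_id
      pr$algorithm <- alg
      pr$dta <- gc$dta
      pr$dose_tol <- gc$dose_tol
      rates[[length(rates) + 1]] <- pr
    }
  }
  out$meta$film_ncc <- reg$ncc
  out$meta$extended_body_voxels <- sum(extended$mask)
  out$diffs <- diffs
  out$regions <- regions
  out$gamma_rates <- do.call(rbind, rates)
  out
}

#' Run the full pipeline and assemble the report bundle
#'
#' Executes every case of the configured cohort and assembles the report:
#' the D50% summary across skin structures (table 1 shape), the rind-shift
#' and calculated-minus-measured summary (table 2 shape), the gamma
#' pass-rate summary (table 3 shape), and the pooled dose-difference
#' histograms with Gaussian fits per algorithm and region. Fully
#' deterministic for a given seed.
#'
#' @param config a [run_config()].
#' @param progress print per-case progress messages.
#' @return An object of class `report_bundle`.
#' @export
run_pipeline <- function(config = run_config(), progress = FALSE) {
  findings <- validate_config(config)
  if (any(findings$level == "error"))
    stop("invalid configuration:\n",
         paste(findings$message[findings$level == "error"],
               collapse = "\n"))
  cases <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    if (progress) message("case ", i, "/", config$n_cases)
    cases[[i]] <- tryCatch(run_case(config, i), error = function(e)
      stop("case ", i, " failed: ", conditionMessage(e)))
  }
  d50_all <- do.call(rbind, lapply(cases, `[[`, "d50"))
  meta <- do.call(rbind, lapply(cases, `[[`, "meta"))
  table1 <- summarize_structures(d50_all)

  bundle <- list(config = config, d50 = d50_all, meta = meta,
                 table1 = table1)
  if (isTRUE(config$with_film)) {
    gamma_all <- do.call(rbind, lapply(cases, `[[`, "gamma_rates"))
    table3 <- gamma_report(gamma_all)
    region_maps <- lapply(cases, `[[`, "regions")
    hists <- list()
    fits <- list()
    for (alg in c("aaa_like", "axb_like")) {
      diffs <- lapply(cases, function(cs) cs$diffs[[alg]])
      for (reg in c("full", "lateral", "inferior")) {
        key <- paste(alg, reg, sep = "_")
        h <- pooled_histogram(diffs, reg, region_maps)
        hists[[key]] <- h
        fits[[key]] <- tryCatch(fit_gaussian(h), error = function(e) {
          # degenerate histogram (e.g. zero-noise runs): fall back on
          # moment estimates so the report stays complete
          vals <- pooled_pixels(diffs, reg, region_maps)
          structure(list(mean = mean(vals), sd = sd(vals),
                         amplitude = NA_real_, r_squared = NA_real_,
                         se_mean = NA_real_, se_sd = NA_real_,
                         coefficient_uncertainty = NA_real_),
                    class = "gaussian_fit")
        })
      }
      }
    table2 <- build_table2(table1, fits)
    ttests <- list()
    diffs_a <- lapply(cases, function(cs) cs$diffs[["aaa_like"]])
    diffs_b <- lapply(cases, function(cs) cs$diffs[["axb_like"]])
    for (reg in c("full", "lateral", "inferior")) {
      for (variant in c("per_case_paired", "pooled_welch")) {
        if (variant == "per_case_paired" && config$n_cases < 2) next
        ttests[[paste(reg, variant, sep = "_")]] <-
          compare_algorithms(diffs_a, diffs_b, variant, reg, region_maps)
      }
    }
    bundle$gamma_rates <- gamma_all
    bundle$table3 <- table3
    bundle$histograms <- hists
    bundle$gaussian_fits <- fits
    bundle$table2 <- table2
    bundle$ttests <- ttests
    bundle$diffs <- list(aaa_like = diffs_a, axb_like = diffs_b)
    bundle$region_maps <- region_maps
  }
  class(bundle) <- "report_bundle"
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

# Table-2-shaped summary: the D50% increase from the surface layer to each
# rind, and calculated-minus-measured cells per region obtained by adding
# that increase to the fitted surface-layer difference.
build_table2 <- function(table1, fits) {
  algs <- c("aaa_like", "axb_like")
  strs <- c("surface", "rind02", "rind05")
  mean_row <- table1[table1$statistic == "mean", ]
  incr <- list()
  for (a in algs) {
    for (s in strs) {
      incr[[paste(a, s, sep = "_")]] <-
        mean_row[[paste(a, s, sep = "_")]] -
        mean_row[[paste(a, "surface", sep = "_")]]
    }
  }
  rows <- list()
  r1 <- list(row = "tps_increase")
  for (a in algs) for (s in strs)
    r1[[paste(a, s, sep = "_")]] <- incr[[paste(a, s, sep = "_")]]
  rows[[1]] <- as.data.frame(r1)
  for (reg in c("full", "lateral", "inferior")) {
    r <- list(row = reg)
    for (a in algs) {
      base <- fits[[paste(a, reg, sep = "_")]]$mean
      for (s in strs)
        r[[paste(a, s, sep = "_")]] <- base + incr[[paste(a, s, sep = "_")]]
    }
    rows[[length(rows) + 1]] <- as.data.frame(r)
  }
  do.call(rbind, rows)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", x$config$n_cases, " case(s)\n", sep = "")
  cat("\nD50% summary (percent of prescription):\n")
  print(x$table1, row.names = FALSE, digits = 3)
  if (!is.null(x$table2)) {
    cat("\nRind shifts and calculated - measured means (percent):\n")
    print(x$table2, row.names = FALSE, digits = 3)
    cat("\nGamma pass rates (percent):\n")
    print(x$table3, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' CSV tables (D50% summary, rind-shift/difference summary, gamma summary),
#' per-case D50% and gamma pass-rate tables, Gaussian fit parameters, and a
#' plain-text run log with the seed and configuration.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param write_maps also write every per-case difference map as CSV
#'   (large; default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir, write_maps = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(bundle$table1, "table1_d50_summary.csv")
  wr(bundle$d50, "per_case_d50.csv")
  wr(bundle$meta, "per_case_parameters.csv")
  if (!is.null(bundle$table2)) {
    wr(bundle$table2, "table2_differences.csv")
    wr(bundle$table3, "table3_gamma_summary.csv")
    wr(bundle$gamma_rates, "per_case_gamma.csv")
    fits <- do.call(rbind, lapply(names(bundle$gaussian_fits), function(k) {
      f <- bundle$gaussian_fits[[k]]
      data.frame(cell = k, mean = f$mean, sd = f$sd,
                 amplitude = f$amplitude, r_squared = f$r_squared,
                 se_mean = f$se_mean, se_sd = f$se_sd)
    }))
    wr(fits, "figure4_gaussian_fits.csv")
    hist_rows <- do.call(rbind, lapply(names(bundle$histograms),
                                       function(k) {
      h <- bundle$histograms[[k]]
      data.frame(cell = k, mid = h$mids, count = h$counts)
    }))
    wr(hist_rows, "figure4_histograms.csv")
    tt <- do.call(rbind, lapply(names(bundle$ttests), function(k) {
      t <- bundle$ttests[[k]]
      data.frame(comparison = k, statistic = t$statistic,
                 p_value = t$p_value, df = t$df, variant = t$variant)
    }))
    wr(tt, "t_tests.csv")
    if (write_maps) {
      mdir <- file.path(dir, "cases")
      dir.create(mdir, showWarnings = FALSE)
      for (alg in names(bundle$diffs)) {
        for (i in seq_along(bundle$diffs[[alg]])) {
          d <- bundle$diffs[[alg]][[i]]
          m <- film_dose_map(d$diff, d$pixel_spacing, d$valid,
                             paste0("diff_", alg, "_case", i))
          write_dose_map_csv(m, file.path(
            mdir, sprintf("diff_%s_case%02d.csv", alg, i)))
        }
      }
    }
  }
  cfg_path <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(unclass(bundle$config), cfg_path)
  log_lines <- c(
    paste0("dermadose ", as.character(utils::packageVersion("dermadose"))),
    paste0("R ", R.version.string),
    paste0("seed: ", bundle$config$seed),
    paste0("n_cases: ", bundle$config$n_cases),
    paste0("config_md5: ", unname(tools::md5sum(cfg_path))),
    paste0("written: table1", if (!is.null(bundle$table2))
      ", table2, table3, figure4" else ""))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
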