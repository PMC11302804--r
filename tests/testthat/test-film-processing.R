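# Calibration, trimming, filtering, registration, fraction averaging.

test_that("calibration fit recovers rational curves", {
  a <- 100000; b <- 12000; cc <- 2.5
  resp <- function(d) (a + b * d) / (cc + d)
  # three exact points: interpolation is exact
  d3 <- c(0, 1, 3)
  cal3 <- fit_calibration(d3, resp(d3))
  expect_lt(max(abs((cal3$a + cal3$b * d3) / (cal3$c + d3) - resp(d3))),
            1e-9)
  # eight noiseless points: coefficients recovered
  d8 <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4)
  cal8 <- fit_calibration(d8, resp(d8))
  expect_lt(abs(cal8$a - a) / a, 1e-6)
  expect_lt(abs(cal8$b - b) / b, 1e-6)
  expect_lt(abs(cal8$c - cc) / cc, 1e-6)
  # duplicate responses and non-monotone responses are rejected
  expect_error(fit_calibration(c(0, 1, 2), c(5, 5, 4)), "monotone")
  expect_error(fit_calibration(c(0, 1, 2), c(5, 7, 4)), "monotone")
  expect_error(fit_calibration(c(0, 0, 0), c(5, 6, 7)), "distinct")
})

test_that("calibration fixture file matches the default curve", {
  path <- system.file("extdata", "synthetic_calibration.csv",
                      package = "dermadose")
  tab <- read_calibration_csv(path)
  cal <- fit_calibration(tab$dose_Gy, tab$mean_green_response)
  def <- default_calibration_curve()
  expect_equal(cal$a, def$a, tolerance = 1e-4)
  expect_equal(cal$b, def$b, tolerance = 1e-4)
  expect_equal(cal$c, def$c, tolerance = 1e-4)
})

test_that("calibration round trip reproduces the dose map", {
  cal <- default_calibration_curve()
  set.seed(5)
  dose <- matrix(runif(40 * 30, 20, 110), 40, 30)
  map <- film_dose_map(dose, 2.54 / 72, provenance = "truth")
  rx <- 2.656
  scan <- render_film_scan(map, cal, rx)
  back <- apply_calibration(scan, cal, rx)
  expect_lt(max(abs(back$dose - dose)), 0.01)
  expect_equal(back$pixel_spacing, 2.54 / 72)
  # uniform zero-dose scan -> uniform 0% map
  zero <- render_film_scan(
    film_dose_map(matrix(0, 10, 10), 2.54 / 72), cal, rx)
  z <- apply_calibration(zero, cal, rx)
  expect_true(all(abs(z$dose) < 1e-9))
})

test_that("out-of-range responses are masked rather than clipped", {
  cal <- default_calibration_curve()
  px <- array(cal_resp <- (cal$a + cal$b * 1) / (cal$c + 1), c(3, 3, 3))
  px[2, 2, 2] <- 1e5 # brighter than the zero-dose response
  scan <- film_scan_image(px, dpi = 72)
  m <- apply_calibration(scan, cal, 2.656)
  expect_false(m$valid[2, 2])
  expect_true(all(m$valid[-5]))
  expect_true(is.na(m$dose[2, 2]))
})

test_that("edge trimming erodes the mask by a Chebyshev margin", {
  full <- film_dose_map(matrix(50, 100, 100), 0.05)
  tr <- trim_edges(full, 2)
  expect_equal(sum(tr$valid), 96 * 96)
  expect_true(all(tr$valid[3:98, 3:98]))
  # n = 0 is the identity
  expect_identical(trim_edges(full, 0)$valid, full$valid)
  # idempotent-safe composition
  expect_identical(trim_edges(trim_edges(full, 2), 0)$valid, tr$valid)
  expect_error(trim_edges(film_dose_map(matrix(1, 4, 10), 0.05), 2),
               "small")
})

test_that("trimming an irregular stencil matches the per-pixel oracle", {
  set.seed(8)
  nr <- 30; nc <- 25
  valid <- matrix(runif(nr * nc) > 0.25, nr, nc)
  dose <- matrix(rnorm(nr * nc, 80, 5), nr, nc)
  dose[!valid] <- NA
  map <- film_dose_map(dose, 0.05, valid)
  n <- 2
  tr <- trim_edges(map, n)
  oracle <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!valid[i, j]) next
      keep <- TRUE
      for (di in -n:n) {
        for (dj in -n:n) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc || !valid[ii, jj])
            keep <- FALSE
        }
      }
      oracle[i, j] <- keep
    }
  }
  expect_identical(tr$valid, oracle)
})

test_that("denoising preserves constants and removes impulses", {
  const <- film_dose_map(matrix(70, 20, 20), 0.05)
  for (ord in c("wiener_median", "median_wiener")) {
    out <- denoise(const, order = ord)
    expect_equal(out$dose, const$dose)
  }
  # single impulse on constant background is removed by the median stage
  imp <- matrix(70, 20, 20); imp[10, 10] <- 120
  out <- denoise(film_dose_map(imp, 0.05), order = "median_wiener")
  expect_equal(out$dose[10, 10], 70)
  # maps smaller than the window pass through with a warning
  tiny <- film_dose_map(matrix(1, 3, 3), 0.05)
  expect_warning(out <- denoise(tiny), "window")
  expect_equal(out$dose, tiny$dose)
})

test_that("denoise equals sequential reference filters", {
  set.seed(12)
  nr <- 24; nc <- 18
  valid <- matrix(runif(nr * nc) > 0.15, nr, nc)
  dose <- matrix(rnorm(nr * nc, 80, 8), nr, nc)
  dose[!valid] <- NA
  map <- film_dose_map(dose, 0.05, valid)
  out <- denoise(map, order = "wiener_median")
  ref1 <- ref_wiener_filter(dose, valid)
  ref2 <- ref_median_filter(ref1, valid)
  expect_lt(max(abs(out$dose[valid] - ref2[valid])), 1e-9)
  # invalid pixels untouched, mask unchanged
  expect_identical(out$valid, valid)
})

test_that("self-registration returns the identity transform", {
  m <- smooth_test_map()
  reg <- register_rigid(m, m)
  px <- m$pixel_spacing
  expect_lt(max(abs(reg$transform$translation)) / px, 0.1)
  expect_lt(abs(reg$transform$rotation), 0.05)
})

test_that("injected shifts and rotations are recovered", {
  base <- smooth_test_map()
  px <- base$pixel_spacing
  # pure integer translation injected by index shifting (independent of
  # the package resampler): content moved +5 rows, -3 columns
  shifted <- matrix(NA_real_, nrow(base$dose), ncol(base$dose))
  shifted[6:nrow(base$dose), 1:(ncol(base$dose) - 3)] <-
    base$dose[1:(nrow(base$dose) - 5), 4:ncol(base$dose)]
  mov <- film_dose_map(shifted, px)
  reg <- register_rigid(mov, base, max_shift = 10.5 * px)
  expect_lt(abs(reg$transform$translation[1] / px - (-5)), 0.5)
  expect_lt(abs(reg$transform$translation[2] / px - 3), 0.5)
  expect_lt(abs(reg$transform$rotation), 0.2)
  # rotation
  rot <- dermadose:::apply_rigid_transform(base, rotation = 3)
  reg2 <- register_rigid(rot, base)
  expect_lt(abs(reg2$transform$rotation - (-3)), 0.2)
  expect_lt(max(abs(reg2$transform$translation)) / px, 0.5)
})

test_that("fraction averaging is the pixel-wise mean on the mask intersection", {
  set.seed(21)
  mk <- function() {
    v <- matrix(runif(15 * 12) > 0.1, 15, 12)
    d <- matrix(rnorm(15 * 12, 80, 6), 15, 12)
    d[!v] <- NA
    film_dose_map(d, 0.05, v)
  }
  maps <- list(mk(), mk(), mk())
  avg <- average_fractions(maps)
  # direct loop oracle
  for (i in 1:15) {
    for (j in 1:12) {
      ok <- all(vapply(maps, function(m) m$valid[i, j], logical(1)))
      expect_identical(avg$valid[i, j], ok)
      if (ok) {
        expect_equal(avg$dose[i, j],
                     mean(vapply(maps, function(m) m$dose[i, j],
                                 numeric(1))))
      }
    }
  }
  # identical maps average to themselves; x and x+2 average to x+1
  one <- mk()
  expect_equal(average_fractions(list(one, one, one))$dose, one$dose)
  two <- film_dose_map(one$dose + 2, 0.05, one$valid)
  expect_equal(average_fractions(list(one, two))$dose[one$valid],
               one$dose[one$valid] + 1)
  expect_error(average_fractions(list()), "empty")
})

test_that("averaging fractions reduces noise", {
  truth <- film_dose_map(matrix(80, 80, 80), 0.05)
  noise <- film_noise_model(noise_sd = 6, ridge_amplitude = 0,
                            misalign_translation_sd = 0,
                            misalign_rotation_sd = 0, seed = 31)
  maps <- generate_film_measurement(truth, noise, 3)
  avg <- average_fractions(maps)
  sd_avg <- sd(avg$dose - truth$dose)
  for (m in maps) expect_lt(sd_avg, sd(m$dose - truth$dose))
})

test_that("the validity mask never grows along the processing chain", {
  set.seed(33)
  valid <- matrix(TRUE, 40, 40)
  valid[cbind(sample(40, 6), sample(40, 6))] <- FALSE
  dose <- matrix(rnorm(40 * 40, 80, 6), 40, 40)
  dose[!valid] <- NA
  m0 <- film_dose_map(dose, 0.05, valid)
  m1 <- trim_edges(m0, 2)
  expect_true(all(m1$valid <= m0$valid))
  m2 <- denoise(m1)
  expect_true(all(m2$valid <= m1$valid))
  m3 <- average_fractions(list(m2, m2))
  expect_true(all(m3$valid <= m2$valid))
})
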