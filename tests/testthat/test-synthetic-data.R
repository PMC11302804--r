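# Phantom CT generation, parametric dose grids, synthetic film fractions.

test_that("phantom CT honours HU bands and the masks tile the grid", {
  spec <- small_spec()
  ph <- generate_phantom_ct(spec)
  hu <- ph$ct$values
  expect_true(all(hu[ph$cradle$mask] >= -800 & hu[ph$cradle$mask] <= -600))
  expect_true(all(hu[ph$air$mask] == -1000))
  expect_true(all(hu[ph$body$mask] == 0))
  # disjoint and tiling
  total <- ph$body$mask + ph$cradle$mask + ph$air$mask
  expect_true(all(total == 1))
  # determinism: regeneration is bit-identical
  ph2 <- generate_phantom_ct(spec)
  expect_identical(ph$ct$values, ph2$ct$values)
  expect_identical(ph$body$mask, ph2$body$mask)
})

test_that("degenerate phantom specifications are rejected", {
  expect_error(phantom_spec(breast_radius = 0), "degenerate")
  expect_error(phantom_spec(breast_radius = -1), "degenerate")
  expect_error(phantom_spec(cradle_tilt = 95), "cradle_tilt")
  expect_error(phantom_spec(breast_length = 20), "unfolded")
  expect_error(
    generate_phantom_ct(phantom_spec(voxel_budget = 1000)),
    "budget")
})

test_that("body voxel count matches a first-principles point-in-solid count", {
  spec <- phantom_spec(breast_radius = 1.0, breast_length = 3,
                       lateral_extent = 1.4, inferior_extent = 1.6,
                       ct_spacing = c(0.15, 0.15, 0.3), margin = 0.8)
  ph <- generate_phantom_ct(spec)
  d <- dim(ph$ct$values)
  tau <- spec$cradle_tilt * pi / 180
  xs <- ph$ct$origin[1] + (seq_len(d[1]) - 1) * spec$ct_spacing[1]
  ys <- ph$ct$origin[2] + (seq_len(d[2]) - 1) * spec$ct_spacing[2]
  zs <- ph$ct$origin[3] + (seq_len(d[3]) - 1) * spec$ct_spacing[3]
  count <- 0L
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      h <- ys[j] * cos(tau) - zs[k] * sin(tau)
      w <- ys[j] * sin(tau) + zs[k] * cos(tau)
      if (h < 0 || w < 0 || w > spec$breast_length) next
      for (i in seq_len(d[1])) {
        if (xs[i]^2 + h^2 <= spec$breast_radius^2) count <- count + 1L
      }
    }
  }
  expect_identical(sum(ph$body$mask), count)
})

test_that("dose grids follow the closed-form buildup model", {
  spec <- small_spec()
  prof <- algorithm_profile("test", surface_dose_fraction = 0.75,
                            buildup_length = 0.35,
                            lateral_scatter_deficit = 5)
  dg <- generate_dose_grid(spec, prof, return_depth = TRUE)
  g <- dg$grid
  d <- dim(g$dose)
  set.seed(42)
  idx <- sample(length(g$dose), 1000)
  # independent formula evaluation, from profile fields and plane geometry
  ii <- (idx - 1) %% d[1] + 1
  jj <- ((idx - 1) %/% d[1]) %% d[2] + 1
  kk <- (idx - 1) %/% (d[1] * d[2]) + 1
  tau <- spec$cradle_tilt * pi / 180
  y <- g$origin[2] + (jj - 1) * g$spacing[2]
  z <- g$origin[3] + (kk - 1) * g$spacing[3]
  w <- y * sin(tau) + z * cos(tau)
  depth <- dg$depth[idx]
  s <- 0.75; lam <- 0.35; delta <- 0.05
  expected <- g$prescription *
    (s + (1 - s) * (1 - exp(-depth / lam))) *
    (1 - (w < spec$inferior_extent) * delta * exp(-depth / lam))
  expect_lt(max(abs(g$dose[idx] - expected)), 1e-9)
  # surface: zero-depth samples away from the scatter region carry the
  # surface dose fraction exactly
  surf <- depth == 0 & w >= spec$inferior_extent
  expect_true(any(surf))
  expect_equal(unique(g$dose[idx][surf]), 0.75 * g$prescription)
})

test_that("dose approaches the prescription beyond the buildup region", {
  spec <- small_spec()
  # deepest interior point of a half-disc section is only r/2 from the
  # surface, so use a short buildup length
  prof <- algorithm_profile("short", 0.7, 0.06,
                            lateral_scatter_deficit = 5)
  dg <- generate_dose_grid(spec, prof, return_depth = TRUE)
  deep <- dg$depth > 8 * 0.06
  expect_true(any(deep))
  expect_lt(max(abs(dg$grid$dose[deep] - dg$grid$prescription)) /
              dg$grid$prescription, 0.001)
})

test_that("surface bias is applied in the first voxel layer only", {
  spec <- small_spec()
  p0 <- algorithm_profile("p0", 0.8, 0.4)
  p1 <- algorithm_profile("p1", 0.8, 0.4, surface_bias = 2)
  g0 <- generate_dose_grid(spec, p0, return_depth = TRUE)
  g1 <- generate_dose_grid(spec, p1)
  dd <- g1$grid$dose - g0$grid$dose
  first <- g0$depth <= g0$grid$spacing[1] + 1e-9 & g0$depth > 0
  expect_equal(unique(round(dd[first], 9)),
               round(0.02 * spec$prescription, 9))
  expect_true(all(dd[g0$depth > g0$grid$spacing[1] + 1e-9] == 0))
})

test_that("algorithm profiles validate their parameters", {
  expect_error(algorithm_profile("bad", 1.2, 0.4), "surface_dose_fraction")
  expect_error(algorithm_profile("bad", 0.8, 0), "buildup_length")
  expect_error(generate_dose_grid(small_spec(), list(name = "nope")),
               "profile")
})

test_that("film measurements reproduce the configured noise model", {
  truth <- film_dose_map(matrix(80, 100, 100), 0.05, provenance = "truth")
  quiet <- film_noise_model(systematic_offset = 0, noise_sd = 0,
                            ridge_amplitude = 0,
                            misalign_translation_sd = 0,
                            misalign_rotation_sd = 0, seed = 7)
  maps <- generate_film_measurement(truth, quiet, 3)
  for (m in maps) expect_equal(m$dose, truth$dose)

  offs <- film_noise_model(systematic_offset = 3, noise_sd = 0,
                           ridge_amplitude = 0,
                           misalign_translation_sd = 0,
                           misalign_rotation_sd = 0, seed = 7)
  m <- generate_film_measurement(truth, offs, 1)[[1]]
  expect_equal(mean(m$dose - truth$dose), 3, tolerance = 1e-12)

  noisy <- film_noise_model(systematic_offset = 0, noise_sd = 6,
                            ridge_amplitude = 0,
                            misalign_translation_sd = 0,
                            misalign_rotation_sd = 0, seed = 11)
  maps <- generate_film_measurement(truth, noisy, 3)
  avg <- Reduce(`+`, lapply(maps, `[[`, "dose")) / 3
  resid_sd <- sd(avg - truth$dose)
  expect_lt(abs(resid_sd - 6 / sqrt(3)) / (6 / sqrt(3)), 0.05)

  # determinism from the model seed
  maps2 <- generate_film_measurement(truth, noisy, 3)
  expect_identical(maps[[2]]$dose, maps2[[2]]$dose)
  expect_error(generate_film_measurement(truth, noisy, 0), "n_fractions")
})

test_that("rind mean dose increases with thickness under buildup", {
  st <- small_case_structures()
  prof <- algorithm_profile("buildup", 0.8, 0.4)
  dg <- generate_dose_grid(st$spec, prof)
  # thickness steps chosen to add at least one voxel layer each
  means <- vapply(c(0, 0.15, 0.3, 0.45), function(th) {
    r <- make_rind(st$contact, st$body, th)
    idx <- which(r$mask)
    pts <- cbind(r$origin[1] + ((idx - 1) %% dim(r$mask)[1]) * r$spacing[1],
                 r$origin[2] + (((idx - 1) %/% dim(r$mask)[1]) %%
                                  dim(r$mask)[2]) * r$spacing[2],
                 r$origin[3] + ((idx - 1) %/% prod(dim(r$mask)[1:2])) *
                   r$spacing[3])
    mean(trilinear_sample(dg$grid$dose, dg$grid$spacing, dg$grid$origin,
                          pts))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
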