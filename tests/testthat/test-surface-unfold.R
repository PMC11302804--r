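# Surface dose extraction, developable unfolding, rasterization,
# lateral/inferior segmentation.

test_that("surface dose sampling is exact for uniform and linear fields", {
  st <- small_case_structures()
  sp <- st$spec
  lat_sp <- rep(0.15, 3)
  # uniform 80% grid
  g <- generate_dose_grid(sp, algorithm_profile("u", 1, 0.1))
  g$grid$dose[] <- 0.8 * sp$prescription
  ss <- extract_surface_dose(g$grid, st$contact)
  expect_true(all(abs(ss$dose - 80) < 1e-12))
  # linear gradient along x: trilinear sampling reproduces it exactly
  d <- dim(g$grid$dose)
  xs <- g$grid$origin[1] + (seq_len(d[1]) - 1) * g$grid$spacing[1]
  g$grid$dose[] <- array(rep(20 + 3 * xs, d[2] * d[3]), d)
  ss <- extract_surface_dose(g$grid, st$contact)
  expected <- 100 * (20 + 3 * ss$x) / sp$prescription
  expect_lt(max(abs(ss$dose - expected)), 1e-9)
  # random smooth field matches an independent trilinear oracle
  set.seed(14)
  g$grid$dose[] <- array(60 + cumsum(rnorm(prod(d), 0, 1e-3)), d)
  ss <- extract_surface_dose(g$grid, st$contact)
  pick <- sample(nrow(ss), 50)
  for (i in pick) {
    ref <- ref_trilinear(g$grid$dose, g$grid$spacing, g$grid$origin,
                         c(ss$x[i], ss$y[i], ss$z[i]))
    expect_lt(abs(ss$dose[i] - 100 * ref / sp$prescription), 1e-9)
  }
  # surface voxels outside the dose grid extent are an error
  tiny <- dose_grid(array(1, c(2, 2, 2)), c(0.1, 0.1, 0.1),
                    origin = c(50, 50, 50), prescription = 42.5)
  expect_error(extract_surface_dose(tiny, st$contact), "extent")
})

test_that("unfolding a flat tilted plane is congruent to the 3D layout", {
  st <- small_case_structures()
  g <- generate_dose_grid(st$spec, algorithm_profile("u", 0.8, 0.4))
  ss <- extract_surface_dose(g$grid, st$contact)
  unf <- unfold_surface(ss)
  p <- unf$points
  # consecutive within-slice pairs: |2D distance - 3D distance| < 1e-9
  for (s in split(p, p$slice)) {
    if (nrow(s) < 2) next
    d3 <- sqrt(diff(s$x)^2 + diff(s$y)^2 + diff(s$z)^2)
    d2 <- sqrt(diff(s$u)^2 + diff(s$v)^2)
    expect_lt(max(abs(d2 - d3)), 1e-9)
  }
  # anchor polyline preserves across-slice spacing
  anchors <- p[p$ord == 1, ]
  anchors <- anchors[order(anchors$v), ]
  d3 <- sqrt(diff(anchors$x)^2 + diff(anchors$y)^2 + diff(anchors$z)^2)
  expect_lt(max(abs(diff(anchors$v) - d3)), 1e-9)
  # flat contact plane: zero distortion
  expect_lt(unf$distortion$max, 1e-9)
})

test_that("unfolding a cylinder sector recovers the arc length", {
  # half-cylinder surface sampled at grid-adjacent arc steps
  r <- 2; step <- 0.1
  th <- seq(0, pi, length.out = ceiling(pi * r / step) + 1)
  slices <- 0:5
  rows <- list()
  for (k in slices) {
    rows[[k + 1]] <- data.frame(
      slice = k, ord = seq_along(th),
      x = r * cos(th), y = r * sin(th), z = k * 0.25,
      dose = 80 + 5 * sin(th))
  }
  samp <- do.call(rbind, rows)
  attr(samp, "diag") <- sqrt(step^2 + step^2 + 0.25^2)
  attr(samp, "prescription") <- 42.5
  class(samp) <- c("surface_sample", "data.frame")
  unf <- unfold_surface(samp)
  # unrolled width per slice = pi * r within half a voxel spacing
  widths <- vapply(split(unf$points, unf$points$slice),
                   function(s) max(s$u), numeric(1))
  expect_true(all(abs(widths - pi * r) < step / 2))
  # isometry of consecutive points
  for (s in split(unf$points, unf$points$slice)) {
    d3 <- sqrt(diff(s$x)^2 + diff(s$y)^2 + diff(s$z)^2)
    expect_lt(max(abs(diff(s$u) - d3)), 1e-9)
  }
  # dose multiset conserved
  expect_identical(sort(unf$points$dose), sort(samp$dose))
})

test_that("non-contiguous contours are rejected", {
  samp <- data.frame(slice = 1, ord = 1:3,
                     x = c(0, 0.1, 5), y = 0, z = 0,
                     dose = 80)
  attr(samp, "diag") <- sqrt(3) * 0.1
  class(samp) <- c("surface_sample", "data.frame")
  expect_error(unfold_surface(samp), "contiguous")
})

test_that("rasterization is exact for uniform and linear fields", {
  mk_sample <- function(dosefun) {
    rows <- list()
    us <- seq(0, 3, by = 0.1)
    for (k in 0:11) {
      v <- k * 0.25
      rows[[k + 1]] <- data.frame(u = us, v = v, dose = dosefun(us, v),
                                  slice = k, ord = seq_along(us),
                                  x = us, y = 0, z = -v)
    }
    structure(list(points = do.call(rbind, rows),
                   slice_v = (0:11) * 0.25,
                   distortion = list(mean = 0, max = 0)),
              class = "unfolded_surface")
  }
  uni <- rasterize_to_film_grid(mk_sample(function(u, v) 80 + 0 * u))
  expect_true(all(abs(uni$dose[uni$valid] - 80) < 1e-9))
  lin <- rasterize_to_film_grid(mk_sample(function(u, v) 40 + 3 * u - 2 * v))
  s <- lin$pixel_spacing
  nr <- nrow(lin$dose); nc <- ncol(lin$dose)
  ug <- (seq_len(nc) - 1) * s
  vg <- (seq_len(nr) - 1) * s
  expected <- outer(vg, ug, function(v, u) 40 + 3 * u - 2 * v)
  expect_lt(max(abs(lin$dose[lin$valid] - expected[lin$valid])), 1e-9)
  # smooth random field matches an independent bracketing interpolation
  set.seed(4)
  f <- function(u, v) 70 + 6 * sin(u) * cos(2 * v) + 2 * u
  sm <- rasterize_to_film_grid(mk_sample(f))
  us <- seq(0, 3, by = 0.1); vs <- (0:11) * 0.25
  pick <- which(sm$valid, arr.ind = TRUE)
  pick <- pick[sample(nrow(pick), 200), ]
  for (rix in seq_len(nrow(pick))) {
    u <- (pick[rix, 2] - 1) * s; v <- (pick[rix, 1] - 1) * s
    iu <- max(which(us <= u + 1e-12)); iu <- min(iu, length(us) - 1)
    iv <- max(which(vs <= v + 1e-12)); iv <- min(iv, length(vs) - 1)
    wu <- (u - us[iu]) / diff(us[iu + 0:1])
    wv <- (v - vs[iv]) / diff(vs[iv + 0:1])
    val <- (1 - wv) * ((1 - wu) * f(us[iu], vs[iv]) +
                         wu * f(us[iu + 1], vs[iv])) +
      wv * ((1 - wu) * f(us[iu], vs[iv + 1]) +
              wu * f(us[iu + 1], vs[iv + 1]))
    expect_lt(abs(sm$dose[pick[rix, 1], pick[rix, 2]] - val), 1e-6)
  }
  # degenerate point sets are rejected
  degen <- mk_sample(function(u, v) 80 + 0 * u)
  degen$points <- degen$points[degen$points$slice == 0, ]
  degen$slice_v <- 0
  expect_error(rasterize_to_film_grid(degen), "degenerate")
})

test_that("pixel provenance finds a nearby source point", {
  st <- small_case_structures()
  g <- generate_dose_grid(st$spec, algorithm_profile("u", 0.8, 0.4))
  ss <- extract_surface_dose(g$grid, st$contact)
  unf <- unfold_surface(ss)
  m <- rasterize_to_film_grid(unf)
  diag_len <- sqrt(sum(st$contact$spacing^2))
  pick <- which(m$valid, arr.ind = TRUE)
  set.seed(6)
  pick <- pick[sample(nrow(pick), 40), ]
  prov <- map_provenance(m, pick[, 1], pick[, 2])
  # the recovered source must unfold to within one voxel diagonal of the
  # queried pixel
  for (i in seq_len(nrow(prov))) {
    src <- unf$points[unf$points$x == prov$x[i] &
                        unf$points$y == prov$y[i] &
                        unf$points$z == prov$z[i], ]
    du <- src$u[1] - (prov$col[i] - 1) * m$pixel_spacing
    dv <- src$v[1] - (prov$row[i] - 1) * m$pixel_spacing
    expect_lt(sqrt(du^2 + dv^2), diag_len)
  }
})

test_that("lateral/inferior segmentation splits the unfolded map", {
  dose <- matrix(80, 709, 100) # (709 - 1) * 2.54/72 cm tall = 24.98 cm
  m <- film_dose_map(dose, 2.54 / 72)
  lab <- segment_lat_inf(m, 11, 14)
  v <- (seq_len(709) - 1) * m$pixel_spacing
  expect_true(all(lab[v <= 11, ] == "lateral"))
  expect_true(all(lab[v > 11, ] == "inferior"))
  # boundary row is lateral
  b <- max(which(v <= 11 + 1e-9))
  expect_equal(unique(lab[b, ]), "lateral")
  # partition: region areas sum to the total
  expect_equal(sum(lab == "lateral") + sum(lab == "inferior"),
               length(lab))
  # degenerate lateral extent: everything inferior
  lab0 <- segment_lat_inf(m, 0, 25)
  expect_true(all(lab0 == "inferior"))
  short <- film_dose_map(matrix(80, 30, 10), 2.54 / 72)
  expect_error(segment_lat_inf(short, 11, 14), "shorter")
})

test_that("unfolded dose values are conserved through the pipeline stages", {
  st <- small_case_structures()
  g <- generate_dose_grid(st$spec, algorithm_profile("t", 0.8, 0.4))
  ss <- extract_surface_dose(g$grid, st$contact)
  unf <- unfold_surface(ss)
  expect_identical(sort(unf$points$dose), sort(ss$dose))
  expect_identical(nrow(unf$points), nrow(ss))
})
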