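# HU thresholding, contour expansion, contact surface, skin rinds.

test_that("thresholding matches a direct per-voxel comparison", {
  set.seed(3)
  vals <- array(sample(seq(-1100, 200, by = 50), 6 * 5 * 4, replace = TRUE),
                c(6, 5, 4))
  ct <- voxel_grid(vals, c(0.1, 0.1, 0.2))
  m <- threshold_structure(ct, -800, -600)
  oracle <- array(FALSE, dim(vals))
  for (i in 1:6) for (j in 1:5) for (k in 1:4)
    oracle[i, j, k] <- vals[i, j, k] >= -800 && vals[i, j, k] <= -600
  expect_identical(m$mask, oracle)
  expect_error(threshold_structure(ct, -600, -800), "hu_lo")
})

test_that("threshold bounds are inclusive at both ends", {
  vals <- array(-1000, c(3, 3, 3))
  ct <- voxel_grid(vals, c(0.1, 0.1, 0.1))
  m <- threshold_structure(ct, -3071, -1000)
  expect_true(all(m$mask)) # an all-air grid fills the air band completely
  # exact band edges included
  vals2 <- array(c(-800, -600, -599, -801), c(4, 1, 1))
  ct2 <- voxel_grid(vals2, c(0.1, 0.1, 0.1))
  m2 <- threshold_structure(ct2, -800, -600)
  expect_identical(as.vector(m2$mask), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("thresholding the synthetic cradle band recovers ground truth", {
  st <- small_case_structures()
  m <- threshold_structure(st$ph$ct, -800, -600)
  expect_identical(m$mask, st$ph$cradle$mask)
  # keep_largest drops disconnected debris
  vals <- st$ph$ct$values
  far_air <- which(!st$ph$body$mask)[1]
  vals[far_air] <- 0 # lone tissue-HU voxel in air
  ct <- voxel_grid(vals, st$ph$ct$spacing, st$ph$ct$origin)
  m2 <- threshold_structure(ct, -300, 3071, keep_largest = TRUE)
  expect_identical(m2$mask, st$ph$body$mask)
  expect_error(threshold_structure(ct, 5000, 6000, keep_largest = TRUE),
               "empty")
})

test_that("contour expansion distances are honoured", {
  # identity at distance zero
  m <- structure_mask(array(c(TRUE, FALSE), c(2, 2, 2)), c(0.1, 0.1, 0.1))
  expect_identical(expand_contour(m, 0)$mask, m$mask)
  # 1-voxel slab at 0.1 cm spacing expanded by 2.0 cm: 20 layers each side
  slab <- array(FALSE, c(61, 7, 7))
  slab[31, , ] <- TRUE
  sm <- structure_mask(slab, c(0.1, 0.1, 0.1))
  ex <- expand_contour(sm, 2.0)
  expect_true(all(ex$mask[11:51, , ]))
  expect_false(any(ex$mask[c(1:10, 52:61), , ]))
  # sphere: matches analytic membership away from the voxelised boundary
  d <- c(31, 31, 31)
  ax <- (seq_len(31) - 16) * 0.1
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  sph <- structure_mask(r2 <= 0.8^2, c(0.1, 0.1, 0.1),
                        origin = c(-1.5, -1.5, -1.5))
  ex <- expand_contour(sph, 0.5)
  rr <- sqrt(r2)
  inner <- rr <= 1.3 - sqrt(3) * 0.1
  outer_r <- rr > 1.3 + sqrt(3) * 0.1
  expect_true(all(ex$mask[inner]))
  expect_false(any(ex$mask[outer_r]))
})

test_that("contact surface is the adjacent body layer", {
  # body slab directly atop a cradle slab -> single bottom body layer
  body <- array(FALSE, c(5, 10, 5)); body[, 6:9, ] <- TRUE
  cradle <- array(FALSE, c(5, 10, 5)); cradle[, 5, ] <- TRUE
  sp <- c(0.1, 0.1, 0.1)
  b <- structure_mask(body, sp, label = "body")
  cr <- structure_mask(cradle, sp, label = "cradle")
  cs <- contact_surface(b, cr)
  expected <- array(FALSE, c(5, 10, 5)); expected[, 6, ] <- TRUE
  expect_identical(cs$mask, expected)
  # separated by an empty layer -> empty -> error
  cradle2 <- array(FALSE, c(5, 10, 5)); cradle2[, 4, ] <- TRUE
  expect_error(contact_surface(b, structure_mask(cradle2, sp)), "empty")
})

test_that("contact surface on the phantom equals a brute-force scan", {
  st <- small_case_structures()
  body <- st$body$mask; cradle <- st$cradle$mask
  d <- dim(body)
  oracle <- array(FALSE, d)
  nb <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  idx <- which(body, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    for (s in nb) {
      ii <- i + s[1]; jj <- j + s[2]; kk <- k + s[3]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3] && cradle[ii, jj, kk]) {
        oracle[i, j, k] <- TRUE
        break
      }
    }
  }
  expect_identical(st$contact$mask, oracle)
  # one voxel thick along the (near-vertical) surface normal: no two
  # contact voxels stacked in y within the same (x, z) column
  cnt <- apply(st$contact$mask, c(1, 3), function(col) {
    runs <- rle(col)
    if (!any(runs$values)) return(0L)
    max(runs$lengths[runs$values])
  })
  expect_true(all(cnt <= 1))
  expect_true(any(cnt == 1))
  # subset of body, disjoint from cradle
  expect_true(all(st$contact$mask <= body))
  expect_false(any(st$contact$mask & cradle))
})

test_that("rinds honour thickness and nest", {
  st <- small_case_structures()
  r0 <- make_rind(st$contact, st$body, 0)
  expect_identical(r0$mask, st$contact$mask)
  r2 <- make_rind(st$contact, st$body, 0.2)
  r5 <- make_rind(st$contact, st$body, 0.5)
  expect_true(all(st$contact$mask <= r2$mask))
  expect_true(all(r2$mask <= r5$mask))
  expect_true(all(r5$mask <= st$body$mask))
  expect_true(sum(r2$mask) <= sum(r5$mask))
  expect_error(make_rind(st$contact, st$body, -0.1), "thickness")
  expect_error(make_rind(st$body, st$contact, 0.1), "subset")
})

test_that("flat-slab rind volume is layer-exact", {
  body <- array(FALSE, c(7, 20, 7)); body[, 1:12, ] <- TRUE
  surf <- array(FALSE, c(7, 20, 7)); surf[, 12, ] <- TRUE
  sp <- c(0.1, 0.1, 0.1)
  r <- make_rind(structure_mask(surf, sp), structure_mask(body, sp), 0.5)
  # surface layer + 5 interior layers = 6x the surface volume
  expect_identical(sum(r$mask), 6L * sum(surf))
  expect_true(all(r$mask[, 7:12, ]))
})

test_that("curved-phantom rind equals a brute-force nearest-point oracle", {
  st <- small_case_structures()
  th <- 0.3
  r <- make_rind(st$contact, st$body, th)
  d <- dim(st$body$mask)
  sp <- st$body$spacing
  surf_idx <- which(st$contact$mask, arr.ind = TRUE)
  surf_pts <- sweep(sweep(surf_idx - 1, 2, sp, "*"), 2, st$body$origin, "+")
  body_idx <- which(st$body$mask, arr.ind = TRUE)
  set.seed(9)
  sel <- sample(nrow(body_idx), 400)
  for (r_i in sel) {
    p <- (body_idx[r_i, ] - 1) * sp + st$body$origin
    dmin <- sqrt(min(colSums((t(surf_pts) - p)^2)))
    expect_identical(
      r$mask[body_idx[r_i, 1], body_idx[r_i, 2], body_idx[r_i, 3]],
      dmin <= th + 1e-9)
  }
})

test_that("footprint restriction trims sideways spill but keeps depth", {
  st <- small_case_structures()
  r5 <- make_rind(st$contact, st$body, 0.5)
  rr <- restrict_to_footprint(r5, st$contact, st$spec)
  expect_true(all(rr$mask <= r5$mask))
  expect_true(all(st$contact$mask <= rr$mask))
  expect_true(sum(rr$mask) < sum(r5$mask))
})
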