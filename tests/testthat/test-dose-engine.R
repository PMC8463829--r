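test_that("Bragg kernel peaks at the range with a sharp distal falloff", {
  R <- 160
  z <- seq(0, 200, by = 0.05)
  b <- bragg_depth_dose(R, z)
  expect_equal(z[which.max(b)], R, tolerance = 0.1)  # brute-force argmax
  expect_equal(max(b), 1.0, tolerance = 1e-9)
  expect_lt(bragg_depth_dose(R, 1.1 * R), 0.01)
  expect_lt(bragg_depth_dose(R, 1.05 * R), 0.01)
  expect_equal(bragg_depth_dose(R, 0), 0.30, tolerance = 0.02)
  # continuity across the peak
  expect_equal(bragg_depth_dose(R, R - 1e-9), bragg_depth_dose(R, R + 1e-9),
               tolerance = 1e-6)
  expect_error(bragg_depth_dose(-5, 10), "> 0")
})

test_that("distal falloff depth scales as one over the range-scale factor", {
  R <- 160
  z <- seq(100, 200, by = 0.02)
  d80 <- function(scale) {
    b <- bragg_depth_dose(R, scale * z)
    pk <- which.max(b)
    z[pk + which(b[(pk + 1):length(z)] <= 0.8)[1]]
  }
  for (s in c(0.965, 1.035))
    expect_equal(d80(s), d80(1) / s, tolerance = 0.15)
})

test_that("spot placement builds a hexagonal lattice with layer coverage", {
  rsp <- water_rsp(c(70, 60, 44), spacing = c(2, 2, 2))
  d <- dim(rsp$values)
  y_hi <- rsp$origin[2] + (d[2] - 1) * rsp$spacing[2] + rsp$spacing[2] / 2
  # box target spanning exactly 30 mm of depth (= 30 mm WET in water)
  otv <- box_mask(rsp, c(-30, 30), c(y_hi - 80, y_hi - 50), c(-20, 20))
  bm <- beam(180, isocenter = c(0, y_hi - 65, 0))
  sp <- place_spots(otv, bm, rsp, lateral_spacing = 5, layer_spacing = 5)
  expect_equal(length(unique(sp$range)), 7L)     # ceil(30/5) + 1 layers
  # interior spots have exactly 6 lateral neighbors at the lattice constant
  pos <- unique(sp[, c("a", "b")])
  D <- as.matrix(dist(pos))
  inner <- which(pos$a > min(pos$a) + 5 & pos$a < max(pos$a) - 5 &
                   pos$b > min(pos$b) + 5 & pos$b < max(pos$b) - 5)
  nb_counts <- vapply(inner, function(i)
    sum(abs(D[i, ] - 5) < 1e-6), integer(1))
  expect_true(all(nb_counts == 6L))
  # halving the lateral spacing at least triples the spot count
  sp2 <- place_spots(otv, bm, rsp, lateral_spacing = 2.5, layer_spacing = 5)
  expect_gte(nrow(sp2), 3 * nrow(sp))
  expect_error(place_spots(otv, bm, rsp, lateral_spacing = 0), "> 0")
})

test_that("influence is linear, sparse-thresholded and scenario-aware", {
  rsp <- water_rsp(c(30, 50, 20), spacing = c(2, 2, 2))
  d <- dim(rsp$values)
  y_hi <- rsp$origin[2] + (d[2] - 1) * rsp$spacing[2] + rsp$spacing[2] / 2
  ctr <- c(0, y_hi - 60, 0)
  roi <- sphere_mask(rsp, ctr, 10)
  bm <- beam(180, isocenter = ctr)
  otv <- sphere_mask(rsp, ctr, 8)
  sp <- place_spots(otv, bm, rsp)
  infl <- compute_influence(sp, bm, rsp, roi)
  expect_true(all(infl$matrix@x >= 0))
  expect_true(all(is.finite(infl$matrix@x)))
  # column concatenation = influence of concatenated spot lists
  h <- nrow(sp) %/% 2
  i1 <- compute_influence(sp[1:h, ], bm, rsp, roi)
  i2 <- compute_influence(sp[(h + 1):nrow(sp), ], bm, rsp, roi)
  expect_equal(as.matrix(infl$matrix),
               cbind(as.matrix(i1$matrix), as.matrix(i2$matrix)),
               tolerance = 1e-12)
  # per-column sparsity threshold
  M <- as.matrix(infl$matrix)
  cm <- apply(M, 2, max)
  nz <- M > 0
  expect_true(all(M[nz] >= rep(cm * 1e-4, each = nrow(M))[nz]))
  expect_error(compute_influence(sp, bm, rsp, roi & FALSE), "empty")
})

test_that("a single spot peaks at its geometric range in water and shifts with scaling", {
  rsp <- water_rsp(c(40, 160, 24), spacing = c(1, 1, 1))
  d <- dim(rsp$values)
  y_hi <- rsp$origin[2] + (d[2] - 1) * rsp$spacing[2] + rsp$spacing[2] / 2
  # column of voxels along the central axis
  roi <- box_mask(rsp, c(-0.6, 0.6), c(y_hi - 140, y_hi - 60), c(-0.6, 0.6))
  bm <- beam(180, isocenter = c(0, y_hi - 100, 0))
  sp <- data.frame(a = 0, b = 0, range = 100, layer = 1)
  depth_of_max <- function(scen) {
    infl <- compute_influence(sp, bm, rsp, roi, scen)
    dose <- compute_dose(infl, 1)
    P <- pbsplan:::mask_centers(roi, rsp)
    y_hi - P[which.max(dose), 2]
  }
  expect_equal(depth_of_max(scenario()), 100, tolerance = 1.2)
  # +3.5% WET scaling pulls the peak proximally to range/1.035
  expect_equal(depth_of_max(scenario(scale = 1.035)), 100 / 1.035,
               tolerance = 1.2)
  expect_equal(depth_of_max(scenario(scale = 0.965)), 100 / 0.965,
               tolerance = 1.2)
})

test_that("dose is exactly linear in the spot weights", {
  rsp <- water_rsp(c(30, 40, 20), spacing = c(2, 2, 2))
  ctr <- c(0, 0, 0)
  roi <- sphere_mask(rsp, ctr, 8)
  bm <- beam(150, isocenter = ctr)
  sp <- place_spots(sphere_mask(rsp, ctr, 6), bm, rsp)
  infl <- compute_influence(sp, bm, rsp, roi)
  w <- runif(nrow(sp))
  expect_equal(compute_dose(infl, w * 0), rep(0, sum(roi)))
  expect_equal(compute_dose(infl, 2 * w), 2 * compute_dose(infl, w),
               tolerance = 1e-12)
  w1 <- runif(nrow(sp)); w2 <- runif(nrow(sp))
  expect_equal(compute_dose(infl, w1 + w2),
               compute_dose(infl, w1) + compute_dose(infl, w2),
               tolerance = 1e-9)
  e1 <- rep(0, nrow(sp)); e1[3] <- 1
  expect_equal(compute_dose(infl, e1), as.numeric(infl$matrix[, 3]))
  expect_error(compute_dose(infl, -w), ">= 0")
  expect_error(compute_dose(infl, w[-1]), "length")
})

test_that("scenario constructor enforces its invariants", {
  expect_error(scenario(c(20, 0, 0)), "10 mm")
  expect_error(scenario(scale = 1.5), "0.9")
  s <- scenario(c(1, -1, 0), 1.035, "test")
  expect_s3_class(s, "scenario")
})
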