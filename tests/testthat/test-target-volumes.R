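test_that("uniform expansion is an isotropic superset with analytic volume", {
  g1 <- water_rsp(c(44, 44, 44), spacing = c(1, 1, 1))
  m <- sphere_mask(g1, c(0, 0, 0), 10)
  expect_identical(expand_uniform(m, g1, 0), m)
  e <- expand_uniform(m, g1, 2)
  expect_true(all(m[e == FALSE] == FALSE))  # superset
  expect_true(all(e[m]))
  ratio <- sum(e) / sum(m)
  expect_lt(abs(ratio - 1.728) / 1.728, 0.05)   # (12/10)^3 concentric spheres
  expect_error(expand_uniform(m, g1, -1), ">= 0")
})

test_that("repeated dilation composes like the single larger dilation", {
  g1 <- water_rsp(c(40, 40, 40), spacing = c(1, 1, 1))
  m <- sphere_mask(g1, c(0, 0, 0), 8)
  comp <- expand_uniform(expand_uniform(m, g1, 2), g1, 2)
  direct <- expand_uniform(m, g1, 4)
  # agreement within one-voxel discretization slack: both masks sandwich
  # between the (a+b -/+ one voxel) expansions
  inner <- expand_uniform(m, g1, 4 - max(g1$spacing))
  outer_ <- expand_uniform(m, g1, 4 + max(g1$spacing))
  for (x in list(comp, direct)) {
    expect_true(all(x[inner]))
    expect_true(all(outer_[x]))
  }
  expect_lt(sum(xor(comp, direct)) / sum(direct), 0.1)
})

test_that("beam-specific expansion matches the water closed form", {
  rsp <- water_rsp(c(60, 140, 40), spacing = c(1, 1, 1))
  d <- dim(rsp$values)
  y_hi <- rsp$origin[2] + (d[2] - 1) * rsp$spacing[2] + rsp$spacing[2] / 2
  ctr <- c(0, y_hi - 100, 0)       # distal surface 108 mm deep
  gtv <- sphere_mask(rsp, ctr, 8)
  bm <- beam(180, isocenter = ctr)
  spec <- otv_spec("beam_specific", lateral_margin = 0,
                   range_fraction = 0.035)
  otv <- expand_beam_specific(gtv, bm, rsp, spec)
  expect_true(all(otv[gtv]))
  eg <- gtv_wet_extents(rsp, gtv, bm, lateral_step = 1)
  eo <- gtv_wet_extents(rsp, otv, bm, lateral_step = 1)
  cg <- eg[which.min(eg$a^2 + eg$b^2), ]
  co <- eo[which.min(eo$a^2 + eo$b^2), ]
  # distal geometric extension = fraction x distal depth (RSP = 1)
  expect_equal(co$t_dist - cg$t_dist, 0.035 * cg$wet_dist, tolerance = 1.3)
  expect_equal(cg$t_prox - co$t_prox, 0.035 * cg$wet_prox, tolerance = 1.3)
})

test_that("zero range fraction reduces to the lateral-only expansion", {
  rsp <- water_rsp(c(40, 60, 30), spacing = c(2, 2, 2))
  ctr <- c(0, 10, 0)
  gtv <- sphere_mask(rsp, ctr, 8)
  bm <- beam(180, isocenter = ctr)
  spec <- otv_spec("beam_specific", lateral_margin = 2, range_fraction = 0)
  otv <- expand_beam_specific(gtv, bm, rsp, spec)
  # manual lateral-only dilation: disk offsets in the (x, z) plane
  off <- as.matrix(expand.grid(-1:1, 0, -1:1))
  off <- off[(off[, 1] * 2)^2 + (off[, 3] * 2)^2 <= 4 + 1e-9, , drop = FALSE]
  manual <- pbsplan:::shift_or(gtv, off)
  expect_true(all(otv[manual & gtv]))
  # agreement up to lattice resampling: small symmetric difference
  expect_lt(sum(xor(otv, manual)) / sum(manual), 0.12)
})

test_that("beam-specific expansion is monotone in the range fraction", {
  rsp <- water_rsp(c(40, 60, 30), spacing = c(2, 2, 2))
  ctr <- c(0, 10, 0)
  gtv <- sphere_mask(rsp, ctr, 8)
  bm <- beam(210, isocenter = ctr)
  prev <- gtv
  for (f in c(0.01, 0.035, 0.07)) {
    otv <- expand_beam_specific(gtv, bm, rsp,
                                otv_spec("beam_specific",
                                         lateral_margin = 2,
                                         range_fraction = f))
    expect_true(all(otv[prev]))   # prev subset of otv
    prev <- otv
  }
})

test_that("the 2 mm uniform OTV nests inside the 5 mm OTV", {
  ph <- make_phantom(small_phantom_config())
  rsp <- hu_to_rsp(ph$grid)
  gtv <- ph$structures$masks$GTV
  o2 <- expand_uniform(gtv, rsp, 2)
  o5 <- expand_uniform(gtv, rsp, 5)
  expect_true(all(o5[o2]))
  expect_gt(sum(o5), sum(o2))
})

test_that("overlap exclusion removes exactly the OAR voxels outside the GTV", {
  ph <- make_phantom(small_phantom_config())
  rsp <- hu_to_rsp(ph$grid)
  st <- ph$structures
  gtv <- st$masks$GTV
  otv <- expand_uniform(gtv, rsp, 4)
  expect_identical(exclude_overlap(otv, st, character()), otv)
  k <- sum(otv & st$masks$duodenum & !gtv)
  expect_gt(k, 0)  # the abutting tube overlaps the 4 mm margin
  cut <- exclude_overlap(otv, st, "duodenum")
  expect_equal(sum(otv) - sum(cut), k)
  expect_true(all(cut[gtv]))  # GTV precedence
  # an OAR disjoint from the OTV changes nothing
  far <- st
  far$masks$far_oar <- array(FALSE, dim(gtv))
  far$masks$far_oar[1, 1, 1] <- TRUE
  expect_identical(exclude_overlap(otv, far, "far_oar"), otv)
  expect_error(exclude_overlap(otv, st, "bogus"), "available")
})

test_that("otv_spec validates its inputs", {
  expect_error(otv_spec(uniform_margin = -1), "margins")
  expect_error(otv_spec(range_fraction = 0.5), "0.2")
  expect_error(expand_beam_specific(array(TRUE, c(2, 2, 2)), beam(180),
                                    water_rsp(), otv_spec("uniform")),
               "beam_specific")
})
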