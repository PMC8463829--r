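test_that("DVH computation matches the counting oracle", {
  set.seed(17)
  dose <- runif(1000, 0, 40)
  dvh <- compute_dvh(dose, bin_width = 0.05, volume_ml = 8)
  expect_equal(dvh$volume_pct, dvh_count_oracle(dose, dvh$dose))
  expect_equal(dvh$volume_pct[1], 100)
  expect_true(all(diff(dvh$volume_pct) <= 0))
  # uniform dose: full volume up to the dose, none past the next bin
  u <- compute_dvh(rep(33, 50), bin_width = 0.05, volume_ml = 1)
  expect_equal(stats::approx(u$dose, u$volume_pct, 33)$y, 100)
  expect_equal(u$volume_pct[length(u$volume_pct)], 0)
  # half at 10, half at 30: V(20) = 50 exactly
  h <- compute_dvh(c(rep(10, 5), rep(30, 5)), bin_width = 0.05,
                   volume_ml = 1)
  expect_equal(volume_at_dose(h, 20)$pct, 50)
  expect_error(compute_dvh(numeric(0)), "empty|no dose")
})

test_that("Dq and Vd extraction behaves on hand-built cases", {
  dvh <- compute_dvh(c(1, 2, 3, 4), bin_width = 0.05, volume_ml = 4 / 1000)
  expect_equal(volume_at_dose(dvh, 2.5)$pct, 50)
  expect_equal(volume_at_dose(dvh, 2.5)$ml, 0.002)
  d50 <- dose_at_volume(dvh, 50)
  expect_gte(d50, 2)
  expect_lte(d50, 3)
  # ordering across volume levels
  qs <- c(100, 98, 50, 2)
  dq <- vapply(qs, function(q) dose_at_volume(dvh, q), numeric(1))
  expect_true(all(diff(dq) >= 0))
  # uniform-dose structure: Dq = that dose for every q
  u <- compute_dvh(rep(12, 40), bin_width = 0.05, volume_ml = 1)
  for (q in c(2, 50, 98))
    expect_equal(dose_at_volume(u, q), 12, tolerance = 0.05)
  expect_error(dose_at_volume(dvh, 0), "0, 100")
  expect_error(volume_at_dose(dvh, -1), ">= 0")
})

test_that("bandwidth follows its formula exactly", {
  expect_equal(bandwidth(33, rep(33, 8)), 0)
  # N = 2, deviations +-1 around 33: 2*sqrt(2/1)/33*100
  expect_equal(bandwidth(33, c(34, 32)), 2 * sqrt(2) / 33 * 100,
               tolerance = 1e-12)
  set.seed(29)
  for (i in 1:50) {
    nom <- runif(1, 10, 40)
    vals <- nom + rnorm(sample(2:12, 1))
    expect_equal(bandwidth(nom, vals), bandwidth_oracle(nom, vals),
                 tolerance = 1e-12)
    # invariant under common rescaling
    c0 <- runif(1, 0.1, 5)
    expect_equal(bandwidth(c0 * nom, c0 * vals), bandwidth(nom, vals),
                 tolerance = 1e-9)
  }
  expect_error(bandwidth(0, c(1, 2)), "nonzero")
  expect_error(bandwidth(10, 11), "at least 2")
})

test_that("line dose sampling is exact on affine fields", {
  g <- water_rsp(c(30, 30, 20), spacing = c(2, 2, 2))
  # constant field
  cg <- voxel_grid(array(7, dim(g$values)), g$spacing, g$origin, "Gy(RBE)")
  pr <- sample_line_dose(cg, c(-10, -10, -5), c(10, 10, 5), step = 0.5)
  expect_true(all(abs(pr$dose - 7) < 1e-12))
  # linear ramp: dose = 2x + 0.5y - z + 40 (trilinear exact on affine)
  d <- dim(g$values)
  P <- voxel_centers(g)
  ramp <- array(2 * P[, 1] + 0.5 * P[, 2] - P[, 3] + 40, d)
  rg <- voxel_grid(ramp, g$spacing, g$origin, "Gy(RBE)")
  p0 <- c(-8, -6, 0); p1 <- c(8, 6, 0)   # length 20, divisible by the step
  pr <- sample_line_dose(rg, p0, p1, step = 0.5)
  u <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  slope <- sum(c(2, 0.5, -1) * u)
  emp <- diff(pr$dose) / diff(pr$r)
  expect_equal(emp, rep(slope, length(emp)), tolerance = 1e-9)
  # reverse sampling mirrors the forward profile
  fwd <- sample_line_dose(rg, p0, p1, step = 0.5)
  rev <- sample_line_dose(rg, p1, p0, step = 0.5)
  expect_equal(rev$dose, base::rev(fwd$dose), tolerance = 1e-9)
  expect_error(sample_line_dose(rg, p0, p1, step = 0), "> 0")
})

test_that("DSF recovers the generating sigma of error-function falloffs", {
  r <- seq(0, 40, by = 0.5)
  for (sg in c(2, 3, 5)) {
    prof <- data.frame(r = r, dose = 100 * pnorm((20 - r) / sg))
    res <- dose_spread_function(prof)
    expect_true(res$ok)
    expect_lt(abs(res$fwhm - 2 * sg * sqrt(2 * log(2))) /
                (2 * sg * sqrt(2 * log(2))), 0.05)
    expect_lt(abs(res$fw20m - 2 * sg * sqrt(2 * log(5))) /
                (2 * sg * sqrt(2 * log(5))), 0.05)
    expect_lte(res$fwhm, res$fw20m)
    expect_lte(res$w100_50, res$w100_20)
    expect_gte(res$w100_50, 0)
  }
})

test_that("DSF widths collapse for a step falloff and widths stay ordered", {
  r <- seq(0, 30, by = 0.5)
  prof <- data.frame(r = r, dose = ifelse(r < 15, 100, 0))
  res <- dose_spread_function(prof)
  expect_lt(res$fwhm, 2 * 0.5)     # below two sampling steps
  expect_lte(res$fwhm, res$fw20m)
})

test_that("DSF flags profiles its fit family cannot represent", {
  r <- seq(0, 40, by = 0.5)
  wob <- 100 * pnorm((20 - r) / 3) + 25 * sin(r / 1.5) * (r > 22)
  res <- dose_spread_function(data.frame(r = r, dose = pmax(wob, 0)))
  expect_false(res$ok)
  expect_true(is.data.frame(res$raw_dsf))     # raw derivative still returned
  expect_error(dose_spread_function(
    data.frame(r = seq(0, 10, 0.5), dose = seq(0, 10, 0.5))), "plateau")
})

test_that("logistic and spline families report consistent width orderings", {
  r <- seq(0, 40, by = 0.25)
  prof <- data.frame(r = r, dose = 100 / (1 + exp((r - 18) / 2)))
  lg <- dose_spread_function(prof, family = "logistic")
  expect_true(lg$ok)
  expect_equal(lg$fwhm, 2 * 2 * log(3 + 2 * sqrt(2)), tolerance = 0.05)
  sp <- dose_spread_function(prof, family = "spline")
  expect_true(sp$ok)
  expect_lte(sp$fwhm, sp$fw20m)
  expect_equal(sp$fwhm, lg$fwhm, tolerance = 0.5)
})

test_that("abutment line passes through the closest-approach gap", {
  g <- water_rsp(c(40, 40, 30), spacing = c(2, 2, 2))
  d <- dim(g$values)
  P <- voxel_centers(g)
  dose <- array(ifelse(sqrt(rowSums(P^2)) <= 10, 40, 0), d)
  dg <- voxel_grid(dose, g$spacing, g$origin, "Gy(RBE)")
  oar <- box_mask(g, c(15, 22), c(-10, 10), c(-8, 8))  # 5 mm gap at x = 10
  seg <- locate_abutment_line(dg, 33, oar)
  expect_false(seg$overlap)
  expect_equal(seg$gap_mm, 5, tolerance = 2.1)
  # segment crosses the gap along +x and its crossing sits at the gap
  # midpoint x = 12.5 within a voxel (closest pairs tie in y and z)
  u <- (seg$p1 - seg$p0) / sqrt(sum((seg$p1 - seg$p0)^2))
  expect_gt(u[1], 0.95)
  mid <- (seg$p0 + 15 * u + seg$p1 - 25 * u) / 2  # strip the extensions
  expect_lt(abs(mid[1] - 12.5), 2.1)
  # swapping isodose and OAR reverses the direction
  dose2 <- array(ifelse(sqrt(rowSums(sweep(P, 2, c(18.5, 0, 0), "-")^2)) <=
                          5, 40, 0), d)
  dg2 <- voxel_grid(dose2, g$spacing, g$origin, "Gy(RBE)")
  oar2 <- sphere_mask(g, c(0, 0, 0), 10)
  seg2 <- locate_abutment_line(dg2, 33, oar2)
  u2 <- (seg2$p1 - seg2$p0) / sqrt(sum((seg2$p1 - seg2$p0)^2))
  expect_lt(sum(u * u2), -0.9)
  # overlapping case still yields a defined segment
  oar3 <- box_mask(g, c(5, 22), c(-10, 10), c(-8, 8))
  seg3 <- locate_abutment_line(dg, 33, oar3)
  expect_true(seg3$overlap)
  expect_true(all(is.finite(c(seg3$p0, seg3$p1))))
  expect_error(locate_abutment_line(dg, 99, oar), "empty")
})
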