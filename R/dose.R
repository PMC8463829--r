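#' Analytic Bragg depth-dose kernel
#'
#' A parametric single-peak depth-dose curve standing in for a measured Bragg
#' curve: an entrance plateau at ~30% of the peak, a proximal build-up, the
#' global maximum (normalized to 1) exactly at `range_mm` of water-equivalent
#' depth, and a sharp Gaussian distal falloff whose 80%-20% width is ~2.8 mm
#' at a 160 mm range and scales linearly with range, so the dose drops below
#' 1% of the peak within 5% of the range beyond the peak. Continuous in depth
#' and exactly linear in spot weight by construction.
#'
#' @param range_mm nominal range(s) in mm water-equivalent (> 0).
#' @param wet_depth water-equivalent depth(s) in mm; recycled against
#'   `range_mm`.
#' @param plateau entrance plateau as a fraction of the peak.
#' @return relative dose (dimensionless, peak = 1).
#' @export
bragg_depth_dose <- function(range_mm, wet_depth, plateau = 0.30) {
  if (any(range_mm <= 0)) stop("range must be > 0")
  n <- max(length(range_mm), length(wet_depth))
  R <- rep_len(range_mm, n)
  z <- rep_len(wet_depth, n)
  sig_p <- 0.07 * R
  sig_d <- 0.015544 * R       # 80-20 distal falloff 2.8 mm at R = 160
  dz <- z - R
  prox <- plateau + (1 - plateau) * exp(-dz^2 / (2 * sig_p^2))
  dist <- exp(-dz^2 / (2 * sig_d^2))
  ifelse(z <= R, prox, dist)
}

#' Perturbation scenario
#'
#' One error scenario: a rigid isocenter shift (mm) plus a multiplicative
#' range scale factor applied to every water-equivalent depth (1.035 models a
#' +3.5% overestimate of stopping power, pulling the peak proximally).
#'
#' @param shift mm shift vector, length 3 (|shift| <= 10 mm).
#' @param scale dimensionless range scale in [0.9, 1.1].
#' @param label free-text label.
#' @export
scenario <- function(shift = c(0, 0, 0), scale = 1, label = "nominal") {
  shift <- as.numeric(shift)
  if (length(shift) != 3 || sqrt(sum(shift^2)) > 10 + 1e-9)
    stop("shift must be a length-3 vector with |shift| <= 10 mm")
  if (scale < 0.9 || scale > 1.1) stop("scale must lie in [0.9, 1.1]")
  structure(list(shift = shift, scale = scale, label = label),
            class = "scenario")
}

#' Place spots on a hexagonal lattice covering an OTV
#'
#' Lateral spot positions form a hexagonal lattice (each interior spot has six
#' neighbors at exactly the lattice spacing) covering the OTV's beam's-eye-view
#' projection plus one spacing of margin. Energy layers span the OTV's
#' proximal-to-distal WET interval at the given water-equivalent layer
#' spacing. A spot is kept when some OTV ray within one lattice spacing of it
#' has a WET interval reaching the spot's layer (half-layer tolerance), so
#' every OTV voxel is within one lattice cell of a spot both laterally and in
#' depth.
#'
#' @param otv logical OTV mask.
#' @param bm a [beam()].
#' @param rsp RSP `voxel_grid`.
#' @param lateral_spacing mm hexagonal lattice constant (> 0).
#' @param layer_spacing mm water-equivalent energy-layer spacing (> 0).
#' @return data.frame of spots: lateral beam coordinates `a`, `b` (mm),
#'   water-equivalent `range` (mm), and `layer` index.
#' @export
place_spots <- function(otv, bm, rsp, lateral_spacing = 5, layer_spacing = 5) {
  if (lateral_spacing <= 0 || layer_spacing <= 0)
    stop("spacings must be > 0")
  if (!any(otv)) stop("OTV mask is empty")
  ext <- gtv_wet_extents(rsp, otv, bm, lateral_step = min(rsp$spacing))
  wp <- min(ext$wet_prox); wd <- max(ext$wet_dist)
  nlayer <- as.integer(ceiling((wd - wp) / layer_spacing)) + 1L
  ranges <- wp + (seq_len(nlayer) - 1L) * layer_spacing

  s <- lateral_spacing
  a0 <- min(ext$a) - s; a1 <- max(ext$a) + s
  b0 <- min(ext$b) - s; b1 <- max(ext$b) + s
  db <- s * sqrt(3) / 2
  b_rows <- seq(b0, b1 + db / 2, by = db)
  pos <- do.call(rbind, lapply(seq_along(b_rows), function(j) {
    offs <- if (j %% 2 == 0) s / 2 else 0
    av <- seq(a0 + offs, a1, by = s)
    cbind(av, b_rows[j])
  }))

  # lateral distance from each candidate position to each OTV ray
  keep <- vector("list", length(ranges))
  d2 <- outer(pos[, 1], ext$a, "-")^2 + outer(pos[, 2], ext$b, "-")^2
  near <- d2 <= (lateral_spacing + 1e-9)^2
  for (l in seq_along(ranges)) {
    R <- ranges[l]
    ok_ray <- ext$wet_prox - layer_spacing / 2 <= R &
      ext$wet_dist + layer_spacing / 2 >= R
    sel <- near %*% ok_ray > 0
    if (any(sel))
      keep[[l]] <- data.frame(a = pos[sel, 1], b = pos[sel, 2],
                              range = R, layer = l)
  }
  spots <- do.call(rbind, keep)
  rownames(spots) <- NULL
  spots
}

#' Influence matrix of a spot list on a region of interest
#'
#' Dose per unit spot weight at each ROI voxel: the Bragg depth-dose evaluated
#' at the scenario-scaled water-equivalent depth of the (scenario-shifted)
#' voxel, times a 2-D Gaussian lateral kernel in the beam's-eye plane. Range
#' scaling multiplies the per-voxel WET (equivalent to a global RSP scaling);
#' the setup shift rigidly displaces the sampled voxel positions. Entries
#' below `threshold` of their spot's maximum are dropped and the matrix is
#' stored sparse.
#'
#' @param spots data.frame from [place_spots()].
#' @param bm the [beam()] the spots belong to.
#' @param rsp RSP `voxel_grid`.
#' @param roi logical mask of the region of interest (non-empty).
#' @param scen a [scenario()] (default nominal).
#' @param lateral_sigma mm Gaussian lateral spot width.
#' @param threshold relative sparsity threshold per spot column.
#' @param wet optional precomputed WET vector for the shifted ROI voxels
#'   (ordering of `which(roi)`), to reuse ray tracing across scenarios.
#' @return list of class `influence` with the sparse `matrix`
#'   (voxels x spots), the ROI voxel indices `vox`, and the `scenario`.
#' @export
compute_influence <- function(spots, bm, rsp, roi, scen = scenario(),
                              lateral_sigma = 5, threshold = 1e-4,
                              wet = NULL) {
  if (!any(roi)) stop("ROI mask is empty")
  idx <- which(roi)
  P <- mask_centers(roi, rsp)
  Ps <- sweep(P, 2, scen$shift, "+")
  if (is.null(wet)) wet <- as.numeric(trace_wet(rsp, Ps, bm$direction))
  rel <- sweep(Ps, 2, bm$isocenter, "-")
  a <- as.numeric(rel %*% bm$u1)
  b <- as.numeric(rel %*% bm$u2)
  zw <- scen$scale * wet
  # depth-dose and lateral kernels as voxel x spot matrices
  D <- outer(zw, spots$range, function(z, R) bragg_depth_dose(R, z))
  L <- exp(-(outer(a, spots$a, "-")^2 + outer(b, spots$b, "-")^2) /
             (2 * lateral_sigma^2))
  M <- D * L
  cm <- apply(M, 2, max)
  M[M < matrix(cm * threshold, nrow(M), ncol(M), byrow = TRUE)] <- 0
  structure(list(matrix = Matrix::Matrix(M, sparse = TRUE), vox = idx,
                 scenario = scen, nspots = nrow(spots)),
            class = "influence")
}

#' Dose from an influence matrix and spot weights
#'
#' `dose = influence %*% weights`; exactly linear and homogeneous in the
#' weights. Negative weights are rejected.
#'
#' @param influence an `influence` object.
#' @param weights nonnegative weight per spot.
#' @return numeric dose vector over the ROI voxels (`influence$vox`).
#' @export
compute_dose <- function(influence, weights) {
  if (length(weights) != ncol(influence$matrix))
    stop("weight length must equal spot count")
  if (any(weights < 0)) stop("weights must be >= 0")
  as.numeric(influence$matrix %*% weights)
}

#' Dose of a whole plan on a region, under a scenario
#'
#' Sums the per-beam influence-times-weights over all beams of a plan. Spot
#' columns are processed in chunks so large regions never materialize a full
#' influence matrix.
#'
#' @param plan a plan from [optimize_sfo()] / [optimize_robust()] /
#'   [make_plan()].
#' @param rsp RSP `voxel_grid`.
#' @param roi logical mask.
#' @param scen a [scenario()].
#' @param chunk spots per chunk.
#' @param wet_by_beam optional list of precomputed WET vectors per beam.
#' @return numeric dose vector over `which(roi)`.
#' @export
plan_dose <- function(plan, rsp, roi, scen = scenario(), chunk = 120,
                      wet_by_beam = NULL) {
  idx <- which(roi)
  dose <- numeric(length(idx))
  P <- mask_centers(roi, rsp)
  Ps <- sweep(P, 2, scen$shift, "+")
  for (bi in seq_along(plan$beams)) {
    bm <- plan$beams[[bi]]
    sp <- plan$spots[[bi]]
    w <- plan$weights[[bi]]
    wet <- if (!is.null(wet_by_beam)) wet_by_beam[[bi]] else
      as.numeric(trace_wet(rsp, Ps, bm$direction))
    rel <- sweep(Ps, 2, bm$isocenter, "-")
    a <- as.numeric(rel %*% bm$u1)
    b <- as.numeric(rel %*% bm$u2)
    zw <- scen$scale * wet
    ns <- nrow(sp)
    start <- 1L
    while (start <= ns) {
      end <- min(ns, start + chunk - 1L)
      cols <- start:end
      D <- outer(zw, sp$range[cols], function(z, R) bragg_depth_dose(R, z))
      L <- exp(-(outer(a, sp$a[cols], "-")^2 +
                   outer(b, sp$b[cols], "-")^2) /
                 (2 * plan$lateral_sigma^2))
      dose <- dose + as.numeric((D * L) %*% w[cols])
      start <- end + 1L
    }
  }
  dose
}

#' Embed an ROI dose vector into a full dose grid
#'
#' @param dose numeric vector over `which(roi)`.
#' @param roi logical mask.
#' @param grid the reference `voxel_grid` (geometry source).
#' @return a `voxel_grid` with unit `"Gy(RBE)"`, zero outside the ROI.
#' @export
dose_to_grid <- function(dose, roi, grid) {
  vals <- array(0, grid_dim(grid))
  vals[which(roi)] <- dose
  voxel_grid(vals, grid$spacing, grid$origin, "Gy(RBE)")
}
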