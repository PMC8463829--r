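#' Beam geometry
#'
#' A beam is defined by its gantry angle (rotation in the axial plane, with
#' 180 degrees = posterior field) and an isocenter. The unit direction of
#' travel and the two lateral beam's-eye-view axes are derived from the angle;
#' couch and collimator are fixed at zero.
#'
#' @param gantry_deg gantry angle in degrees (normalized mod 360).
#' @param isocenter mm world position the beam is aimed at.
#' @return list of class `beam` with `gantry`, `isocenter`, `direction`
#'   (travel direction, source toward isocenter), and lateral axes `u1`
#'   (in the axial plane) and `u2` (longitudinal, +z).
#' @export
beam <- function(gantry_deg, isocenter = c(0, 0, 0)) {
  if (!is.finite(gantry_deg)) stop("gantry angle must be finite")
  g <- gantry_deg %% 360
  d <- beam_unit_vector(g)
  rad <- g * pi / 180
  structure(list(gantry = g, isocenter = as.numeric(isocenter),
                 direction = d,
                 u1 = c(cos(rad), -sin(rad), 0),
                 u2 = c(0, 0, 1)),
            class = "beam")
}

#' Beam travel direction for a gantry angle
#'
#' Maps 180 degrees to the posterior-to-anterior axis `(0, -1, 0)` in the
#' package's patient convention (x = left, y = posterior, z = superior);
#' 210 and 150 degrees give the two posterior obliques, symmetric about 180.
#'
#' @param gantry_deg gantry angle in degrees.
#' @return unit length-3 vector.
#' @export
beam_unit_vector <- function(gantry_deg) {
  rad <- (gantry_deg %% 360) * pi / 180
  v <- c(sin(rad), cos(rad), 0)
  v / sqrt(sum(v^2))
}

# Distance from each point backwards (against `direction`) to the grid
# bounding box boundary.  Points are assumed inside the box.
ray_entry_dist <- function(grid, pts, direction) {
  d <- grid_dim(grid)
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (d - 1) * grid$spacing + grid$spacing / 2
  tmax <- rep(Inf, nrow(pts))
  for (k in 1:3) {
    if (abs(direction[k]) < 1e-12) next
    # q(t) = p - t*dir leaves through lo if dir>0, through hi if dir<0
    bound <- if (direction[k] > 0) lo[k] else hi[k]
    tk <- (pts[, k] - bound) / direction[k]
    tmax <- pmin(tmax, tk)
  }
  pmax(tmax, 0)
}

#' Water-equivalent thickness at points along a beam
#'
#' WET(p) is the line integral of RSP from the grid entrance to `p` along the
#' beam direction, evaluated with fixed-step midpoint sampling (step at most
#' half the smallest voxel spacing by default). RSP is treated as
#' piecewise-constant per voxel, as is standard for CT-derived stopping
#' power, so the fixed-step integral converges to the exact
#' voxel-intersection (Siddon) line integral within one step times the
#' maximum RSP. Air upstream of the body is integrated as-is (RSP ~ 0.001),
#' not zeroed. Rays that never cross material with appreciable stopping
#' power are flagged in the `"missed"` attribute.
#'
#' @param rsp a `voxel_grid` with unit `"RSP"`.
#' @param pts n x 3 matrix (or length-3 vector) of points inside the grid.
#' @param direction unit travel direction of the beam.
#' @param step sampling step in mm.
#' @param chunk maximum number of interpolation samples held at once.
#' @return numeric vector of WET in mm of water, with a logical attribute
#'   `"missed"` marking rays whose integral is below 0.5 mm.
#' @export
trace_wet <- function(rsp, pts, direction, step = 0.5, chunk = 2e6) {
  stopifnot(inherits(rsp, "voxel_grid"))
  if (rsp$unit != "RSP") stop("grid must carry RSP values")
  if (step > min(rsp$spacing) / 2 + 1e-9)
    step <- min(rsp$spacing) / 2
  pts <- rbind(pts)
  direction <- direction / sqrt(sum(direction^2))
  tmax <- ray_entry_dist(rsp, pts, direction)
  n <- pmax(1L, as.integer(ceiling(tmax / step)))
  h <- tmax / n
  wet <- numeric(nrow(pts))
  # process points in chunks to bound the flattened sample count
  start <- 1L
  npts <- nrow(pts)
  while (start <= npts) {
    end <- start
    tot <- 0L
    while (end <= npts && tot + n[end] <= chunk) {
      tot <- tot + n[end]; end <- end + 1L
    }
    end <- max(end - 1L, start)
    sel <- start:end
    ridx <- rep(sel, n[sel])
    k <- sequence(n[sel])
    tk <- (k - 0.5) * h[ridx]
    sp <- pts[ridx, , drop = FALSE] -
      outer(tk, direction)
    vals <- sample_values_nn(rsp, sp)
    wet[sel] <- as.numeric(rowsum(vals * h[ridx], ridx))
    start <- end + 1L
  }
  attr(wet, "missed") <- wet < 0.5
  wet
}

# Regular beam-coordinate lattice trace shared by the WET-extent, OTV and
# spot-placement machinery.  Rays are indexed by lateral beam coordinates
# (a, b) = (u1, u2) offsets from the isocenter; every ray is sampled over a
# common depth range [t0, t1] at step h, so results form dense 3-D arrays
# [na, nb, nt].  Depths are measured from the isocenter along `direction`.
beam_lattice_trace <- function(rsp, bm, a_vals, b_vals, step = 0.5,
                               masks = NULL) {
  d <- grid_dim(rsp)
  lo <- rsp$origin - rsp$spacing / 2
  hi <- rsp$origin + (d - 1) * rsp$spacing + rsp$spacing / 2
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  tc <- as.numeric((corners - matrix(bm$isocenter, 8, 3, byrow = TRUE)) %*%
                     bm$direction)
  t0 <- min(tc); t1 <- max(tc)
  nt <- as.integer(ceiling((t1 - t0) / step))
  h <- (t1 - t0) / nt
  tmid <- t0 + (seq_len(nt) - 0.5) * h
  na <- length(a_vals); nb <- length(b_vals)
  # flattened lattice points: index order (a, b, t)
  A <- rep(a_vals, times = nb * nt)
  B <- rep(rep(b_vals, each = na), times = nt)
  Tm <- rep(tmid, each = na * nb)
  pts <- cbind(bm$isocenter[1] + A * bm$u1[1] + B * bm$u2[1] + Tm * bm$direction[1],
               bm$isocenter[2] + A * bm$u1[2] + B * bm$u2[2] + Tm * bm$direction[2],
               bm$isocenter[3] + A * bm$u1[3] + B * bm$u2[3] + Tm * bm$direction[3])
  rsp_arr <- array(sample_values_nn(rsp, pts), c(na, nb, nt))
  out <- list(a = a_vals, b = b_vals, t = tmid, h = h, t0 = t0,
              rsp = rsp_arr, beam = bm)
  if (!is.null(masks)) {
    out$masks <- lapply(masks, function(m)
      array(sample_mask(m, rsp, pts), c(na, nb, nt)))
  }
  out
}

# cumulative WET along depth for a lattice trace: WET at the *far edge* of
# sample j (depth t0 + j*h from the lattice start)
lattice_cum_wet <- function(tr) {
  cs <- apply(tr$rsp, c(1, 2), cumsum)      # nt x na x nb
  aperm(cs, c(2, 3, 1)) * tr$h
}

#' Proximal and distal WET of a target per lateral beam ray
#'
#' For every lateral ray (on a regular lattice in beam coordinates) that
#' intersects the target mask, returns the water-equivalent depth of the
#' first (proximal) and last (distal) crossing, plus the geometric depths of
#' those crossings relative to the isocenter.
#'
#' @param rsp RSP `voxel_grid`.
#' @param target logical mask congruent with `rsp` (non-empty).
#' @param bm a [beam()].
#' @param lateral_step lateral lattice spacing in mm.
#' @param step depth sampling step in mm.
#' @param pad mm of lateral padding around the target's beam's-eye-view
#'   projection.
#' @return data.frame with one row per intersecting ray: lateral coordinates
#'   `a`, `b`, geometric depths `t_prox`, `t_dist` (mm from isocenter) and
#'   water-equivalent depths `wet_prox`, `wet_dist` (mm, from grid entrance).
#' @export
gtv_wet_extents <- function(rsp, target, bm, lateral_step = min(rsp$spacing),
                            step = 0.5, pad = 0) {
  if (!any(target)) stop("target mask is empty")
  ctr <- mask_centers(target, rsp)
  rel <- sweep(ctr, 2, bm$isocenter, "-")
  a <- rel %*% bm$u1
  b <- rel %*% bm$u2
  a_vals <- seq(min(a) - pad - lateral_step, max(a) + pad + lateral_step,
                by = lateral_step)
  b_vals <- seq(min(b) - pad - lateral_step, max(b) + pad + lateral_step,
                by = lateral_step)
  tr <- beam_lattice_trace(rsp, bm, a_vals, b_vals, step,
                           masks = list(tgt = target))
  extents_from_trace(tr)
}

# shared by gtv_wet_extents and expand_beam_specific
extents_from_trace <- function(tr) {
  cw <- lattice_cum_wet(tr)
  m <- tr$masks$tgt
  na <- length(tr$a); nb <- length(tr$b); nt <- length(tr$t)
  rows <- vector("list", na * nb)
  ri <- 0L
  for (jb in seq_len(nb)) {
    for (ja in seq_len(na)) {
      mv <- m[ja, jb, ]
      if (!any(mv)) next
      w <- which(mv)
      first <- w[1]; last <- w[length(w)]
      ri <- ri + 1L
      rows[[ri]] <- c(ja, jb, first, last,
                      # boundary just before the first inside sample /
                      # at the far edge of the last inside sample
                      tr$t0 + (first - 1) * tr$h,
                      tr$t0 + last * tr$h,
                      if (first > 1) cw[ja, jb, first - 1] else 0,
                      cw[ja, jb, last])
    }
  }
  if (ri == 0L) stop("beam misses the target entirely")
  rows <- do.call(rbind, rows[seq_len(ri)])
  data.frame(a = tr$a[rows[, 1]], b = tr$b[rows[, 2]],
             ia = rows[, 1], ib = rows[, 2],
             i_first = rows[, 3], i_last = rows[, 4],
             t_prox = rows[, 5], t_dist = rows[, 6],
             wet_prox = rows[, 7], wet_dist = rows[, 8])
}
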