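#' Optimization target volume specification
#'
#' @param scheme `"uniform"` (isotropic geometric expansion) or
#'   `"beam_specific"` (WET-based margins along the beam axis plus a lateral
#'   setup margin in the beam's-eye view).
#' @param uniform_margin mm margin for the uniform scheme.
#' @param lateral_margin mm lateral setup margin for the beam-specific scheme.
#' @param range_fraction dimensionless range-uncertainty fraction applied to
#'   the proximal and distal WET (default 0.035, i.e. 3.5%).
#' @param exclude character vector of OAR names whose overlap is carved out
#'   of the OTV before optimization (GTV voxels are never removed).
#' @param per_ray logical; `TRUE` (default) applies the WET margin ray by ray,
#'   `FALSE` applies the worst-case (largest) margin of the beam uniformly.
#' @export
otv_spec <- function(scheme = c("uniform", "beam_specific"),
                     uniform_margin = 2, lateral_margin = 2,
                     range_fraction = 0.035, exclude = character(),
                     per_ray = TRUE) {
  scheme <- match.arg(scheme)
  if (uniform_margin < 0 || lateral_margin < 0) stop("margins must be >= 0")
  if (range_fraction < 0 || range_fraction > 0.2)
    stop("range fraction must lie in [0, 0.2]")
  structure(list(scheme = scheme, uniform_margin = uniform_margin,
                 lateral_margin = lateral_margin,
                 range_fraction = range_fraction, exclude = exclude,
                 per_ray = per_ray),
            class = "otv_spec")
}

#' Uniform isotropic expansion of a target mask
#'
#' A voxel joins the expanded mask when its center lies within `margin_mm`
#' of the voxelized target solid (center-sampling convention). The target
#' solid is represented by supersampling every target voxel at half-voxel
#' resolution, which removes most of the half-voxel surface bias a
#' center-point distance transform would introduce: for a sphere the
#' expanded volume tracks the analytic concentric-sphere volume to a few
#' percent at millimetric spacing. The result is always a superset of the
#' input and is monotone in the margin.
#'
#' @param target logical mask.
#' @param grid the `voxel_grid` the mask lives on.
#' @param margin_mm margin in mm (>= 0).
#' @export
expand_uniform <- function(target, grid, margin_mm) {
  if (margin_mm < 0) stop("margin must be >= 0")
  if (margin_mm == 0 || !any(target)) return(target)
  sp <- grid$spacing
  d <- dim(target)
  # work in a cropped bounding box for speed
  idx <- which_idx(target)
  pad <- ceiling(margin_mm / sp) + 1
  lo <- pmax(apply(idx, 2, min) - pad, 1)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  sub <- target[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  # supersample the target at half-voxel resolution (8 children per voxel)
  fine <- sub[rep(seq_len(ds[1]), each = 2),
              rep(seq_len(ds[2]), each = 2),
              rep(seq_len(ds[3]), each = 2), drop = FALSE]
  # coarse-center-to-fine-sample offsets are odd multiples of spacing/4;
  # keep those within the margin ball
  tmax <- ceiling(margin_mm / (sp / 2)) + 1
  tt <- lapply(1:3, function(k) {
    t_ <- (-tmax[k]):tmax[k]
    o <- sp[k] / 4 - t_ * sp[k] / 2
    list(t = t_, o = o)
  })
  combos <- expand.grid(i1 = seq_along(tt[[1]]$t), i2 = seq_along(tt[[2]]$t),
                        i3 = seq_along(tt[[3]]$t))
  dist2 <- tt[[1]]$o[combos$i1]^2 + tt[[2]]$o[combos$i2]^2 +
    tt[[3]]$o[combos$i3]^2
  combos <- combos[dist2 <= margin_mm^2 + 1e-9, , drop = FALSE]
  out_sub <- array(FALSE, ds)
  df <- dim(fine)
  for (r in seq_len(nrow(combos))) {
    t1 <- tt[[1]]$t[combos$i1[r]]
    t2 <- tt[[2]]$t[combos$i2[r]]
    t3 <- tt[[3]]$t[combos$i3[r]]
    # coarse voxel i maps to fine index 2i - 1 + t
    i1 <- seq_len(ds[1]); j1 <- 2 * i1 - 1 + t1
    i2 <- seq_len(ds[2]); j2 <- 2 * i2 - 1 + t2
    i3 <- seq_len(ds[3]); j3 <- 2 * i3 - 1 + t3
    k1 <- j1 >= 1 & j1 <= df[1]
    k2 <- j2 >= 1 & j2 <= df[2]
    k3 <- j3 >= 1 & j3 <= df[3]
    if (!any(k1) || !any(k2) || !any(k3)) next
    out_sub[i1[k1], i2[k2], i3[k3]] <-
      out_sub[i1[k1], i2[k2], i3[k3]] | fine[j1[k1], j2[k2], j3[k3]]
  }
  out <- array(FALSE, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- out_sub
  out | target
}

#' Beam-specific (WET-based) expansion of a target mask
#'
#' For each lateral ray through the target, the target's depth interval is
#' extended distally by `range_fraction * distal WET` and proximally by
#' `range_fraction * proximal WET`, converting each water-equivalent margin
#' back to geometric length by marching through the local RSP along the ray.
#' A lateral setup margin is then applied as a 2-D disk dilation in the plane
#' perpendicular to the beam axis. In uniform water the distal geometric
#' extension equals `range_fraction * distal depth`.
#'
#' @param target logical mask (non-empty).
#' @param bm a [beam()].
#' @param rsp RSP `voxel_grid`.
#' @param spec an [otv_spec()] with `scheme = "beam_specific"`.
#' @param lattice_step mm resolution of the internal beam-coordinate lattice
#'   (default half the smallest voxel spacing, to avoid aliasing holes).
#' @return logical mask, a superset of `target`.
#' @export
expand_beam_specific <- function(target, bm, rsp, spec = otv_spec("beam_specific"),
                                 lattice_step = min(rsp$spacing) / 2) {
  if (spec$scheme != "beam_specific")
    stop("spec$scheme must be 'beam_specific'")
  if (!any(target)) stop("target mask is empty")
  f <- spec$range_fraction
  lat <- spec$lateral_margin
  ctr <- mask_centers(target, rsp)
  rel <- sweep(ctr, 2, bm$isocenter, "-")
  a <- rel %*% bm$u1
  b <- rel %*% bm$u2
  pad <- lat + max(rsp$spacing)
  a_vals <- seq(min(a) - pad, max(a) + pad, by = lattice_step)
  b_vals <- seq(min(b) - pad, max(b) + pad, by = lattice_step)
  tr <- beam_lattice_trace(rsp, bm, a_vals, b_vals, step = lattice_step / 1,
                           masks = list(tgt = target))
  ext <- extents_from_trace(tr)

  h <- tr$h
  nt <- length(tr$t)
  # geometric extensions by marching through local RSP (water-equivalent
  # budget f * WET converted to mm)
  t_lo <- numeric(nrow(ext)); t_hi <- numeric(nrow(ext))
  for (r in seq_len(nrow(ext))) {
    ja <- ext$ia[r]; jb <- ext$ib[r]
    rv <- tr$rsp[ja, jb, ]
    # distal: march forward from the last inside sample
    budget <- f * ext$wet_dist[r]
    j <- ext$i_last[r]
    acc <- 0
    t_end <- ext$t_dist[r]
    while (acc < budget && j < nt) {
      j <- j + 1L
      seg <- rv[j] * h
      if (acc + seg >= budget) {
        t_end <- tr$t0 + (j - 1) * h + (budget - acc) / max(rv[j], 1e-6)
        acc <- budget
      } else {
        acc <- acc + seg
        t_end <- tr$t0 + j * h
      }
    }
    t_hi[r] <- t_end
    # proximal: march backward from the first inside sample
    budget <- f * ext$wet_prox[r]
    j <- ext$i_first[r]
    acc <- 0
    t_beg <- ext$t_prox[r]
    while (acc < budget && j > 1) {
      j <- j - 1L
      seg <- rv[j] * h
      if (acc + seg >= budget) {
        t_beg <- tr$t0 + j * h - (budget - acc) / max(rv[j], 1e-6)
        acc <- budget
      } else {
        acc <- acc + seg
        t_beg <- tr$t0 + (j - 1) * h
      }
    }
    t_lo[r] <- t_beg
  }
  if (!spec$per_ray) {
    # worst-case mode: apply the beam's largest proximal/distal margins on
    # every ray
    dmar <- max(t_hi - ext$t_dist); pmar <- max(ext$t_prox - t_lo)
    t_hi <- ext$t_dist + dmar
    t_lo <- ext$t_prox - pmar
  }

  # mark extended depth intervals on the lattice
  na <- length(tr$a); nb <- length(tr$b)
  lat_mask <- array(FALSE, c(na, nb, nt))
  for (r in seq_len(nrow(ext))) {
    jlo <- max(1L, as.integer(floor((t_lo[r] - tr$t0) / h)) + 1L)
    jhi <- min(nt, as.integer(ceiling((t_hi[r] - tr$t0) / h)))
    if (jhi >= jlo) lat_mask[ext$ia[r], ext$ib[r], jlo:jhi] <- TRUE
  }
  # lateral 2-D disk dilation per depth slab (beam's-eye-view directions)
  if (lat > 0) {
    rmax <- floor(lat / lattice_step)
    off <- as.matrix(expand.grid(-rmax:rmax, -rmax:rmax))
    off <- off[(off[, 1]^2 + off[, 2]^2) * lattice_step^2 <= lat^2 + 1e-9, ,
               drop = FALSE]
    off <- cbind(off, 0L)
    lat_mask <- shift_or(lat_mask, off)
  }
  # sample the lattice mask at voxel centers (center-sampling convention):
  # a voxel joins the OTV when its center falls in a marked lattice cell
  d <- grid_dim(rsp)
  idx <- which_idx(lat_mask)
  A <- tr$a[idx[, 1]]; B <- tr$b[idx[, 2]]; Tm <- tr$t[idx[, 3]]
  pts <- cbind(bm$isocenter[1] + A * bm$u1[1] + B * bm$u2[1] + Tm * bm$direction[1],
               bm$isocenter[2] + A * bm$u1[2] + B * bm$u2[2] + Tm * bm$direction[2],
               bm$isocenter[3] + A * bm$u1[3] + B * bm$u2[3] + Tm * bm$direction[3])
  vi <- round(world_to_index(rsp, pts))
  keep <- vi[, 1] >= 1 & vi[, 1] <= d[1] & vi[, 2] >= 1 & vi[, 2] <= d[2] &
    vi[, 3] >= 1 & vi[, 3] <= d[3]
  cand <- unique(vi[keep, , drop = FALSE])
  if (nrow(cand) > 0) {
    ctr_c <- voxel_centers(rsp, cand)
    rel_c <- sweep(ctr_c, 2, bm$isocenter, "-")
    ja <- round((rel_c %*% bm$u1 - tr$a[1]) / lattice_step) + 1
    jb <- round((rel_c %*% bm$u2 - tr$b[1]) / lattice_step) + 1
    jt <- round((rel_c %*% bm$direction - tr$t0) / h + 0.5)
    ok <- ja >= 1 & ja <= na & jb >= 1 & jb <= nb & jt >= 1 & jt <= nt
    hit <- rep(FALSE, nrow(cand))
    hit[ok] <- lat_mask[cbind(ja[ok], jb[ok], jt[ok])]
    cand <- cand[hit, , drop = FALSE]
  }
  out <- array(FALSE, d)
  if (nrow(cand) > 0) out[cand] <- TRUE
  out | target
}

#' Carve OAR overlap out of an OTV
#'
#' Removes the union of the named OAR masks from an OTV, never removing GTV
#' voxels (GTV precedence).
#'
#' @param otv logical OTV mask.
#' @param structures a [structure_set()].
#' @param names OAR names to exclude; unknown names raise an error listing
#'   the available structures.
#' @param gtv optional logical mask given precedence (defaults to the
#'   structure set's GTV).
#' @export
exclude_overlap <- function(otv, structures, names, gtv = structures$masks$GTV) {
  if (length(names) == 0) return(otv)
  missing <- setdiff(names, names(structures$masks))
  if (length(missing) > 0)
    stop(sprintf("unknown structure(s) %s; available: %s",
                 paste(missing, collapse = ", "),
                 paste(names(structures$masks), collapse = ", ")))
  cut <- Reduce(`|`, structures$masks[names])
  out <- otv & !cut
  if (!is.null(gtv)) out <- out | (otv & gtv)
  out
}
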