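#' Phantom configuration
#'
#' Defines a water-equivalent, abdomen-scale phantom emulating the geometry of
#' locally advanced pancreatic cancer treated with posterior-oblique proton
#' fields: an elliptic-cylinder water body on an air background, an ellipsoidal
#' GTV seated deep enough that its distal surface lies 16-19 cm from the
#' posterior beam entrance, a curved duodenum-surrogate tube abutting the GTV
#' anteriorly, and optional stomach / kidney / cord blobs. All structure HU
#' values are soft-tissue-like; the body is water (0 HU) so water-equivalent
#' and geometric depths coincide to within the calibration curve.
#'
#' @param dim integer length-3 grid dimensions (voxels).
#' @param spacing voxel spacing in mm (default 2 mm isotropic).
#' @param body_semi_axes mm semi-axes of the body ellipse in (x, y).
#' @param gtv_semi_axes mm semi-axes of the ellipsoidal GTV.
#' @param gtv_depth mm from the posterior body surface to the GTV *center*
#'   along the posterior-anterior axis at the GTV's (x, z) position. With the
#'   default 16 mm radius this places the distal GTV surface ~171 mm deep.
#' @param gtv_xz mm lateral (x) and longitudinal (z) position of the GTV center.
#' @param duodenum_radius mm radius of the duodenum-surrogate tube.
#' @param duodenum_gap mm gap between GTV and duodenum surfaces; 0 = abutting.
#' @param duodenum_half_length mm half-extent of the tube along z.
#' @param duodenum_curvature 1/mm quadratic bowing of the tube in x per z^2.
#' @param include_extras logical; add stomach, kidneys and cord blobs.
#' @param hu named list of tissue HU assignments.
#' @param jitter_mm uniform jitter applied to the optional blob centers (mm).
#' @param seed integer random seed controlling blob jitter (the only source
#'   of randomness in the generator).
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(160L, 128L, 64L),
                           spacing = c(2, 2, 2),
                           body_semi_axes = c(140, 110),
                           gtv_semi_axes = c(16, 16, 16),
                           gtv_depth = 155,
                           gtv_xz = c(-10, 0),
                           duodenum_radius = 9,
                           duodenum_gap = 0,
                           duodenum_half_length = 40,
                           duodenum_curvature = 0.004,
                           include_extras = TRUE,
                           hu = list(body = 0, gtv = 20, duodenum = 30,
                                     stomach = 20, kidney = 35, cord = 40,
                                     air = -1000),
                           jitter_mm = 3,
                           seed = 1234L) {
  if (duodenum_gap < 0) stop("duodenum gap must be >= 0")
  cfg <- list(dim = as.integer(dim), spacing = as.numeric(spacing),
              body_semi_axes = body_semi_axes, gtv_semi_axes = gtv_semi_axes,
              gtv_depth = gtv_depth, gtv_xz = gtv_xz,
              duodenum_radius = duodenum_radius, duodenum_gap = duodenum_gap,
              duodenum_half_length = duodenum_half_length,
              duodenum_curvature = duodenum_curvature,
              include_extras = include_extras, hu = hu,
              jitter_mm = jitter_mm, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

#' Build the synthetic phantom
#'
#' Voxelizes the configured geometry into an HU grid plus a structure set.
#' Structures are carved with GTV precedence (a voxel claimed by the GTV is
#' removed from every OAR), so GTV and OAR masks are disjoint by construction.
#' Deterministic for a given `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @return list with elements `grid` (HU `voxel_grid`) and
#'   `structures` (a [structure_set()]).
#' @export
make_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  d <- cfg$dim
  sp <- cfg$spacing
  origin <- -(d - 1) / 2 * sp   # grid centered on the world origin
  # voxel center coordinate fields
  xs <- origin[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  ax <- cfg$body_semi_axes[1]; ay <- cfg$body_semi_axes[2]
  body <- (X / ax)^2 + (Y / ay)^2 <= 1

  # GTV center: depth measured from the posterior body surface at (x, z)
  gx <- cfg$gtv_xz[1]; gz <- cfg$gtv_xz[2]
  y_surf <- ay * sqrt(pmax(0, 1 - (gx / ax)^2))
  gc <- c(gx, y_surf - cfg$gtv_depth, gz)
  sa <- cfg$gtv_semi_axes
  gtv <- ((X - gc[1]) / sa[1])^2 + ((Y - gc[2]) / sa[2])^2 +
    ((Z - gc[3]) / sa[3])^2 <= 1
  if (!any(gtv)) stop("zero-volume GTV after voxelization")
  if (any(gtv & !body)) {
    out_idx <- which_idx(gtv & !body)
    p <- voxel_centers(voxel_grid(array(0, d), sp, origin, "HU"), out_idx)
    ex <- c(x = max(abs(p[, 1]) / ax), y = max(abs(p[, 2]) / ay),
            z = as.numeric(max(abs(p[, 3])) > max(abs(zs))))
    stop(sprintf("GTV extends outside the body along axis '%s'",
                 names(which.max(ex))))
  }

  # duodenum surrogate: curved tube along z, anterior of the GTV, abutting
  # (surface gap = duodenum_gap at z = gz)
  off <- sa[2] + cfg$duodenum_radius + cfg$duodenum_gap
  dz <- Z - gc[3]
  in_z <- abs(dz) <= cfg$duodenum_half_length
  cx <- gc[1] + cfg$duodenum_curvature * dz^2
  cy <- gc[2] - off
  duo <- in_z & ((X - cx)^2 + (Y - cy)^2 <= cfg$duodenum_radius^2) & body

  masks <- list(GTV = gtv, duodenum = duo & !gtv)

  if (cfg$include_extras) {
    set.seed(cfg$seed)
    jit <- function() stats::runif(3, -cfg$jitter_mm, cfg$jitter_mm)
    blob <- function(center, semi) {
      ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
        ((Z - center[3]) / semi[3])^2 <= 1
    }
    stomach <- blob(c(45, -55, 10) + jit(), c(30, 20, 25)) & body
    kid_l <- blob(c(90, 40, 0) + jit(), c(25, 15, 30)) & body
    kid_r <- blob(c(-90, 40, 0) + jit(), c(25, 15, 30)) & body
    cord <- ((X - 0)^2 + (Y - 75)^2 <= 6^2) & body
    taken <- gtv | duo
    masks$stomach <- stomach & !taken
    masks$kidney_L <- kid_l & !taken
    masks$kidney_R <- kid_r & !taken
    masks$cord <- cord & !taken & !stomach & !kid_l & !kid_r
  }

  hu <- cfg$hu
  vals <- array(hu$air, d)
  vals[body] <- hu$body
  assign_hu <- list(GTV = hu$gtv, duodenum = hu$duodenum,
                    stomach = hu$stomach, kidney_L = hu$kidney,
                    kidney_R = hu$kidney, cord = hu$cord)
  for (nm in names(masks)) {
    h <- assign_hu[[nm]]
    if (!is.null(h)) vals[masks[[nm]]] <- h
  }
  grid <- voxel_grid(vals, sp, origin, "HU")
  list(grid = grid, structures = structure_set(grid, masks),
       gtv_center = gc, config = cfg)
}

#' Default HU to relative-stopping-power calibration curve
#'
#' A 4-node piecewise-linear surrogate for a stoichiometric calibration:
#' air, lung-like, water, bone-like. Water (0 HU) maps exactly to RSP 1.
#'
#' @return data.frame with columns `hu` and `rsp`.
#' @export
default_hu_rsp_curve <- function() {
  data.frame(hu = c(-1000, -700, 0, 1500),
             rsp = c(0.001, 0.30, 1.0, 1.85))
}

#' Convert an HU grid to relative stopping power
#'
#' Per-voxel linear interpolation on a calibration curve, clamped at the curve
#' ends; output is non-negative everywhere.
#'
#' @param grid a `voxel_grid` with unit `"HU"`.
#' @param calibration data.frame with strictly increasing `hu` and `rsp`
#'   columns (>= 2 nodes).
#' @return a `voxel_grid` with unit `"RSP"`.
#' @export
hu_to_rsp <- function(grid, calibration = default_hu_rsp_curve()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grid$unit != "HU") stop("input grid must carry HU values")
  if (nrow(calibration) < 2) stop("calibration needs at least 2 nodes")
  if (any(diff(calibration$hu) <= 0))
    stop("calibration HU nodes must be strictly increasing")
  v <- stats::approx(calibration$hu, calibration$rsp,
                     xout = as.vector(grid$values), rule = 2)$y
  v <- pmax(v, 0)
  voxel_grid(array(v, grid_dim(grid)), grid$spacing, grid$origin, "RSP")
}
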