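#' Voxel grid container
#'
#' A `voxel_grid` is the shared spatial container for every stage of the
#' pipeline: CT-like Hounsfield grids, relative-stopping-power (RSP) grids and
#' dose grids all live on it. Values are stored as a 3-D array in the fixed
#' patient-coordinate convention x = patient-left, y = patient-posterior,
#' z = superior, with `origin` giving the world position (mm) of the center of
#' voxel `[1, 1, 1]`.
#'
#' @param values 3-D numeric array of per-voxel scalars.
#' @param spacing numeric length-3, voxel spacing in mm per axis (all > 0).
#' @param origin numeric length-3, mm position of the first voxel center.
#' @param unit one of `"HU"`, `"RSP"`, `"Gy(RBE)"`; declares what `values`
#'   mean so stages cannot silently mix units.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0),
                       unit = c("HU", "RSP", "Gy(RBE)")) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (any(dim(values) < 1L)) stop("all grid dimensions must be >= 1")
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = unit),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid [%s]> %d x %d x %d voxels, spacing %s mm\n",
              x$unit, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

grid_dim <- function(grid) dim(grid$values)

#' Voxel volume in mm^3 / structure volume in mL
#'
#' Volumes are derived by voxel counting: count x voxel volume.
#' @param grid a `voxel_grid`.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' @param mask logical array congruent with `grid`.
#' @rdname voxel_volume_mm3
#' @export
mask_volume_ml <- function(mask, grid) {
  sum(mask) * voxel_volume_mm3(grid) / 1000
}

#' World coordinates of voxel centers
#'
#' @param grid a `voxel_grid`.
#' @param idx integer matrix (n x 3) of voxel indices; default all voxels.
#' @return n x 3 matrix of mm positions.
#' @export
voxel_centers <- function(grid, idx = NULL) {
  if (is.null(idx)) {
    d <- grid_dim(grid)
    idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  }
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Voxel centers of the TRUE voxels of a mask
#' @noRd
mask_centers <- function(mask, grid) {
  voxel_centers(grid, which_idx(mask))
}

which_idx <- function(mask) {
  which(mask, arr.ind = TRUE, useNames = FALSE)
}

#' Convert world points to (fractional) voxel indices
#' @noRd
world_to_index <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

#' Trilinear interpolation of a voxel grid at arbitrary points
#'
#' Points outside the grid are clamped to the boundary voxel centers (constant
#' extrapolation).
#'
#' @param grid a `voxel_grid`.
#' @param pts n x 3 matrix of world positions (mm).
#' @return numeric vector of interpolated values.
#' @export
interp_trilinear <- function(grid, pts) {
  pts <- rbind(pts)
  d <- grid_dim(grid)
  f <- world_to_index(grid, pts)
  for (k in 1:3) f[, k] <- pmin(pmax(f[, k], 1), d[k])
  i0 <- pmin(floor(f), rep(pmax(d - 1L, 1L), each = nrow(f)))
  w <- f - i0
  arr <- grid$values
  n <- nrow(f)
  out <- numeric(n)
  ip <- function(dx, dy, dz) {
    ii <- cbind(pmin(i0[, 1] + dx, d[1]),
                pmin(i0[, 2] + dy, d[2]),
                pmin(i0[, 3] + dz, d[3]))
    arr[ii]
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 1) w[, 1] else 1 - w[, 1]
    wy <- if (dy == 1) w[, 2] else 1 - w[, 2]
    wz <- if (dz == 1) w[, 3] else 1 - w[, 3]
    out <- out + wx * wy * wz * ip(dx, dy, dz)
  }
  out
}

#' Nearest-voxel sampling of a grid at world points
#'
#' Treats the field as piecewise-constant per voxel (the standard treatment
#' of CT-derived stopping power); points outside the grid are clamped.
#' @noRd
sample_values_nn <- function(grid, pts) {
  pts <- rbind(pts)
  d <- grid_dim(grid)
  ii <- round(world_to_index(grid, pts))
  for (k in 1:3) ii[, k] <- pmin(pmax(ii[, k], 1), d[k])
  grid$values[ii]
}

#' Nearest-neighbor sampling of a logical mask at world points
#' @noRd
sample_mask <- function(mask, grid, pts) {
  pts <- rbind(pts)
  d <- dim(mask)
  f <- world_to_index(grid, pts)
  ii <- round(f)
  inside <- ii[, 1] >= 1 & ii[, 1] <= d[1] &
    ii[, 2] >= 1 & ii[, 2] <= d[2] &
    ii[, 3] >= 1 & ii[, 3] <= d[3]
  out <- logical(nrow(pts))
  if (any(inside)) out[inside] <- mask[ii[inside, , drop = FALSE]]
  out
}

#' Structure set: named binary masks on one grid
#'
#' @param grid the `voxel_grid` the masks live on.
#' @param masks named list of logical arrays, each congruent with `grid`.
#'   Must contain a non-empty `GTV`; the GTV must be disjoint from every
#'   other structure (carving precedence is enforced upstream by
#'   [make_phantom()]).
#' @export
structure_set <- function(grid, masks) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("all masks must be named")
  d <- grid_dim(grid)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), d))
      stop(sprintf("mask '%s' is not a logical array congruent with the grid", nm))
  }
  if (!is.null(masks$GTV)) {
    if (!any(masks$GTV)) stop("GTV mask is empty")
    for (nm in setdiff(names(masks), "GTV"))
      if (any(masks$GTV & masks[[nm]]))
        stop(sprintf("GTV overlaps structure '%s'", nm))
  }
  structure(list(grid = grid, masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  v <- vapply(x$masks, mask_volume_ml, numeric(1), grid = x$grid)
  cat("<structure_set>\n")
  for (nm in names(v)) cat(sprintf("  %-12s %8.2f mL\n", nm, v[nm]))
  invisible(x)
}

#' Dilate a binary mask by a Euclidean ball (isotropic margin)
#'
#' A voxel belongs to the dilated mask when its center lies within
#' `margin_mm` of the center of some mask voxel (center-sampling convention).
#'
#' @param mask logical 3-D array.
#' @param spacing voxel spacing (mm, length 3).
#' @param margin_mm margin in mm (>= 0).
#' @return logical array, a superset of `mask`.
#' @export
dilate_mask <- function(mask, spacing, margin_mm) {
  if (margin_mm < 0) stop("margin must be >= 0")
  if (margin_mm == 0) return(mask)
  r <- floor(margin_mm / spacing)
  off <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  dist2 <- (off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
    (off[, 3] * spacing[3])^2
  off <- off[dist2 <= margin_mm^2 + 1e-9, , drop = FALSE]
  shift_or(mask, off)
}

# OR of shifted copies of a logical array (structuring-element dilation)
shift_or <- function(mask, offsets) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    xs <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    ys <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    zs <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    out[xs, ys, zs] <- out[xs, ys, zs] | mask[xs - o[1], ys - o[2], zs - o[3]]
  }
  out
}

#' Write / read a voxel grid container
#'
#' Grids are stored as a raw little-endian float64 array plus a JSON sidecar
#' carrying dimensions, spacing, origin and the unit tag, so that any stage
#' (or an external tool) can re-load them without guessing metadata.
#'
#' @param grid a `voxel_grid`.
#' @param prefix path prefix; `<prefix>.bin` and `<prefix>.json` are written.
#' @return `write_voxel_grid` returns `prefix` invisibly;
#'   `read_voxel_grid` returns a `voxel_grid`.
#' @export
write_voxel_grid <- function(grid, prefix) {
  meta <- list(dim = grid_dim(grid), spacing = grid$spacing,
               origin = grid$origin, unit = grid$unit,
               dtype = "float64le",
               axes = "x=left, y=posterior, z=superior")
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid$values), con, size = 8, endian = "little")
  invisible(prefix)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  voxel_grid(array(vals, dim = meta$dim), meta$spacing, meta$origin, meta$unit)
}

#' Write / read a binary mask as per-slice run-length text
#'
#' Plain-text run-length encoding, one line per axial (z) slice:
#' `z <slice> : start,len start,len ...` over the flattened (x,y) plane.
#' Useful for diffing structure sets between runs.
#'
#' @param mask logical array.
#' @param grid the grid the mask lives on (metadata header).
#' @param path output text file.
#' @export
write_mask_rle <- function(mask, grid, path) {
  d <- dim(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dim %d %d %d spacing %g %g %g origin %g %g %g",
                     d[1], d[2], d[3],
                     grid$spacing[1], grid$spacing[2], grid$spacing[3],
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  for (z in seq_len(d[3])) {
    v <- as.vector(mask[, , z])
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    on <- r$values
    if (!any(on)) next
    runs <- paste(sprintf("%d,%d", starts[on], r$lengths[on]), collapse = " ")
    writeLines(sprintf("z %d : %s", z, runs), con)
  }
  invisible(path)
}

#' @param path text file written by [write_mask_rle()].
#' @rdname write_mask_rle
#' @export
read_mask_rle <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(sub("^# dim ", "", lines[1]),
                             "[ a-z]+")[[1]])
  hdr <- hdr[is.finite(hdr)]
  d <- as.integer(hdr[1:3])
  mask <- array(FALSE, d)
  for (ln in lines[-1]) {
    parts <- strsplit(ln, " : ")[[1]]
    z <- as.integer(sub("^z ", "", parts[1]))
    sl <- logical(d[1] * d[2])
    for (run in strsplit(parts[2], " ")[[1]]) {
      se <- as.integer(strsplit(run, ",")[[1]])
      sl[se[1]:(se[1] + se[2] - 1)] <- TRUE
    }
    mask[, , z] <- sl
  }
  mask
}
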