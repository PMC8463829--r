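# Shared fixtures, built in code at test time.

# uniform-water RSP grid centered on the origin
water_rsp <- function(dim = c(40, 60, 20), spacing = c(2, 2, 2), value = 1) {
  origin <- -(dim - 1) / 2 * spacing
  voxel_grid(array(value, dim), spacing, origin, "RSP")
}

# analytic sphere mask on a grid
sphere_mask <- function(grid, center, radius) {
  d <- dim(grid$values)
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= radius^2
}

# box mask by world-coordinate bounds
box_mask <- function(grid, xlim, ylim, zlim) {
  d <- dim(grid$values)
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  outer(outer(xs >= xlim[1] & xs <= xlim[2],
              ys >= ylim[1] & ys <= ylim[2]),
        zs >= zlim[1] & zs <= zlim[2]) > 0
}

# small, fast phantom for unit tests (same generator, smaller conditions)
small_phantom_config <- function(...) {
  args <- list(dim = c(48L, 72L, 36L), spacing = c(2, 2, 2),
               body_semi_axes = c(60, 64),
               gtv_semi_axes = c(8, 8, 8), gtv_depth = 60,
               gtv_xz = c(0, 0),
               duodenum_radius = 6, duodenum_half_length = 25,
               include_extras = FALSE)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# a quick OTV_2mm plan on the small phantom, shared by evaluation tests
quick_plan_fixture <- function() {
  memo("quick_plan", function() {
    ph <- make_phantom(small_phantom_config())
    rsp <- hu_to_rsp(ph$grid)
    cfg <- study_config(phantom = small_phantom_config())
    pl <- make_plan("otv2mm", ph, rsp, cfg,
                    control = opt_control(maxit = 200))
    list(phantom = ph, rsp = rsp, cfg = cfg, plan = pl)
  })
}
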