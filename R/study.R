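#' Study configuration
#'
#' One configuration object drives the whole planning study: phantom, beams,
#' prescription, OTV margins, scenario settings, objective weights, OAR
#' constraints and output location. Defaults reproduce the study protocol:
#' 33 Gy(RBE) in 5 fractions, two posterior-oblique fields at gantry 210 and
#' 150 degrees, 2 mm setup / 3.5% range uncertainty, OTV margins of 2 mm,
#' 5 mm and the WET-based beam-specific scheme, and serial-OAR constraints
#' V(33) < 1 cm^3, V(20) < 20 cm^3, V(15) < 15 cm^3 on the duodenum.
#'
#' @param phantom a [phantom_config()].
#' @param gantry_deg beam gantry angles in degrees.
#' @param prescription list with `total` Gy(RBE) and `fractions`.
#' @param uniform_margins named mm margins for the uniform OTV schemes.
#' @param range_fraction range-uncertainty fraction for OTV_WET and
#'   scenarios.
#' @param setup_mm setup-uncertainty magnitude in mm.
#' @param lateral_spacing,layer_spacing spot lattice settings (mm).
#' @param lateral_sigma mm lateral spot sigma.
#' @param ro_scenarios 21 or 42: composition used during robust optimization
#'   (both appear in the protocol; 21 is the default).
#' @param exclude_oars OARs carved out of optimization target volumes
#'   ([exclude_overlap()]). Default: none. With this package's sharp analytic
#'   distal falloff, carving the abutting duodenum out of the optimization
#'   volume would leave the distal-margin region behind the abutment without
#'   any coverage objective, collapsing margin-plan robustness there; the
#'   default instead keeps the overlap in the target and controls the
#'   duodenum with its max-dose penalty (see the methods vignette).
#' @param constraints duodenum constraint list (dose Gy(RBE) -> max cm^3).
#' @param objective an [objective_spec()]; `NULL` uses
#'   [default_objective()].
#' @param outdir output directory for [run_study()] artifacts.
#' @param seed study seed (propagated to the phantom generator).
#' @export
study_config <- function(phantom = phantom_config(),
                         gantry_deg = c(210, 150),
                         prescription = list(total = 33, fractions = 5),
                         uniform_margins = c(otv2mm = 2, otv5mm = 5),
                         range_fraction = 0.035,
                         setup_mm = 2,
                         lateral_spacing = 5, layer_spacing = 5,
                         lateral_sigma = 5,
                         ro_scenarios = 21,
                         exclude_oars = character(0),
                         constraints = list(V33_cm3 = 1, V20_cm3 = 20,
                                            V15_cm3 = 15),
                         objective = NULL,
                         outdir = "pbsplan_out",
                         seed = 1234L) {
  if (length(gantry_deg) < 1) stop("at least one beam is required")
  if (!ro_scenarios %in% c(21, 42)) stop("ro_scenarios must be 21 or 42")
  phantom$seed <- as.integer(seed)
  if (is.null(objective)) objective <- default_objective(prescription$total)
  structure(list(phantom = phantom, gantry_deg = gantry_deg,
                 prescription = prescription,
                 uniform_margins = uniform_margins,
                 range_fraction = range_fraction, setup_mm = setup_mm,
                 lateral_spacing = lateral_spacing,
                 layer_spacing = layer_spacing,
                 lateral_sigma = lateral_sigma,
                 ro_scenarios = ro_scenarios,
                 exclude_oars = exclude_oars, constraints = constraints,
                 objective = objective, outdir = outdir,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Top-level keys mirror the [study_config()] arguments; `phantom` keys
#' mirror [phantom_config()]. Unknown keys raise an error.
#'
#' @param path YAML file.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph_args <- y$phantom
  y$phantom <- NULL
  known <- names(formals(study_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  ph <- if (is.null(ph_args)) phantom_config() else
    do.call(phantom_config, ph_args)
  do.call(study_config, c(list(phantom = ph), y))
}

#' Build the optimization target volumes for one scheme
#'
#' @param scheme `"otv2mm"`, `"otv5mm"`, `"otvwet"` or `"ro"`.
#' @param phantom result of [make_phantom()].
#' @param rsp RSP grid.
#' @param beams list of [beam()]s.
#' @param cfg a [study_config()].
#' @return per-beam list of OTV masks (identical elements for the uniform
#'   schemes; the raw GTV for `"ro"`).
#' @export
build_otvs <- function(scheme, phantom, rsp, beams, cfg) {
  st <- phantom$structures
  gtv <- st$masks$GTV
  if (scheme %in% c("otv2mm", "otv5mm")) {
    m <- cfg$uniform_margins[[scheme]]
    otv <- expand_uniform(gtv, rsp, m)
    otv <- exclude_overlap(otv, st, cfg$exclude_oars, gtv = gtv)
    rep(list(otv), length(beams))
  } else if (scheme == "otvwet") {
    spec <- otv_spec("beam_specific", lateral_margin = cfg$setup_mm,
                     range_fraction = cfg$range_fraction)
    lapply(beams, function(bm) {
      otv <- expand_beam_specific(gtv, bm, rsp, spec)
      exclude_overlap(otv, st, cfg$exclude_oars, gtv = gtv)
    })
  } else if (scheme == "ro") {
    rep(list(gtv), length(beams))
  } else stop("unknown scheme: ", scheme)
}

# spot placement region: for RO, spots must cover the scenario envelope, so
# they are placed on the WET-expanded GTV with a setup-sized lateral pad;
# margin-based schemes place spots on their own OTV.
spot_region <- function(scheme, otv_b, phantom, rsp, bm, cfg) {
  if (scheme != "ro") return(otv_b)
  spec <- otv_spec("beam_specific", lateral_margin = cfg$setup_mm,
                   range_fraction = cfg$range_fraction)
  expand_beam_specific(phantom$structures$masks$GTV, bm, rsp, spec)
}

#' Optimize one plan on a phantom
#'
#' End-to-end plan construction for one scheme: OTVs, hexagonal spot
#' placement, nominal (or per-scenario) influence matrices, single-field or
#' robust minimax optimization, and a final renormalization of all weights so
#' that the nominal GTV D98 equals the prescription (the protocol's nominal
#' coverage goal).
#'
#' @param scheme `"otv2mm"`, `"otv5mm"`, `"otvwet"` or `"ro"`.
#' @param phantom result of [make_phantom()].
#' @param rsp RSP grid (from [hu_to_rsp()]; computed if missing).
#' @param cfg a [study_config()].
#' @param normalize renormalize to GTV D98 = prescription (default TRUE).
#' @param control solver settings.
#' @return a `pbs_plan`; `$otvs` carries the per-beam target masks.
#' @export
make_plan <- function(scheme, phantom, rsp = NULL, cfg = study_config(),
                      normalize = TRUE, control = opt_control()) {
  if (is.null(rsp)) rsp <- hu_to_rsp(phantom$grid)
  st <- phantom$structures
  gtv <- st$masks$GTV
  iso <- colMeans(mask_centers(gtv, rsp))
  beams <- lapply(cfg$gantry_deg, beam, isocenter = iso)
  otvs <- build_otvs(scheme, phantom, rsp, beams, cfg)
  spots <- lapply(seq_along(beams), function(b)
    place_spots(spot_region(scheme, otvs[[b]], phantom, rsp, beams[[b]],
                            cfg),
                beams[[b]], rsp, cfg$lateral_spacing, cfg$layer_spacing))
  spec <- cfg$objective
  oars <- setdiff(unique(vapply(spec$terms, `[[`, character(1),
                                "structure")), "target")
  roi_masks <- function(b) {
    out <- list(target = otvs[[b]])
    for (s in oars) out[[s]] <- st$masks[[s]]
    out
  }
  if (scheme == "ro") {
    sset <- make_scenarios("ro21", cfg$setup_mm, cfg$range_fraction)
    scens <- sset$scenarios
    if (cfg$ro_scenarios == 42)
      scens <- make_scenarios("eval42", cfg$setup_mm,
                              cfg$range_fraction)$scenarios
    scen_infl <- lapply(seq_along(beams), function(b) {
      masks <- roi_masks(b)
      # WET traces depend only on (structure, shift); share them across the
      # scenarios' range scalings
      cache <- new.env(parent = emptyenv())
      wet_for <- function(nm, shift) {
        key <- paste(nm, paste(signif(shift, 10), collapse = ","))
        if (is.null(cache[[key]])) {
          P <- sweep(mask_centers(masks[[nm]], rsp), 2, shift, "+")
          cache[[key]] <- as.numeric(trace_wet(rsp, P,
                                               beams[[b]]$direction))
        }
        cache[[key]]
      }
      lapply(scens, function(sc)
        stats::setNames(lapply(names(masks), function(nm)
          compute_influence(spots[[b]], beams[[b]], rsp, masks[[nm]], sc,
                            lateral_sigma = cfg$lateral_sigma,
                            wet = wet_for(nm, sc$shift))),
          names(masks)))
    })
    plan <- optimize_robust(scen_infl, spec, beams, spots, scens,
                            prescription = cfg$prescription,
                            lateral_sigma = cfg$lateral_sigma,
                            control = control)
  } else {
    infl <- lapply(seq_along(beams), function(b) {
      masks <- roi_masks(b)
      lapply(masks, function(m)
        compute_influence(spots[[b]], beams[[b]], rsp, m,
                          lateral_sigma = cfg$lateral_sigma))
    })
    plan <- optimize_sfo(infl, spec, beams, spots,
                         scheme = toupper(scheme),
                         prescription = cfg$prescription,
                         lateral_sigma = cfg$lateral_sigma,
                         control = control)
    plan$scheme <- c(otv2mm = "OTV_2mm", otv5mm = "OTV_5mm",
                     otvwet = "OTV_WET")[[scheme]]
  }
  plan$otvs <- otvs
  if (normalize) plan <- normalize_plan(plan, rsp, gtv)
  plan
}

#' Renormalize a plan so nominal GTV D98 equals the prescription
#'
#' Scales every spot weight by a single factor so that at least 98% of GTV
#' voxels receive the prescription under the nominal scenario. Records the
#' factor in `$norm_factor`.
#'
#' @param plan a `pbs_plan`.
#' @param rsp RSP grid.
#' @param gtv GTV mask.
#' @param coverage_pct volume percentage pinned to the prescription.
#' @export
normalize_plan <- function(plan, rsp, gtv, coverage_pct = 98) {
  dose <- plan_dose(plan, rsp, gtv)
  n <- length(dose)
  k <- min(n, floor((1 - coverage_pct / 100) * n) + 1L)
  dq <- sort(dose)[k]   # largest d with >= coverage_pct% of voxels >= d
  f <- plan$prescription$total / dq
  plan$weights <- lapply(plan$weights, function(w) w * f)
  plan$norm_factor <- f
  plan
}

# evaluation region for dose grids: a generous ball around the GTV plus the
# duodenum (a fast region mask, not a margin construct)
eval_region <- function(phantom, margin_mm = 20) {
  st <- phantom$structures
  grid <- phantom$grid
  ctr <- mask_centers(st$masks$GTV, grid)
  c0 <- colMeans(ctr)
  rmax <- sqrt(max(rowSums(sweep(ctr, 2, c0, "-")^2)))
  P <- voxel_centers(grid)
  ball <- array(rowSums(sweep(P, 2, c0, "-")^2) <= (rmax + margin_mm)^2,
                grid_dim(grid))
  ball | st$masks$duodenum
}

#' Run the full planning study
#'
#' Executes the whole pipeline on one configuration: phantom construction,
#' HU-to-RSP conversion, OTV construction, plan optimization for the four
#' schemes (OTV_2mm, OTV_5mm, OTV_WET, RO), 42-scenario passing rates,
#' 8-scenario DVH bandwidths (GTV D98 / D50, duodenum V20), the dose spread
#' function at the target-duodenum abutment, and a duodenum constraint
#' compliance table. All artifacts are written as CSV / JSON plus the
#' voxel-grid container under `cfg$outdir`; the run is deterministic for a
#' given seed.
#'
#' @param cfg a [study_config()].
#' @param schemes subset of schemes to run.
#' @param control solver settings (exposed to allow faster smoke runs).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the phantom, plans and all result tables.
#' @export
run_study <- function(cfg = study_config(),
                      schemes = c("otv2mm", "otv5mm", "otvwet", "ro"),
                      control = opt_control(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say("phantom: %dx%dx%d @ %g mm, seed %d", cfg$phantom$dim[1],
      cfg$phantom$dim[2], cfg$phantom$dim[3], cfg$phantom$spacing[1],
      cfg$seed)
  ph <- make_phantom(cfg$phantom)
  rsp <- hu_to_rsp(ph$grid)
  write_voxel_grid(ph$grid, file.path(cfg$outdir, "phantom_hu"))
  for (nm in names(ph$structures$masks))
    write_mask_rle(ph$structures$masks[[nm]], ph$grid,
                   file.path(cfg$outdir, sprintf("mask_%s.rle.txt", nm)))
  say("margins: uniform %s mm, WET fraction %.3f, lateral %g mm; spots %g/%g mm; RO scenarios %d",
      paste(cfg$uniform_margins, collapse = "/"), cfg$range_fraction,
      cfg$setup_mm, cfg$lateral_spacing, cfg$layer_spacing,
      cfg$ro_scenarios)

  ev42 <- make_scenarios("eval42", cfg$setup_mm, cfg$range_fraction)
  bw8 <- make_scenarios("bandwidth8", cfg$setup_mm, cfg$range_fraction)
  region <- eval_region(ph)
  rx <- cfg$prescription$total
  duo <- ph$structures$masks$duodenum

  plans <- list()
  pass_rows <- list()
  bw_rows <- list()
  dsf_rows <- list()
  con_rows <- list()
  for (sch in schemes) {
    say("optimizing %s ...", sch)
    pl <- make_plan(sch, ph, rsp, cfg, control = control)
    plans[[sch]] <- pl
    utils::write.csv(
      do.call(rbind, lapply(seq_along(pl$spots), function(b)
        cbind(beam = b, gantry = pl$beams[[b]]$gantry, pl$spots[[b]],
              weight = pl$weights[[b]]))),
      file.path(cfg$outdir, sprintf("plan_%s_spots.csv", sch)),
      row.names = FALSE)

    ev <- evaluate_passing(pl, rsp, ph$structures, ev42, rx)
    utils::write.csv(ev$table,
                     file.path(cfg$outdir,
                               sprintf("passing_%s.csv", sch)),
                     row.names = FALSE)
    pass_rows[[sch]] <- data.frame(scheme = pl$scheme, passing_rate = ev$rate,
                                   worst_vrx = min(ev$table$gtv_vrx_pct))

    fam_g <- perturbed_dvh_family(pl, rsp, ph$structures, bw8, "GTV")
    fam_d <- perturbed_dvh_family(pl, rsp, ph$structures, bw8, "duodenum")
    met <- function(fam, fun) vapply(fam, fun, numeric(1))
    d98 <- met(fam_g, function(c) dose_at_volume(c, 98))
    d50 <- met(fam_g, function(c) dose_at_volume(c, 50))
    v20 <- met(fam_d, function(c) volume_at_dose(c, 20)$pct)
    bw_rows[[sch]] <- data.frame(
      scheme = pl$scheme,
      Wd_D98 = bandwidth(d98[1], d98[-1]),
      Wd_D50 = bandwidth(d50[1], d50[-1]),
      Wd_V20 = if (v20[1] > 0) bandwidth(v20[1], v20[-1]) else NA_real_)

    dose_rg <- dose_to_grid(plan_dose(pl, rsp, region), region, rsp)
    # one anatomy-anchored line for every scheme, so falloff widths compare
    # plan steepness rather than sampling location
    seg <- abutment_axis(ph$structures, "GTV", "duodenum")
    prof <- sample_line_dose(dose_rg, seg$p0, seg$p1)
    dsf <- dose_spread_function(prof)
    utils::write.csv(cbind(scheme = pl$scheme, dsf$fitted),
                     file.path(cfg$outdir, sprintf("dsf_%s.csv", sch)),
                     row.names = FALSE)
    dsf_rows[[sch]] <- data.frame(scheme = pl$scheme, fwhm = dsf$fwhm,
                                  fw20m = dsf$fw20m,
                                  w100_50 = dsf$w100_50,
                                  w100_20 = dsf$w100_20, fit_ok = dsf$ok)

    duo_dose <- plan_dose(pl, rsp, duo)
    dvh_d <- compute_dvh(duo_dose, bin_width = 0.05,
                         volume_ml = mask_volume_ml(duo, rsp),
                         structure = "duodenum")
    con_rows[[sch]] <- data.frame(
      scheme = pl$scheme,
      V33_cm3 = volume_at_dose(dvh_d, rx)$ml,
      V20_cm3 = volume_at_dose(dvh_d, 20)$ml,
      V15_cm3 = volume_at_dose(dvh_d, 15)$ml,
      V33_ok = volume_at_dose(dvh_d, rx)$ml < cfg$constraints$V33_cm3,
      V20_ok = volume_at_dose(dvh_d, 20)$ml < cfg$constraints$V20_cm3,
      V15_ok = volume_at_dose(dvh_d, 15)$ml < cfg$constraints$V15_cm3)
  }
  passing <- do.call(rbind, pass_rows)
  bandwidths <- do.call(rbind, bw_rows)
  dsf_tab <- do.call(rbind, dsf_rows)
  constraints <- do.call(rbind, con_rows)
  utils::write.csv(passing, file.path(cfg$outdir, "passing_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bandwidths, file.path(cfg$outdir, "bandwidths.csv"),
                   row.names = FALSE)
  utils::write.csv(dsf_tab, file.path(cfg$outdir, "dsf_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(constraints, file.path(cfg$outdir, "constraints.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(passing = passing, bandwidths = bandwidths, dsf = dsf_tab,
         constraints = constraints),
    file.path(cfg$outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(phantom = ph, rsp = rsp, plans = plans, passing = passing,
                 bandwidths = bandwidths, dsf = dsf_tab,
                 constraints = constraints, config = cfg))
}
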