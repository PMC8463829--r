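#' Scenario sets for robustness optimization and evaluation
#'
#' Builds the documented scenario compositions:
#' \describe{
#'   \item{eval42}{the full evaluation set: 14 setup shifts (nominal, the five
#'     cardinal directions anterior / posterior / right / left / inferior, and
#'     the eight diagonal corner directions, every non-null shift normalized
#'     to `setup_mm`) crossed with three range scalings `1 - f, 1, 1 + f` —
#'     42 scenarios.}
#'   \item{bandwidth8}{the separate DVH-bandwidth set: six cardinal shifts at
#'     `setup_mm` with nominal range, plus under- and over-range at zero
#'     shift — 8 scenarios.}
#'   \item{ro21}{the optimization set: nominal plus six cardinal shifts,
#'     each at the three range scalings — 21 scenarios.}
#' }
#' The cardinal list for `eval42` follows the study protocol literally and
#' omits the superior direction; `include_superior = TRUE` selects the
#' 15-shift variant (45 scenarios).
#'
#' @param label one of `"eval42"`, `"bandwidth8"`, `"ro21"`.
#' @param setup_mm setup-error magnitude in mm (> 0); every shift vector has
#'   this exact Euclidean norm.
#' @param range_fraction range-uncertainty fraction (> 0), e.g. 0.035.
#' @param include_superior add the superior cardinal shift to `eval42`.
#' @return list of class `scenario_set`: `scenarios` (list of [scenario()]),
#'   `label`, `setup_mm`, `range_fraction`.
#' @export
make_scenarios <- function(label = c("eval42", "bandwidth8", "ro21"),
                           setup_mm = 2, range_fraction = 0.035,
                           include_superior = FALSE) {
  label <- match.arg(label)
  if (setup_mm <= 0) stop("setup_mm must be > 0")
  if (range_fraction <= 0) stop("range_fraction must be > 0")
  f <- range_fraction
  # patient axes: x = left, y = posterior, z = superior
  card <- list(anterior = c(0, -1, 0), posterior = c(0, 1, 0),
               right = c(-1, 0, 0), left = c(1, 0, 0),
               inferior = c(0, 0, -1), superior = c(0, 0, 1))
  diag_dirs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  scen <- list()
  add <- function(shift, scale, lab)
    scen[[length(scen) + 1]] <<- scenario(shift, scale, lab)
  if (label == "eval42") {
    use <- if (include_superior) names(card) else setdiff(names(card),
                                                          "superior")
    shifts <- c(list(nominal = c(0, 0, 0)),
                lapply(card[use], function(v) v * setup_mm),
                stats::setNames(
                  lapply(seq_len(nrow(diag_dirs)),
                         function(i) diag_dirs[i, ] * setup_mm),
                  sprintf("diag%d", seq_len(nrow(diag_dirs)))))
    for (sn in names(shifts)) for (sc in c(1 - f, 1, 1 + f))
      add(shifts[[sn]], sc, sprintf("%s/%+.3f", sn, sc - 1))
  } else if (label == "ro21") {
    shifts <- c(list(nominal = c(0, 0, 0)),
                lapply(card, function(v) v * setup_mm))
    for (sn in names(shifts)) for (sc in c(1 - f, 1, 1 + f))
      add(shifts[[sn]], sc, sprintf("%s/%+.3f", sn, sc - 1))
  } else {
    for (sn in names(card)) add(card[[sn]] * setup_mm, 1, sn)
    add(c(0, 0, 0), 1 - f, "under-range")
    add(c(0, 0, 0), 1 + f, "over-range")
  }
  keys <- vapply(scen, function(s)
    paste(signif(c(s$shift, s$scale), 10), collapse = ","), character(1))
  if (anyDuplicated(keys)) stop("duplicate scenarios in set")
  structure(list(scenarios = scen, label = label, setup_mm = setup_mm,
                 range_fraction = range_fraction),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set %s> %d scenarios, setup %g mm, range %.1f%%\n",
              x$label, length(x$scenarios), x$setup_mm,
              100 * x$range_fraction))
  invisible(x)
}

# GTV (or any ROI) dose under every scenario of a set, with WET ray traces
# cached per unique (beam, shift)
scenario_doses <- function(plan, rsp, roi, sset) {
  scens <- if (inherits(sset, "scenario_set")) sset$scenarios else sset
  P <- mask_centers(roi, rsp)
  cache <- new.env(parent = emptyenv())
  wet_for <- function(bi, shift) {
    key <- paste(bi, paste(signif(shift, 10), collapse = ","))
    if (is.null(cache[[key]])) {
      Ps <- sweep(P, 2, shift, "+")
      cache[[key]] <- as.numeric(
        trace_wet(rsp, Ps, plan$beams[[bi]]$direction))
    }
    cache[[key]]
  }
  out <- matrix(0, nrow(P), length(scens))
  for (si in seq_along(scens)) {
    sc <- scens[[si]]
    wet_by_beam <- lapply(seq_along(plan$beams), function(bi)
      wet_for(bi, sc$shift))
    out[, si] <- plan_dose(plan, rsp, roi, sc, wet_by_beam = wet_by_beam)
  }
  out
}

#' Scenario passing rate of a plan
#'
#' Recomputes the GTV dose under every scenario of the set and marks a
#' scenario as passing when at least `volume_pct`% of the GTV volume receives
#' the full prescription dose.
#'
#' @param plan a `pbs_plan`.
#' @param rsp RSP `voxel_grid`.
#' @param structures a [structure_set()] (the GTV mask is evaluated).
#' @param sset a [make_scenarios()] set (non-empty).
#' @param prescription dose threshold in Gy(RBE); defaults to the plan's.
#' @param volume_pct passing criterion in % of GTV volume (default 95).
#' @return list with `rate` (% of scenarios passing) and `table`
#'   (per-scenario label, shift, scale, GTV V(Rx) in %, pass flag).
#' @export
evaluate_passing <- function(plan, rsp, structures, sset,
                             prescription = plan$prescription$total,
                             volume_pct = 95) {
  scens <- sset$scenarios
  if (length(scens) == 0) stop("scenario set is empty")
  gtv <- structures$masks$GTV
  doses <- scenario_doses(plan, rsp, gtv, sset)
  vrx <- 100 * colMeans(doses >= prescription)
  tab <- data.frame(
    label = vapply(scens, `[[`, character(1), "label"),
    shift_x = vapply(scens, function(s) s$shift[1], numeric(1)),
    shift_y = vapply(scens, function(s) s$shift[2], numeric(1)),
    shift_z = vapply(scens, function(s) s$shift[3], numeric(1)),
    scale = vapply(scens, `[[`, numeric(1), "scale"),
    gtv_vrx_pct = vrx,
    pass = vrx >= volume_pct)
  list(rate = 100 * mean(tab$pass), table = tab)
}

#' Perturbed DVH family of a plan for one structure
#'
#' One DVH per scenario, with the nominal DVH first; if the set already
#' contains the nominal scenario it is not duplicated.
#'
#' @param plan a `pbs_plan`.
#' @param rsp RSP `voxel_grid`.
#' @param structures a [structure_set()].
#' @param sset a [make_scenarios()] set.
#' @param structure structure name.
#' @param bin_width DVH bin width in Gy(RBE).
#' @return list of `dvh_curve`s; names are scenario labels, `"nominal"`
#'   first.
#' @export
perturbed_dvh_family <- function(plan, rsp, structures, sset, structure,
                                 bin_width = 0.05) {
  mask <- structures$masks[[structure]]
  if (is.null(mask)) stop(sprintf("unknown structure '%s'", structure))
  scens <- sset$scenarios
  has_nom <- any(vapply(scens, function(s)
    all(s$shift == 0) && s$scale == 1, logical(1)))
  if (!has_nom) scens <- c(list(scenario()), scens)
  # move the nominal to the front
  nom_i <- which(vapply(scens, function(s)
    all(s$shift == 0) && s$scale == 1, logical(1)))[1]
  scens <- c(scens[nom_i], scens[-nom_i])
  doses <- scenario_doses(plan, rsp, mask, scens)
  vol <- mask_volume_ml(mask, rsp)
  out <- lapply(seq_along(scens), function(i)
    compute_dvh(doses[, i], bin_width = bin_width, volume_ml = vol,
                structure = structure))
  names(out) <- c("nominal", vapply(scens[-1], `[[`, character(1),
                                    "label"))
  out
}
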