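#' Objective terms and specification
#'
#' The planning objective is a weighted sum of one-sided quadratic penalties:
#' for a minimum-dose term, voxels below the target dose are penalized; for a
#' maximum-dose term, voxels above the cap; a uniform-dose term penalizes any
#' deviation. Each term is normalized by its structure's voxel count, so
#' structure sizes do not skew the balance.
#'
#' @param structure structure name the term applies to.
#' @param type one of `"min"`, `"max"`, `"uniform"`.
#' @param dose reference dose in Gy(RBE) (>= 0), stated for the *whole plan*;
#'   per-field optimization scales it by the per-beam share.
#' @param weight term weight (>= 0).
#' @export
objective_term <- function(structure, type = c("min", "max", "uniform"),
                           dose, weight = 1) {
  type <- match.arg(type)
  if (dose < 0 || weight < 0) stop("dose and weight must be >= 0")
  list(structure = structure, type = type, dose = dose, weight = weight)
}

#' @param ... [objective_term()]s.
#' @rdname objective_term
#' @export
objective_spec <- function(...) {
  terms <- list(...)
  if (length(terms) == 1 && is.null(terms[[1]]$structure)) terms <- terms[[1]]
  if (!any(vapply(terms, function(t) t$type %in% c("min", "uniform"),
                  logical(1))))
    stop("at least one target (min or uniform) term is required")
  # infeasibility: a max cap below a min target on the same structure
  for (s in unique(vapply(terms, `[[`, character(1), "structure"))) {
    mins <- vapply(Filter(function(t) t$structure == s && t$type == "min",
                          terms), `[[`, numeric(1), "dose")
    maxs <- vapply(Filter(function(t) t$structure == s && t$type == "max",
                          terms), `[[`, numeric(1), "dose")
    if (length(mins) && length(maxs) && min(maxs) < max(mins))
      stop(sprintf("infeasible objective: Dmax < Dmin on structure '%s'", s))
  }
  structure(list(terms = terms), class = "objective_spec")
}

#' Default study objective
#'
#' Coverage-driven defaults in the style clinical planners use: a strong
#' minimum-dose term at 101.5% of prescription (so the whole optimization
#' volume — its edge included — carries at least the prescription, rather
#' than riding the distal falloff), a uniform term at prescription, a 108%
#' maximum-dose cap on the target, and a maximum-dose penalty on the duodenum
#' at the prescription itself — the direct objective translation of the
#' serial-OAR V(prescription) < 1 cm^3 constraint.
#'
#' @param prescription total prescription in Gy(RBE).
#' @param target name of the optimization target structure.
#' @param oar name of the serial OAR to penalize (NULL to skip).
#' @export
default_objective <- function(prescription = 33, target = "target",
                              oar = "duodenum") {
  terms <- list(
    objective_term(target, "min", 1.015 * prescription, weight = 300),
    objective_term(target, "uniform", prescription, weight = 1),
    objective_term(target, "max", 1.08 * prescription, weight = 5))
  if (!is.null(oar))
    terms <- c(terms, list(objective_term(oar, "max", prescription,
                                          weight = 8)))
  objective_spec(terms)
}

#' Objective value for given per-structure doses
#'
#' @param doses named list: structure name -> numeric dose vector.
#' @param spec an [objective_spec()].
#' @param share per-beam prescription share multiplier applied to the term
#'   doses (1 = whole plan).
#' @return scalar >= 0; exactly 0 iff every term is satisfied.
#' @export
objective_value <- function(doses, spec, share = 1) {
  f <- 0
  for (t in spec$terms) {
    d <- doses[[t$structure]]
    if (is.null(d)) stop(sprintf("missing structure '%s'", t$structure))
    ref <- t$dose * share
    r <- switch(t$type,
                min = pmax(0, ref - d),
                max = pmax(0, d - ref),
                uniform = d - ref)
    f <- f + t$weight * sum(r^2) / length(d)
  }
  f
}

#' Solver settings
#'
#' @param maxit projected-gradient iteration cap for single-field solves.
#' @param tol relative objective-change tolerance.
#' @param inner_maxit iteration cap of each inner minimax solve.
#' @param outer_maxit worst-case-selection outer iteration cap.
#' @export
opt_control <- function(maxit = 500L, tol = 1e-5, inner_maxit = 250L,
                        outer_maxit = 8L) {
  list(maxit = as.integer(maxit), tol = tol,
       inner_maxit = as.integer(inner_maxit),
       outer_maxit = as.integer(outer_maxit))
}

# objective and gradient for one scenario's influence matrices
obj_grad <- function(w, mats, terms, share) {
  f <- 0
  g <- numeric(length(w))
  for (t in terms) {
    A <- mats[[t$structure]]
    d <- as.numeric(A %*% w)
    n <- length(d)
    ref <- t$dose * share
    if (t$type == "min") {
      r <- pmax(0, ref - d)
      f <- f + t$weight * sum(r^2) / n
      g <- g - (2 * t$weight / n) * as.numeric(Matrix::crossprod(A, r))
    } else if (t$type == "max") {
      r <- pmax(0, d - ref)
      f <- f + t$weight * sum(r^2) / n
      g <- g + (2 * t$weight / n) * as.numeric(Matrix::crossprod(A, r))
    } else {
      r <- d - ref
      f <- f + t$weight * sum(r^2) / n
      g <- g + (2 * t$weight / n) * as.numeric(Matrix::crossprod(A, r))
    }
  }
  list(f = f, g = g)
}

# projected-gradient descent with backtracking on f(w) = max over the given
# scenario list of the per-scenario objective (length-1 list = plain descent)
pgd_minimax <- function(w0, scen_mats, terms, share, maxit, tol) {
  evalF <- function(w) {
    fs <- vapply(scen_mats, function(m) obj_grad(w, m, terms, share)$f,
                 numeric(1))
    list(F = max(fs), which = which.max(fs))
  }
  w <- w0
  cur <- evalF(w)
  Fv <- cur$F
  alpha <- 1 / max(sum(w0^2), 1)
  # scale the initial step to the gradient magnitude
  g0 <- obj_grad(w, scen_mats[[cur$which]], terms, share)$g
  gn <- sqrt(sum(g0^2))
  if (gn > 0) alpha <- max(Fv, 1e-8) / gn^2
  hist <- Fv
  stall <- 0L
  for (it in seq_len(maxit)) {
    g <- obj_grad(w, scen_mats[[cur$which]], terms, share)$g
    accepted <- FALSE
    for (bt in seq_len(40)) {
      wn <- pmax(0, w - alpha * g)
      new <- evalF(wn)
      dec <- sum(g * (w - wn))
      if (new$F <= Fv - 1e-4 * dec || new$F < Fv) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break
    rel <- (Fv - new$F) / max(Fv, 1e-12)
    w <- wn
    Fv <- new$F
    cur <- new
    hist <- c(hist, Fv)
    alpha <- alpha * 1.4
    if (rel < tol) stall <- stall + 1L else stall <- 0L
    if (stall >= 3L || Fv < 1e-14) break
  }
  list(w = w, F = Fv, history = hist)
}

new_plan <- function(beams, spots, weights, scheme, prescription,
                     lateral_sigma, extra = list()) {
  structure(c(list(beams = beams, spots = spots, weights = weights,
                   scheme = scheme, prescription = prescription,
                   lateral_sigma = lateral_sigma), extra),
            class = "pbs_plan")
}

#' @export
print.pbs_plan <- function(x, ...) {
  ns <- vapply(x$spots, nrow, integer(1))
  cat(sprintf("<pbs_plan %s> %d beam(s), %s spots, Rx %g Gy(RBE) / %d fx\n",
              x$scheme, length(x$beams), paste(ns, collapse = "+"),
              x$prescription$total, x$prescription$fractions))
  invisible(x)
}

#' Single-field optimization of spot weights
#'
#' Each field is optimized independently so that it alone delivers the
#' per-beam share (prescription / number of beams) uniformly to its own
#' optimization target volume, with any OAR penalty terms active. Weights
#' stay nonnegative after every iteration; the objective is non-increasing
#' and iteration stops at the cap or when the relative change falls below the
#' tolerance.
#'
#' @param influences per-beam list; element `b` is a named list mapping each
#'   structure referenced by `spec` to its nominal [compute_influence()]
#'   object (or bare matrix) for beam `b`'s spots. The target structure must
#'   be named `"target"`.
#' @param spec an [objective_spec()] with whole-plan reference doses.
#' @param beams list of [beam()]s.
#' @param spots per-beam spot data.frames.
#' @param scheme plan label.
#' @param prescription list with `total` (Gy(RBE)) and `fractions`.
#' @param lateral_sigma mm lateral spot sigma the influences were built with.
#' @param control solver settings from `opt_control()`.
#' @return a `pbs_plan` with per-beam optimized weights and objective
#'   histories.
#' @export
optimize_sfo <- function(influences, spec, beams, spots, scheme = "OTV",
                         prescription = list(total = 33, fractions = 5),
                         lateral_sigma = 5, control = opt_control()) {
  nb <- length(influences)
  share <- 1 / nb
  weights <- vector("list", nb)
  hist <- vector("list", nb)
  for (b in seq_len(nb)) {
    mats <- lapply(influences[[b]], function(x)
      if (inherits(x, "influence")) x$matrix else x)
    w0 <- init_weights(coverage_matrix(mats, spec),
                       prescription$total * share)
    sol <- pgd_minimax(w0, list(mats), spec$terms, share,
                       control$maxit, control$tol)
    weights[[b]] <- sol$w
    hist[[b]] <- sol$history
  }
  new_plan(beams, spots, weights, scheme, prescription, lateral_sigma,
           extra = list(history = hist))
}

init_weights <- function(A, target_dose) {
  m <- mean(as.numeric(A %*% rep(1, ncol(A))))
  rep(target_dose / max(m, 1e-9), ncol(A))
}

# influence matrix of the first coverage (min/uniform) term, used to scale
# the uniform initialization
coverage_matrix <- function(mats, spec) {
  for (t in spec$terms)
    if (t$type %in% c("min", "uniform") && !is.null(mats[[t$structure]]))
      return(mats[[t$structure]])
  stop("no influence matrix found for a coverage term")
}

#' Robust (minimax) optimization of spot weights
#'
#' Minimizes, per field, the maximum over scenarios of the objective: an
#' iterative worst-case scheme solves against the current active scenario
#' set, re-evaluates every scenario, adds the new worst one, and repeats
#' until the worst-case objective stops improving. With a single (nominal)
#' scenario this degenerates to [optimize_sfo()].
#'
#' @param scen_influences per-beam list; element `b` is a list over scenarios,
#'   each a named list mapping structure names (the optimization target must
#'   be `"target"`, normally the GTV) to influence objects/matrices under
#'   that scenario.
#' @param spec an [objective_spec()].
#' @param beams,spots,prescription,lateral_sigma,control as in
#'   [optimize_sfo()].
#' @param scenarios the list of [scenario()]s matching `scen_influences`
#'   ordering (the nominal scenario is located automatically).
#' @return a `pbs_plan`; `$worst_objective` records the achieved per-beam
#'   worst-case objective and `$worst_history` its (non-increasing) trace
#'   across outer iterations.
#' @export
optimize_robust <- function(scen_influences, spec, beams, spots, scenarios,
                            prescription = list(total = 33, fractions = 5),
                            lateral_sigma = 5, control = opt_control()) {
  if (length(scenarios) == 0) stop("scenario list is empty")
  nb <- length(scen_influences)
  share <- 1 / nb
  nom <- which(vapply(scenarios, function(s)
    all(s$shift == 0) && s$scale == 1, logical(1)))
  nom <- if (length(nom)) nom[1] else 1L
  weights <- vector("list", nb)
  worst <- numeric(nb)
  whist <- vector("list", nb)
  for (b in seq_len(nb)) {
    mats <- lapply(scen_influences[[b]], function(sc)
      lapply(sc, function(x) if (inherits(x, "influence")) x$matrix else x))
    w <- init_weights(coverage_matrix(mats[[nom]], spec),
                      prescription$total * share)
    active <- nom
    evalAll <- function(w) vapply(mats, function(m)
      obj_grad(w, m, spec$terms, share)$f, numeric(1))
    F_best <- max(evalAll(w))
    w_best <- w
    hist_b <- F_best
    for (outer in seq_len(control$outer_maxit)) {
      sol <- pgd_minimax(w, mats[active], spec$terms, share,
                         control$inner_maxit, control$tol)
      w <- sol$w
      fs <- evalAll(w)
      F_all <- max(fs)
      if (F_all < F_best) {
        F_best <- F_all
        w_best <- w
      }
      hist_b <- c(hist_b, F_best)
      worst_s <- which.max(fs)
      improved <- (hist_b[length(hist_b) - 1] - F_best) >
        control$tol * max(F_best, 1e-12)
      if (worst_s %in% active && !improved) break
      if (!(worst_s %in% active)) active <- c(active, worst_s)
      else if (!improved) break
    }
    weights[[b]] <- w_best
    worst[b] <- F_best
    whist[[b]] <- hist_b
  }
  new_plan(beams, spots, weights, "RO", prescription, lateral_sigma,
           extra = list(worst_objective = worst, worst_history = whist))
}

#' Worst-case objective of an existing plan over scenarios
#'
#' Re-evaluates a plan's combined dose under each scenario and returns the
#' maximum objective value (whole-plan reference doses). Used to check the
#' minimax dominance of robust plans over margin-based plans.
#'
#' @param plan a `pbs_plan`.
#' @param rsp RSP `voxel_grid`.
#' @param structures a [structure_set()]; the objective's `"target"` maps to
#'   the GTV mask.
#' @param spec an [objective_spec()].
#' @param scenarios list of [scenario()]s.
#' @export
worst_case_objective <- function(plan, rsp, structures, spec, scenarios) {
  structs <- unique(vapply(spec$terms, `[[`, character(1), "structure"))
  masks <- lapply(structs, function(s)
    if (s == "target") structures$masks$GTV else structures$masks[[s]])
  names(masks) <- structs
  dose_mats <- lapply(masks, function(m)
    scenario_doses(plan, rsp, m, scenarios))
  vals <- vapply(seq_along(scenarios), function(si) {
    objective_value(lapply(dose_mats, function(dm) dm[, si]), spec)
  }, numeric(1))
  max(vals)
}
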