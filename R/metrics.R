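#' Cumulative dose-volume histogram
#'
#' Counting DVH: for each dose bin edge, the percentage of structure voxels
#' receiving at least that dose. The curve starts at 100% at dose 0 and is
#' monotone non-increasing.
#'
#' @param dose numeric vector of voxel doses for one structure (or a
#'   `voxel_grid` combined with `mask`).
#' @param mask optional logical mask when `dose` is a grid.
#' @param bin_width bin width in Gy(RBE).
#' @param volume_ml absolute structure volume in cm^3 (attached to the curve;
#'   computed automatically in the grid + mask form).
#' @param structure structure name carried along for reporting.
#' @return list of class `dvh_curve`: `dose` (bin edges), `volume_pct`,
#'   `volume_ml`, `structure`.
#' @export
compute_dvh <- function(dose, mask = NULL, bin_width = 0.05,
                        volume_ml = NA_real_, structure = "") {
  if (inherits(dose, "voxel_grid")) {
    if (is.null(mask)) stop("a mask is required with a dose grid")
    if (!any(mask)) stop("mask is empty")
    volume_ml <- mask_volume_ml(mask, dose)
    dose <- dose$values[mask]
  }
  if (length(dose) == 0) stop("no dose values (empty structure)")
  top <- max(dose, 0)
  edges <- seq(0, top + bin_width, by = bin_width)
  sorted <- sort(dose)
  # voxels with dose >= edge, via binary search on the sorted doses
  n_ge <- length(dose) - findInterval(edges - 1e-12, sorted)
  structure(list(dose = edges, volume_pct = 100 * n_ge / length(dose),
                 volume_ml = volume_ml, structure = structure),
            class = "dvh_curve")
}

#' Dose at volume (Dq) and volume at dose (Vd)
#'
#' `dose_at_volume` returns the largest dose received by at least `q`% of the
#' structure (linear interpolation between DVH bin edges, clamped at the curve
#' ends). `volume_at_dose` returns the volume receiving at least dose `d`,
#' both in % and in cm^3.
#'
#' @param dvh a `dvh_curve`.
#' @param q volume percentage in (0, 100].
#' @export
dose_at_volume <- function(dvh, q) {
  if (q <= 0 || q > 100) stop("q must lie in (0, 100]")
  v <- dvh$volume_pct
  d <- dvh$dose
  ge <- which(v >= q)
  if (length(ge) == 0) return(0)
  i <- max(ge)
  if (i == length(d) || v[i] <= q) return(d[i])
  # interpolate toward the next edge where the curve has fallen below q
  d[i] + (v[i] - q) / (v[i] - v[i + 1]) * (d[i + 1] - d[i])
}

#' @param d dose in Gy(RBE) (>= 0).
#' @rdname dose_at_volume
#' @export
volume_at_dose <- function(dvh, d) {
  if (d < 0) stop("dose must be >= 0")
  pct <- if (d >= max(dvh$dose)) 0 else
    stats::approx(dvh$dose, dvh$volume_pct, xout = d, rule = 2)$y
  list(pct = pct, ml = pct / 100 * dvh$volume_ml)
}

#' DVH bandwidth of a metric across scenarios
#'
#' The spread of a DVH metric under perturbation, normalized to its nominal
#' value:
#' `Wd = 2 * sqrt( sum_i (D_i - D_nominal)^2 / (N - 1) ) / D_nominal * 100%`,
#' where the `D_i` are the metric's values under the N perturbation
#' scenarios. Zero exactly when every scenario reproduces the nominal value;
#' invariant under a common rescaling of all doses.
#'
#' @param nominal nominal metric value (> 0).
#' @param scenario_values metric values under the scenarios (N >= 2).
#' @return `Wd` in percent.
#' @export
bandwidth <- function(nominal, scenario_values) {
  if (length(scenario_values) < 2) stop("need at least 2 scenario values")
  if (!is.finite(nominal) || nominal == 0)
    stop("nominal value must be nonzero (normalization undefined)")
  n <- length(scenario_values)
  100 * 2 * sqrt(sum((scenario_values - nominal)^2) / (n - 1)) / nominal
}

#' Sample a line dose profile through a dose grid
#'
#' Trilinear interpolation at uniform steps from `p0` toward `p1`; positions
#' are the distance in mm from `p0`.
#'
#' @param dose_grid a `voxel_grid` with unit `"Gy(RBE)"`.
#' @param p0,p1 mm endpoints inside the grid.
#' @param step sampling step in mm (> 0).
#' @return data.frame with columns `r` (mm from `p0`) and `dose`.
#' @export
sample_line_dose <- function(dose_grid, p0, p1, step = 0.5) {
  if (step <= 0) stop("step must be > 0")
  L <- sqrt(sum((p1 - p0)^2))
  r <- seq(0, L, by = step)
  u <- (p1 - p0) / L
  pts <- cbind(p0[1] + r * u[1], p0[2] + r * u[2], p0[3] + r * u[3])
  data.frame(r = r, dose = interp_trilinear(dose_grid, pts))
}

#' Dose spread function of a line dose profile
#'
#' Fits a smooth monotone falloff family to a sampled line dose that starts on
#' a high-dose plateau and falls off, then differentiates the fit
#' analytically: `DSF(r) = |d/dr LD(r)|`. The falloff steepness is summarized
#' by the full widths of the DSF peak at 50% (FWHM) and 20% (FW20M) of its
#' maximum; the alternative reading — the distance for the fitted profile
#' itself to drop from the plateau to 50% / 20% — is reported separately as
#' the dose-drop widths `w100_50` / `w100_20` (plateau crossing taken at 98%
#' of the plateau level).
#'
#' Fit families: `"erf"` (Gaussian-CDF falloff; DSF is an exact Gaussian with
#' closed-form widths), `"logistic"` (sech^2 DSF, closed-form widths), or
#' `"spline"` (smoothing spline, numeric derivative and widths).
#'
#' @param profile data.frame from [sample_line_dose()] with columns `r`,
#'   `dose`; must begin on a plateau (>= 95% of the profile maximum over at
#'   least 3 consecutive samples).
#' @param family fit family.
#' @param max_resid_frac fit acceptance threshold: RMS residual as a fraction
#'   of the falloff amplitude. Above it the result is flagged (`ok = FALSE`)
#'   and only the raw numeric derivative is returned for inspection.
#' @return list of class `dsf_result`: `fwhm`, `fw20m`, `w100_50`,
#'   `w100_20` (mm), `fit` (parameters), `fitted` (data.frame r, dose, dsf),
#'   `ok`, `family`, and the raw numeric derivative `raw_dsf`.
#' @export
dose_spread_function <- function(profile, family = c("erf", "logistic",
                                                     "spline"),
                                 max_resid_frac = 0.05) {
  family <- match.arg(family)
  r <- profile$r
  y <- profile$dose
  if (length(r) < 8) stop("profile too short")
  top <- max(y)
  plat <- y >= 0.95 * top
  runs <- rle(plat)
  if (!any(runs$values & runs$lengths >= 3))
    stop("no plateau detected (need >= 3 consecutive samples at >= 95% of max)")
  raw_dsf <- data.frame(r = (r[-1] + r[-length(r)]) / 2,
                        dsf = abs(diff(y) / diff(r)))
  fail <- function() structure(list(fwhm = NA_real_, fw20m = NA_real_,
                                    w100_50 = NA_real_, w100_20 = NA_real_,
                                    fit = NULL, fitted = NULL, ok = FALSE,
                                    family = family, raw_dsf = raw_dsf),
                               class = "dsf_result")
  dat <- data.frame(r = r, y = y)
  fit <- NULL
  if (family != "spline") {
    # basis shape: cdf of the falling falloff, linear in (A, K) given (M, s)
    shape <- if (family == "erf") {
      function(M, s) stats::pnorm((M - r) / s)
    } else {
      function(M, s) 1 / (1 + exp((r - M) / s))
    }
    init <- falloff_grid_init(r, y, shape)
    fml <- if (family == "erf")
      y ~ A + (K - A) * pnorm((M - r) / sigma)
    else
      y ~ A + (K - A) / (1 + exp((r - M) / sigma))
    fit <- try(minpack.lm::nlsLM(
      fml, data = dat,
      start = list(A = init$A, K = init$K, M = init$M, sigma = init$s),
      lower = c(-Inf, -Inf, min(r), 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error") || is.null(fit)) {
      # fall back to the deterministic grid-search fit
      cf0 <- list(A = init$A, K = init$K, M = init$M, sigma = init$s)
      fit <- list(grid = cf0, resid = init$resid)
      class(fit) <- "falloff_grid_fit"
    }
  }
  if (family == "spline") {
    sp <- stats::smooth.spline(r, y)
    rf <- seq(min(r), max(r), length.out = 512)
    yf <- stats::predict(sp, rf)$y
    df <- abs(stats::predict(sp, rf, deriv = 1)$y)
    res <- y - stats::predict(sp, r)$y
    amp <- max(yf) - min(yf)
    if (sqrt(mean(res^2)) > max_resid_frac * amp) return(fail())
    pk <- which.max(df)
    widths50 <- peak_width(rf, df, df[pk] * 0.5)
    widths20 <- peak_width(rf, df, df[pk] * 0.2)
    plat_lvl <- mean(y[which(plat)[1]:(which(plat)[1] + 2)])
    drops <- drop_widths(rf, yf, plat_lvl)
    return(structure(list(fwhm = widths50, fw20m = widths20,
                          w100_50 = drops[1], w100_20 = drops[2],
                          fit = sp,
                          fitted = data.frame(r = rf, dose = yf, dsf = df),
                          ok = TRUE, family = family, raw_dsf = raw_dsf),
                     class = "dsf_result"))
  }
  if (inherits(fit, "falloff_grid_fit")) {
    cf <- fit$grid
    resid <- fit$resid
  } else {
    cf <- as.list(stats::coef(fit))
    resid <- sqrt(mean(stats::resid(fit)^2))
  }
  names(cf)[names(cf) == "sigma"] <- if (family == "erf") "sigma" else "s"
  amp <- abs(cf$K - cf$A)
  if (amp < 1e-9 || resid > max_resid_frac * amp) return(fail())
  rf <- seq(min(r), max(r), length.out = 512)
  if (family == "erf") {
    yf <- cf$A + (cf$K - cf$A) * stats::pnorm((cf$M - rf) / cf$sigma)
    dsf <- amp * stats::dnorm((rf - cf$M) / cf$sigma) / cf$sigma
    fwhm <- 2 * cf$sigma * sqrt(2 * log(2))
    fw20m <- 2 * cf$sigma * sqrt(2 * log(5))
  } else {
    e <- exp((rf - cf$M) / cf$s)
    yf <- cf$A + (cf$K - cf$A) / (1 + e)
    dsf <- amp * e / (cf$s * (1 + e)^2)
    fwhm <- 2 * cf$s * log(3 + 2 * sqrt(2))
    fw20m <- 2 * cf$s * log(9 + 4 * sqrt(5))
  }
  plat_lvl <- mean(y[which(plat)[1]:(which(plat)[1] + 2)])
  drops <- drop_widths(rf, yf, plat_lvl)
  structure(list(fwhm = fwhm, fw20m = fw20m,
                 w100_50 = drops[1], w100_20 = drops[2],
                 fit = cf, fitted = data.frame(r = rf, dose = yf, dsf = dsf),
                 ok = TRUE, family = family, raw_dsf = raw_dsf),
            class = "dsf_result")
}

# deterministic coarse fit of A + (K - A) * shape(M, s) by grid search over
# (M, s) with linear least squares for (A, K); robust starting point for the
# nonlinear polish, and the fallback when the polish fails (e.g. on
# step-like falloffs where the gradient in s degenerates)
falloff_grid_init <- function(r, y, shape) {
  span <- diff(range(r))
  step <- min(diff(r))
  ss <- exp(seq(log(max(step / 10, 0.02)), log(span / 3), length.out = 36))
  amp <- max(y) - min(y)
  mid <- which(y <= min(y) + 0.9 * amp & y >= min(y) + 0.1 * amp)
  Ms <- if (length(mid) > 0) unique(r[mid]) else r
  if (length(Ms) > 25) Ms <- Ms[round(seq(1, length(Ms), length.out = 25))]
  Ms <- sort(unique(c(Ms, Ms + step / 2, Ms - step / 2)))
  best <- list(rss = Inf)
  for (M in Ms) for (s in ss) {
    b <- shape(M, s)
    X <- cbind(1, b)
    beta <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (is.null(beta) || any(!is.finite(beta))) next
    rss <- sum((y - X %*% beta)^2)
    if (rss < best$rss)
      best <- list(rss = rss, A = beta[1], K = beta[1] + beta[2],
                   M = M, s = s)
  }
  best$resid <- sqrt(best$rss / length(y))
  best
}

# full width of a sampled peak at a given level (linear interpolation)
peak_width <- function(x, y, level) {
  above <- y >= level
  if (!any(above)) return(0)
  i <- range(which(above))
  x_lo <- if (i[1] > 1) {
    j <- i[1]
    x[j - 1] + (level - y[j - 1]) / (y[j] - y[j - 1]) * (x[j] - x[j - 1])
  } else x[1]
  x_hi <- if (i[2] < length(x)) {
    j <- i[2]
    x[j] + (y[j] - level) / (y[j] - y[j + 1]) * (x[j + 1] - x[j])
  } else x[length(x)]
  x_hi - x_lo
}

# distances from the 98%-of-plateau crossing of a falling profile to its
# 50% and 20% crossings
drop_widths <- function(rf, yf, plateau) {
  cross <- function(level) {
    below <- which(yf <= level)
    if (!length(below)) return(NA_real_)
    j <- below[1]
    if (j == 1) return(rf[1])
    rf[j - 1] + (yf[j - 1] - level) / (yf[j - 1] - yf[j]) *
      (rf[j] - rf[j - 1])
  }
  r100 <- cross(0.98 * plateau)
  r50 <- cross(0.50 * plateau)
  r20 <- cross(0.20 * plateau)
  c(r50 - r100, r20 - r100)
}

#' @export
print.dsf_result <- function(x, ...) {
  cat(sprintf("<dsf_result %s%s> FWHM %.2f mm, FW20M %.2f mm, w(100-50) %.2f mm, w(100-20) %.2f mm\n",
              x$family, if (x$ok) "" else " (fit rejected)",
              x$fwhm, x$fw20m, x$w100_50, x$w100_20))
  invisible(x)
}

#' Plan-independent sampling axis through a target / OAR abutment
#'
#' For falloff comparisons *between* plans the sampled line must be the same
#' for every plan, otherwise surface geometry confounds plan steepness. This
#' axis depends only on anatomy: it runs along the target-to-OAR centroid
#' direction, anchored at the midpoint between the target's last voxel and
#' the OAR's first voxel along that direction, extended one plateau length
#' back into the target and one falloff length beyond.
#'
#' @param structures a [structure_set()].
#' @param target,oar structure names.
#' @param plateau_mm,falloff_mm segment extensions (mm).
#' @return list with `p0`, `p1` (mm endpoints) and the contact point `c`.
#' @export
abutment_axis <- function(structures, target = "GTV", oar = "duodenum",
                          plateau_mm = 15, falloff_mm = 25) {
  grid <- structures$grid
  mt <- structures$masks[[target]]
  mo <- structures$masks[[oar]]
  if (is.null(mt) || is.null(mo)) stop("unknown structure name")
  ct <- colMeans(mask_centers(mt, grid))
  co <- colMeans(mask_centers(mo, grid))
  u <- co - ct
  u <- u / sqrt(sum(u^2))
  # march from the target centroid toward the OAR
  tt <- seq(0, sqrt(sum((co - ct)^2)) + 30, by = min(grid$spacing) / 2)
  pts <- cbind(ct[1] + tt * u[1], ct[2] + tt * u[2], ct[3] + tt * u[3])
  in_t <- sample_mask(mt, grid, pts)
  in_o <- sample_mask(mo, grid, pts)
  t_exit <- if (any(in_t)) tt[max(which(in_t))] else 0
  t_enter <- if (any(in_o)) tt[min(which(in_o))] else t_exit
  cpt <- ct + (t_exit + t_enter) / 2 * u
  list(p0 = cpt - plateau_mm * u, p1 = cpt + falloff_mm * u, c = cpt)
}

#' Locate the line-dose segment across the isodose / OAR abutment
#'
#' Finds the closest approach between the prescription (100%) isodose region
#' and an OAR, and returns a sampling segment through it, directed from the
#' isodose toward the OAR, extended one plateau length into the isodose and
#' one falloff length beyond the OAR surface. When the isodose already
#' overlaps the OAR the segment runs through the overlap centroid along the
#' line joining the two region centroids.
#'
#' @param dose_grid a `voxel_grid` with unit `"Gy(RBE)"`.
#' @param prescription isodose threshold in Gy(RBE).
#' @param oar logical OAR mask.
#' @param plateau_mm extension into the isodose (mm).
#' @param falloff_mm extension beyond the OAR surface (mm).
#' @return list with `p0`, `p1` (mm endpoints), `gap_mm` (closest distance,
#'   0 if overlapping) and `overlap` flag.
#' @export
locate_abutment_line <- function(dose_grid, prescription, oar,
                                 plateau_mm = 15, falloff_mm = 25) {
  iso <- dose_grid$values >= prescription
  if (!any(iso)) stop("100% isodose region is empty (underdosed plan)")
  if (!any(oar)) stop("OAR mask is empty")
  ov <- iso & oar
  ci <- colMeans(mask_centers(iso, dose_grid))
  co <- colMeans(mask_centers(oar, dose_grid))
  if (any(ov)) {
    mid <- colMeans(mask_centers(ov, dose_grid))
    u <- co - ci
    u <- u / sqrt(sum(u^2))
    return(list(p0 = mid - plateau_mm * u, p1 = mid + falloff_mm * u,
                gap_mm = 0, overlap = TRUE))
  }
  Pi <- mask_centers(iso, dose_grid)
  Po <- mask_centers(oar, dose_grid)
  # closest voxel pair; on discrete surfaces many pairs tie within a voxel
  # diagonal, so ties are broken first toward pairs whose connecting line
  # aligns with the centroid axis, then toward the most central midpoint —
  # the segment then crosses the abutment centrally, not at a tangential
  # edge
  diag2 <- sum(dose_grid$spacing^2)
  axis_u <- co - ci
  axis_u <- axis_u / max(sqrt(sum(axis_u^2)), 1e-9)
  best <- list(d2 = Inf, align = -Inf, off = Inf, pi = NA, po = NA)
  step <- max(1L, as.integer(floor(2e6 / nrow(Po))))
  start <- 1L
  while (start <= nrow(Pi)) {
    end <- min(nrow(Pi), start + step - 1L)
    Pc <- Pi[start:end, , drop = FALSE]
    d2 <- outer(rowSums(Pc^2), rowSums(Po^2), "+") - 2 * Pc %*% t(Po)
    cand <- which(d2 <= min(d2, best$d2) + diag2)
    for (m in cand) {
      ij <- arrayInd(m, dim(d2))
      p1_ <- Pc[ij[1], ]
      p2_ <- Po[ij[2], ]
      dvec <- p2_ - p1_
      align <- if (sum(dvec^2) > 1e-12)
        abs(sum(dvec * axis_u)) / sqrt(sum(dvec^2)) else 1
      v <- (p1_ + p2_) / 2 - ci
      off <- sum((v - sum(v * axis_u) * axis_u)^2)
      better <- d2[m] < best$d2 - diag2 ||
        (d2[m] <= best$d2 + diag2 &&
           (align > best$align + 1e-9 ||
              (align >= best$align - 1e-9 && off < best$off)))
      if (better) best <- list(d2 = min(d2[m], best$d2), align = align,
                               off = off, pi = p1_, po = p2_)
    }
    start <- end + 1L
  }
  pi_ <- best$pi
  po_ <- best$po
  gap <- sqrt(max(sum((po_ - pi_)^2), 0))
  u <- if (gap > 1e-9) (po_ - pi_) / gap else {
    v <- co - ci
    v / sqrt(sum(v^2))
  }
  list(p0 = pi_ - plateau_mm * u, p1 = po_ + falloff_mm * u,
       gap_mm = gap, overlap = FALSE)
}
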