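# Growth and metabolite calculations for fermentation time courses:
# OD-to-biomass conversion, maximum specific growth rate, growth yield,
# specific-carbon totals through an exponential-rise fit, sigmoidal titer
# fits, specific rates, and the cytosolic concentration conversion.

#' Cell constants for biomass and volume conversions
#'
#' Defaults are the platform's worked values: 2.01 mg DCW/mL/OD600 for the
#' OD conversion, a cell volume of 160 um^3 and a cell mass of 60 pg, and
#' the stated (rounded) cytosolic volume of 2.7 mL/g DCW used for specific
#' to cytosolic concentration conversion. [deriveCellConstants()] fills in
#' the quantities derived from mass and volume (about 1.7e10 cells/g DCW
#' and 2.67 mL/g DCW unrounded).
#'
#' @param dcw_per_od mg DCW per mL per OD600 unit
#' @param cell_volume_um3 single-cell volume, um^3
#' @param cell_mass_pg single-cell dry mass, pg
#' @param cytosolic_volume_mL_per_g cytosolic volume used for concentration
#'   conversion, mL/g DCW
#' @return list of class "CellConstants"
#' @export
cellConstants <- function(dcw_per_od = 2.01, cell_volume_um3 = 160,
                          cell_mass_pg = 60,
                          cytosolic_volume_mL_per_g = 2.7) {
  stopifnot(dcw_per_od > 0, cell_volume_um3 > 0, cell_mass_pg > 0,
            cytosolic_volume_mL_per_g > 0)
  structure(list(dcw_per_od = dcw_per_od,
                 cell_volume_um3 = cell_volume_um3,
                 cell_mass_pg = cell_mass_pg,
                 cytosolic_volume_mL_per_g = cytosolic_volume_mL_per_g),
            class = "CellConstants")
}

#' Derive per-gram cell quantities from single-cell mass and volume
#'
#' cells/g DCW is the reciprocal of the single-cell mass; the cytosolic
#' volume per g DCW is cells/g times the single-cell volume. With the
#' default 60 pg and 160 um^3 this gives 1.7e10 cells/g and 2.7 mL/g to
#' two significant figures.
#'
#' @param constants a [cellConstants()]
#' @return the constants list extended with cells_per_g and
#'   derived_cytosolic_volume_mL_per_g (unrounded)
#' @export
deriveCellConstants <- function(constants = cellConstants()) {
  cells_per_g <- 1 / (constants$cell_mass_pg * 1e-12)
  vol <- cells_per_g * constants$cell_volume_um3 * 1e-12   # um^3 -> mL
  constants$cells_per_g <- cells_per_g
  constants$derived_cytosolic_volume_mL_per_g <- vol
  constants
}

#' Convert OD600 to dry cell weight
#'
#' @param od600 optical density (>= 0)
#' @param constants a [cellConstants()]
#' @return mg DCW/mL (numerically equal to g DCW/L)
#' @export
odToDcw <- function(od600, constants = cellConstants()) {
  if (any(od600 < 0)) stop("negative OD600")
  od600 * constants$dcw_per_od
}

#' Convert a specific concentration to a cytosolic concentration
#'
#' Divides umol/g DCW by the cytosolic volume (mL/g DCW); umol/mL is mM.
#' With the default 2.7 mL/g DCW, 520 umol/g DCW gives about 192 mM and
#' 351 umol/g DCW about 129 mM.
#'
#' @param specific_conc umol/g DCW (>= 0)
#' @param constants a [cellConstants()]
#' @return mM
#' @export
cytosolicConcentration <- function(specific_conc,
                                   constants = cellConstants()) {
  if (any(specific_conc < 0)) stop("negative specific concentration")
  specific_conc / constants$cytosolic_volume_mL_per_g
}

#' Fold change
#'
#' @param a,b values in the same units; b must be positive
#' @return a/b
#' @export
foldChange <- function(a, b) {
  if (any(b <= 0)) stop("fold change needs a positive reference value")
  a / b
}

#' Maximum specific growth rate from a growth series
#'
#' Log-linear least squares of ln(DCW) against time over the exponential
#' window. Unless `window` is given, the window is auto-selected as the
#' contiguous stretch of at least `min_points` points with positive slope
#' maximizing R^2 (ties: longer, then earlier). Returns mu_max = 0 with a
#' warning flag when no positive-slope window exists.
#'
#' @param time_h time points, strictly increasing
#' @param dcw biomass (any fixed unit, e.g. g DCW/L); only positive points
#'   enter the fit
#' @param window optional c(t_start, t_end) to fit over
#' @param min_points minimum window length (default 4)
#' @return list(mu_max (1/h), window = c(t_start, t_end), r2, flat =
#'   logical flag)
#' @export
fitMuMax <- function(time_h, dcw, window = NULL, min_points = 4L) {
  ok <- dcw > 0 & is.finite(dcw)
  t <- time_h[ok]; y <- log(dcw[ok])
  if (length(t) < min_points)
    stop("need at least ", min_points, " positive biomass points")
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    if (sum(sel) < 2) stop("window contains fewer than 2 points")
    f <- stats::lm(y[sel] ~ t[sel])
    mu <- unname(stats::coef(f)[2])
    r2 <- suppressWarnings(summary(f)$r.squared)
    return(list(mu_max = max(mu, 0), window = window, r2 = r2,
                flat = mu <= 0))
  }
  n <- length(t)
  best <- NULL
  slope_tol <- 1e-10 * max(abs(y), 1)
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      tt <- t[i:j]; yy <- y[i:j]
      f <- stats::lm(yy ~ tt)
      sl <- unname(stats::coef(f)[2])
      if (!is.finite(sl) || sl <= slope_tol) next
      r2 <- suppressWarnings(summary(f)$r.squared)
      if (!is.finite(r2)) next
      if (is.null(best) || r2 > best$r2 + 1e-12 ||
          (abs(r2 - best$r2) <= 1e-12 && (j - i) > (best$j - best$i))) {
        best <- list(mu = sl, r2 = r2, i = i, j = j)
      }
    }
  }
  if (is.null(best)) {
    warning("no positive-slope exponential window found; mu_max set to 0")
    return(list(mu_max = 0, window = c(NA_real_, NA_real_), r2 = NA_real_,
                flat = TRUE))
  }
  list(mu_max = best$mu, window = c(t[best$i], t[best$j]), r2 = best$r2,
       flat = FALSE)
}

#' Growth yield on glucose
#'
#' Maximum grams of DCW formed per gram of glucose consumed, taken over
#' all time points relative to inoculation.
#'
#' @param time_h time points
#' @param dcw_gL biomass, g DCW/L
#' @param glucose_gL residual glucose, g/L
#' @return g DCW/g glucose
#' @export
growthYield <- function(time_h, dcw_gL, glucose_gL) {
  stopifnot(length(time_h) == length(dcw_gL),
            length(time_h) == length(glucose_gL))
  o <- order(time_h)
  dcw_gL <- dcw_gL[o]; glucose_gL <- glucose_gL[o]
  dx <- dcw_gL - dcw_gL[1]
  ds <- glucose_gL[1] - glucose_gL
  if (all(ds <= 0)) stop("no glucose consumed")
  sel <- ds > 0
  max(pmax(dx[sel], 0) / ds[sel])
}

#' Two-parameter exponential rise to maximum fit
#'
#' Nonlinear least squares of y = A (1 - exp(-k t)). Returns the
#' parameters, the fitted value at `t_eval` (48 h by default, the
#' conventional read-off point for specific-carbon totals) and the standard error of
#' that fitted value (delta method on the parameter covariance).
#'
#' @param time_h times (h), at least 3 points
#' @param values responses
#' @param t_eval evaluation time for the reported value (default 48)
#' @return list(A, k, value_at_eval, fit_error, t_eval)
#' @export
fitExponentialRise <- function(time_h, values, t_eval = 48) {
  if (length(time_h) < 3) stop("need at least 3 points for a 2-parameter fit")
  df <- data.frame(t = time_h, y = values)
  A0 <- max(values)
  if (A0 <= 0) stop("responses must rise above zero")
  pos <- df$t > 0 & df$y > 0 & df$y < A0
  k0 <- if (any(pos)) {
    stats::median(-log(1 - df$y[pos] / (A0 * 1.05)) / df$t[pos])
  } else 0.1
  k0 <- max(k0, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = df,
                      start = list(A = A0, k = k0),
                      lower = c(A = 0, k = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("exponential-rise fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["k"]] <= 0) stop("exponential-rise fit rejected: k <= 0")
  val <- cf[["A"]] * (1 - exp(-cf[["k"]] * t_eval))
  grad <- c(1 - exp(-cf[["k"]] * t_eval),
            cf[["A"]] * t_eval * exp(-cf[["k"]] * t_eval))
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (is.null(vc) || any(!is.finite(vc))) NA_real_
        else sqrt(max(0, drop(t(grad) %*% vc %*% grad)))
  list(A = unname(cf[["A"]]), k = unname(cf[["k"]]), value_at_eval = val,
       fit_error = se, t_eval = t_eval)
}

#' Specific-carbon total downstream of a pathway step
#'
#' Sums specific concentrations (umol/g DCW) over a set of downstream
#' metabolites at each time point up to `t_max`, fits the summed series
#' with the 2-parameter exponential rise, and reports the fitted value at
#' 48 h with the fit's standard error. `mode = "carbon_mol"` weights each
#' metabolite by its carbon count (umol C/g DCW) instead of counting
#' molecules.
#'
#' @param timecourse data.frame with a time_h column and one column per
#'   metabolite (umol/g DCW); replicate columns should be averaged first
#' @param downstream_set metabolite column names to sum
#' @param mode "metabolite_mol" (default) or "carbon_mol"
#' @param carbon_counts named vector of carbon counts, required for
#'   carbon_mol mode
#' @param t_max time cutoff for the fit (default 48 h)
#' @param t_eval evaluation time (default 48 h)
#' @return list(downstream_set, A, k, value_at_48h, fit_error)
#' @export
carbonTotal <- function(timecourse, downstream_set,
                        mode = c("metabolite_mol", "carbon_mol"),
                        carbon_counts = NULL, t_max = 48, t_eval = 48) {
  mode <- match.arg(mode)
  if (!length(downstream_set)) stop("empty downstream set")
  miss <- setdiff(downstream_set, names(timecourse))
  if (length(miss)) stop("metabolite column(s) absent: ",
                         paste(miss, collapse = ", "))
  w <- rep(1, length(downstream_set))
  if (mode == "carbon_mol") {
    if (is.null(carbon_counts) ||
        !all(downstream_set %in% names(carbon_counts)))
      stop("carbon_mol mode needs carbon_counts for every set member")
    w <- carbon_counts[downstream_set]
  }
  sel <- timecourse$time_h <= t_max
  tot <- as.matrix(timecourse[sel, downstream_set, drop = FALSE]) %*% w
  fit <- fitExponentialRise(timecourse$time_h[sel], drop(tot),
                            t_eval = t_eval)
  list(downstream_set = downstream_set, mode = mode, A = fit$A, k = fit$k,
       value_at_48h = fit$value_at_eval, fit_error = fit$fit_error)
}

#' Three-parameter sigmoidal titer fit
#'
#' Least-squares fit of y = a / (1 + exp(-(t - t0)/b)); the plateau `a` is
#' the estimated final titer. Monotone-decreasing series are rejected.
#'
#' @param time_h times (h), at least 4 points
#' @param values titers
#' @return list(a, b, t0, final_titer)
#' @export
fitSigmoid3 <- function(time_h, values) {
  if (length(time_h) < 4) stop("need at least 4 points for a 3-parameter fit")
  if (unname(stats::coef(stats::lm(values ~ time_h))[2]) <= 0)
    stop("series is not increasing; sigmoidal titer fit rejected")
  a0 <- max(values)
  t00 <- stats::median(time_h)
  b0 <- max(diff(range(time_h)) / 8, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a / (1 + exp(-(t - t0) / b)),
                      data = data.frame(t = time_h, y = values),
                      start = list(a = a0, b = b0, t0 = t00),
                      lower = c(a = 0, b = 1e-6, t0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("sigmoidal fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  list(a = unname(cf[["a"]]), b = unname(cf[["b"]]), t0 = unname(cf[["t0"]]),
       final_titer = unname(cf[["a"]]))
}

#' Specific uptake/production rate over a phase window
#'
#' Least-squares slope of the metabolite amount (mmol/L) against the
#' biomass-time integral (g DCW h/L, trapezoidal) over the window: the
#' standard estimator of a constant specific rate q in dM/dt = q X(t).
#' Negative slopes indicate consumption.
#'
#' @param time_h times (h)
#' @param dcw_gL biomass, g DCW/L
#' @param amount_mM metabolite concentration, mmol/L
#' @param phase c(t_start, t_end) window; at least 3 points inside
#' @return mmol/g DCW/h
#' @export
rateEstimate <- function(time_h, dcw_gL, amount_mM,
                         phase = range(time_h)) {
  o <- order(time_h)
  time_h <- time_h[o]; dcw_gL <- dcw_gL[o]; amount_mM <- amount_mM[o]
  cumX <- c(0, cumsum(diff(time_h) *
                      (utils::head(dcw_gL, -1) + utils::tail(dcw_gL, -1)) / 2))
  sel <- time_h >= phase[1] & time_h <= phase[2]
  if (sum(sel) < 3) stop("phase window contains fewer than 3 points")
  x <- cumX[sel]
  if (diff(range(x)) < 1e-12) stop("degenerate window: no biomass integral")
  unname(stats::coef(stats::lm(amount_mM[sel] ~ x))[2])
}

#' Read a fermentation time-course CSV
#'
#' Expects columns `time_h`, `replicate`, `od600`, optionally
#' `glucose_gL`, and one column per measurement named
#' `<species>__intra` (umol/g DCW) or `<species>__extra` (mM).
#'
#' @param path CSV path
#' @return data.frame sorted by replicate and time
#' @export
readTimeCourse <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time_h", "replicate", "od600")
  if (!all(need %in% names(df)))
    stop("time-course CSV needs columns: ", paste(need, collapse = ", "))
  df <- df[order(df$replicate, df$time_h), , drop = FALSE]
  for (rep_id in unique(df$replicate)) {
    tt <- df$time_h[df$replicate == rep_id]
    if (any(diff(tt) <= 0))
      stop("time not strictly increasing for replicate ", rep_id)
  }
  rownames(df) <- NULL
  df
}
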