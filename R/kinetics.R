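#' Assay configuration
#'
#' @param epsilon Molar extinction coefficient of the detected product,
#'   L/(mol*cm); default 25000 (conjugated-diene hydroperoxide at 234 nm).
#' @param path_length Cuvette path length, cm.
#' @param reaction_volume Assay volume, L.
#' @param enzyme_mass Enzyme in the assay, mg.
#' @param enzyme_molar_conc Enzyme concentration, mol/L (needed for kcat).
#' @return List of class `assay_config`.
#' @export
assay_config <- function(epsilon = 25000, path_length = 1,
                         reaction_volume = 1e-3, enzyme_mass = 1,
                         enzyme_molar_conc = NA_real_) {
  vals <- list(epsilon = epsilon, path_length = path_length,
               reaction_volume = reaction_volume, enzyme_mass = enzyme_mass,
               enzyme_molar_conc = enzyme_molar_conc)
  pos <- unlist(vals[c("epsilon", "path_length", "reaction_volume",
                       "enzyme_mass")])
  if (any(pos <= 0)) stop("assay_config values must be positive")
  structure(vals, class = "assay_config")
}

#' Fit first-order thermal inactivation
#'
#' Residual activity after heat treatment is modeled as first-order
#' decay: ordinary least squares of `ln Y` on time `X` gives
#' `ln Y = -kd*X + b`, with half-life `t1/2 = ln 2 / kd`. Points with
#' non-positive residual activity cannot enter the log fit and are
#' excluded with a warning. An optional nonlinear mode fits
#' `Y = exp(b - kd*X)` directly, which weights noisy late points less.
#'
#' @param time Minutes, strictly increasing.
#' @param residual_activity Fraction of the untreated control.
#' @param method `"loglinear"` (default) or `"nonlinear"`.
#' @return List of class `inactivation_fit`: `kd` (1/min), `b`,
#'   `t_half` (min; `Inf` with `decaying = FALSE` for non-decaying
#'   series), `r_squared`, `n_used`.
#' @export
fit_inactivation <- function(time, residual_activity,
                             method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  if (length(time) != length(residual_activity))
    stop("time and residual_activity must have equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing")
  usable <- residual_activity > 0
  if (any(!usable))
    warning(sum(!usable), " point(s) with non-positive residual activity excluded")
  x <- time[usable]
  y <- residual_activity[usable]
  if (length(x) < 3L) stop("need at least 3 usable points")
  fit <- stats::lm(log(y) ~ x)
  kd <- -unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((log(y) - mean(log(y)))^2)
  if (method == "nonlinear") {
    nl <- minpack.lm::nlsLM(y ~ exp(b0 - k0 * x),
                            start = list(b0 = b, k0 = max(kd, 1e-6)))
    kd <- unname(stats::coef(nl)[["k0"]])
    b <- unname(stats::coef(nl)[["b0"]])
    r2 <- 1 - sum(stats::resid(nl)^2) / sum((y - mean(y))^2)
  }
  decaying <- kd > 0
  if (!decaying)
    warning("series is not decaying (kd <= 0); half-life reported as Inf")
  structure(list(kd = kd, b = b,
                 t_half = if (decaying) log(2) / kd else Inf,
                 r_squared = r2, n_used = length(x), decaying = decaying),
            class = "inactivation_fit")
}

## Two-state melt model: linear native and denatured baselines joined by
## a Boltzmann sigmoid with midpoint Tm and steepness k (in degrees).
melt_model <- function(temp, tm, k, an, bn, ad, bd) {
  f <- 1 / (1 + exp((tm - temp) / k))
  (an + bn * temp) * (1 - f) + (ad + bd * temp) * f
}

#' Fit a two-state thermal melting curve
#'
#' Nonlinear least squares of a Boltzmann sigmoid with linear pre- and
#' post-transition baselines; the unfolding midpoint is `Tm`. The fit is
#' initialized at the temperature of the steepest numerical derivative,
#' with baselines estimated from the first and last quarters of the
#' scan. A curve whose sigmoid fit is not better than a straight line
#' (by AIC) has no detectable transition and raises an error.
#'
#' @param temperature Degrees C, increasing.
#' @param signal Spectroscopic or calorimetric melt signal (e.g. 222 nm
#'   ellipticity), arbitrary units.
#' @return List of class `melt_fit`: `tm` (deg C), `steepness` (deg C),
#'   `baselines` (native/denatured intercept+slope), `r_squared`.
#' @export
fit_melting <- function(temperature, signal) {
  if (length(temperature) != length(signal))
    stop("temperature and signal must have equal length")
  if (length(temperature) < 8L) stop("need at least 8 points spanning a transition")
  ord <- order(temperature)
  temp <- temperature[ord]; y <- signal[ord]

  lin <- stats::lm(y ~ temp)
  dy <- diff(y) / diff(temp)
  tm0 <- temp[which.max(abs(dy))]
  q <- max(3L, length(temp) %/% 4L)
  nfit <- stats::lm(y[seq_len(q)] ~ temp[seq_len(q)])
  dtail <- seq(length(temp) - q + 1L, length(temp))
  dfit <- stats::lm(y[dtail] ~ temp[dtail])
  start <- list(tm = tm0, k = max(diff(range(temp)) / 20, 0.5),
                an = unname(stats::coef(nfit)[1]), bn = unname(stats::coef(nfit)[2]),
                ad = unname(stats::coef(dfit)[1]), bd = unname(stats::coef(dfit)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ melt_model(temp, tm, k, an, bn, ad, bd),
                      start = start,
                      lower = c(min(temp), 1e-3, rep(-Inf, 4)),
                      upper = c(max(temp), diff(range(temp)), rep(Inf, 4)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit) || stats::AIC(fit) >= stats::AIC(lin))
    stop("no detectable unfolding transition (sigmoid fit no better than linear)")
  cf <- as.list(stats::coef(fit))
  amp <- abs((cf$ad + cf$bd * cf$tm) - (cf$an + cf$bn * cf$tm))
  if (diff(range(y)) == 0 || amp < 1e-3 * diff(range(y)))
    stop("no detectable unfolding transition (negligible amplitude)")
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(list(tm = cf$tm, steepness = cf$k,
                 baselines = list(native = c(intercept = cf$an, slope = cf$bn),
                                  denatured = c(intercept = cf$ad, slope = cf$bd)),
                 r_squared = r2),
            class = "melt_fit")
}

#' Fit Michaelis–Menten kinetics
#'
#' Nonlinear least squares of `v = Vmax*S/(Km + S)`, initialized from
#' the Hanes–Woolf linearization (`S/v` vs `S`). When the enzyme molar
#' concentration is supplied, `kcat = Vmax / [E]` and the catalytic
#' efficiency `kcat/Km` follow. A fit whose Km exceeds the largest
#' tested substrate concentration is flagged as non-saturating.
#'
#' @param substrate Substrate concentrations, umol/L.
#' @param rate Initial rates (units of the assay; Vmax inherits them).
#' @param config An [assay_config()]; `enzyme_molar_conc` enables kcat.
#'   Rates must then be in mol/L/s for kcat in 1/s.
#' @return List of class `kinetics_fit`: `km` (umol/L), `vmax`, `kcat`
#'   (1/s or `NA`), `efficiency` (L/(mmol*s) or `NA`), `r_squared`,
#'   `saturating`.
#' @export
fit_michaelis_menten <- function(substrate, rate, config = assay_config()) {
  if (length(substrate) < 5L) stop("need at least 5 substrate levels")
  if (any(rate <= 0) || any(substrate <= 0))
    stop("substrate and rate values must be positive")
  hanes <- stats::lm(I(substrate / rate) ~ substrate)
  vmax0 <- 1 / unname(stats::coef(hanes)[2])
  km0 <- unname(stats::coef(hanes)[1]) * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(rate)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(substrate)
  fit <- minpack.lm::nlsLM(rate ~ vmax * substrate / (km + substrate),
                           start = list(vmax = vmax0, km = km0),
                           lower = c(1e-12, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  km <- unname(cf[["km"]]); vmax <- unname(cf[["vmax"]])
  saturating <- km <= max(substrate)
  if (!saturating)
    warning("Km estimate exceeds the largest tested substrate concentration; ",
            "data may be non-saturating")
  kcat <- if (is.finite(config$enzyme_molar_conc) && config$enzyme_molar_conc > 0)
    vmax / config$enzyme_molar_conc else NA_real_
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((rate - mean(rate))^2)
  structure(list(km = km, vmax = vmax, kcat = kcat,
                 efficiency = if (is.na(kcat)) NA_real_
                              else catalytic_efficiency(kcat, km),
                 r_squared = r2, saturating = saturating),
            class = "kinetics_fit")
}

#' Catalytic efficiency kcat/Km in L/(mmol*s)
#'
#' With kcat in 1/s and Km in umol/L, `kcat/Km` is in L/(umol*s); the
#' conventional reporting unit L/(mmol*s) is 1000-fold larger.
#'
#' @param kcat Turnover number, 1/s.
#' @param km Michaelis constant, umol/L.
#' @return Efficiency in L/(mmol*s).
#' @export
catalytic_efficiency <- function(kcat, km) {
  if (any(km <= 0)) stop("Km must be positive")
  kcat / km * 1000
}

#' Product formation rate and specific activity from an absorbance slope
#'
#' Beer–Lambert: a slope of `dA/dt` (per minute) corresponds to a
#' product concentration increase of `slope / (epsilon * path)` mol/L
#' per minute. One international unit (IU) is taken as the enzyme
#' producing 1 umol/L product per minute in the assay; specific activity
#' is IU per mg enzyme.
#'
#' @param slope Absorbance change per minute.
#' @param config An [assay_config()].
#' @return List: `rate_uM_per_min`, `iu`, `specific_activity` (IU/mg).
#' @export
activity_from_absorbance <- function(slope, config = assay_config()) {
  rate <- slope / (config$epsilon * config$path_length) * 1e6
  list(rate_uM_per_min = rate, iu = rate,
       specific_activity = rate / config$enzyme_mass)
}

#' Optimal temperature of an activity profile
#'
#' Temperature of maximum measured activity, without interpolation.
#' Ties go to the lowest temperature; a maximum at either end of the
#' tested range is flagged as a boundary estimate.
#'
#' @param temperature Degrees C.
#' @param activity Measured activity at each temperature.
#' @return List: `t_opt`, `boundary` (logical), `tie` (logical).
#' @export
optimal_temperature <- function(temperature, activity) {
  if (length(temperature) < 3L) stop("need at least 3 temperatures")
  if (length(temperature) != length(activity))
    stop("temperature and activity must have equal length")
  winners <- temperature[activity == max(activity)]
  t_opt <- min(winners)
  list(t_opt = t_opt,
       boundary = t_opt %in% range(temperature),
       tie = length(winners) > 1L)
}
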