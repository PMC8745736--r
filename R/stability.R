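#' Two-state melt-curve model
#'
#' Boltzmann sigmoid between two linear baselines: the CD signal at
#' temperature T is `folded(T) + (unfolded(T) - folded(T)) * f_u(T)` with
#' unfolded fraction `f_u = 1 / (1 + exp((t_m - T) / width))`. At `T = t_m`
#' the signal is the midpoint of the two baselines.
#'
#' @param temperature Temperatures, degrees C.
#' @param t_m Midpoint (melting) temperature, degrees C.
#' @param width Transition width, degrees C (> 0).
#' @param folded,unfolded Baselines as `c(intercept, slope)` in signal units
#'   (signal = intercept + slope * T).
#' @return Model signal values.
#' @export
melt_signal <- function(temperature, t_m, width, folded = c(0, 0),
                        unfolded = c(-1, 0)) {
  bf <- folded[1] + folded[2] * temperature
  bu <- unfolded[1] + unfolded[2] * temperature
  fu <- 1 / (1 + exp((t_m - temperature) / width))
  bf + (bu - bf) * fu
}

#' Fit a melting temperature from a CD melt curve
#'
#' Fits the two-state sigmoid [melt_signal()] with linear folded/unfolded
#' baselines to an ellipticity-versus-temperature ramp by
#' Levenberg-Marquardt. The transition width is log-parameterized to stay
#' positive. Baselines are initialized from the outer 15% of the ramp and
#' `t_m` from the temperature where the baseline-corrected signal crosses
#' its midpoint.
#'
#' @param curve Data frame with columns `temperature` (strictly increasing,
#'   >= 10 points) and `signal`.
#' @return Object of class `melt_fit`: `t_m`, `t_m_se`, `transition_width`,
#'   `folded`, `unfolded` (intercept/slope pairs), `r2`, `fitted`.
#' @export
fit_melting_curve <- function(curve) {
  temp <- curve$temperature
  sig <- curve$signal
  check_increasing(temp, "temperature")
  if (length(temp) < 10L) stop_input("melt curve needs >= 10 points")

  n <- length(temp)
  k <- max(3L, ceiling(0.15 * n))
  lo <- lsq_line(temp[1:k], sig[1:k])
  hi <- lsq_line(temp[(n - k + 1):n], sig[(n - k + 1):n])
  bf0 <- lo$intercept; bf1 <- lo$slope
  bu0 <- hi$intercept; bu1 <- hi$slope
  # unfolded-fraction estimate from the baseline-corrected signal
  denom <- (bu0 + bu1 * temp) - (bf0 + bf1 * temp)
  amp0 <- mean(denom[(n - k + 1):n]) # amplitude near the hot end
  resid_sd <- sd(c(sig[1:k] - (bf0 + bf1 * temp[1:k]),
                   sig[(n - k + 1):n] - (bu0 + bu1 * temp[(n - k + 1):n])))
  if (abs(amp0) <= 4 * max(resid_sd, .Machine$double.eps))
    stop_input("no transition detected: monotone baseline only")
  fu <- (sig - (bf0 + bf1 * temp)) / denom
  tm0 <- temp[which.min(abs(fu - 0.5))]
  w0 <- max(diff(range(temp)) / 30, 0.5)

  dat <- data.frame(T = temp, y = sig)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (bf0 + bf1 * T) +
        ((bu0 + bu1 * T) - (bf0 + bf1 * T)) / (1 + exp((tm - T) / exp(lw))),
      data = dat,
      start = list(bf0 = bf0, bf1 = bf1, bu0 = bu0, bu1 = bu1,
                   tm = tm0, lw = log(w0)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) stop_input("melt fit did not converge: %s",
                                   conditionMessage(e)))
  p <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 6))
  t_m <- p[["tm"]]
  if (t_m < min(temp) || t_m > max(temp))
    stop_input("no transition detected: fitted midpoint outside the ramp")
  pred <- melt_signal(temp, t_m, exp(p[["lw"]]),
                      folded = c(p[["bf0"]], p[["bf1"]]),
                      unfolded = c(p[["bu0"]], p[["bu1"]]))
  structure(
    list(t_m = t_m, t_m_se = se[[5]], transition_width = exp(p[["lw"]]),
         folded = c(intercept = p[["bf0"]], slope = p[["bf1"]]),
         unfolded = c(intercept = p[["bu0"]], slope = p[["bu1"]]),
         r2 = 1 - sum((sig - pred)^2) / sum((sig - mean(sig))^2),
         fitted = pred),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state melt fit: T_m = %.2f +/- %.2g C (width %.2f C, R2 = %.4f)\n",
              x$t_m, x$t_m_se, x$transition_width, x$r2))
  invisible(x)
}

#' Fit a first-order thermal inactivation constant
#'
#' Fits `a(t) = exp(-k_in * t)` to a residual-activity time course
#' normalized to 1 at t = 0. The log-linear slope initializes a direct
#' nonlinear fit (primary), which avoids the noise bias of fitting on the
#' log scale. Points below the detection floor are excluded.
#'
#' @param series Data frame with columns `time_h` (>= 0) and `activity`
#'   (fraction of the t = 0 value; values < 0 or > 1.5 are rejected).
#' @param floor Detection floor as a fraction of initial activity
#'   (default 0.01); points below it are dropped from the fit.
#' @return Object of class `inactivation_fit`: `k_in` (1/h), `k_in_se`,
#'   `half_life` (h; `Inf` with `stable = TRUE` when k_in is 0), `n_used`.
#' @export
fit_inactivation_decay <- function(series, floor = 0.01) {
  t <- series$time_h
  a <- series$activity
  if (any(t < 0)) stop_input("'time_h' must be non-negative")
  if (any(a < 0 | a > 1.5))
    stop_input("'activity' must lie in [0, 1.5] (fraction of initial)")
  if (length(t) < 3L) stop_input("need >= 3 time points")
  keep <- a >= floor
  if (sum(keep) < 2L) stop_input("all points below the detection floor")
  tk <- t[keep]; ak <- a[keep]

  # log-linear initializer
  k0 <- if (length(unique(tk)) > 1L) max(-lsq_line(tk, log(ak))$slope, 0) else 0
  if (k0 == 0 && max(ak) - min(ak) < .Machine$double.eps * 100) {
    # constant series: no decay
    res <- list(k_in = 0, k_in_se = 0, half_life = Inf, stable = TRUE,
                n_used = sum(keep))
    return(structure(res, class = "inactivation_fit"))
  }
  dat <- data.frame(t = tk, a = ak)
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ exp(-k * t), data = dat, start = list(k = max(k0, 1e-6)),
                      lower = 0,
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-15)),
    error = function(e) stop_input("inactivation fit did not converge: %s",
                                   conditionMessage(e)))
  k <- coef(fit)[["k"]]
  se <- tryCatch(sqrt(diag(vcov(fit)))[[1]], error = function(e) NA_real_)
  structure(
    list(k_in = k, k_in_se = se,
         half_life = if (k > 0) log(2) / k else Inf,
         stable = k <= 0, n_used = nrow(dat)),
    class = "inactivation_fit")
}

#' @export
print.inactivation_fit <- function(x, ...) {
  hl <- if (is.infinite(x$half_life)) "Inf (no measurable decay)"
        else sprintf("%.3g h", x$half_life)
  cat(sprintf("First-order inactivation: k_in = %.4g +/- %.2g 1/h, half-life %s\n",
              x$k_in, x$k_in_se, hl))
  invisible(x)
}

#' Comparative stability report across enzyme variants
#'
#' Tabulates melting temperatures and inactivation constants for a set of
#' variants against a designated reference: Delta T_m (variant - reference)
#' and fold-changes of `k_in` in both directions, explicitly labeled.
#'
#' @param fits Named list; each element is a list with optional components
#'   `melt` (a `melt_fit` or a numeric T_m) and `decay` (an
#'   `inactivation_fit` or a numeric k_in in 1/h).
#' @param reference Name of the reference variant (must be in `fits`).
#' @return Data frame of class `stability_comparison` with columns
#'   `variant`, `t_m`, `delta_t_m`, `k_in`, `fold_vs_reference`
#'   (k_in variant / reference) and `fold_reference_vs` (reference /
#'   variant).
#' @export
stability_report <- function(fits, reference) {
  if (!reference %in% names(fits))
    stop_input("reference variant '%s' not present", reference)
  get_tm <- function(x) {
    if (is.null(x$melt)) return(NA_real_)
    if (inherits(x$melt, "melt_fit")) x$melt$t_m else as.numeric(x$melt)
  }
  get_k <- function(x) {
    if (is.null(x$decay)) return(NA_real_)
    if (inherits(x$decay, "inactivation_fit")) x$decay$k_in else as.numeric(x$decay)
  }
  tm <- vapply(fits, get_tm, numeric(1))
  k <- vapply(fits, get_k, numeric(1))
  ref_tm <- tm[[reference]]; ref_k <- k[[reference]]
  out <- data.frame(
    variant = names(fits),
    t_m = tm,
    delta_t_m = tm - ref_tm,
    k_in = k,
    fold_vs_reference = k / ref_k,
    fold_reference_vs = ref_k / k,
    row.names = NULL)
  structure(out, class = c("stability_comparison", "data.frame"),
            reference = reference)
}

#' Read a CD melt curve CSV (columns temp_C, signal)
#' @param path CSV path.
#' @return Data frame with columns `temperature`, `signal`.
#' @export
read_melt_csv <- function(path) {
  df <- read_meta_csv(path)
  data.frame(temperature = df$temp_C, signal = df$signal)
}

#' Read a residual-activity time course CSV (columns time_h, activity_frac)
#' @param path CSV path.
#' @return Data frame with columns `time_h`, `activity`.
#' @export
read_activity_csv <- function(path) {
  df <- read_meta_csv(path)
  data.frame(time_h = df$time_h, activity = df$activity_frac)
}
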