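#' Turbidity trace container
#'
#' Bundles a raw OD600 time series from the turbidimetric nanoparticle assay
#' with its buffer-only blank and the enzyme concentration used, the inputs
#' needed to compute the relative turbidity.
#'
#' @param times Sampling times in seconds, strictly increasing.
#' @param od600 Absorbance readings at 600 nm, same length as `times`.
#' @param od600_blank Absorbance of the buffer-only cuvette.
#' @param enzyme_conc Enzyme concentration in mg/mL (>= 0).
#' @param substrate_load Nanoparticle load in ug/mL (metadata only).
#' @return An object of class `turbidity_trace`.
#' @export
turbidity_trace <- function(times, od600, od600_blank, enzyme_conc,
                            substrate_load = NA_real_) {
  check_increasing(times, "times")
  if (length(od600) != length(times))
    stop_input("'od600' and 'times' must have the same length")
  check_number(od600_blank, "od600_blank")
  check_number(enzyme_conc, "enzyme_conc", min = 0)
  structure(
    list(times = as.numeric(times), od600 = as.numeric(od600),
         od600_blank = od600_blank, enzyme_conc = enzyme_conc,
         substrate_load = substrate_load),
    class = "turbidity_trace")
}

#' @export
print.turbidity_trace <- function(x, ...) {
  cat(sprintf("Turbidity trace: %d points, %.1f min, [E] = %g mg/mL, blank = %g\n",
              length(x$times), diff(range(x$times)) / 60, x$enzyme_conc,
              x$od600_blank))
  invisible(x)
}

#' Relative turbidity transform
#'
#' Converts a raw OD600 trace to the dimensionless relative turbidity
#' tau/tau0 = |OD600 - OD600_blank|_t / |OD600 - OD600_blank|_0, the
#' normalized scattering signal of the remaining nanoparticle population.
#' The first element is exactly 1 by construction.
#'
#' @param trace A [turbidity_trace()].
#' @return A data frame of class `relative_turbidity` with columns
#'   `time_min` (minutes from start) and `tau_rel`.
#' @export
compute_relative_turbidity <- function(trace) {
  stopifnot(inherits(trace, "turbidity_trace"))
  sig <- abs(trace$od600 - trace$od600_blank)
  if (sig[1] <= .Machine$double.eps * 100)
    stop_input("degenerate input: initial blank-corrected OD600 is zero")
  out <- data.frame(time_min = (trace$times - trace$times[1]) / 60,
                    tau_rel = sig / sig[1])
  structure(out, class = c("relative_turbidity", "data.frame"),
            enzyme_conc = trace$enzyme_conc)
}

#' Initial square-root turbidity decline rate
#'
#' Extracts -d(tau/tau0)^(1/2)/dt from the linear region of the square-root
#' relative turbidity. Candidate windows are all contiguous runs of at least
#' `min_points` points starting after the lag; the earliest window whose
#' linear fit reaches `r2_threshold` is used (longest such window at that
#' start), falling back to the globally best window when none qualifies.
#'
#' @param series A `relative_turbidity` data frame (or one with columns
#'   `time_min`, `tau_rel`).
#' @param lag Lag time in minutes to exclude before the linear region
#'   (mixing/settling transient). Default 1.5 min.
#' @param min_points Minimum window size (default 5).
#' @param r2_threshold R^2 needed for a window to qualify (default 0.98).
#' @param enzyme_conc Optional enzyme concentration (mg/mL); taken from the
#'   series attribute when absent.
#' @return An object of class `rate_measurement` with fields `enzyme_conc`,
#'   `rate` (1/min, >= 0), `window` (start/end, min), `window_r2`, and flags
#'   `clamped` (negative slope clamped to 0) and `nonmonotone`.
#' @export
estimate_initial_rate <- function(series, lag = 1.5, min_points = 5,
                                  r2_threshold = 0.98, enzyme_conc = NULL) {
  t <- series$time_min
  y <- sqrt(pmax(series$tau_rel, 0))
  if (is.null(enzyme_conc))
    enzyme_conc <- attr(series, "enzyme_conc", exact = TRUE)
  keep <- which(t >= lag)
  if (length(keep) < min_points)
    stop_input("too few points after the lag (%d < %d)", length(keep), min_points)
  t <- t[keep]; y <- y[keep]
  n <- length(t)
  nonmono <- any(diff(series$tau_rel) > sqrt(.Machine$double.eps))

  # Earliest start whose windows reach the R^2 threshold wins; at that start
  # the window maximizing R^2 is used (ties -> longer window), so on an exact
  # trace the fit stops exactly where the linear decline ends (e.g. at the
  # fully-cleared, zero-turbidity tail). Fallback: globally best window.
  best <- NULL
  sel <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    at_start <- NULL
    for (j in seq(i + min_points - 1L, n)) {
      fit <- lsq_line(t[i:j], y[i:j])
      if (is.na(fit$r2)) next
      cand <- list(i = i, j = j, slope = fit$slope, r2 = fit$r2)
      if (is.null(best) || fit$r2 > best$r2) best <- cand
      if (fit$r2 >= r2_threshold &&
          (is.null(at_start) || fit$r2 >= at_start$r2 - 1e-9)) at_start <- cand
    }
    if (!is.null(at_start)) { sel <- at_start; break }
  }
  if (is.null(sel)) sel <- best
  if (is.null(sel)) { # flat series: no window has signal variance
    sel <- list(i = 1L, j = n, slope = 0, r2 = NA_real_)
  }
  rate <- -sel$slope
  clamped <- rate < 0
  if (clamped) rate <- 0
  structure(
    list(enzyme_conc = if (is.null(enzyme_conc)) NA_real_ else enzyme_conc,
         rate = rate, window = c(start = t[sel$i], end = t[sel$j]),
         window_r2 = sel$r2, clamped = clamped, nonmonotone = nonmono),
    class = "rate_measurement")
}

#' @export
print.rate_measurement <- function(x, ...) {
  cat(sprintf("Initial rate: %.5g 1/min over [%.2f, %.2f] min (R2 = %.4f)%s\n",
              x$rate, x$window[1], x$window[2],
              ifelse(is.na(x$window_r2), NaN, x$window_r2),
              if (isTRUE(x$clamped)) " [clamped at 0]" else ""))
  invisible(x)
}

#' Langmuir-type rate law for heterogeneous PET hydrolysis
#'
#' Predicted initial square-root turbidity decline rate at enzyme
#' concentration `e`: `k_tau * K_A * e / (1 + K_A * e)`. The rate saturates
#' at `k_tau` as the particle surface becomes enzyme-covered; `K_A` is the
#' adsorption equilibrium constant (mL/mg).
#'
#' @param e Enzyme concentration(s), mg/mL.
#' @param k_tau Maximal rate, 1/min.
#' @param K_A Adsorption equilibrium constant, mL/mg.
#' @return Predicted rates, 1/min.
#' @export
langmuir_rate <- function(e, k_tau, K_A) k_tau * K_A * e / (1 + K_A * e)

as_rate_table <- function(points) {
  if (inherits(points, "rate_measurement")) points <- list(points)
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, inherits, logical(1), "rate_measurement"))) {
    points <- data.frame(
      enzyme_conc = vapply(points, `[[`, numeric(1), "enzyme_conc"),
      rate = vapply(points, `[[`, numeric(1), "rate"))
  }
  if (!is.data.frame(points) || !all(c("enzyme_conc", "rate") %in% names(points)))
    stop_input("'points' must be rate measurements or a data frame with enzyme_conc and rate")
  points
}

#' Fit the Langmuir adsorption kinetic model
#'
#' Nonlinear least-squares fit of initial rates versus enzyme concentration
#' to the saturating rate law [langmuir_rate()]. Fitting is done by
#' Levenberg-Marquardt on log-parameters, which enforces positivity of both
#' `k_tau` and `K_A`; standard errors are propagated back from the log scale.
#'
#' @param points Rate measurements: a list of [estimate_initial_rate()]
#'   results or a data frame with columns `enzyme_conc` (mg/mL), `rate`
#'   (1/min) and optionally `sd` (replicate SD used as 1/sd^2 weights).
#' @param weights `"uniform"` (default) or `"sd"` to weight by 1/sd^2.
#' @param exclude_above Optional concentration cutoff (mg/mL): points above
#'   it are dropped from the fit and reported in the result. Use this to
#'   exclude the high-concentration regime where surface coverage exceeds a
#'   monolayer and the Langmuir model no longer applies; never applied
#'   silently.
#' @return An object of class `langmuir_fit`: `k_tau`, `K_A`, `k_tau_se`,
#'   `K_A_se`, `r2`, `n_points`, `excluded`, `fitted`, `residuals`.
#' @export
fit_langmuir_kinetics <- function(points, weights = c("uniform", "sd"),
                                  exclude_above = NULL) {
  weights <- match.arg(weights)
  pts <- as_rate_table(points)
  excluded <- data.frame(enzyme_conc = numeric(), rate = numeric())
  if (!is.null(exclude_above)) {
    drop <- pts$enzyme_conc > exclude_above
    excluded <- pts[drop, , drop = FALSE]
    pts <- pts[!drop, , drop = FALSE]
  }
  if (length(unique(pts$enzyme_conc)) < 3L)
    stop_input("need rates at >= 3 distinct enzyme concentrations")
  if (all(pts$rate <= 0)) stop_input("no activity: all rates are zero")

  w <- rep(1, nrow(pts))
  if (weights == "sd") {
    if (!"sd" %in% names(pts)) stop_input("weights = 'sd' needs an 'sd' column")
    w <- 1 / pmax(pts$sd, .Machine$double.eps)^2
  }

  k0 <- max(pts$rate)
  half <- pts$enzyme_conc[which.min(abs(pts$rate - k0 / 2))]
  K0 <- if (half > 0) 1 / half else 1 / median(pts$enzyme_conc[pts$enzyme_conc > 0])
  dat <- data.frame(e = pts$enzyme_conc, r = pts$rate, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ exp(lk) * exp(lK) * e / (1 + exp(lK) * e),
      data = dat, weights = w,
      start = list(lk = log(k0), lK = log(K0)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) stop_input("Langmuir fit did not converge: %s",
                                   conditionMessage(e)))
  lp <- coef(fit)
  se_l <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  k_tau <- exp(lp[["lk"]]); K_A <- exp(lp[["lK"]])
  pred <- langmuir_rate(dat$e, k_tau, K_A)
  ss_res <- sum((dat$r - pred)^2)
  ss_tot <- sum((dat$r - mean(dat$r))^2)
  structure(
    list(k_tau = k_tau, K_A = K_A,
         k_tau_se = k_tau * se_l[[1]], K_A_se = K_A * se_l[[2]],
         r2 = 1 - ss_res / ss_tot, n_points = nrow(pts),
         excluded = excluded, fitted = pred, residuals = dat$r - pred,
         data = pts),
    class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("Langmuir kinetic fit (n = %d):\n", x$n_points))
  cat(sprintf("  k_tau = %.4g +/- %.2g 1/min\n", x$k_tau, x$k_tau_se))
  cat(sprintf("  K_A   = %.4g +/- %.2g mL/mg\n", x$K_A, x$K_A_se))
  cat(sprintf("  R2    = %.4f\n", x$r2))
  if (nrow(x$excluded) > 0)
    cat(sprintf("  %d point(s) excluded above the stated cutoff\n", nrow(x$excluded)))
  invisible(x)
}

#' Read a turbidity trace CSV
#'
#' Expects columns `time_s` and `od600`; blank, enzyme concentration and
#' substrate load are taken from `# key: value` metadata lines (keys
#' `od600_blank`, `enzyme_conc`, `substrate_load`) unless given explicitly.
#'
#' @param path CSV path.
#' @param od600_blank,enzyme_conc Override metadata values.
#' @return A [turbidity_trace()].
#' @export
read_turbidity_csv <- function(path, od600_blank = NULL, enzyme_conc = NULL) {
  df <- read_meta_csv(path)
  meta <- attr(df, "metadata")
  if (is.null(od600_blank)) od600_blank <- meta$od600_blank
  if (is.null(enzyme_conc)) enzyme_conc <- meta$enzyme_conc
  if (is.null(od600_blank) || is.null(enzyme_conc))
    stop_input("blank and enzyme_conc must be in metadata or passed explicitly")
  turbidity_trace(df$time_s, df$od600, od600_blank, enzyme_conc,
                  substrate_load = if (is.null(meta$substrate_load)) NA_real_
                                   else meta$substrate_load)
}
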