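# Default molar mass constants (g/mol): the PET repeat unit (C10H8O4) used
# for molar depolymerization yields, and terephthalic acid for
# aromatic-equivalent mass rates. Both are arguments, never hardwired into
# the math.

#' @rdname depolymerization_yield
#' @export
MW_PET_REPEAT <- 192.17

#' @rdname convert_specific_rate
#' @export
MW_TPA <- 166.13

#' Beer-Lambert absorbance-to-concentration conversion
#'
#' `c = a * dilution / (epsilon * path)`, in mM when `epsilon` is given in
#' 1/(mM cm). Used with epsilon 13.8 for the pooled aromatic PET hydrolysis
#' products at 240 nm and 11.6 for p-nitrophenolate at 405 nm.
#'
#' @param a Absorbance (may be a vector).
#' @param epsilon Molar extinction coefficient, 1/(mM cm) (> 0).
#' @param path Optical path length, cm (> 0, default 1).
#' @param dilution Dilution factor applied before reading (>= 1, default 1).
#' @return Concentration(s), mM.
#' @export
absorbance_to_concentration <- function(a, epsilon, path = 1, dilution = 1) {
  check_number(epsilon, "epsilon", min = 0, allow_min = FALSE)
  check_number(path, "path", min = 0, allow_min = FALSE)
  check_number(dilution, "dilution", min = 1)
  a * dilution / (epsilon * path)
}

#' Depolymerization yield
#'
#' Fraction of the polymer converted to soluble products. On the molar
#' basis, the released product concentration (mM, one aromatic unit per
#' repeat unit) is divided by the theoretical repeat-unit concentration
#' `substrate (mg/mL) / mw_repeat * 1000` (mM). On the mass basis, degraded
#' mass over initial mass. Yields above 100% are flagged, not clamped.
#'
#' @param products Released products: mM (molar basis) or mg degraded (mass
#'   basis).
#' @param substrate Substrate load: mg/mL (molar basis) or mg initial (mass
#'   basis). Must be > 0.
#' @param basis `"molar"` or `"mass"`.
#' @param mw_repeat Repeat-unit molar mass, g/mol (default
#'   [MW_PET_REPEAT] = 192.17 for C10H8O4).
#' @return Object of class `yield_result`: `yield_pct`, `basis`,
#'   `products_mm` or `product_mass`, `over_100` flag.
#' @export
depolymerization_yield <- function(products, substrate,
                                   basis = c("molar", "mass"),
                                   mw_repeat = MW_PET_REPEAT) {
  basis <- match.arg(basis)
  check_number(substrate, "substrate", min = 0, allow_min = FALSE)
  check_number(products, "products", min = 0)
  if (basis == "molar") {
    check_number(mw_repeat, "mw_repeat", min = 0, allow_min = FALSE)
    repeat_units_mm <- substrate / mw_repeat * 1000
    pct <- products / repeat_units_mm * 100
    res <- list(yield_pct = pct, basis = "molar", products_mm = products,
                repeat_units_mm = repeat_units_mm, mw_repeat = mw_repeat)
  } else {
    pct <- products / substrate * 100
    res <- list(yield_pct = pct, basis = "mass", product_mass = products,
                initial_mass = substrate)
  }
  res$over_100 <- pct > 100
  structure(res, class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf("Depolymerization yield (%s basis): %.1f%%%s\n", x$basis,
              x$yield_pct, if (isTRUE(x$over_100)) " [exceeds 100%: check inputs]" else ""))
  invisible(x)
}

#' Specific-rate unit conversion
#'
#' Converts a depolymerization rate expressed per enzyme mass per day
#' (uM products / ug enzyme / day, on a 1 mL volume basis, i.e. umol per ug
#' per day = mol per g per day) into g product-equivalents per litre per
#' gram of enzyme per hour: `rate * mw / 24`.
#'
#' @param rate Specific rate, uM/ug/day (>= 0).
#' @param mw_product_equiv Molar mass of the product equivalent, g/mol
#'   (default [MW_TPA] = 166.13 for terephthalic acid).
#' @return Rate in g/L per g enzyme per hour.
#' @export
convert_specific_rate <- function(rate, mw_product_equiv = MW_TPA) {
  check_number(rate, "rate", min = 0)
  check_number(mw_product_equiv, "mw_product_equiv", min = 0, allow_min = FALSE)
  rate * mw_product_equiv / 24
}

#' Analyze a bioconversion time course
#'
#' Converts A240 readings to pooled aromatic-product concentrations, then
#' computes the molar depolymerization yield at the end of the stated
#' window and the specific rate `products(t_end) / (enzyme_conc * t_end)`
#' in uM products per ug enzyme per day. Product concentration at `t_end`
#' is linearly interpolated between readings.
#'
#' @param course Data frame with columns `time_h`, `a240` and optionally
#'   `dilution` (default 1).
#' @param enzyme_conc Enzyme concentration, ug/mL (> 0).
#' @param substrate_load Substrate load, mg/mL (> 0).
#' @param epsilon Extinction coefficient at 240 nm, 1/(mM cm) (default 13.8).
#' @param path Path length, cm (default 1).
#' @param window `c(t_start, t_end)` in hours; default full course.
#' @param mw_repeat Repeat-unit molar mass for the yield (default 192.17).
#' @return Object of class `bioconversion_result`: per-timepoint
#'   `concentrations` (data frame time_h, products_mm), `yield`
#'   (a `yield_result`), `specific_rate` (uM/ug/day) and `window`.
#' @export
analyze_bioconversion <- function(course, enzyme_conc, substrate_load,
                                  epsilon = 13.8, path = 1, window = NULL,
                                  mw_repeat = MW_PET_REPEAT) {
  check_increasing(course$time_h, "time_h", strict = FALSE)
  check_number(enzyme_conc, "enzyme_conc", min = 0, allow_min = FALSE)
  check_number(substrate_load, "substrate_load", min = 0, allow_min = FALSE)
  dil <- if ("dilution" %in% names(course)) course$dilution else 1
  conc <- absorbance_to_concentration(course$a240, epsilon, path, 1) * dil
  if (is.null(window)) window <- range(course$time_h)
  if (window[2] <= window[1] || window[2] > max(course$time_h))
    stop_input("'window' must be increasing and end within the course")
  c_end <- stats::approx(course$time_h, conc, xout = window[2])$y
  c_start <- stats::approx(course$time_h, conc, xout = window[1])$y
  days <- (window[2] - window[1]) / 24
  rate <- (c_end - c_start) * 1000 / enzyme_conc / days # mM -> uM
  structure(
    list(concentrations = data.frame(time_h = course$time_h, products_mm = conc),
         yield = depolymerization_yield(c_end, substrate_load, "molar",
                                        mw_repeat = mw_repeat),
         specific_rate = max(rate, 0), window = window),
    class = "bioconversion_result")
}

#' @export
print.bioconversion_result <- function(x, ...) {
  cat(sprintf("Bioconversion: %.2f mM products at %.1f h; yield %.1f%% (molar); %.3g uM/ug/day over [%g, %g] h\n",
              max(x$concentrations$products_mm), max(x$concentrations$time_h),
              x$yield$yield_pct, x$specific_rate, x$window[1], x$window[2]))
  invisible(x)
}

#' Read a bioconversion course CSV (columns time_h, a240, optional dilution)
#' @param path CSV path.
#' @return Data frame suitable for [analyze_bioconversion()].
#' @export
read_bioconversion_csv <- function(path) read_meta_csv(path)
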