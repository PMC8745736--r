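#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm median nls.control qnorm rnorm runif sd setNames vcov
#' @importFrom utils head read.csv write.csv
NULL

# Internal input checkers. All raise classed errors naming the offending
# field so callers (and tests) can match on the message.

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, allow_min = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("'%s' must be a single finite number", name)
  if ((allow_min && x < min) || (!allow_min && x <= min) || x > max)
    stop_input("'%s' = %g is outside the allowed range", name, x)
  invisible(x)
}

check_increasing <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x))
    stop_input("'%s' must be a numeric vector of length >= 2 with no NAs", name)
  d <- diff(x)
  if ((strict && any(d <= 0)) || (!strict && any(d < 0)))
    stop_input("'%s' must be strictly increasing", name)
  invisible(x)
}

# Linear regression through (x, y) by closed form; returns slope, intercept
# and R^2 (NA when y has no variance, so flat windows never win on R^2).
lsq_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  r2 <- if (syy <= .Machine$double.eps * n * max(1, my^2)) NA_real_ else (sxy^2) / (sxx * syy)
  list(slope = slope, intercept = my - slope * mx, r2 = r2)
}

# CSV with '# key: value' metadata header lines, used by all writers so a
# file is self-describing (seed, parameters, units).
write_meta_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 15), collapse = ",")), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_meta_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    meta[[trimws(key)]] <- if (anyNA(num)) val else num
  }
  df <- read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  attr(df, "metadata") <- meta
  df
}

#' Write an analysis result as JSON
#'
#' Serializes any petkin fit or report object (a classed list or data
#' frame) to pretty-printed JSON for downstream tooling.
#'
#' @param x A fit/report object (e.g. from [fit_langmuir_kinetics()],
#'   [stability_report()], [summarize_library()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
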