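# 96-well phenol red (PSP) screening: hydrolysis releases carboxylic
# products, the well acidifies, and A540 drops. Activity is therefore read
# on an inverted absorbance scale anchored to the on-plate controls.

WELL_IDS <- as.vector(outer(LETTERS[1:8], 1:12, paste0))

#' Define a 96-well plate layout
#'
#' @param roles Named character vector or data frame (`well`, `role`)
#'   assigning each well one of `"sample"`, `"parent_control"`,
#'   `"negative_control"`, `"blank"`, `"empty"`. Wells not listed are
#'   `"empty"`. At least one parent control and one negative control are
#'   required.
#' @return Data frame of class `plate_layout` with columns `well`, `role`.
#' @export
plate_layout <- function(roles) {
  if (is.data.frame(roles)) roles <- setNames(as.character(roles$role), roles$well)
  bad <- setdiff(names(roles), WELL_IDS)
  if (length(bad)) stop_input("unknown well id(s): %s", paste(bad, collapse = ", "))
  valid <- c("sample", "parent_control", "negative_control", "blank", "empty")
  if (!all(roles %in% valid))
    stop_input("roles must be one of: %s", paste(valid, collapse = ", "))
  if (!any(roles == "parent_control"))
    stop_input("layout must contain >= 1 parent_control well")
  if (!any(roles == "negative_control"))
    stop_input("layout must contain >= 1 negative_control well")
  out <- data.frame(well = WELL_IDS,
                    role = ifelse(WELL_IDS %in% names(roles),
                                  roles[WELL_IDS], "empty"))
  structure(out, class = c("plate_layout", "data.frame"))
}

#' Standard screening layout: controls in column 12
#'
#' Samples in columns 1-11; parent controls in A12-D12, negative controls
#' in E12-H12.
#'
#' @return A [plate_layout()].
#' @export
default_screen_layout <- function() {
  roles <- setNames(rep("sample", 88), as.vector(outer(LETTERS[1:8], 1:11, paste0)))
  roles[paste0(LETTERS[1:4], 12)] <- "parent_control"
  roles[paste0(LETTERS[5:8], 12)] <- "negative_control"
  plate_layout(roles)
}

#' Plate reading container
#'
#' @param layout A [plate_layout()].
#' @param a540 Named numeric vector of A540 absorbances; every non-empty
#'   well must be present, values >= 0.
#' @param substrate `"PET-nanoparticles"` or `"BHET"` (metadata).
#' @param incubation Incubation time, hours (metadata).
#' @return Object of class `plate_reading`.
#' @export
plate_reading <- function(layout, a540, substrate = "PET-nanoparticles",
                          incubation = 3) {
  stopifnot(inherits(layout, "plate_layout"))
  need <- layout$well[layout$role != "empty"]
  missing <- setdiff(need, names(a540))
  if (length(missing))
    stop_input("a540 missing for non-empty well(s): %s",
               paste(head(missing, 5), collapse = ", "))
  if (any(a540 < 0)) stop_input("a540 values must be >= 0")
  structure(list(layout = layout, a540 = a540[need], substrate = substrate,
                 incubation = incubation),
            class = "plate_reading")
}

#' Score a PSP screening plate against its on-plate controls
#'
#' Relative activity of each well:
#' `(mean_A540_negative - A540_well) / (mean_A540_negative -
#' mean_A540_parent) * 100`, so negative-control wells score ~0% and
#' parent-control wells ~100%; clones more active than the parent score
#' above 100%. A well is flagged as a hit when it exceeds 100% by more than
#' `margin` pooled control standard deviations (on the activity scale).
#'
#' @param reading A [plate_reading()].
#' @param margin Hit margin in pooled-control-SD units (default 2).
#' @param aggregate `"mean"` (default) or `"median"` control aggregation.
#' @return Data frame of class `plate_scores`: `well`, `role`,
#'   `activity_pct`, `z_margin` (separation from parent in control-SD
#'   units; NA when controls have zero spread), `hit` (samples only).
#' @export
score_plate <- function(reading, margin = 2, aggregate = c("mean", "median")) {
  stopifnot(inherits(reading, "plate_reading"))
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else median
  lay <- reading$layout
  a <- reading$a540
  neg_wells <- lay$well[lay$role == "negative_control"]
  par_wells <- lay$well[lay$role == "parent_control"]
  m_neg <- agg(a[neg_wells]); m_par <- agg(a[par_wells])
  if (isTRUE(all.equal(m_neg, m_par)))
    stop_input("no assay dynamic range: control means are equal")
  span <- m_neg - m_par
  to_act <- function(x) (m_neg - x) / span * 100
  # pooled control SD on the activity scale (same linear map for both roles)
  ctrl_sd <- sqrt(mean(c(
    if (length(par_wells) > 1) (sd(a[par_wells]) / abs(span) * 100)^2 else NULL,
    if (length(neg_wells) > 1) (sd(a[neg_wells]) / abs(span) * 100)^2 else NULL)))
  scored <- lay[lay$role %in% c("sample", "parent_control", "negative_control"), ]
  act <- to_act(a[scored$well])
  z <- if (is.finite(ctrl_sd) && ctrl_sd > 0) (act - 100) / ctrl_sd else
    rep(NA_real_, length(act))
  hit_cut <- if (is.finite(ctrl_sd) && ctrl_sd > 0) 100 + margin * ctrl_sd else 100
  out <- data.frame(well = scored$well, role = scored$role,
                    activity_pct = act, z_margin = z,
                    hit = scored$role == "sample" & act > hit_cut,
                    row.names = NULL)
  structure(out, class = c("plate_scores", "data.frame"),
            control_sd = ctrl_sd, margin = margin,
            control_means = c(negative = m_neg, parent = m_par))
}

#' Summarize a screened SSM library
#'
#' Fractions of sample wells below and above parent activity (beyond the
#' hit margin used during scoring) and the top-ranked wells.
#'
#' @param scores A `plate_scores` data frame from [score_plate()] (or a
#'   concatenation of several, e.g. via `rbind`).
#' @param top_k Number of top wells to rank (default 10).
#' @return Object of class `library_summary`: `n_samples`,
#'   `fraction_lower`, `fraction_improved`, `top` (data frame of the
#'   `top_k` highest-activity sample wells).
#' @export
summarize_library <- function(scores, top_k = 10) {
  s <- scores[scores$role == "sample", , drop = FALSE]
  if (nrow(s) == 0) stop_input("no sample wells to summarize")
  ctrl_sd <- attr(scores, "control_sd", exact = TRUE)
  margin <- attr(scores, "margin", exact = TRUE)
  m <- if (!is.null(ctrl_sd) && is.finite(ctrl_sd) && !is.null(margin))
    margin * ctrl_sd else 0
  ord <- order(s$activity_pct, decreasing = TRUE)
  structure(
    list(n_samples = nrow(s),
         fraction_lower = mean(s$activity_pct < 100 - m),
         fraction_improved = mean(s$activity_pct > 100 + m),
         top = s[head(ord, top_k), c("well", "activity_pct", "hit")]),
    class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  cat(sprintf("Library summary: %d sample wells; %.1f%% below parent, %.1f%% improved\n",
              x$n_samples, 100 * x$fraction_lower, 100 * x$fraction_improved))
  cat("Top wells:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Read a plate from CSV
#'
#' Accepts long format (columns `well`, `a540`) or an 8 x 12 row-major grid
#' (8 rows A-H, 12 columns).
#'
#' @param path Plate CSV path.
#' @param layout A [plate_layout()] or path to a layout CSV with columns
#'   `well`, `role`.
#' @param ... Passed to [plate_reading()].
#' @return A [plate_reading()].
#' @export
read_plate_csv <- function(path, layout, ...) {
  if (is.character(layout)) layout <- plate_layout(read_meta_csv(layout))
  df <- read_meta_csv(path)
  if (all(c("well", "a540") %in% names(df))) {
    a <- setNames(df$a540, df$well)
  } else {
    if (nrow(df) != 8 || ncol(df) != 12)
      stop_input("grid plate CSV must be 8 rows x 12 columns")
    a <- setNames(as.vector(t(as.matrix(df))),
                  as.vector(t(outer(LETTERS[1:8], 1:12, paste0))))
  }
  plate_reading(layout, a, ...)
}
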