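#' Box-plot statistics with Tukey fences
#'
#' Median and quartiles by linear interpolation between order statistics
#' (R's default type-7 quantile, the common spreadsheet convention), whisker
#' fences at `q1 - k*iqr` and `q3 + k*iqr`, and a stable partition of the
#' values strictly outside the fences.  The quartile convention is recorded
#' in the result so reports are self-describing.
#'
#' @param values Numeric vector, length >= 1, no NAs.
#' @param k Whisker multiplier (1.5 = Tukey's rule).
#' @return An object of class `box_stats`: list with `n`, `median`, `q1`,
#'   `q3`, `iqr`, `lower_fence`, `upper_fence`, `outliers_low`,
#'   `outliers_high`, `quartile_convention`.
#' @examples
#' box_stats(table2_fixture()$difference)
#' @export
box_stats <- function(values, k = 1.5) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  stopifnot(is.numeric(values), !anyNA(values), k >= 0)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lf <- q[1] - k * iqr
  uf <- q[3] + k * iqr
  structure(
    list(n = length(values), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         lower_fence = lf, upper_fence = uf,
         outliers_low = sort(values[values < lf]),
         outliers_high = sort(values[values > uf]),
         quartile_convention = "linear interpolation of order statistics (type 7)",
         k = k),
    class = "box_stats"
  )
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("Box statistics (n = %d): median %.3f, Q1 %.3f, Q3 %.3f, IQR %.3f\n",
              x$n, x$median, x$q1, x$q3, x$iqr))
  cat(sprintf("  fences (k = %g): [%.3f, %.3f]; outliers: %d low, %d high\n",
              x$k, x$lower_fence, x$upper_fence,
              length(x$outliers_low), length(x$outliers_high)))
  cat(sprintf("  quartiles: %s\n", x$quartile_convention))
  invisible(x)
}

#' Batch comparison of clinical plans against the analytic predictor
#'
#' For every non-excluded target computes the analytic spill prediction
#' (from the measured surface area, or from the equal-volume sphere under
#' `sa_policy = "sphere_approx"`), the achieved clinical spill where the
#' 50%-isodose volume is available, and their Difference
#' (clinical - analytic); then summarises the Differences with [box_stats()].
#' Excluded targets (e.g. merged 50%-isodose clouds) are carried through
#' with their reasons, never silently dropped.
#'
#' @param targets Data.frame of plan targets (see [read_clinical_csv()]).
#' @param model A `delta_r_model`.
#' @param sa_policy `"actual"` (use `sa_ptv_cm2`, falling back to the sphere
#'   approximation where it is missing) or `"sphere_approx"` (sphere
#'   approximation everywhere).
#' @param k Whisker multiplier passed to [box_stats()].
#' @return An object of class `r50_report`: list with `records` (one row per
#'   target: analytic, clinical, difference, sa_source), `stats`
#'   (a `box_stats` over the defined differences), `excluded`, `sa_policy`,
#'   and `model`.
#' @examples
#' rep <- compare_batch(table2_plan_targets(), default_gk_icon_model())
#' rep$stats$median
#' @export
compare_batch <- function(targets, model = default_gk_icon_model(),
                          sa_policy = c("actual", "sphere_approx"), k = 1.5) {
  sa_policy <- match.arg(sa_policy)
  stopifnot(is.data.frame(targets), inherits(model, "delta_r_model"))
  need <- c("plan_id", "target_id", "v_ptv_cc")
  stopifnot(all(need %in% names(targets)))
  if (!"excluded" %in% names(targets)) targets$excluded <- FALSE
  if (!"exclusion_reason" %in% names(targets)) {
    targets$exclusion_reason <- NA_character_
  }
  targets$excluded[is.na(targets$excluded)] <- FALSE
  active <- targets[!targets$excluded, , drop = FALSE]
  if (nrow(active) == 0) {
    stop("no non-excluded targets; nothing to report", call. = FALSE)
  }

  sa_meas <- if ("sa_ptv_cm2" %in% names(active)) active$sa_ptv_cm2 else NA_real_
  use_sphere <- sa_policy == "sphere_approx" | is.na(sa_meas)
  sa <- ifelse(use_sphere, sphere_surface_area_from_volume(active$v_ptv_cc),
               sa_meas)
  analytic <- r50_analytic_gk(active$v_ptv_cc, sa, model)
  v50 <- if ("v_idc50_cc" %in% names(active)) active$v_idc50_cc else NA_real_
  clinical <- ifelse(is.na(v50), NA_real_, v50 / active$v_ptv_cc)

  records <- data.frame(
    plan_id = active$plan_id,
    target_id = active$target_id,
    v_ptv_cc = active$v_ptv_cc,
    sa_used_cm2 = sa,
    sa_source = ifelse(use_sphere, "sphere_approx", "measured"),
    delta_r_cm = eval_delta_r(model, active$v_ptv_cc),
    r50_analytic = analytic,
    r50_clinical = clinical,
    difference = clinical - analytic,
    stringsAsFactors = FALSE
  )
  diffs <- records$difference[!is.na(records$difference)]
  if (length(diffs) == 0) {
    stop("no target has a 50%-isodose volume; no differences to summarise",
         call. = FALSE)
  }
  structure(
    list(records = records,
         stats = box_stats(diffs, k = k),
         excluded = targets[targets$excluded,
                            intersect(c("plan_id", "target_id", "exclusion_reason"),
                                      names(targets)),
                            drop = FALSE],
         sa_policy = sa_policy,
         model = model),
    class = "r50_report"
  )
}

#' @export
print.r50_report <- function(x, ...) {
  cat(sprintf("Intermediate dose spill report: %d target(s), %d excluded, SA policy '%s'\n",
              nrow(x$records), nrow(x$excluded), x$sa_policy))
  print(x$stats)
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' Per-target records, the Difference box statistics, model coefficients and
#' tool version, in one self-describing document.
#'
#' @param report An `r50_report` from [compare_batch()].
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "r50_report"))
  doc <- list(
    tool = paste0("gkr50 ", as.character(utils::packageVersion("gkr50"))),
    sa_policy = report$sa_policy,
    model = list(
      boundary_cc = report$model$boundary_volume,
      low_coeffs = report$model$low_coeffs,
      high_coeffs = report$model$high_coeffs,
      valid_range_cc = report$model$valid_range,
      provenance = report$model$provenance
    ),
    records = report$records,
    stats = unclass(report$stats),
    excluded = report$excluded
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(path)
}
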