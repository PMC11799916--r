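#' Analytic intermediate dose spill ratio
#'
#' Closed-form lower-bound predictor of the 50%-isodose spill ratio
#' R50% = V_IDC50% / V_PTV from target geometry alone:
#' \deqn{R50\%_{Analytic} = 1 + \frac{SA_{PTV}}{4\pi r_{PTV}^2}
#'   \left[\left(\frac{r_{PTV}+\Delta r}{r_{PTV}}\right)^3 - 1\right]}
#' with \eqn{r_{PTV}} the equivalent-sphere radius of the target.  The term
#' in brackets is the concentric-sphere volume ratio of a shell of thickness
#' \eqn{\Delta r}; the surface-area factor scales that shell to the target's
#' actual surface.  For a perfect sphere (SA = \eqn{4\pi r^2}) the expression
#' reduces exactly to \eqn{((r+\Delta r)/r)^3}.
#'
#' @param v_ptv Target volume, cm^3.
#' @param sa_ptv Target surface area, cm^2.
#' @param delta_r Dose drop-off distance, cm.
#' @return Dimensionless ratio, always >= 1; strictly increasing in both
#'   `sa_ptv` and `delta_r`.
#' @examples
#' m <- default_gk_icon_model()
#' r50_analytic(0.886, 4.66, eval_delta_r(m, 0.886))  # ~2.53
#' @seealso [r50_analytic_gk()], [r50_spherical_approx()]
#' @export
r50_analytic <- function(v_ptv, sa_ptv, delta_r) {
  check_positive(v_ptv, "v_ptv")
  check_positive(sa_ptv, "sa_ptv")
  check_positive(delta_r, "delta_r")
  r <- effective_radius(v_ptv)
  1 + sa_ptv / (4 * pi * r^2) * (((r + delta_r) / r)^3 - 1)
}

#' @rdname r50_analytic
#' @param model A `delta_r_model` used to evaluate the drop-off at `v_ptv`
#'   (default: the published Gamma Knife Icon calibration).
#' @export
r50_analytic_gk <- function(v_ptv, sa_ptv, model = default_gk_icon_model()) {
  r50_analytic(v_ptv, sa_ptv, eval_delta_r(model, v_ptv))
}

#' Spherical-approximation spill ratio
#'
#' [r50_analytic_gk()] with the target surface area replaced by the surface
#' area of the equal-volume sphere, for use when no structure set (and hence
#' no measured surface area) is available.  Because the sphere minimises
#' surface area at fixed volume, this is always less than or equal to the
#' prediction from the actual (physical) surface area.
#'
#' @inheritParams r50_analytic_gk
#' @export
r50_spherical_approx <- function(v_ptv, model = default_gk_icon_model()) {
  r50_analytic_gk(v_ptv, sphere_surface_area_from_volume(v_ptv), model)
}

#' Clinical spill ratio and gradient index
#'
#' The achieved intermediate dose spill of a plan:
#' `r50_clinical` is V_IDC50% / V_PTV and `gradient_index` is
#' V_IDC50% / V_IDC100% (the classical GI).
#'
#' @param v_idc50 Volume of the 50%-of-prescription isodose cloud, cm^3.
#' @param v_ptv Target volume, cm^3.
#' @param v_idc100 Volume of the prescription isodose cloud, cm^3.
#' @return Dimensionless ratio.
#' @export
r50_clinical <- function(v_idc50, v_ptv) {
  check_positive(v_idc50, "v_idc50")
  check_positive(v_ptv, "v_ptv")
  v_idc50 / v_ptv
}

#' @rdname r50_clinical
#' @export
gradient_index <- function(v_idc50, v_idc100) {
  check_positive(v_idc50, "v_idc50")
  check_positive(v_idc100, "v_idc100")
  v_idc50 / v_idc100
}

#' Read / write the clinical target table
#'
#' Column dialect: `plan_id, target_id, v_ptv_cc, sa_ptv_cm2, v_idc50_cc,
#' v_idc100_cc, prescription_gy, dn_pct, excluded, exclusion_reason`.
#' Optional columns may be empty (`NA`).  Targets whose 50% isodose cloud
#' merged with a neighbour's are kept with `excluded = TRUE` and a
#' machine-readable reason (`"overlapping_idc50"` or `"no_contoured_ptv"`),
#' never dropped.
#'
#' @param path File path.
#' @return A data.frame of plan targets.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("plan_id", "target_id", "v_ptv_cc")
  if (!all(need %in% names(df))) {
    stop("clinical CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  opt <- c("sa_ptv_cm2", "v_idc50_cc", "v_idc100_cc", "prescription_gy",
           "dn_pct")
  for (col in opt) if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  df$excluded <- as.logical(df$excluded)
  if (!"exclusion_reason" %in% names(df)) df$exclusion_reason <- NA_character_
  df
}

#' @rdname read_clinical_csv
#' @param targets Data.frame of plan targets.
#' @export
write_clinical_csv <- function(targets, path) {
  utils::write.csv(targets, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
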