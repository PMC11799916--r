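#' Piecewise dose drop-off model for the Gamma Knife
#'
#' The dose drop-off parameter \eqn{\Delta r} is the radial distance from the
#' surface of a spherical target to the 50%-of-prescription isodose surface.
#' It is machine- and energy-specific and is calibrated from phantom plans.
#' For the Gamma Knife Icon it is modelled piecewise in target volume `V`
#' (cm^3):
#' \deqn{\Delta r = c_0 + c_1 V + c_2 V^{2/3} + c_3 V^{1/3}, \quad V \le V_b}
#' \deqn{\Delta r = a + b V^{1/3}, \quad V \ge V_b}
#' with the two branches matched at the boundary volume \eqn{V_b}
#' (default 1 cm^3).  The rise of \eqn{\Delta r} at very small volumes is a
#' machine characteristic: below the 4 mm collimator diameter the 50% isodose
#' cloud of a single shot no longer shrinks with the target.
#'
#' @param low_coeffs Numeric length 4, `(c0, c1, c2, c3)` for the
#'   small-volume branch.
#' @param high_coeffs Numeric length 2, `(a, b)` for the large-volume branch.
#' @param boundary_volume Branch boundary, cm^3.
#' @param valid_range Length-2 numeric, the calibrated volume range (cm^3);
#'   evaluation outside it warns.
#' @param continuity_tol Allowed mismatch of the two branches at the
#'   boundary, cm.  Freshly fitted models must be continuous to 1e-9;
#'   published rounded coefficients are given more slack.
#' @param provenance Free-text note stored with the model.
#' @param high_exponent High-branch exponent; `NULL` (the default) means the
#'   cube-root law.  Set by [fit_delta_r_model()] with `free_exponent = TRUE`.
#' @return An object of class `delta_r_model`.
#' @seealso [default_gk_icon_model()], [eval_delta_r()], [fit_delta_r_model()]
#' @export
delta_r_model <- function(low_coeffs, high_coeffs, boundary_volume = 1,
                          valid_range = c(0.001, 44.91),
                          continuity_tol = 1e-9,
                          provenance = "user",
                          high_exponent = NULL) {
  stopifnot(length(low_coeffs) == 4, length(high_coeffs) == 2,
            is.numeric(low_coeffs), is.numeric(high_coeffs))
  check_positive(boundary_volume, "boundary_volume")
  stopifnot(length(valid_range) == 2, valid_range[1] < valid_range[2])
  m <- structure(
    list(low_coeffs = as.numeric(low_coeffs),
         high_coeffs = as.numeric(high_coeffs),
         boundary_volume = boundary_volume,
         valid_range = as.numeric(valid_range),
         continuity_tol = continuity_tol,
         provenance = provenance,
         high_exponent = high_exponent),
    class = "delta_r_model"
  )
  gap <- abs(delta_r_low(m, boundary_volume) - delta_r_high(m, boundary_volume))
  if (gap > continuity_tol) {
    stop(sprintf(
      "branches differ by %.3g cm at the boundary (%.3g cm^3); tolerance %.3g",
      gap, boundary_volume, continuity_tol
    ), call. = FALSE)
  }
  m
}

delta_r_low <- function(model, v) {
  cf <- model$low_coeffs
  cf[1] + cf[2] * v + cf[3] * v^(2 / 3) + cf[4] * v^(1 / 3)
}

delta_r_high <- function(model, v) {
  cf <- model$high_coeffs
  p <- if (!is.null(model$high_exponent)) model$high_exponent else 1 / 3
  cf[1] + cf[2] * v^p
}

#' Published drop-off calibration for the Gamma Knife Icon
#'
#' The piecewise fit to eleven spherical phantom plans (volumes 0.001 to
#' 44.91 cm^3) planned for an idealized minimum dose spill on the Icon:
#' low branch `0.5278 + 0.5730 V - 0.2871 V^(2/3) - 0.5845 V^(1/3)` below
#' 1 cm^3 and high branch `-0.018 + 0.2424 V^(1/3)` above.  The printed
#' coefficients agree at the boundary to ~0.005 cm (rounding), so this model
#' carries a relaxed continuity tolerance; both branches give
#' 0.226 +/- 0.003 cm at 1 cm^3.
#'
#' @return A `delta_r_model`.
#' @examples
#' m <- default_gk_icon_model()
#' eval_delta_r(m, c(0.1, 1, 20.41))
#' @export
default_gk_icon_model <- function() {
  delta_r_model(
    low_coeffs = c(0.5278, 0.5730, -0.2871, -0.5845),
    high_coeffs = c(-0.018, 0.2424),
    boundary_volume = 1,
    valid_range = c(0.001, 44.91),
    continuity_tol = 0.005,
    provenance = "gk-icon published calibration"
  )
}

#' Evaluate a drop-off model
#'
#' Selects the branch by volume: low branch strictly below the boundary,
#' high branch strictly above, and the mean of the two branches exactly at
#' the boundary (the calibration evaluates both there).  Evaluation outside
#' `valid_range` extrapolates with a warning; the low branch goes negative
#' below ~4e-4 cm^3, and a negative drop-off is a hard error.
#'
#' @param model A `delta_r_model`.
#' @param volume Volume(s), cm^3, strictly positive.
#' @return Drop-off distance(s) in cm.
#' @export
eval_delta_r <- function(model, volume) {
  stopifnot(inherits(model, "delta_r_model"))
  check_positive(volume, "volume")
  b <- model$boundary_volume
  out <- ifelse(volume < b, delta_r_low(model, volume),
         ifelse(volume > b, delta_r_high(model, volume),
                (delta_r_low(model, volume) + delta_r_high(model, volume)) / 2))
  oob <- volume < model$valid_range[1] | volume > model$valid_range[2]
  if (any(oob)) {
    warning(sprintf(
      "%d volume(s) outside the calibrated range [%.3g, %.3g] cm^3; extrapolating",
      sum(oob), model$valid_range[1], model$valid_range[2]
    ), call. = FALSE)
  }
  if (any(out <= 0)) {
    stop(sprintf(
      "model yields non-positive drop-off (%.4g cm) at V = %.4g cm^3",
      min(out), volume[which.min(out)]
    ), call. = FALSE)
  }
  out
}

#' Measured drop-off from one phantom sphere plan
#'
#' For a spherical target and its (spherical) 50% isodose cloud the measured
#' drop-off is the difference of equivalent-sphere radii,
#' \eqn{\Delta r = r_{IDC50\%} - r_{PTV}}.
#'
#' @param v_ptv Target volume, cm^3.
#' @param v_idc50 Volume of the 50%-isodose cloud, cm^3; must exceed `v_ptv`
#'   (the dose cloud cannot lie inside the target).
#' @return Drop-off in cm (vectorised).
#' @export
measured_delta_r <- function(v_ptv, v_idc50) {
  check_positive(v_ptv, "v_ptv")
  check_positive(v_idc50, "v_idc50")
  if (any(v_idc50 <= v_ptv)) {
    stop("invalid measurement: v_idc50 must exceed v_ptv (the 50% isodose cloud encloses the target)",
         call. = FALSE)
  }
  effective_radius(v_idc50) - effective_radius(v_ptv)
}

#' Phantom calibration measurements
#'
#' Builds the measurement table used by [fit_delta_r_model()] from paired
#' volumes, deriving the measured drop-off of each pair.
#'
#' @param v_ptv,v_idc50 Paired volumes, cm^3.
#' @param label Optional source labels.
#' @return A data.frame with columns `v_ptv_cc`, `v_idc50_cc`,
#'   `delta_r_measured_cm`, `label`.
#' @export
phantom_measurements <- function(v_ptv, v_idc50, label = NULL) {
  dr <- measured_delta_r(v_ptv, v_idc50)
  data.frame(
    v_ptv_cc = v_ptv,
    v_idc50_cc = v_idc50,
    delta_r_measured_cm = dr,
    label = if (is.null(label)) sprintf("m%02d", seq_along(v_ptv)) else label,
    stringsAsFactors = FALSE
  )
}

#' Fit a drop-off model to phantom measurements
#'
#' Least-squares fit of the two branch forms with the exponents fixed at
#' 1/3 (high branch) and \{1, 2/3, 1/3\} (low branch), subject to the linear
#' equality constraint that both branches agree at the boundary volume.  The
#' constraint is handled by eliminating the high-branch constant
#' \eqn{a = \Delta r_{low}(V_b) - b V_b^{1/3}} and solving the reduced
#' ordinary least-squares problem by QR, which is deterministic and leaves
#' the returned model continuous to machine precision.
#'
#' With `free_exponent = TRUE` the high-branch exponent is profiled: for each
#' candidate exponent the constrained linear problem is solved and the
#' exponent minimising the residual sum of squares is selected by
#' one-dimensional optimisation (for calibrating machines whose drop-off does
#' not follow a cube-root law).
#'
#' @param measurements A data.frame as returned by [phantom_measurements()]
#'   or [read_phantom_csv()] (columns `v_ptv_cc`, `v_idc50_cc`).
#' @param boundary_volume Branch boundary, cm^3 (default 1).
#' @param free_exponent Fit the high-branch exponent as well (default fixed
#'   at 1/3).
#' @param exponent_range Search interval for the free exponent.
#' @return A `delta_r_model` whose `fit` element holds the per-point
#'   residuals (`residuals`), `max_abs_residual`, and the fitted exponent.
#' @export
fit_delta_r_model <- function(measurements, boundary_volume = 1,
                              free_exponent = FALSE,
                              exponent_range = c(0.05, 1.5)) {
  stopifnot(is.data.frame(measurements),
            all(c("v_ptv_cc", "v_idc50_cc") %in% names(measurements)))
  v <- measurements$v_ptv_cc
  y <- measured_delta_r(v, measurements$v_idc50_cc)
  b <- boundary_volume
  n_low <- sum(v <= b)
  n_high <- sum(v >= b)
  if (n_low < 4) {
    stop(sprintf("low branch underdetermined: %d measurement(s) with V <= %g cm^3, need >= 4",
                 n_low, b), call. = FALSE)
  }
  if (n_high < 2) {
    stop(sprintf("high branch underdetermined: %d measurement(s) with V >= %g cm^3, need >= 2",
                 n_high, b), call. = FALSE)
  }

  solve_fixed_p <- function(p) {
    # unknowns: c0, c1, c2, c3, b_hi with a eliminated via continuity
    lo <- v <= b
    X <- matrix(0, length(v), 5)
    X[lo, 1] <- 1
    X[lo, 2] <- v[lo]
    X[lo, 3] <- v[lo]^(2 / 3)
    X[lo, 4] <- v[lo]^(1 / 3)
    X[!lo, 1] <- 1
    X[!lo, 2] <- b
    X[!lo, 3] <- b^(2 / 3)
    X[!lo, 4] <- b^(1 / 3)
    X[!lo, 5] <- v[!lo]^p - b^p
    qrX <- qr(X)
    if (qrX$rank < 5) {
      stop("singular design matrix: measurement volumes do not identify the model",
           call. = FALSE)
    }
    beta <- qr.coef(qrX, y)
    fitted <- drop(X %*% beta)
    list(beta = beta, rss = sum((y - fitted)^2), fitted = fitted)
  }

  p <- 1 / 3
  if (free_exponent) {
    p <- stats::optimize(function(q) solve_fixed_p(q)$rss,
                         interval = exponent_range, tol = 1e-8)$minimum
  }
  sol <- solve_fixed_p(p)
  cf <- sol$beta
  a <- cf[1] + cf[2] * b + cf[3] * b^(2 / 3) + cf[4] * b^(1 / 3) - cf[5] * b^p
  model <- delta_r_model(
    low_coeffs = cf[1:4],
    high_coeffs = c(a, cf[5]),
    boundary_volume = b,
    valid_range = range(v),
    continuity_tol = 1e-9,
    provenance = sprintf("fitted from %d measurements (exponent %s)",
                         length(v), if (free_exponent) format(p) else "1/3"),
    high_exponent = if (free_exponent) p else NULL
  )
  res <- y - sol$fitted
  model$fit <- list(
    residuals = data.frame(v_ptv_cc = v, delta_r_measured_cm = y,
                           fitted_cm = sol$fitted, residual_cm = res),
    max_abs_residual = max(abs(res)),
    exponent = p
  )
  model
}


#' @export
print.delta_r_model <- function(x, ...) {
  cf <- x$low_coeffs
  cat("Gamma Knife dose drop-off model (cm vs cm^3)\n")
  cat(sprintf("  V <= %.3g: %.4f %+.4f V %+.4f V^(2/3) %+.4f V^(1/3)\n",
              x$boundary_volume, cf[1], cf[2], cf[3], cf[4]))
  p <- if (!is.null(x$high_exponent)) x$high_exponent else 1 / 3
  cat(sprintf("  V >= %.3g: %.4f %+.4f V^(%.4g)\n",
              x$boundary_volume, x$high_coeffs[1], x$high_coeffs[2], p))
  cat(sprintf("  calibrated range [%.3g, %.3g] cm^3; %s\n",
              x$valid_range[1], x$valid_range[2], x$provenance))
  if (!is.null(x$fit)) {
    cat(sprintf("  fit: max |residual| = %.4f cm over %d points\n",
                x$fit$max_abs_residual, nrow(x$fit$residuals)))
  }
  invisible(x)
}

#' Read / write phantom calibration CSV
#'
#' Column dialect: `v_ptv_cc, v_idc50_cc[, label]`, header required, decimal
#' point, UTF-8.
#'
#' @param path File path.
#' @return `read_phantom_csv`: a data.frame as from [phantom_measurements()].
#' @export
read_phantom_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("v_ptv_cc", "v_idc50_cc") %in% names(df))) {
    stop("phantom CSV must have columns v_ptv_cc, v_idc50_cc", call. = FALSE)
  }
  phantom_measurements(df$v_ptv_cc, df$v_idc50_cc,
                       label = if ("label" %in% names(df)) df$label else NULL)
}

#' @rdname read_phantom_csv
#' @param measurements Data.frame with `v_ptv_cc`, `v_idc50_cc` (and
#'   optionally `label`).
#' @export
write_phantom_csv <- function(measurements, path) {
  keep <- intersect(c("v_ptv_cc", "v_idc50_cc", "label"), names(measurements))
  utils::write.csv(measurements[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a drop-off model as JSON
#'
#' Document layout: `{boundary_cc, low_coeffs[4], high_coeffs[2],
#' valid_range_cc[2], provenance}` (plus `high_exponent` for free-exponent
#' fits).
#'
#' @param model A `delta_r_model`.
#' @param path Destination / source path.
#' @export
write_delta_r_model <- function(model, path) {
  stopifnot(inherits(model, "delta_r_model"))
  doc <- list(
    boundary_cc = model$boundary_volume,
    low_coeffs = model$low_coeffs,
    high_coeffs = model$high_coeffs,
    valid_range_cc = model$valid_range,
    continuity_tol = model$continuity_tol,
    provenance = model$provenance
  )
  if (!is.null(model$high_exponent)) doc$high_exponent <- model$high_exponent
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_delta_r_model
#' @export
read_delta_r_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- delta_r_model(
    low_coeffs = doc$low_coeffs,
    high_coeffs = doc$high_coeffs,
    boundary_volume = doc$boundary_cc,
    valid_range = doc$valid_range_cc,
    continuity_tol = if (!is.null(doc$continuity_tol)) doc$continuity_tol else 1e-9,
    provenance = if (!is.null(doc$provenance)) doc$provenance else "json",
    high_exponent = doc$high_exponent
  )
  m
}
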