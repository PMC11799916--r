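# Synthetic structure and calibration generators.  Every fixture carries its
# analytic oracle (true volume / surface area / drop-off) so the mesh and
# fitting code can be tested closed-loop without any external data.

# run code with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic voxelated structure
#'
#' Describes an analytic solid to be sliced into planar contours the way a
#' planning system stores them: `sphere` (radius `r`), `ellipsoid`
#' (semi-axes `a`, `b`, `c`) or `two_lobe` (two disjoint spheres of radii
#' `r1`, `r2` with centres `separation` apart along x).  `pixel_quantum > 0`
#' snaps contour vertices to a square grid of that pitch, emulating the
#' pixelation of structures drawn on an image grid — the mechanism that
#' makes mesh surface areas of very small targets non-physical.
#'
#' @param shape One of `"sphere"`, `"ellipsoid"`, `"two_lobe"`.
#' @param slice_spacing Axial slice spacing, cm.
#' @param points_per_ring Vertices per contour ring (>= 8).
#' @param pixel_quantum Grid pitch for vertex snapping, cm (0 = off).
#' @param jitter_sd Gaussian vertex jitter, cm (0 = off).
#' @param seed Integer seed for the jitter stream (mandatory when
#'   `jitter_sd > 0`; no global RNG state is consumed).
#' @param ... Size parameters for the chosen shape, in cm: `r`; or `a`,
#'   `b`, `c`; or `r1`, `r2`, `separation`.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(shape = c("sphere", "ellipsoid", "two_lobe"),
                         slice_spacing = 0.1, points_per_ring = 64,
                         pixel_quantum = 0, jitter_sd = 0, seed = NULL, ...) {
  shape <- match.arg(shape)
  dims <- list(...)
  defaults <- switch(shape,
    sphere = list(r = 1),
    ellipsoid = list(a = 1, b = 0.8, c = 1.2),
    two_lobe = list(r1 = 0.8, r2 = 0.5, separation = 2)
  )
  dims <- utils::modifyList(defaults, dims)
  lapply(dims, check_positive, name = "size parameter")
  check_positive(slice_spacing, "slice_spacing")
  stopifnot(points_per_ring >= 8, pixel_quantum >= 0, jitter_sd >= 0)
  if (jitter_sd > 0 && is.null(seed)) {
    stop("jitter requires an explicit seed", call. = FALSE)
  }
  if (shape == "two_lobe" && dims$separation <= dims$r1 + dims$r2) {
    stop("two_lobe fixture requires disjoint spheres (separation > r1 + r2)",
         call. = FALSE)
  }
  structure(
    list(shape = shape, dims = dims, slice_spacing = slice_spacing,
         points_per_ring = as.integer(points_per_ring),
         pixel_quantum = pixel_quantum, jitter_sd = jitter_sd, seed = seed),
    class = "fixture_spec"
  )
}

# surface area of an ellipsoid by quadrature of |r_theta x r_phi|
ellipsoid_surface_area <- function(a, b, c_) {
  nu <- 400L; nv <- 200L
  u <- (seq_len(nu) - 0.5) / nu * 2 * pi   # azimuth
  v <- (seq_len(nv) - 0.5) / nv * pi       # polar
  su <- sin(u); cu <- cos(u)
  sv <- sin(v); cv <- cos(v)
  # |dS| = sv * sqrt(b^2 c^2 cu^2 sv^2 + a^2 c^2 su^2 sv^2 + a^2 b^2 cv^2)
  term <- outer(cu^2, sv^2) * (b * c_)^2 +
          outer(su^2, sv^2) * (a * c_)^2 +
          matrix((a * b)^2 * cv^2, nu, nv, byrow = TRUE)
  integrand <- sqrt(term) * matrix(sv, nu, nv, byrow = TRUE)
  sum(integrand) * (2 * pi / nu) * (pi / nv)
}

# cross-section rings of the analytic solid at height z; list of n x 2
# matrices (possibly empty)
cross_section <- function(spec, z, theta) {
  d <- spec$dims
  rings <- list()
  if (spec$shape == "sphere") {
    if (abs(z) < d$r) {
      rho <- d$r * sqrt(1 - (z / d$r)^2)
      rings <- list(cbind(rho * cos(theta), rho * sin(theta)))
    }
  } else if (spec$shape == "ellipsoid") {
    if (abs(z) < d$c) {
      s <- sqrt(1 - (z / d$c)^2)
      rings <- list(cbind(d$a * s * cos(theta), d$b * s * sin(theta)))
    }
  } else {
    for (lobe in list(c(-d$separation / 2, d$r1), c(d$separation / 2, d$r2))) {
      if (abs(z) < lobe[2]) {
        rho <- lobe[2] * sqrt(1 - (z / lobe[2])^2)
        rings <- c(rings, list(cbind(lobe[1] + rho * cos(theta),
                                     rho * sin(theta))))
      }
    }
  }
  rings
}

shape_half_height <- function(spec) {
  d <- spec$dims
  switch(spec$shape, sphere = d$r, ellipsoid = d$c,
         two_lobe = max(d$r1, d$r2))
}

shape_oracle <- function(spec) {
  d <- spec$dims
  switch(spec$shape,
    sphere = list(volume = 4 * pi / 3 * d$r^3, area = 4 * pi * d$r^2),
    ellipsoid = list(volume = 4 * pi / 3 * d$a * d$b * d$c,
                     area = ellipsoid_surface_area(d$a, d$b, d$c)),
    two_lobe = list(volume = 4 * pi / 3 * (d$r1^3 + d$r2^3),
                    area = 4 * pi * (d$r1^2 + d$r2^2))
  )
}

#' Generate a synthetic contour stack
#'
#' Slices the analytic solid of a [fixture_spec()] into planar rings at the
#' requested spacing, optionally jittering and grid-snapping the vertices.
#' The returned [contour_set()] carries the analytic volume and surface area
#' of the ideal shape as attributes `analytic_volume` / `analytic_area` for
#' oracle comparisons.  A shape thinner than one slice yields a degenerate
#' single-slice fixture with a warning.
#'
#' @param spec A `fixture_spec`.
#' @return A `contour_set`.
#' @examples
#' cs <- make_structure(fixture_spec("sphere", r = 1, slice_spacing = 0.1))
#' mesh <- contours_to_mesh(cs)
#' mesh_volume(mesh)  # ~4.19 cm^3
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  h <- spec$slice_spacing
  hh <- shape_half_height(spec)
  k <- seq(floor(-hh / h), ceiling(hh / h))
  zs <- (k + 0.5) * h
  zs <- zs[abs(zs) < hh]
  theta <- 2 * pi * (seq_len(spec$points_per_ring) - 1) / spec$points_per_ring
  single <- FALSE
  if (length(zs) == 0) {
    warning("shape thinner than one slice; emitting a degenerate single-slice fixture",
            call. = FALSE)
    zs <- 0
    single <- TRUE
  }

  build <- function() {
    slices <- lapply(zs, function(z) {
      rings <- cross_section(spec, z, theta)
      if (length(rings) == 0) return(NULL)
      rings <- lapply(rings, function(ring) {
        if (spec$jitter_sd > 0) {
          ring <- ring + matrix(stats::rnorm(length(ring), 0, spec$jitter_sd),
                                ncol = 2)
        }
        if (spec$pixel_quantum > 0) {
          ring <- round(ring / spec$pixel_quantum) * spec$pixel_quantum
        }
        ring
      })
      list(z = z, polygons = rings)
    })
    slices[!vapply(slices, is.null, logical(1))]
  }
  slices <- if (is.null(spec$seed)) build() else with_seed(spec$seed, build())

  cs <- contour_set(slices,
                    roi_name = sprintf("synthetic_%s", spec$shape),
                    spacing = c(spec$pixel_quantum, h),
                    degenerate = single)
  oracle <- shape_oracle(spec)
  attr(cs, "analytic_volume") <- oracle$volume
  attr(cs, "analytic_area") <- oracle$area
  cs
}

#' Sphere fixture by target volume
#'
#' Convenience wrapper: a sphere [fixture_spec()] whose radius is the
#' equivalent-sphere radius of `volume`.
#'
#' @param volume Sphere volume, cm^3.
#' @inheritParams fixture_spec
#' @export
sphere_fixture <- function(volume, slice_spacing = 0.1, points_per_ring = 64,
                           pixel_quantum = 0, jitter_sd = 0, seed = NULL) {
  fixture_spec("sphere", r = effective_radius(volume),
               slice_spacing = slice_spacing, points_per_ring = points_per_ring,
               pixel_quantum = pixel_quantum, jitter_sd = jitter_sd, seed = seed)
}

#' Synthesize a phantom calibration dataset
#'
#' Inverts the drop-off measurement: for each volume the 50%-isodose volume
#' is the sphere of radius \eqn{r_{PTV} + \Delta r(V) + \epsilon} with
#' Gaussian noise \eqn{\epsilon}.  Noiseless output reproduces the model
#' drop-off exactly; draws that would make the isodose cloud smaller than
#' the target are resampled with a warning, so the output is always a valid
#' measurement set.
#'
#' @param model A `delta_r_model`.
#' @param volumes Target volumes, cm^3.
#' @param noise_sd Noise standard deviation on the drop-off, cm.
#' @param seed Mandatory integer seed (no global RNG state is consumed).
#' @return A data.frame as from [phantom_measurements()].
#' @export
make_phantom_calibration_set <- function(model, volumes, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "delta_r_model"))
  check_positive(volumes, "volumes")
  dr <- eval_delta_r(model, volumes)
  r_ptv <- effective_radius(volumes)
  draw <- function() {
    eps <- if (noise_sd > 0) stats::rnorm(length(volumes), 0, noise_sd) else 0
    r50 <- r_ptv + dr + eps
    bad <- which(r50 <= r_ptv)
    n_resample <- 0L
    while (length(bad) > 0 && n_resample < 100L) {
      r50[bad] <- r_ptv[bad] + dr[bad] + stats::rnorm(length(bad), 0, noise_sd)
      bad <- which(r50 <= r_ptv)
      n_resample <- n_resample + 1L
    }
    if (n_resample > 0) {
      warning(sprintf("resampled %d draw(s) that inverted the measurement (noise too large)",
                      n_resample), call. = FALSE)
    }
    r50
  }
  r50 <- if (noise_sd > 0) with_seed(seed, draw()) else r_ptv + dr
  phantom_measurements(volumes, sphere_volume(r50),
                       label = sprintf("synthetic_V%.3g", volumes))
}

#' Bundled calibration and clinical tables
#'
#' `table1_fixture()` returns the phantom calibration table: eleven measured
#' drop-off values for spherical targets of 0.001 to 44.91 cm^3, alongside
#' the values of the two published fit branches (the 1 cm^3 row has no
#' measurement; it displays the boundary matching).  `table1_measurements()`
#' reconstructs the paired-volume form used for refitting by inverting the
#' drop-off relation (`v_idc50 = sphere volume of r_ptv + delta_r`).
#' `table2_fixture()` returns the 35-target clinical comparison table.
#'
#' @return Data.frames; see each description.
#' @export
table1_fixture <- function() {
  utils::read.csv(pkg_extdata("table1.csv"), stringsAsFactors = FALSE)
}

#' @rdname table1_fixture
#' @export
table1_measurements <- function() {
  t1 <- table1_fixture()
  t1 <- t1[!is.na(t1$delta_r_measured_cm), ]
  phantom_measurements(
    t1$v_ptv_cc,
    sphere_volume(effective_radius(t1$v_ptv_cc) + t1$delta_r_measured_cm),
    label = sprintf("phantom_V%.3g", t1$v_ptv_cc)
  )
}

#' @rdname table1_fixture
#' @export
table2_fixture <- function() {
  utils::read.csv(pkg_extdata("table2.csv"), stringsAsFactors = FALSE)
}

#' @rdname table1_fixture
#' @export
table2_plan_targets <- function() {
  t2 <- table2_fixture()
  data.frame(
    plan_id = t2$plan_id,
    target_id = t2$target_id,
    v_ptv_cc = t2$v_ptv_cc,
    sa_ptv_cm2 = t2$sa_ptv_cm2,
    v_idc50_cc = t2$r50_clinical * t2$v_ptv_cc,
    v_idc100_cc = NA_real_,
    prescription_gy = t2$prescription_gy,
    dn_pct = t2$dn_pct,
    excluded = FALSE,
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "gkr50")
  if (path == "") stop("bundled file not found: ", file, call. = FALSE)
  path
}
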