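#' Triangle mesh of a structure
#'
#' A closed triangle surface built from planar contours.  Vertices are in cm
#' in patient coordinates; triangles are vertex-index triples with outward
#' orientation (positive signed volume).
#'
#' @param vertices Numeric n x 3 matrix, cm.
#' @param triangles Integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `gk_mesh` with a `watertight` flag (every edge
#'   shared by exactly two triangles, consistently oriented).
#' @export
gk_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3, nrow(triangles) >= 1,
            max(triangles) <= nrow(vertices), min(triangles) >= 1)
  m <- structure(
    list(vertices = vertices, triangles = triangles),
    class = "gk_mesh"
  )
  m$watertight <- is_edge_manifold(m)
  if (m$watertight && mesh_signed_volume(m) < 0) {
    m$triangles <- m$triangles[, c(1, 3, 2)]
  }
  m
}

# every undirected edge in exactly 2 triangles and each directed edge once
is_edge_manifold <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  dir_key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dir_key)) return(FALSE)
  und_key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(und_key) == 2L)
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  u <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  w <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Surface area of a mesh
#'
#' Sum of triangle areas.  Degenerate (zero-area) triangles are dropped from
#' the sum and counted in the `dropped_degenerate` attribute.  The result
#' carries an isoperimetric diagnostic: if the area falls below the surface
#' area of the sphere with volume `reference_volume` (by default the mesh's
#' own volume), the `nonphysical_sa` attribute is set and a warning is
#' emitted.  Against its own volume a valid closed mesh can never trip the
#' bound (the sphere is the minimal-surface solid); pass the
#' planning-system volume of the structure as `reference_volume` to detect
#' the pixelation pathology of very small targets, where the contour mesh
#' understates both area and volume relative to the planning system.
#'
#' @param mesh A `gk_mesh`.
#' @param reference_volume Volume (cm^3) whose equal-volume sphere defines
#'   the physical lower bound; default `NULL` uses the mesh volume (only
#'   possible for watertight meshes).
#' @return Surface area in cm^2 with attributes `nonphysical_sa`,
#'   `sphere_bound`, `dropped_degenerate`.
#' @export
mesh_surface_area <- function(mesh, reference_volume = NULL) {
  stopifnot(inherits(mesh, "gk_mesh"))
  areas <- triangle_areas(mesh)
  degen <- sum(areas <= 0)
  sa <- sum(areas[areas > 0])
  bound <- NA_real_
  nonphys <- FALSE
  vol <- reference_volume
  if (is.null(vol) && isTRUE(mesh$watertight)) vol <- mesh_volume(mesh)
  if (!is.null(vol) && is.finite(vol) && vol > 0) {
    bound <- sphere_surface_area_from_volume(vol)
    nonphys <- sa < bound
    if (nonphys) {
      warning(sprintf(
        "non-physical surface area: mesh SA %.4f cm^2 is below the equal-volume sphere bound %.4f cm^2 (pixelation artefact)",
        sa, bound
      ), call. = FALSE)
    }
  }
  structure(sa, nonphysical_sa = nonphys, sphere_bound = bound,
            dropped_degenerate = degen)
}

#' Volume enclosed by a watertight mesh
#'
#' Divergence-theorem sum of signed tetrahedra against the origin; the
#' absolute value is returned, so the result is independent of global
#' orientation.
#'
#' @param mesh A watertight `gk_mesh`.
#' @return Volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "gk_mesh"))
  if (!isTRUE(mesh$watertight)) {
    stop("mesh is not watertight; enclosed volume is undefined", call. = FALSE)
  }
  abs(mesh_signed_volume(mesh))
}

#' @export
print.gk_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d triangles, %swatertight\n",
              nrow(x$vertices), nrow(x$triangles),
              if (isTRUE(x$watertight)) "" else "NOT "))
  if (isTRUE(x$watertight)) {
    cat(sprintf("  volume %.4f cm^3, area %.4f cm^2\n",
                mesh_volume(x), sum(triangle_areas(x))))
  }
  if (isTRUE(attr(x, "resolution_warning"))) {
    cat("  [resolution warning: structure near the contour resolution floor]\n")
  }
  invisible(x)
}

# --- slice-to-slice stitching -------------------------------------------

# ear-clipping triangulation of a CCW simple polygon; falls back to a fan
# if no ear is found (non-simple snapped rings)
ear_clip <- function(ring) {
  n <- nrow(ring)
  if (n == 3) return(matrix(1:3, 1))
  idx <- seq_len(n)
  tris <- matrix(0L, 0, 3)
  guard <- 0L
  while (length(idx) > 3 && guard < 2L * n * n) {
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- idx[if (k == 1) m else k - 1]
      i1 <- idx[k]
      i2 <- idx[if (k == m) 1 else k + 1]
      a <- ring[i0, ]; b <- ring[i1, ]; c_ <- ring[i2, ]
      cross <- (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])
      if (cross <= 1e-14) next  # reflex or collinear
      others <- setdiff(idx, c(i0, i1, i2))
      if (length(others) > 0 &&
          any(point_in_triangle(ring[others, , drop = FALSE], a, b, c_))) next
      tris <- rbind(tris, c(i0, i1, i2))
      idx <- idx[-k]
      clipped <- TRUE
      break
    }
    if (!clipped) break
    guard <- guard + 1L
  }
  if (length(idx) == 3) {
    tris <- rbind(tris, idx)
  } else if (length(idx) > 3) {
    # fallback: fan from the first remaining vertex
    for (k in 2:(length(idx) - 1)) {
      tris <- rbind(tris, c(idx[1], idx[k], idx[k + 1]))
    }
  }
  tris
}

point_in_triangle <- function(p, a, b, c_) {
  s1 <- (b[1] - a[1]) * (p[, 2] - a[2]) - (b[2] - a[2]) * (p[, 1] - a[1])
  s2 <- (c_[1] - b[1]) * (p[, 2] - b[2]) - (c_[2] - b[2]) * (p[, 1] - b[1])
  s3 <- (a[1] - c_[1]) * (p[, 2] - c_[2]) - (a[2] - c_[2]) * (p[, 1] - c_[1])
  (s1 >= 0 & s2 >= 0 & s3 >= 0)
}

tri_area3d <- function(a, b, c_) {
  u <- b - a; w <- c_ - a
  sqrt(sum(c(u[2] * w[3] - u[3] * w[2],
             u[3] * w[1] - u[1] * w[3],
             u[1] * w[2] - u[2] * w[1])^2)) / 2
}

# advancing-front band between two CCW rings (A below, B above).  The
# fronts advance in lockstep along normalized arc length (after centroid
# registration and start-point alignment), which keeps the band from
# collapsing into fans on rings of unequal size; exact arc-length ties are
# resolved by the smaller candidate triangle.  Returns global index triples
# wound consistently (outward for CCW rings).
stitch_rings <- function(va, vb, ia, ib) {
  na <- nrow(va); nb <- nrow(vb)
  # centroid registration, then start B at the vertex closest to A's start
  shift <- ring_centroid(va[, 1:2, drop = FALSE]) -
           ring_centroid(vb[, 1:2, drop = FALSE])
  bxy <- sweep(vb[, 1:2, drop = FALSE], 2, -shift)
  d0 <- (bxy[, 1] - va[1, 1])^2 + (bxy[, 2] - va[1, 2])^2
  j0 <- which.min(d0)
  ord_b <- (j0 + seq_len(nb) - 2L) %% nb + 1L
  ai <- function(k) ia[(k - 1L) %% na + 1L]
  bi <- function(k) ib[ord_b[(k - 1L) %% nb + 1L]]
  av <- function(k) va[(k - 1L) %% na + 1L, ]
  bv <- function(k) vb[ord_b[(k - 1L) %% nb + 1L], ]
  # normalized cumulative arc length of each ring from its aligned start;
  # parameter of vertex k is t[k], with t[n+1] = 1 closing the loop
  cum_param <- function(vm, ord) {
    pts <- vm[ord, , drop = FALSE]
    seg <- sqrt(rowSums((pts[c(2:nrow(pts), 1), ] - pts)^2))
    c(0, cumsum(seg)) / sum(seg)
  }
  ta <- cum_param(va, seq_len(na))
  tb <- cum_param(vb, ord_b)
  i <- 1L; j <- 1L
  tris <- matrix(0L, na + nb, 3)
  t <- 0L
  while (i <= na || j <= nb) {
    adv_a <- i <= na
    adv_b <- j <= nb
    if (adv_a && adv_b) {
      da <- ta[i + 1L]; db <- tb[j + 1L]
      if (abs(da - db) < 1e-9) {
        area_a <- tri_area3d(av(i), av(i + 1L), bv(j))
        area_b <- tri_area3d(av(i), bv(j + 1L), bv(j))
        if (area_a <= area_b) adv_b <- FALSE else adv_a <- FALSE
      } else if (da < db) adv_b <- FALSE else adv_a <- FALSE
    }
    t <- t + 1L
    if (adv_a) {
      tris[t, ] <- c(ai(i), ai(i + 1L), bi(j))
      i <- i + 1L
    } else {
      tris[t, ] <- c(ai(i), bi(j + 1L), bi(j))
      j <- j + 1L
    }
  }
  tris[seq_len(t), , drop = FALSE]
}

# greedy one-to-one ring matching between consecutive slices by
# bounding-box overlap area (centroid distance breaks ties)
match_rings <- function(polys_a, polys_b) {
  na <- length(polys_a); nb <- length(polys_b)
  score <- matrix(0, na, nb)
  dist <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    ra <- apply(polys_a[[i]], 2, range)
    ca <- ring_centroid(polys_a[[i]])
    for (j in seq_len(nb)) {
      rb <- apply(polys_b[[j]], 2, range)
      ov <- pmax(0, pmin(ra[2, ], rb[2, ]) - pmax(ra[1, ], rb[1, ]))
      score[i, j] <- ov[1] * ov[2]
      dist[i, j] <- sum((ca - ring_centroid(polys_b[[j]]))^2)
    }
  }
  pairs <- matrix(0L, 0, 2)
  while (any(score > 0)) {
    best <- which(score == max(score), arr.ind = TRUE)
    if (nrow(best) > 1) best <- best[which.min(dist[best]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    pairs <- rbind(pairs, c(i, j))
    score[i, ] <- 0
    score[, j] <- 0
  }
  pairs
}

#' Build a closed surface mesh from a contour stack
#'
#' Stitches the rings of consecutive slices into a lateral triangle band
#' (ring correspondence by maximal bounding-box overlap; vertex
#' correspondence by centroid registration and an advancing front that
#' greedily minimises triangle area) and closes the surface with ear-clipped
#' caps over terminal or unmatched rings.  Single-slice structures are
#' extruded by the slice spacing and flagged degenerate, mirroring
#' planning-system slab volumes.
#'
#' @param contours A `contour_set`.
#' @param slab_thickness Extrusion thickness (cm) for single-slice
#'   structures; defaults to the contour set's slice spacing.
#' @return A watertight `gk_mesh`.  Structures whose smallest ring has fewer
#'   than 8 vertices carry a `resolution_warning` attribute: at that size
#'   contour pixelation dominates the surface estimate.
#' @export
contours_to_mesh <- function(contours, slab_thickness = NULL) {
  stopifnot(inherits(contours, "contour_set"))
  slices <- contours$slices
  if (length(slices) == 1) {
    t <- slab_thickness
    if (is.null(t)) t <- contours$source_spacing[2]
    if (is.na(t) || t <= 0) {
      stop("single-slice structure: supply slab_thickness or a slice spacing",
           call. = FALSE)
    }
    z <- slices[[1]]$z
    slices <- list(
      list(z = z - t / 2, polygons = slices[[1]]$polygons),
      list(z = z + t / 2, polygons = slices[[1]]$polygons)
    )
    degenerate <- TRUE
  } else {
    degenerate <- FALSE
  }

  verts <- matrix(0, 0, 3)
  idx_of <- vector("list", length(slices))  # per slice: list of index vectors
  for (s in seq_along(slices)) {
    idx_of[[s]] <- vector("list", length(slices[[s]]$polygons))
    for (r in seq_along(slices[[s]]$polygons)) {
      ring <- slices[[s]]$polygons[[r]]
      idx_of[[s]][[r]] <- nrow(verts) + seq_len(nrow(ring))
      verts <- rbind(verts, cbind(ring, slices[[s]]$z))
    }
  }

  tris <- matrix(0L, 0, 3)
  n_sl <- length(slices)
  # matched_up[[s]][r]: ring r of slice s has a partner in slice s+1
  matched_up <- lapply(slices, function(s) rep(FALSE, length(s$polygons)))
  matched_dn <- lapply(slices, function(s) rep(FALSE, length(s$polygons)))
  for (s in seq_len(n_sl - 1)) {
    pa <- slices[[s]]$polygons
    pb <- slices[[s + 1]]$polygons
    pairs <- match_rings(pa, pb)
    if (nrow(pairs) == 0) {
      stop(sprintf("no ring correspondence between slices %d and %d (z = %.3f, %.3f)",
                   s, s + 1, slices[[s]]$z, slices[[s + 1]]$z), call. = FALSE)
    }
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      matched_up[[s]][i] <- TRUE
      matched_dn[[s + 1]][j] <- TRUE
      tris <- rbind(tris, stitch_rings(
        cbind(pa[[i]], slices[[s]]$z), cbind(pb[[j]], slices[[s + 1]]$z),
        idx_of[[s]][[i]], idx_of[[s + 1]][[j]]
      ))
    }
  }
  # caps: ring without a partner below gets a bottom cap (faces -z, i.e.
  # reversed CCW); without a partner above, a top cap (faces +z)
  for (s in seq_len(n_sl)) {
    for (r in seq_along(slices[[s]]$polygons)) {
      ring <- slices[[s]]$polygons[[r]]
      gi <- idx_of[[s]][[r]]
      if (!matched_dn[[s]][r]) {
        local <- ear_clip(ring)
        tris <- rbind(tris, cbind(gi[local[, 1]], gi[local[, 3]], gi[local[, 2]]))
      }
      if (!matched_up[[s]][r]) {
        local <- ear_clip(ring)
        tris <- rbind(tris, cbind(gi[local[, 1]], gi[local[, 2]], gi[local[, 3]]))
      }
    }
  }

  mesh <- gk_mesh(verts, tris)
  attr(mesh, "degenerate") <- degenerate
  min_ring <- min(vapply(slices, function(s)
    min(vapply(s$polygons, nrow, integer(1))), integer(1)))
  # a ring spanning <= ~3x3 pixels of the source grid is pixelation-limited
  pixel <- contours$source_spacing[1]
  min_area <- min(vapply(slices, function(s)
    min(vapply(s$polygons, function(p) abs(ring_signed_area(p)), numeric(1))),
    numeric(1)))
  attr(mesh, "resolution_warning") <- min_ring < 8 || degenerate ||
    (!is.na(pixel) && pixel > 0 && min_area <= 9 * pixel^2)
  if (isTRUE(attr(mesh, "resolution_warning"))) {
    warning("structure is at the contour resolution floor; surface area is pixelation-limited",
            call. = FALSE)
  }
  mesh
}

#' Export a mesh for visual inspection
#'
#' `write_stl` writes ASCII STL; `write_off` writes the OFF polygon format.
#'
#' @param mesh A `gk_mesh`.
#' @param path Output file.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "gk_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid gkr50", con)
  for (k in seq_len(nrow(tr))) {
    a <- v[tr[k, 1], ]; b <- v[tr[k, 2], ]; c_ <- v[tr[k, 3], ]
    u <- b - a; w <- c_ - a
    n <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %g %g %g", a[1], a[2], a[3]),
      sprintf("      vertex %g %g %g", b[1], b[2], b[3]),
      sprintf("      vertex %g %g %g", c_[1], c_[2], c_[3]),
      "    endloop",
      "  endfacet"
    ), con)
  }
  writeLines("endsolid gkr50", con)
  invisible(path)
}

#' @rdname write_stl
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "gk_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  lines <- c(
    "OFF",
    sprintf("%d %d 0", nrow(v), nrow(tr)),
    sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]),
    sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L)
  )
  writeLines(lines, path)
  invisible(path)
}
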