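# ---------------------------------------------------------------------------
# Resected / edge / cavity electrode labeling.
#
# Intraoperative arm: the resection is a polygon drawn in the photo plane
# (mm after scale calibration); each contact is a disc of radius r.  With d
# the signed distance of the contact center to the polygon boundary
# (negative inside):
#
#   resected  <=>  d < r          (disc overlaps interior or boundary)
#   edge      <=>  -r < d < r     (partly on top, i.e. exactly on the edge)
#              or  r <= d  and  d - r <= edge_mm   (disc within edge_mm
#                                                   outside the boundary)
#
# edge_mm defaults to 5 mm (0.5 cm).  The gap is measured from the disc
# boundary (d - r), and the threshold is inclusive.  A contact whose center
# lies inside a cavity polygon/mask from an earlier surgery is "cavity" and
# records no brain signal, so cavity suppresses resected/edge.
#
# Long-term arm: identical thresholds, with d taken as the distance to the
# voxelized boundary of a 3D resection mask (sign from mask membership).
# ---------------------------------------------------------------------------

#' Photo-plane resection outline
#'
#' @param vertices Two-column matrix (x, y) in mm; the polygon is closed
#'   implicitly and must be simple with at least 3 vertices.
#' @param provenance Photo filename the outline was drawn on.
#' @return Object of class `resection_outline`.
#' @export
resection_outline <- function(vertices, provenance = "") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("a resection outline needs at least 3 vertices")
  if (ncol(vertices) != 2L) stop("vertices must be an n x 2 (x, y) matrix")
  # drop an explicitly repeated closing vertex
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (polygon_self_intersects(vertices)) {
    stop("resection outline is self-intersecting")
  }
  structure(list(vertices = vertices, provenance = provenance),
            class = "resection_outline")
}

# segment-segment proper intersection test over non-adjacent edges
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- function(i) rbind(v[i, ], v[if (i == n) 1 else i + 1, ])
  cross2 <- function(o, a, b) (a[1]-o[1])*(b[2]-o[2]) - (a[2]-o[2])*(b[1]-o[1])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent around the wrap
      s1 <- seg(i); s2 <- seg(j)
      d1 <- cross2(s2[1, ], s2[2, ], s1[1, ]); d2 <- cross2(s2[1, ], s2[2, ], s1[2, ])
      d3 <- cross2(s1[1, ], s1[2, ], s2[1, ]); d4 <- cross2(s1[1, ], s1[2, ], s2[2, ])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Photo-plane electrode plan
#'
#' @param labels Contact labels.
#' @param x,y Contact centers in mm (photo plane after calibration).
#' @param radius Exposed contact radius in mm (default 2, typical clinical
#'   contact); recycled.
#' @param pitch_mm Nominal inter-contact spacing, default 10 mm.
#' @return `data.frame` of class `electrode_plan`.
#' @export
electrode_plan <- function(labels, x, y, radius = 2, pitch_mm = 10) {
  if (anyDuplicated(labels)) stop("contact labels must be unique")
  if (any(radius <= 0)) stop("contact radius must be positive")
  out <- data.frame(label = as.character(labels), x = as.numeric(x),
                    y = as.numeric(y), radius = as.numeric(radius),
                    stringsAsFactors = FALSE)
  attr(out, "pitch_mm") <- pitch_mm
  class(out) <- c("electrode_plan", "data.frame")
  out
}

#' Photo scale calibration
#'
#' The operating-room photo has no intrinsic units; the known inter-contact
#' pitch of the implanted hardware calibrates it.  The scale is
#' `pitch_mm / median(pixel distances)`, robust to individual measurement
#' error.
#'
#' @param pixel_distances Measured pixel distances between adjacent contacts.
#' @param pitch_mm Nominal contact pitch in mm (default 10).
#' @return mm-per-pixel scale factor.
#' @export
calibrate_scale <- function(pixel_distances, pitch_mm = 10) {
  pixel_distances <- as.numeric(pixel_distances)
  if (!length(pixel_distances)) {
    stop("at least one adjacent-contact pixel distance is required")
  }
  if (any(pixel_distances <= 0)) stop("pixel distances must be positive")
  pitch_mm / stats::median(pixel_distances)
}

#' Signed distance from a point to a polygon boundary
#'
#' Magnitude is the Euclidean distance to the nearest boundary segment; the
#' sign is negative iff the point is interior by the even-odd rule.
#'
#' @param x,y Point coordinates in mm (vectorized).
#' @param poly A [resection_outline()].
#' @return Numeric vector of signed distances in mm.
#' @export
signed_distance_2d <- function(x, y, poly) {
  stopifnot(inherits(poly, "resection_outline"))
  v <- poly$vertices
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  vapply(seq_along(x), function(i) {
    px <- x[i]; py <- y[i]
    tt <- ((px - a[, 1]) * ab[, 1] + (py - a[, 2]) * ab[, 2]) / len2
    tt <- pmin(1, pmax(0, tt))
    dx <- a[, 1] + tt * ab[, 1] - px
    dy <- a[, 2] + tt * ab[, 2] - py
    d <- sqrt(min(dx^2 + dy^2))
    if (point_in_polygon(px, py, v)) -d else d
  }, numeric(1))
}

# even-odd ray casting; boundary points count as inside (distance 0 anyway)
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# shared threshold logic, given signed distance d and contact radius r
classify_from_distance <- function(d, r, edge_mm, in_cavity) {
  resected <- !in_cavity & (d < r)
  edge <- !in_cavity &
    ((d > -r & d < r) | (d >= r & (d - r) <= edge_mm))
  data.frame(resected = resected, edge = edge, cavity = in_cavity)
}

#' Classify contacts against a 2D resection outline
#'
#' Applies the photo-plane rule: a disc overlapping the resection interior
#' or boundary is `resected`; a disc partly on top of the boundary or whose
#' gap outside the boundary is at most `edge_mm` is `edge`; a center inside
#' any cavity outline from an earlier surgery is `cavity` (and records no
#' brain signal, so resected/edge are suppressed).
#'
#' @param plan An [electrode_plan()].
#' @param resection A [resection_outline()].
#' @param cavities List of [resection_outline()]s from earlier surgeries.
#' @param edge_mm Edge band width in mm, default 5 (0.5 cm), inclusive.
#' @param photo_bounds Optional `c(xmin, xmax, ymin, ymax)`; contacts outside
#'   are still classified but flagged with a warning.
#' @return `label_set` data.frame: `label`, `resected`, `edge`, `cavity`
#'   (logical).
#' @export
classify_2d <- function(plan, resection, cavities = list(), edge_mm = 5,
                        photo_bounds = NULL) {
  stopifnot(inherits(plan, "electrode_plan"))
  if (!is.null(photo_bounds)) {
    off <- plan$x < photo_bounds[1] | plan$x > photo_bounds[2] |
      plan$y < photo_bounds[3] | plan$y > photo_bounds[4]
    if (any(off)) {
      warning("contacts outside photo bounds: ",
              paste(plan$label[off], collapse = ", "))
    }
  }
  d <- signed_distance_2d(plan$x, plan$y, resection)
  in_cavity <- rep(FALSE, nrow(plan))
  for (cav in cavities) {
    in_cavity <- in_cavity |
      vapply(seq_len(nrow(plan)),
             function(i) point_in_polygon(plan$x[i], plan$y[i], cav$vertices),
             logical(1))
  }
  out <- cbind(data.frame(label = plan$label, stringsAsFactors = FALSE),
               classify_from_distance(d, plan$radius, edge_mm, in_cavity))
  class(out) <- c("label_set", "data.frame")
  out
}

#' 3D resection mask
#'
#' @param voxels 3D logical array (`TRUE` = resected tissue).
#' @param affine 4x4 voxel-to-mm affine (1-based voxel indices map through
#'   `affine %*% c(i-1, j-1, k-1, 1)`).
#' @param cavity_masks List of logical arrays on the same grid marking
#'   cavities from earlier surgeries.
#' @return Object of class `resection_mask`.
#' @export
resection_mask <- function(voxels, affine = diag(4), cavity_masks = list()) {
  stopifnot(length(dim(voxels)) == 3L, is.logical(voxels))
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  structure(list(voxels = voxels, affine = affine, cavity_masks = cavity_masks),
            class = "resection_mask")
}

# mm coordinates of voxel centers where arr is TRUE
voxel_centers_mm <- function(arr, affine) {
  idx <- which(arr, arr.ind = TRUE) - 1  # 0-based
  if (!nrow(idx)) return(matrix(numeric(0), ncol = 3))
  t(affine %*% t(cbind(idx, 1)))[, 1:3, drop = FALSE]
}

# boundary voxels: TRUE voxels with at least one FALSE 6-neighbour (or on the
# array edge)
mask_boundary <- function(arr) {
  d <- dim(arr)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_all <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  inner & !nb_all
}

# point membership: nearest voxel of the grid, FALSE outside the array
point_in_mask <- function(xyz, mask) {
  inv <- solve(mask$affine)
  vox <- t(inv %*% t(cbind(xyz, 1)))[, 1:3, drop = FALSE]
  ijk <- round(vox) + 1  # back to 1-based
  d <- dim(mask$voxels)
  vapply(seq_len(nrow(ijk)), function(r) {
    v <- ijk[r, ]
    if (any(v < 1) || any(v > d)) return(FALSE)
    mask$voxels[v[1], v[2], v[3]]
  }, logical(1))
}

#' Signed distance to the voxelized boundary of a 3D mask
#'
#' Distance of each point to the nearest boundary voxel center of the mask,
#' with negative sign for points whose nearest grid voxel is inside the
#' mask.  Accuracy is limited by voxelization: about one voxel diagonal.
#'
#' @param xyz n x 3 matrix of mm coordinates.
#' @param mask A [resection_mask()].
#' @return Numeric vector of signed distances in mm.
#' @export
signed_distance_3d <- function(xyz, mask) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (!any(mask$voxels)) stop("resection mask is empty")
  bnd <- voxel_centers_mm(mask_boundary(mask$voxels), mask$affine)
  inside <- point_in_mask(xyz, mask)
  vapply(seq_len(nrow(xyz)), function(i) {
    dd <- sqrt(min(colSums((t(bnd) - xyz[i, ])^2)))
    if (inside[i]) -dd else dd
  }, numeric(1))
}

#' Classify contacts against a 3D resection mask
#'
#' Same thresholds as [classify_2d()], with the signed distance taken from
#' the voxelized mask boundary and cavity membership from the mask's
#' `cavity_masks`.
#'
#' @param labels Contact labels.
#' @param xyz n x 3 matrix of contact positions in mm (mask space).
#' @param mask A [resection_mask()].
#' @param radius Contact radius in mm (default 2); recycled.
#' @param edge_mm Edge band width in mm, default 5, inclusive.
#' @return `label_set` data.frame as in [classify_2d()].
#' @export
classify_3d <- function(labels, xyz, mask, radius = 2, edge_mm = 5) {
  stopifnot(inherits(mask, "resection_mask"))
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(labels) != nrow(xyz)) stop("labels and xyz disagree in length")
  radius <- rep_len(radius, length(labels))

  # sanity: contacts far outside the mask grid are suspicious
  corners <- as.matrix(expand.grid(c(0, dim(mask$voxels)[1] - 1),
                                   c(0, dim(mask$voxels)[2] - 1),
                                   c(0, dim(mask$voxels)[3] - 1)))
  box <- t(mask$affine %*% t(cbind(corners, 1)))[, 1:3]
  lo <- apply(box, 2, min) - 50; hi <- apply(box, 2, max) + 50
  far <- apply(xyz, 1, function(p) any(p < lo | p > hi))
  if (any(far)) {
    warning("contacts > 50 mm outside the mask bounding box: ",
            paste(labels[far], collapse = ", "))
  }

  d <- signed_distance_3d(xyz, mask)
  in_cavity <- rep(FALSE, length(labels))
  for (cav in mask$cavity_masks) {
    cm <- resection_mask(cav, mask$affine)
    in_cavity <- in_cavity | point_in_mask(xyz, cm)
  }
  out <- cbind(data.frame(label = as.character(labels), stringsAsFactors = FALSE),
               classify_from_distance(d, radius, edge_mm, in_cavity))
  class(out) <- c("label_set", "data.frame")
  out
}

# -- outline file I/O --------------------------------------------------------

#' Read / write resection outlines as GeoJSON polygons
#'
#' The photo-plane outline interchange format: a GeoJSON `Polygon` feature in
#' mm coordinates, with the source photo filename in the feature properties.
#'
#' @param outline A [resection_outline()].
#' @param path File path.
#' @return `write_outline_geojson()` returns `path` invisibly;
#'   `read_outline_geojson()` returns a [resection_outline()].
#' @export
write_outline_geojson <- function(outline, path) {
  v <- outline$vertices
  ring <- lapply(c(seq_len(nrow(v)), 1L), function(i) c(v[i, 1], v[i, 2]))
  obj <- list(type = "Feature",
              properties = list(provenance = outline$provenance),
              geometry = list(type = "Polygon", coordinates = list(ring)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_outline_geojson
#' @export
read_outline_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  stopifnot(identical(obj$geometry$type, "Polygon"))
  ring <- obj$geometry$coordinates[[1]]
  v <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  prov <- obj$properties$provenance
  resection_outline(v, if (is.null(prov)) "" else prov)
}

#' Load a resection mask from NIfTI volumes
#'
#' Reads a boolean resection volume (non-zero = resected) and optional
#' cavity volumes on the same grid into a [resection_mask()], using the
#' image's qform/sform affine.  Requires the `RNifti` package.
#'
#' @param path NIfTI file with the resection volume.
#' @param cavity_paths Optional NIfTI files with earlier-surgery cavities.
#' @return A [resection_mask()].
#' @export
read_mask_nifti <- function(path, cavity_paths = character(0)) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("read_mask_nifti() needs the RNifti package")
  }
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = "matrix")
  vox <- array(as.array(img) != 0, dim = dim(img))
  cavities <- lapply(cavity_paths, function(p) {
    cv <- RNifti::readNifti(p)
    if (!identical(dim(cv), dim(img))) {
      stop("cavity volume ", p, " is not on the resection grid")
    }
    array(as.array(cv) != 0, dim = dim(cv))
  })
  resection_mask(vox, affine, cavity_masks = cavities)
}
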