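#' Names of the 14 3D shape descriptors, in their fixed order
#' @return character vector of length 14.
#' @export
shape_feature_names <- function() c(
  "mesh_volume", "voxel_volume", "surface_area", "surface_volume_ratio",
  "sphericity", "max_3d_diameter", "max_2d_diameter_slice",
  "max_2d_diameter_column", "max_2d_diameter_row",
  "major_axis_length", "minor_axis_length", "least_axis_length",
  "elongation", "flatness"
)

#' Whole-tumor binary mask (labels 1, 2 and 4)
#'
#' @param mask a [segmentation_mask()].
#' @return object of class `binary_mask` with fields `voxels` (logical 3D
#'   array) and `spacing_mm`.
#' @export
whole_tumor_mask <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  vox <- mask$labels %in% c(1L, 2L, 4L)
  dim(vox) <- dim(mask$labels)
  if (!any(vox)) stop2("whole-tumor mask is empty", class = "empty_tumor_error")
  structure(list(voxels = vox, spacing_mm = mask$spacing_mm),
            class = "binary_mask")
}

#' Extract the tumor surface as a closed triangle mesh
#'
#' Iso-surface of the binary mask at level 0.5, after zero-padding by one
#' voxel on every side so single-voxel and boundary-touching masks yield
#' closed meshes. Vertices are in physical mm; every mesh edge is shared
#' by exactly two faces.
#'
#' @param mask a [whole_tumor_mask()] result (class `binary_mask`).
#' @return object of class `tri_mesh` with `vertices` (n x 3, mm) and
#'   `faces` (m x 3 vertex indices, outward orientation).
#' @export
build_surface_mesh <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop2("mask has no voxels", class = "empty_tumor_error")
  d <- dim(mask$voxels)
  f <- array(0, d + 2L)
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask$voxels * 1
  m <- .mc_mesh(as.numeric(f), dim(f), 0.5)
  # padded node (i) corresponds to voxel center (i - 1) in 0-based grid units
  v <- sweep(m$vertices, 2, 1)
  v <- sweep(v, 2, mask$spacing_mm, "*")
  structure(list(vertices = v, faces = m$faces,
                 spacing_mm = mask$spacing_mm),
            class = "tri_mesh")
}

#' Check mesh closedness (every edge shared by exactly two faces)
#' @param mesh a `tri_mesh`.
#' @return logical scalar.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(tabulate(match(key, unique(key))) == 2L)
}

#' Mesh-based measures: volume, area, their ratio, sphericity
#'
#' Volume is the absolute signed-tetrahedron sum over faces,
#' `|sum_f (1/6) a . (b x c)|`; area the summed triangle areas;
#' sphericity `(36 pi V^2)^(1/3) / A`.
#'
#' @param mesh a closed `tri_mesh`.
#' @return named numeric: mesh_volume (mm^3), surface_area (mm^2),
#'   surface_volume_ratio (1/mm), sphericity.
#' @export
mesh_measures <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  A <- V[Fc[, 1], , drop = FALSE]
  B <- V[Fc[, 2], , drop = FALSE]
  C <- V[Fc[, 3], , drop = FALSE]
  crBC <- cbind(B[, 2] * C[, 3] - B[, 3] * C[, 2],
                B[, 3] * C[, 1] - B[, 1] * C[, 3],
                B[, 1] * C[, 2] - B[, 2] * C[, 1])
  vol <- abs(sum(A * crBC) / 6)
  e1 <- B - A; e2 <- C - A
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  if (vol <= .Machine$double.eps * area)
    stop2("degenerate mesh with zero enclosed volume",
          class = "degenerate_mesh_error")
  c(mesh_volume = vol, surface_area = area,
    surface_volume_ratio = area / vol,
    sphericity = (36 * pi * vol^2)^(1 / 3) / area)
}

#' Maximum 3D and in-plane 2D diameters over mesh vertices
#'
#' The 3D diameter is the largest pairwise Euclidean vertex distance; each
#' 2D variant restricts the pairs to vertices whose coordinate along the
#' axis perpendicular to the named plane agrees within half a voxel
#' (slice: axial plane, perpendicular to the third axis; column:
#' perpendicular to the first axis; row: perpendicular to the second).
#' Exact O(n^2) search.
#'
#' @param mesh a `tri_mesh`.
#' @return named numeric: max_3d_diameter, max_2d_diameter_slice,
#'   max_2d_diameter_column, max_2d_diameter_row (mm).
#' @export
diameter_features <- function(mesh) {
  d <- .mc_diameters(mesh$vertices, mesh$spacing_mm / 2)
  c(max_3d_diameter = d[1], max_2d_diameter_slice = d[2],
    max_2d_diameter_column = d[3], max_2d_diameter_row = d[4])
}

#' Principal-axis lengths, elongation and flatness
#'
#' Eigen-decomposition of the population covariance of physical
#' voxel-center coordinates; axis length `4 sqrt(lambda)`, elongation
#' `sqrt(lambda2/lambda1)`, flatness `sqrt(lambda3/lambda1)`. Degenerate
#' masks (single voxel, collinear sets) return 0 for the affected lengths
#' and ratios with a warning.
#'
#' @param mask a `binary_mask`.
#' @return named numeric: major_axis_length, minor_axis_length,
#'   least_axis_length (mm), elongation, flatness.
#' @export
axis_features <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$voxels, arr.ind = TRUE)
  xyz <- sweep(idx - 1, 2, mask$spacing_mm, "*")
  n <- nrow(xyz)
  if (n == 1) {
    warning("single-voxel mask: axis features degenerate, returning zeros")
    return(c(major_axis_length = 0, minor_axis_length = 0,
             least_axis_length = 0, elongation = 0, flatness = 0))
  }
  cv <- cov(xyz) * (n - 1) / n
  lam <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
              decreasing = TRUE)
  tol <- max(lam) * 1e-12
  if (any(lam <= tol))
    warning("degenerate voxel distribution: some axis features are zero")
  lengths <- ifelse(lam > tol, 4 * sqrt(lam), 0)
  elo <- if (lam[1] > tol && lam[2] > tol) sqrt(lam[2] / lam[1]) else 0
  fla <- if (lam[1] > tol && lam[3] > tol) sqrt(lam[3] / lam[1]) else 0
  c(major_axis_length = lengths[1], minor_axis_length = lengths[2],
    least_axis_length = lengths[3], elongation = elo, flatness = fla)
}

#' The 14-descriptor shape feature vector of a tumor segmentation
#'
#' Computes, on the whole tumor (labels 1+2+4): mesh volume, voxel volume
#' (true-voxel count times voxel volume), surface area, surface/volume
#' ratio, sphericity, maximum 3D diameter, the three in-plane maximum 2D
#' diameters, the three principal axis lengths, elongation and flatness —
#' exactly 14 values in the order of [shape_feature_names()].
#'
#' @param mask a [segmentation_mask()] (or an already-built
#'   `binary_mask`).
#' @return named numeric vector of length 14, class `shape_features`.
#' @export
extract_shape_features <- function(mask) {
  bin <- if (inherits(mask, "binary_mask")) mask else whole_tumor_mask(mask)
  mesh <- build_surface_mesh(bin)
  mm <- mesh_measures(mesh)
  dm <- diameter_features(mesh)
  ax <- axis_features(bin)
  out <- c(
    mesh_volume = unname(mm["mesh_volume"]),
    voxel_volume = sum(bin$voxels) * prod(bin$spacing_mm),
    surface_area = unname(mm["surface_area"]),
    surface_volume_ratio = unname(mm["surface_volume_ratio"]),
    sphericity = unname(mm["sphericity"]),
    max_3d_diameter = unname(dm["max_3d_diameter"]),
    max_2d_diameter_slice = unname(dm["max_2d_diameter_slice"]),
    max_2d_diameter_column = unname(dm["max_2d_diameter_column"]),
    max_2d_diameter_row = unname(dm["max_2d_diameter_row"]),
    major_axis_length = unname(ax["major_axis_length"]),
    minor_axis_length = unname(ax["minor_axis_length"]),
    least_axis_length = unname(ax["least_axis_length"]),
    elongation = unname(ax["elongation"]),
    flatness = unname(ax["flatness"])
  )
  structure(out[shape_feature_names()], class = c("shape_features", "numeric"))
}

#' Shape feature table for a cohort
#'
#' @param manifest cohort manifest data.frame; when the path columns are
#'   NA, `patients` must supply in-memory `synthetic_patient` objects.
#' @param patients optional list of `synthetic_patient` objects matching
#'   the manifest rows.
#' @return data.frame with patient_id and the 14 feature columns.
#' @export
shape_feature_table <- function(manifest, patients = NULL) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    mask <- if (!is.null(patients)) patients[[i]]$mask
            else read_patient(manifest[i, ])$mask
    extract_shape_features(mask)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(patient_id = manifest$patient_id, out)
}
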