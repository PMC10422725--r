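#' CEJ cutting plane from landmarks
#'
#' The cervical cutting plane contains the buccal and lingual
#' cementoenamel-junction landmarks (CEJB, CEJL). Two points underdetermine
#' a plane; the third constraint makes the plane parallel to the
#' mesio-distal direction: its normal is the component of the tooth long
#' axis (cusp centroid towards apex centroid, pointing occlusally)
#' orthogonal to the CEJB-CEJL line. This reproduces a near-transverse
#' cervical cut. "Above" the plane is the occlusal (crown) side.
#'
#' @param landmarks named list of 3D points containing `CEJB`, `CEJL`, at
#'   least one `cusp_*` and at least one `apex*` landmark.
#' @return `rm_plane` whose normal points occlusally.
#' @export
cej_plane <- function(landmarks) {
  need <- c("CEJB", "CEJL")
  if (!all(need %in% names(landmarks)))
    stop("landmarks must contain CEJB and CEJL")
  cejb <- as.numeric(landmarks$CEJB)
  cejl <- as.numeric(landmarks$CEJL)
  if (sqrt(sum((cejb - cejl)^2)) < 1e-6)
    stop("CEJB and CEJL coincide; cutting plane undefined")
  cusps <- landmarks[grep("^cusp", names(landmarks))]
  apices <- landmarks[grep("^apex", names(landmarks))]
  if (!length(cusps) || !length(apices))
    stop("landmarks must contain cusp and apex points to orient the plane")
  axis <- colMeans(do.call(rbind, cusps)) - colMeans(do.call(rbind, apices))
  axis <- axis / sqrt(sum(axis^2))
  u <- (cejb - cejl); u <- u / sqrt(sum(u^2))
  n <- axis - sum(axis * u) * u
  if (sqrt(sum(n^2)) < 1e-9)
    stop("tooth axis is parallel to the CEJ line; plane undefined")
  new_plane((cejb + cejl) / 2, n / sqrt(sum(n^2)))
}

#' Root length from cusp tip to apex
#'
#' Euclidean distance from the root's assigned cusp tip landmark to the
#' most apical point of that root: molar mesiobuccal root from the MB
#' cusp, distobuccal from DB, palatal from ML; premolar roots from the
#' buccal cusp. By default the apex is re-detected as the mesh vertex of
#' the root's region (vertices nearest that root's apex landmark) farthest
#' along the apical direction; `mode = "landmark"` uses the apex landmark
#' itself.
#'
#' @param landmarks named landmark list (needs the cusp, and apex
#'   landmarks of every root for region assignment).
#' @param mesh the tooth or root `rm_mesh` in the same frame.
#' @param root root label: `"P1"`, `"P2"`, `"M1m"`, `"M1d"`, `"M1p"`.
#' @param mode `"vertex"` (re-detected most apical surface point, default)
#'   or `"landmark"`.
#' @return length in mm.
#' @export
root_length <- function(landmarks, mesh, root, mode = c("vertex", "landmark")) {
  mode <- match.arg(mode)
  cusp_name <- cusp_for_root(root)
  apex_name <- apex_for_root(root)
  if (!cusp_name %in% names(landmarks))
    stop("missing cusp landmark ", cusp_name, " for root ", root)
  if (!apex_name %in% names(landmarks))
    stop("missing apex landmark ", apex_name, " for root ", root)
  cusp <- as.numeric(landmarks[[cusp_name]])
  if (mode == "landmark")
    return(sqrt(sum((cusp - as.numeric(landmarks[[apex_name]]))^2)))
  apices <- landmarks[grep("^apex", names(landmarks))]
  A <- do.call(rbind, apices)
  V <- mesh$vertices
  # region: vertices whose nearest apex landmark is this root's apex
  d2 <- vapply(seq_len(nrow(A)), function(k)
    rowSums(sweep(V, 2, A[k, ])^2), numeric(nrow(V)))
  nearest <- max.col(-d2)
  region <- which(nearest == which(names(apices) == apex_name))
  if (!length(region))
    return(sqrt(sum((cusp - as.numeric(landmarks[[apex_name]]))^2)))
  # apical direction of this root: cusp towards its apex landmark
  axis <- as.numeric(landmarks[[apex_name]]) - cusp
  axis <- axis / sqrt(sum(axis^2))
  proj <- drop(V[region, , drop = FALSE] %*% axis)
  apex <- V[region[which.max(proj)], ]
  sqrt(sum((cusp - apex)^2))
}

#' Build the radicular template (CEJ cut of the T0 model)
#'
#' Duplicates the T0 tooth model and cuts it at the CEJ plane, keeping the
#' apical side, capped; this root-only template defines the level at which
#' both timepoints are subsequently cut.
#'
#' @param t0_mesh watertight T0 tooth `rm_mesh`.
#' @param landmarks T0 landmark set (CEJB, CEJL, cusps, apices).
#' @return list with `template` (watertight root `rm_mesh`) and `plane`
#'   (the CEJ `rm_plane`).
#' @export
build_radicular_template <- function(t0_mesh, landmarks) {
  plane <- cej_plane(landmarks)
  template <- cut_mesh(t0_mesh, plane, keep = "below", cap = TRUE)
  if (nrow(template$faces) == 0L)
    stop("CEJ plane does not intersect the tooth model")
  template$provenance <- paste(t0_mesh$provenance, "radicular template")
  list(template = template, plane = plane)
}

#' Cut both timepoints at the same cervical level
#'
#' With T1 already registered onto T0, both models are cut by the single
#' template plane (the lower surface of the radicular template is that
#' plane), apical sides kept and capped, yielding the final T0/T1
#' radicular models.
#'
#' @param t0_mesh T0 tooth model.
#' @param t1_registered_mesh T1 model after registration into the T0
#'   frame.
#' @param template_plane the CEJ `rm_plane` from
#'   [build_radicular_template()].
#' @return list with `t0_root`, `t1_root` (watertight `rm_mesh`).
#' @export
cut_roots_synchronized <- function(t0_mesh, t1_registered_mesh, template_plane) {
  t0_root <- cut_mesh(t0_mesh, template_plane, keep = "below", cap = TRUE)
  t1_root <- cut_mesh(t1_registered_mesh, template_plane, keep = "below", cap = TRUE)
  if (nrow(t0_root$faces) == 0L || nrow(t1_root$faces) == 0L)
    stop("cutting plane misses one of the models")
  list(t0_root = t0_root, t1_root = t1_root)
}

#' Radicular volume change between timepoints
#'
#' @param t0_root,t1_root watertight radicular `rm_mesh` models.
#' @param tooth_id optional identifier carried into the record.
#' @return list of class `rm_volume_change`: `v_t0`, `v_t1`, `delta_v`
#'   (mm^3) and `delta_v_pct` = 100 (v_t0 - v_t1) / v_t0.
#' @export
volume_change <- function(t0_root, t1_root, tooth_id = NA_character_) {
  v0 <- mesh_volume(t0_root)
  v1 <- mesh_volume(t1_root)
  if (v0 <= 0 || v1 <= 0) stop("root volumes must be positive")
  structure(list(tooth_id = tooth_id, v_t0 = v0, v_t1 = v1,
                 delta_v = v0 - v1, delta_v_pct = 100 * (v0 - v1) / v0),
            class = "rm_volume_change")
}

#' Signed surface deviation analysis
#'
#' For every vertex of the T0 radicular shell, the distance to the nearest
#' point on the registered T1 surface, signed negative where the T1
#' surface lies inside the T0 surface (material loss) and positive where
#' it lies outside (gain). The sign is decided by a generalized
#' winding-number inside/outside test of the T0 vertex against the closed
#' T1 shell. The matching percentage is the share of samples with
#' `|d| <= tolerance`.
#'
#' @param t0_root reference radicular `rm_mesh` (all vertices sampled).
#' @param t1_root registered T1 radicular `rm_mesh` (closed).
#' @param tolerance tolerance band, mm (default 0.3, the scan voxel size).
#' @return object of class `rm_deviation`: `points` (sample points),
#'   `distance` (signed mm), `tolerance`, `matching_pct`.
#' @export
deviation_analysis <- function(t0_root, t1_root, tolerance = 0.3) {
  if (nrow(t0_root$faces) == 0L || nrow(t1_root$faces) == 0L)
    stop("deviation analysis needs non-empty meshes")
  P <- t0_root$vertices
  cp <- closest_point_on_mesh(P, t1_root)
  w <- winding_number(P, t1_root)
  sgn <- ifelse(w > 0.5, 1, -1)       # inside T1 => local gain
  d <- sgn * cp$distance
  structure(list(points = P, distance = d, tolerance = tolerance,
                 matching_pct = 100 * mean(abs(d) <= tolerance)),
            class = "rm_deviation")
}

#' @export
print.rm_deviation <- function(x, ...) {
  cat(sprintf(
    "rm_deviation: %d samples, mean %.3f mm, range [%.3f, %.3f] mm, matching %.1f%% (tol %.2f mm)\n",
    length(x$distance), mean(x$distance), min(x$distance), max(x$distance),
    x$matching_pct, x$tolerance))
  invisible(x)
}

#' Deviation color map
#'
#' Standard deviation-analysis colouring: green inside the tolerance band,
#' ramp to saturated blue for negative deviations (material loss) and to
#' saturated red for positive ones, clamped at `range`.
#'
#' @param field an `rm_deviation`, or a numeric vector of signed
#'   distances.
#' @param tolerance tolerance band mm (taken from the field if given).
#' @param range clamp range mm.
#' @return integer matrix n x 3 of RGB values in 0..255.
#' @export
deviation_colormap <- function(field, tolerance = 0.3, range = 0.5) {
  d <- if (inherits(field, "rm_deviation")) field$distance else as.numeric(field)
  if (inherits(field, "rm_deviation")) tolerance <- field$tolerance
  if (range <= tolerance) range <- tolerance * (5 / 3)
  n <- length(d)
  rgb <- matrix(0L, n, 3)
  inband <- abs(d) <= tolerance
  rgb[inband, ] <- matrix(rep(c(0L, 200L, 0L), each = sum(inband)), ncol = 3)
  neg <- d < -tolerance
  if (any(neg)) {
    f <- pmin(1, (-d[neg] - tolerance) / (range - tolerance))
    rgb[neg, 1] <- 0L
    rgb[neg, 2] <- as.integer(round(200 * (1 - f)))
    rgb[neg, 3] <- as.integer(round(255 * f))
  }
  pos <- d > tolerance
  if (any(pos)) {
    f <- pmin(1, (d[pos] - tolerance) / (range - tolerance))
    rgb[pos, 1] <- as.integer(round(255 * f))
    rgb[pos, 2] <- as.integer(round(200 * (1 - f)))
    rgb[pos, 3] <- 0L
  }
  rgb
}

#' Sign-convention check for deviation analysis
#'
#' Verifies, per T0 sample, that negative signed distances correspond to
#' the T1 surface lying inside the T0 surface, using an independent
#' ray-free inside test (winding number of the matched T1 closest points
#' with respect to the T0 shell). Intended for tests and audit output.
#'
#' @param t0_root,t1_root registered radicular models.
#' @param tolerance band for "no change" samples excluded from the check.
#' @return list: `agreement` (share of off-band samples whose sign matches
#'   the oracle), `n_checked`.
#' @export
sign_convention_check <- function(t0_root, t1_root, tolerance = 1e-6) {
  dev <- deviation_analysis(t0_root, t1_root, tolerance = 0.3)
  cp <- closest_point_on_mesh(t0_root$vertices, t1_root)
  # oracle: where the T1 closest point lies inside the T0 shell the
  # surface moved inwards there (loss) => negative deviation expected
  w_t1_in_t0 <- winding_number(cp$point, t0_root)
  off <- abs(dev$distance) > tolerance
  # exclude points where the closest T1 point sits essentially on the T0
  # surface (tangential contact)
  ok <- off & (abs(w_t1_in_t0 - 0.5) > 0.25)
  expect_neg <- w_t1_in_t0[ok] > 0.5
  agree <- mean((dev$distance[ok] < 0) == expect_neg)
  list(agreement = agree, n_checked = sum(ok))
}
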