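#' Synthetic tooth template specification
#'
#' Parametric, stylized tooth model used to validate the resorption
#' pipeline against known ground truth. The tooth surface is star-shaped
#' about a centre placed at the furcation: a radial extent function
#' `R(u)` over unit directions `u` combines an ellipsoidal crown/trunk
#' body with one tapered "finger" per root, blended with a power mean, so
#' the sampled surface is watertight by construction. Frame: +z occlusal,
#' -z apical, +x buccal, +y mesial; the cementoenamel junction (CEJ) sits
#' at `z = cej_z`.
#'
#' Dimensions follow typical permanent maxillary tooth anatomy: premolar
#' root length about 13-14 mm, molar roots 12-13 mm, crown heights 7-8 mm,
#' giving radicular volumes of roughly 120 mm^3 (premolars) to 320 mm^3
#' (first molar).
#'
#' @param tooth_class `"P1"`, `"P2"` (premolars, one root) or `"M1"`
#'   (first molar, three roots: mesiobuccal, distobuccal, palatal).
#' @param crown_height mm above the CEJ.
#' @param root_lengths mm per root, measured from the furcation centre to
#'   each apex (defaults per class).
#' @param root_directions unit vectors from the furcation centre to each
#'   apex (rows). Defaults per class.
#' @param root_widths angular half-width (radians) of each root finger.
#' @param body `c(ax, ay, trunk_depth)`: lateral semiaxes of the
#'   crown/trunk ellipsoid (mm) and how far it reaches below the
#'   furcation centre; its vertical extent is derived so the ellipsoid
#'   top coincides with the crown top (`cej_z + crown_height`).
#' @param cej_z height of the CEJ above the furcation centre, mm.
#' @param blend power-mean exponent blending components.
#' @param mesh_resolution target edge length mm (sets the angular grid).
#' @return object of class `rm_tooth_spec`.
#' @export
tooth_template <- function(tooth_class = c("P1", "P2", "M1"),
                           crown_height = NULL, root_lengths = NULL,
                           root_directions = NULL, root_widths = NULL,
                           body = NULL, cej_z = 2.0, blend = 8,
                           mesh_resolution = 1.0) {
  tooth_class <- match.arg(tooth_class)
  def <- switch(tooth_class,
    P1 = list(crown_height = 7.5,
              roots = c("P1"),
              lengths = 14.5,
              dirs = rbind(c(0.12, 0, -1)),
              widths = 0.23,
              body = c(3.8, 4.2, 1.0)),
    P2 = list(crown_height = 7.5,
              roots = c("P2"),
              lengths = 14.0,
              dirs = rbind(c(0.10, 0, -1)),
              widths = 0.245,
              body = c(3.9, 4.3, 1.0)),
    M1 = list(crown_height = 7.0,
              roots = c("M1m", "M1d", "M1p"),
              lengths = c(13.0, 12.5, 13.5),
              dirs = rbind(c(0.38, 0.33, -1), c(0.38, -0.33, -1),
                           c(-0.45, 0.02, -1)),
              widths = c(0.26, 0.25, 0.27),
              body = c(5.2, 5.5, 1.5)))
  n_roots <- length(def$roots)
  if (is.null(crown_height)) crown_height <- def$crown_height
  if (is.null(root_lengths)) root_lengths <- def$lengths
  if (is.null(root_directions)) root_directions <- def$dirs
  if (is.null(root_widths)) root_widths <- def$widths
  if (is.null(body)) body <- def$body
  root_directions <- as.matrix(root_directions)
  root_directions <- root_directions / sqrt(rowSums(root_directions^2))
  if (length(root_lengths) != n_roots || nrow(root_directions) != n_roots)
    stop("root parameter lengths do not match the tooth class root count")
  if (any(root_lengths <= 0)) stop("root lengths must be positive")
  structure(list(tooth_class = tooth_class, n_roots = n_roots,
                 root_labels = def$roots, crown_height = crown_height,
                 root_lengths = root_lengths,
                 root_directions = root_directions,
                 root_widths = rep(root_widths, length.out = n_roots),
                 body = body, cej_z = cej_z, blend = blend,
                 mesh_resolution = mesh_resolution),
            class = "rm_tooth_spec")
}

# Unit direction grid (UV sphere) plus face lattice; root tip directions
# are snapped onto the grid so each apex is an exact mesh vertex.
tooth_grid <- function(spec) {
  # angular step from target edge length at a nominal 8 mm radius
  n_theta <- max(24L, as.integer(round(2 * pi * 8 / spec$mesh_resolution / 4) * 4))
  n_phi <- n_theta
  phi <- seq(0, pi, length.out = n_phi + 1)[2:n_phi]
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[seq_len(n_theta)]
  g <- expand.grid(theta = theta, phi = phi)   # theta fastest
  D <- cbind(sin(g$phi) * cos(g$theta), sin(g$phi) * sin(g$theta), cos(g$phi))
  D <- rbind(c(0, 0, 1), D, c(0, 0, -1))
  # snap nearest grid direction to each root tip direction
  for (k in seq_len(spec$n_roots)) {
    d <- spec$root_directions[k, ]
    i <- which.max(D %*% d)
    D[i, ] <- d
  }
  nv <- nrow(D)
  idx <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- vector("list", 3)
  j <- seq_len(n_theta)
  faces[[1]] <- cbind(1L, idx(1L, j), idx(1L, j + 1L))
  quads <- list()
  for (i in seq_len(n_phi - 2L)) {
    a <- idx(i, j); b <- idx(i, j + 1L); c_ <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    quads[[i]] <- rbind(cbind(a, c_, d), cbind(a, d, b))
  }
  faces[[2]] <- do.call(rbind, quads)
  faces[[3]] <- cbind(nv, idx(n_phi - 1L, j + 1L), idx(n_phi - 1L, j))
  F <- do.call(rbind, faces)
  list(dirs = D, faces = F, n_theta = n_theta, n_phi = n_phi)
}

# Resolve the body ellipsoid (semiaxes + centre height) from the spec:
# top at the crown top, bottom trunk_depth below the furcation centre.
body_geometry <- function(spec) {
  top <- spec$cej_z + spec$crown_height
  az <- (top + spec$body[3]) / 2
  zb <- top - az
  c(spec$body[1], spec$body[2], az, zb)
}

# Radial extent of the offset ellipsoid body along directions D (origin
# must be inside the ellipsoid).
body_radius <- function(D, body) {
  ax <- body[1]; ay <- body[2]; az <- body[3]; zb <- body[4]
  A <- D[, 1]^2 / ax^2 + D[, 2]^2 / ay^2 + D[, 3]^2 / az^2
  B <- D[, 3] * zb / az^2
  C <- zb^2 / az^2 - 1
  (B + sqrt(B^2 - A * C)) / A
}

# Radial extent function of the full tooth (body + root fingers), with
# optional per-root length overrides and apical tip clips (flat
# truncation of a root finger at distance `clip` along its axis, i.e. a
# capped cut of the apex).
tooth_radius <- function(D, spec, root_lengths = NULL, root_clips = NULL) {
  if (is.null(root_lengths)) root_lengths <- spec$root_lengths
  if (is.null(root_clips)) root_clips <- vector("list", spec$n_roots)
  q <- spec$blend
  acc <- body_radius(D, body_geometry(spec))^q
  for (k in seq_len(spec$n_roots)) {
    cosang <- pmin(1, pmax(-1, drop(D %*% spec$root_directions[k, ])))
    ang <- acos(cosang)
    lobe <- root_lengths[k] * exp(-(ang / spec$root_widths[k])^2)
    cl <- root_clips[[k]]
    if (!is.null(cl)) {
      # flat apical facet: half-space (x . m) <= c
      cosm <- drop(D %*% cl$m)
      lim <- ifelse(cosm > 0.2, cl$c / cosm, Inf)
      lobe <- pmin(lobe, lim)
    }
    acc <- acc + lobe^q
  }
  acc^(1 / q)
}

# surface point in direction u (unit), optionally at a given z height
surface_point <- function(u, spec, ...) {
  u <- u / sqrt(sum(u^2))
  drop(u * tooth_radius(matrix(u, 1, 3), spec, ...))
}

# surface point at height z on the meridian theta (buccal theta = 0)
surface_point_at_z <- function(z, theta, spec) {
  f <- function(phi) {
    u <- c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    tooth_radius(matrix(u, 1, 3), spec)[1] * cos(phi) - z
  }
  phi <- stats::uniroot(f, c(1e-3, pi - 1e-3))$root
  u <- c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  drop(u * tooth_radius(matrix(u, 1, 3), spec))
}

#' Generate a synthetic tooth mesh with landmarks
#'
#' Builds the watertight surface mesh of a [tooth_template()] and places
#' the anatomical landmarks the pipeline consumes: cusp tips (MB, DB, ML
#' for the molar; the buccal cusp for premolars), CEJB/CEJL at the CEJ
#' level, one apex per root (exact mesh vertices), and five registration
#' points on the buccal, lingual, mesial, distal and occlusal aspects.
#'
#' @param spec an `rm_tooth_spec`, or a tooth class string.
#' @param seed integer; adds reproducible per-tooth size/shape variation
#'   (about 5% scale, small root length jitter). `NULL` for the nominal
#'   template.
#' @return object of class `rm_tooth`: list with `mesh`, `landmarks`
#'   (named list of 3D points), `spec` (realized), `root_labels`.
#' @export
generate_tooth <- function(spec = tooth_template("P1"), seed = NULL) {
  if (is.character(spec)) spec <- tooth_template(spec)
  stopifnot(inherits(spec, "rm_tooth_spec"))
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    s <- exp(rnorm(1, 0, 0.05))
    spec$root_lengths <- spec$root_lengths * s * exp(rnorm(spec$n_roots, 0, 0.02))
    spec$crown_height <- spec$crown_height * s
    spec$body[1:3] <- spec$body[1:3] * s * exp(rnorm(3, 0, 0.02))
  }
  build_tooth(spec)
}

build_tooth <- function(spec, root_lengths = NULL, root_clips = NULL,
                        provenance = "synthetic tooth") {
  if (is.null(root_lengths)) root_lengths <- spec$root_lengths
  if (is.null(root_clips)) root_clips <- vector("list", spec$n_roots)
  grid <- tooth_grid(spec)
  R <- tooth_radius(grid$dirs, spec, root_lengths = root_lengths,
                    root_clips = root_clips)
  if (any(R <= 0)) stop("internal error: non-positive radial extent")
  V <- grid$dirs * R
  mesh <- mesh3(V, grid$faces, provenance = provenance, clean = FALSE)
  wt <- mesh_is_watertight(mesh)
  if (!wt) stop("internal error: generated tooth mesh is not watertight")
  lm <- tooth_landmarks(spec, root_lengths = root_lengths,
                        root_clips = root_clips)
  structure(list(mesh = mesh, landmarks = lm, spec = spec,
                 root_labels = spec$root_labels,
                 root_lengths = root_lengths, root_clips = root_clips),
            class = "rm_tooth")
}

tooth_landmarks <- function(spec, root_lengths = NULL, root_clips = NULL) {
  if (is.null(root_lengths)) root_lengths <- spec$root_lengths
  if (is.null(root_clips)) root_clips <- vector("list", spec$n_roots)
  lm <- list()
  # cusp tips on the occlusal aspect
  if (spec$tooth_class == "M1") {
    lm$cusp_MB <- surface_point(c(0.45, 0.40, 1), spec)
    lm$cusp_DB <- surface_point(c(0.45, -0.40, 1), spec)
    lm$cusp_ML <- surface_point(c(-0.45, 0.40, 1), spec)
  } else {
    lm$cusp_B <- surface_point(c(0.40, 0, 1), spec)
  }
  lm$CEJB <- surface_point_at_z(spec$cej_z, 0, spec)
  lm$CEJL <- surface_point_at_z(spec$cej_z, pi, spec)
  # apices: exact tip of each root finger
  apex_names <- apex_names_for(spec)
  for (k in seq_len(spec$n_roots)) {
    d <- spec$root_directions[k, ]
    cl <- root_clips[[k]]
    L <- if (is.null(cl)) root_lengths[k] else
      min(root_lengths[k], cl$c / sum(d * cl$m))
    lm[[apex_names[k]]] <- d * L
  }
  # five registration points (mid-crown aspects + occlusal)
  lm$reg_buccal <- surface_point(c(1, 0, 0.45), spec)
  lm$reg_lingual <- surface_point(c(-1, 0, 0.45), spec)
  lm$reg_mesial <- surface_point(c(0, 1, 0.45), spec)
  lm$reg_distal <- surface_point(c(0, -1, 0.45), spec)
  lm$reg_occlusal <- surface_point(c(0, 0, 1), spec)
  lm
}

apex_names_for <- function(spec) {
  if (spec$tooth_class == "M1") c("apex_m", "apex_d", "apex_p") else "apex"
}

cusp_for_root <- function(root_label) {
  switch(root_label,
         M1m = "cusp_MB", M1d = "cusp_DB", M1p = "cusp_ML",
         "cusp_B")
}

apex_for_root <- function(root_label) {
  switch(root_label, M1m = "apex_m", M1d = "apex_d", M1p = "apex_p", "apex")
}

#' @export
print.rm_tooth <- function(x, ...) {
  cat(sprintf("rm_tooth %s: %d root(s), %d vertices\n",
              x$spec$tooth_class, x$spec$n_roots, nrow(x$mesh$vertices)))
  invisible(x)
}
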