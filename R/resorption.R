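#' Resorption specification for a synthetic tooth
#'
#' Describes simulated external root resorption: apical shortening per
#' root (measured as the reduction of the cusp-to-apex distance) and
#' shallow "lacuna" pits on the buccal root surface with Gaussian falloff,
#' optionally scaled so the total radicular volume loss hits a target.
#'
#' @param truncation named numeric, mm of cusp-apex length reduction per
#'   root label (negative values lengthen the root, used for the control
#'   arch where apparent gain is possible).
#' @param lacunae list of sites, each `list(point, radius, depth)`:
#'   `point` a 3D surface point at the pit centre, `radius` the pit
#'   radius in mm (Gaussian falloff), `depth` the maximum inward
#'   displacement along the surface normal in mm. `NULL` uses
#'   [default_lacuna_sites()] when a volume target is set.
#' @param target_volume_loss optional total volume loss mm^3; lacuna
#'   depths are scaled (signed) so the whole-tooth volume change matches.
#' @return object of class `rm_resorption_spec`.
#' @export
resorption_spec <- function(truncation = numeric(0), lacunae = NULL,
                            target_volume_loss = NULL) {
  structure(list(truncation = truncation, lacunae = lacunae,
                 target_volume_loss = target_volume_loss),
            class = "rm_resorption_spec")
}

#' Default lacuna sites on the buccal root surfaces
#'
#' Two pits per buccal-facing root, on its buccal flank at mid-root and in
#' the apical third, matching the clinically reported localization of
#' resorption (apical, bucco-apical and bucco-medial areas). The palatal
#' molar root receives no lacuna (its simulated change is apical only).
#'
#' @param tooth an `rm_tooth` (or `rm_tooth_spec`).
#' @param radius pit radius mm (Gaussian falloff scale).
#' @param depth nominal pit depth mm (rescaled when a volume target is
#'   set).
#' @return list of lacuna sites (`point`, `radius`, `depth`).
#' @export
default_lacuna_sites <- function(tooth, radius = 2.0, depth = 1.0) {
  spec <- if (inherits(tooth, "rm_tooth")) tooth$spec else tooth
  stopifnot(inherits(spec, "rm_tooth_spec"))
  sites <- list()
  for (k in seq_len(spec$n_roots)) {
    d <- spec$root_directions[k, ]
    if (d[1] < -0.2) next            # skip the palatal root
    for (f in c(0.45, 0.75)) {
      q <- f * spec$root_lengths[k] * d + c(2.0, 0, 0)
      p <- surface_point(q, spec)
      sites[[length(sites) + 1L]] <- list(point = p, radius = radius,
                                          depth = depth)
    }
  }
  sites
}

# shortened root length realizing a cusp-apex distance reduction dlen
shortened_root_length <- function(spec, landmarks, k, dlen) {
  lab <- spec$root_labels[k]
  a <- landmarks[[cusp_for_root(lab)]]
  d <- spec$root_directions[k, ]
  L <- spec$root_lengths[k]
  m <- sqrt(sum((a - L * d)^2)) - dlen
  if (m <= 0) stop("truncation exceeds root length for root ", lab)
  ad <- sum(a * d)
  disc <- ad^2 - sum(a^2) + m^2
  if (disc < 0) stop("truncation exceeds root length for root ", lab)
  roots <- ad + c(-1, 1) * sqrt(disc)
  Lp <- roots[which.min(abs(roots - L))]
  if (Lp <= 0.5) stop("truncation exceeds root length for root ", lab)
  Lp
}

#' Apply simulated resorption to a synthetic tooth
#'
#' Produces the post-treatment (T1) model of a synthetic tooth by
#' re-evaluating its parametric surface with shortened roots and inward
#' Gaussian lacuna displacements, and measures the resulting ground truth
#' from the generated meshes themselves: radicular volumes on both sides
#' of the CEJ plane and cusp-apex lengths per root.
#'
#' @param tooth an `rm_tooth` from [generate_tooth()] (T0, unperturbed
#'   frame).
#' @param resorption an [resorption_spec()].
#' @param volume_tol relative tolerance of the volume-target solve.
#' @return list with `t1` (`rm_tooth`) and `ground_truth`: a list with
#'   `true_dv` (radicular volume loss mm^3), `true_v0_root`,
#'   `true_dv_pct`, `true_dlen` (named per root, mm), `lacuna_sites`.
#' @export
apply_resorption <- function(tooth, resorption = resorption_spec(),
                             volume_tol = 1e-3) {
  stopifnot(inherits(tooth, "rm_tooth"),
            inherits(resorption, "rm_resorption_spec"))
  spec <- tooth$spec
  spec$root_lengths <- tooth$root_lengths
  trunc <- resorption$truncation
  L1 <- spec$root_lengths
  clips <- vector("list", spec$n_roots)
  tip_bulge <- 5e-3                    # mm; see below
  for (k in seq_len(spec$n_roots)) {
    lab <- spec$root_labels[k]
    dl <- if (lab %in% names(trunc)) trunc[[lab]] else 0
    if (dl > 0) {
      # resorption: flat apical facet (capped cut of the tip) oriented
      # perpendicular to the cusp-apex line, so every facet point keeps
      # the same cusp distance; the lateral root surface is untouched
      cusp <- as.numeric(tooth$landmarks[[cusp_for_root(lab)]])
      Lp <- shortened_root_length(spec, tooth$landmarks, k, dl + tip_bulge)
      d <- spec$root_directions[k, ]
      # facet normal along the cusp -> truncated-apex line
      m <- Lp * d - cusp
      m <- m / sqrt(sum(m^2))
      clips[[k]] <- list(m = m, c = Lp * sum(d * m))
    } else if (dl < 0) {
      # apparent growth (control teeth): lengthen the root finger
      L1[k] <- shortened_root_length(spec, tooth$landmarks, k, dl)
    }
  }
  sites <- resorption$lacunae
  target <- resorption$target_volume_loss
  if (is.null(sites) && !is.null(target))
    sites <- default_lacuna_sites(tooth)
  plane <- cej_plane(tooth$landmarks)
  v0r <- mesh_volume(cut_mesh(tooth$mesh, plane, keep = "below", cap = TRUE))

  t1 <- build_tooth(spec, root_lengths = L1, root_clips = clips,
                    provenance = paste(tooth$mesh$provenance, "T1"))
  # a tiny outward bulge at the exact apex vertex of each truncated root
  # keeps apex re-detection deterministic on the flat facet and realizes
  # the configured cusp-apex length exactly
  for (k in seq_len(spec$n_roots)) {
    if (is.null(clips[[k]])) next
    d <- spec$root_directions[k, ]
    Vn <- t1$mesh$vertices / sqrt(rowSums(t1$mesh$vertices^2))
    idx <- which.max(drop(Vn %*% d))
    t1$mesh$vertices[idx, ] <- t1$mesh$vertices[idx, ] +
      tip_bulge * clips[[k]]$m
    t1$landmarks[[apex_for_root(spec$root_labels[k])]] <-
      t1$mesh$vertices[idx, ]
  }
  scale <- if (is.null(target)) 1 else 0
  if (length(sites)) {
    V1 <- t1$mesh$vertices
    N <- mesh_vertex_normals(t1$mesh)
    W <- rowSums(vapply(sites, function(s) {
      d2 <- rowSums(sweep(V1, 2, as.numeric(s$point))^2)
      s$depth * exp(-d2 / s$radius^2)
    }, numeric(nrow(V1))))
    # mask the pits away from every apex so the apical geometry (and the
    # realized length change) stays exactly as constructed
    for (k in seq_len(spec$n_roots)) {
      a <- as.numeric(t1$landmarks[[apex_for_root(spec$root_labels[k])]])
      d2 <- rowSums(sweep(V1, 2, a)^2)
      W <- W * (1 - exp(-d2 / 1.8^2))
    }
    displaced <- function(s) {
      m <- t1$mesh
      m$vertices <- V1 - (s * W) * N
      m
    }
    if (!is.null(target)) {
      vol_full <- function(s) mesh_volume(displaced(s), check = FALSE)
      v0_full <- mesh_volume(tooth$mesh, check = FALSE)
      hi <- min(4, 1.6 / max(W)); lo <- -hi
      solve_scale <- function(tgt) {
        if (v0_full - vol_full(hi) < tgt)
          stop("volume-loss target unattainable: ", tgt)
        stats::uniroot(function(s) (v0_full - vol_full(s)) - tgt,
                       c(lo, hi), tol = 1e-9)$root
      }
      scale <- solve_scale(target)
      # part of the pit tails can sit occlusally of the (tilted) CEJ
      # plane; re-target once so the radicular loss matches
      m1 <- displaced(scale)
      v1r <- mesh_volume(cut_mesh(m1, plane, keep = "below", cap = TRUE))
      if (abs((v0r - v1r) - target) > max(volume_tol * abs(target), 1e-6)) {
        gap <- (v0_full - vol_full(scale)) - (v0r - v1r)
        scale <- solve_scale(target + gap)
      }
    }
    t1$mesh <- displaced(scale)
  }
  # ground truth measured from the generated meshes
  v1r <- mesh_volume(cut_mesh(t1$mesh, plane, keep = "below", cap = TRUE))
  dlen <- vapply(seq_len(spec$n_roots), function(k) {
    lab <- spec$root_labels[k]
    cusp <- tooth$landmarks[[cusp_for_root(lab)]]
    a0 <- tooth$landmarks[[apex_for_root(lab)]]
    a1 <- t1$landmarks[[apex_for_root(lab)]]
    sqrt(sum((cusp - a0)^2)) - sqrt(sum((cusp - a1)^2))
  }, numeric(1))
  names(dlen) <- spec$root_labels
  gt <- list(true_dv = v0r - v1r, true_v0_root = v0r,
             true_dv_pct = 100 * (v0r - v1r) / v0r,
             true_dlen = dlen,
             lacuna_sites = sites, lacuna_scale = scale)
  list(t1 = t1, ground_truth = gt)
}

#' Apply a random rigid frame perturbation
#'
#' Simulates the independent scanner coordinate frame of the second
#' timepoint: one rigid transform (rotation up to `max_rotation` degrees
#' about a random axis, translation up to `max_translation` mm) applied to
#' both the mesh and the landmarks, returned for recovery testing.
#'
#' @param tooth an `rm_tooth` (or any `rm_mesh`).
#' @param max_rotation maximum rotation, degrees.
#' @param max_translation maximum translation, mm.
#' @param seed integer RNG seed (optional).
#' @return for a tooth: list `tooth`, `transform`; for a mesh: list
#'   `mesh`, `transform`.
#' @export
perturb_frame <- function(tooth, max_rotation = 15, max_translation = 10,
                          seed = NULL) {
  if (max_rotation < 0 || max_translation < 0)
    stop("perturbation bounds must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_rotation)
  tr <- runif(3, -1, 1)
  nt <- sqrt(sum(tr^2))
  if (nt > 0) tr <- tr / nt * runif(1, 0, max_translation)
  tf <- rigid_transform(rotation_about_axis(ax, ang), tr)
  if (inherits(tooth, "rm_tooth")) {
    tooth$mesh <- apply_transform(tooth$mesh, tf)
    tooth$landmarks <- apply_transform(tooth$landmarks, tf)
    list(tooth = tooth, transform = tf)
  } else {
    list(mesh = apply_transform(tooth, tf), transform = tf)
  }
}
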