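#' Closest points on a mesh surface
#'
#' For each query point, the nearest point on the triangle surface of
#' `mesh` (not the nearest vertex), its distance, and the face it lies on.
#'
#' @param points n x 3 matrix (mm).
#' @param mesh target `rm_mesh`.
#' @return list with `point` (n x 3), `distance` (n), `face` (n, 1-based).
#' @export
closest_point_on_mesh <- function(points, mesh) {
  P <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  cpp_closest_point_on_mesh(P, mesh$vertices, mesh$faces)
}

#' Generalized winding number
#'
#' Winding number of query points with respect to a closed mesh: about 1
#' inside, 0 outside. Used for the sign of surface deviations.
#'
#' @param points n x 3 matrix.
#' @param mesh closed `rm_mesh`.
#' @return numeric vector.
#' @export
winding_number <- function(points, mesh) {
  P <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  cpp_winding_number(P, mesh$vertices, mesh$faces)
}

#' Iterative closest point surface registration (best fit)
#'
#' ICP of a source mesh onto a target mesh, starting from an initial
#' transform (typically from [landmark_align()]). Source vertices
#' (subsampled to at most `max_points`) are matched to their nearest
#' points on the target surface; correspondences farther than
#' `max(3 * median distance, reject_floor)` are rejected. The default
#' rigid update minimizes the linearized point-to-plane error of the
#' matched pairs (fast convergence on smooth anatomy, where pure
#' point-to-point updates crawl along tangential sliding directions);
#' `method = "point_to_point"` uses the Kabsch update instead. Iterations
#' stop when the point-to-surface RMS improvement falls below `tol` or
#' `max_iter` is reached; an update that would increase the RMS is
#' discarded, so the reported RMS sequence is non-increasing.
#'
#' @param source `rm_mesh` to be moved (T1 model).
#' @param target reference `rm_mesh` (T0 model).
#' @param init initial `rm_transform` (default identity).
#' @param max_iter maximum iterations.
#' @param tol RMS-change convergence tolerance, mm.
#' @param max_points number of source vertices sampled (deterministic,
#'   evenly spaced).
#' @param reject_floor lower bound of the correspondence rejection radius,
#'   mm; prevents the 3 x median rule degenerating when most
#'   correspondences are exact.
#' @param max_correspondence maximum correspondence distance, mm; if no
#'   pair survives, registration fails with an error carrying the report.
#' @param method update rule: `"point_to_plane"` (default) or
#'   `"point_to_point"`.
#' @param trim fraction of best-matching points over which the monitored
#'   RMS is computed (default 0.5). Judging convergence on a trimmed RMS
#'   keeps locally changed regions (resorption) from dragging the pose:
#'   on the full RMS, a shift towards the defects can masquerade as an
#'   improvement. The default assumes at least half of the surface is
#'   unchanged between timepoints (the crown alone typically is).
#' @return list with `transform` (`rm_transform`, init composed with the
#'   refinement) and `report` (initial_rms, final_rms, iterations,
#'   converged, rms_trace).
#' @export
icp_register <- function(source, target, init = identity_transform(),
                         max_iter = 100, tol = 1e-7, max_points = 2000,
                         reject_floor = 0.005, max_correspondence = Inf,
                         method = c("point_to_plane", "point_to_point"),
                         trim = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(source, "rm_mesh"), inherits(target, "rm_mesh"))
  if (nrow(source$faces) == 0L || nrow(target$faces) == 0L)
    stop("cannot register empty meshes")
  S <- source$vertices
  if (nrow(S) > max_points) {
    idx <- unique(round(seq(1, nrow(S), length.out = max_points)))
    S <- S[idx, , drop = FALSE]
  }
  FN <- face_normals(target)
  trimmed_rms <- function(d) {
    keep <- d <= quantile(d, trim)
    if (!any(keep)) keep <- rep(TRUE, length(d))
    sqrt(mean(d[keep]^2))
  }
  current <- init
  P <- apply_transform(S, current)
  cp <- closest_point_on_mesh(P, target)
  rms <- trimmed_rms(cp$distance)
  initial_rms <- rms
  trace <- rms
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    thr <- min(max(3 * median(cp$distance), reject_floor), max_correspondence)
    ok <- cp$distance <= thr
    if (!any(ok)) {
      report <- list(initial_rms = initial_rms, final_rms = rms,
                     iterations = iter, converged = FALSE, rms_trace = trace)
      stop(structure(class = c("rm_registration_failure", "error", "condition"),
                     list(message = "no correspondences within the rejection radius",
                          call = sys.call(-1), report = report)))
    }
    upd <- if (method == "point_to_plane") {
      point_to_plane_update(P[ok, , drop = FALSE],
                            cp$point[ok, , drop = FALSE],
                            FN[cp$face[ok], , drop = FALSE])
    } else {
      landmark_align(P[ok, , drop = FALSE], cp$point[ok, , drop = FALSE])
    }
    cand <- compose_transform(current, upd)
    P2 <- apply_transform(S, cand)
    cp2 <- closest_point_on_mesh(P2, target)
    rms2 <- trimmed_rms(cp2$distance)
    iter <- iter + 1L
    if (rms2 > rms + 1e-12) {          # reject worsening update
      if (rms2 - rms < tol) converged <- TRUE   # stuck at a fixed point
      break
    }
    improved <- rms - rms2
    current <- cand; P <- P2; cp <- cp2; rms <- rms2
    trace <- c(trace, rms)
    if (improved < tol) { converged <- TRUE; break }
  }
  if (iter == max_iter && !converged) converged <- FALSE
  list(transform = current,
       report = list(initial_rms = initial_rms, final_rms = rms,
                     iterations = iter, converged = converged,
                     rms_trace = trace))
}

# Linearized point-to-plane rigid update: minimize
# sum(((p + w x p + t - q) . n)^2) over rotation vector w and translation
# t, then re-orthonormalize the small rotation.
point_to_plane_update <- function(P, Q, N) {
  r <- rowSums((P - Q) * N)
  A <- cbind(P[, 2] * N[, 3] - P[, 3] * N[, 2],
             P[, 3] * N[, 1] - P[, 1] * N[, 3],
             P[, 1] * N[, 2] - P[, 2] * N[, 1],
             N)
  x <- tryCatch(qr.solve(A, -r), error = function(e) rep(0, 6))
  w <- x[1:3]
  ang <- sqrt(sum(w^2))
  R <- if (ang < 1e-14) diag(3) else
    rotation_about_axis(w / ang, ang * 180 / pi)
  rigid_transform(R, x[4:6])
}
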