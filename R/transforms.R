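#' Rigid transform constructor
#'
#' A proper rigid-body transform `x -> R x + t`. The rotation must be
#' orthonormal with determinant +1 (no reflection, no scaling).
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return object of class `rm_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- as.matrix(rotation)
  t <- as.numeric(translation)
  if (!all(dim(R) == c(3, 3)) || length(t) != 3)
    stop("rotation must be 3x3 and translation length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(R) < 0)
    stop("rotation has negative determinant (reflection)")
  structure(list(rotation = R, translation = t), class = "rm_transform")
}

#' @export
print.rm_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("rm_transform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation angle of a rotation matrix, degrees
#' @param R 3 x 3 rotation matrix.
#' @return angle in degrees in `[0, 180]`.
#' @export
rotation_angle_deg <- function(R) {
  tr <- sum(diag(R))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Rotation matrix about an axis
#' @param axis rotation axis (normalized internally).
#' @param angle_deg rotation angle, degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- as.numeric(axis); u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to points or a mesh
#' @param x an `rm_mesh`, a point matrix (n x 3) or a length-3 point.
#' @param t an `rm_transform`.
#' @return transformed copy of `x`.
#' @export
apply_transform <- function(x, t) {
  stopifnot(inherits(t, "rm_transform"))
  tp <- function(P) {
    P <- if (is.null(dim(P))) matrix(P, ncol = 3) else as.matrix(P)
    sweep(P %*% t(t$rotation), 2, t$translation, "+")
  }
  if (inherits(x, "rm_mesh")) {
    x$vertices <- tp(x$vertices)
    x
  } else if (is.list(x)) {           # landmark set: named list of points
    lapply(x, function(p) drop(tp(p)))
  } else if (is.null(dim(x))) {
    drop(tp(x))
  } else {
    tp(x)
  }
}

#' Compose two rigid transforms (`a` applied first, then `b`)
#' @param a,b `rm_transform` objects.
#' @return `rm_transform` equal to `x -> b(a(x))`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(b$rotation %*% a$rotation,
                  drop(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param t `rm_transform`.
#' @return inverse `rm_transform`.
#' @export
invert_transform <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, drop(-Rt %*% t$translation))
}

#' Identity transform
#' @return `rm_transform`.
#' @export
identity_transform <- function() rigid_transform()

#' Least-squares rigid landmark alignment (Kabsch)
#'
#' Finds the proper rigid transform (rotation + translation, no scaling,
#' no reflection) minimizing the sum of squared distances between matched
#' source and target points. This is the point-based pre-alignment of the
#' registration protocol, typically run on five matched surface landmarks
#' (buccal, palatal/lingual, mesial, distal, occlusal).
#'
#' @param source_points n x 3 matrix (or named list of points), n >= 3.
#' @param target_points matched points, same size/names.
#' @return `rm_transform`; attribute `rms` carries the residual RMS in mm.
#' @export
landmark_align <- function(source_points, target_points) {
  S <- as_point_matrix(source_points)
  T_ <- as_point_matrix(target_points, names_from = source_points)
  if (nrow(S) != nrow(T_)) stop("source and target point counts differ")
  if (nrow(S) < 3) stop("at least 3 matched points are required")
  cs <- colMeans(S); ct <- colMeans(T_)
  S0 <- sweep(S, 2, cs); T0 <- sweep(T_, 2, ct)
  if (svd(S0)$d[2] < 1e-9 * max(1, svd(S0)$d[1]))
    stop("points are collinear: rotation is underdetermined")
  H <- crossprod(S0, T0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - drop(R %*% cs)
  out <- rigid_transform(R, t)
  res <- apply_transform(S, out) - T_
  attr(out, "rms") <- sqrt(mean(rowSums(res^2)))
  out
}

as_point_matrix <- function(x, names_from = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    nm <- if (is.list(names_from)) names(names_from) else names(x)
    if (!is.null(nm) && all(nm %in% names(x))) x <- x[nm]
    do.call(rbind, lapply(x, as.numeric))
  } else {
    as.matrix(x)
  }
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' Row-major 3 x 3 rotation plus translation, the on-disk interchange
#' format used by the pipeline.
#'
#' @param t `rm_transform`.
#' @param path output file.
#' @return `read_transform_json` returns an `rm_transform`.
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(list(rotation = matrix(t$rotation, 3, 3),
                            translation = t$translation),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(unlist(x$rotation), 3, 3), unlist(x$translation))
}
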