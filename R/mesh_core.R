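#' Triangle mesh constructor
#'
#' Builds a triangle surface mesh from a vertex matrix and a face index
#' matrix. Coordinates are millimetres. Faces are 1-based vertex index
#' triples with counter-clockwise winding seen from outside.
#'
#' @param vertices numeric matrix, n x 3 (mm).
#' @param faces integer matrix, m x 3, 1-based indices into `vertices`.
#' @param provenance free-text label (tooth id, timepoint, processing step).
#' @param clean merge coincident vertices and drop degenerate faces
#'   (default TRUE).
#' @param tol vertex merge tolerance in mm.
#' @return an object of class `rm_mesh` with elements `vertices`, `faces`,
#'   `provenance`.
#' @export
mesh3 <- function(vertices, faces, provenance = "", clean = TRUE, tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces,
                      provenance = as.character(provenance)[1]),
                 class = "rm_mesh")
  if (clean) m <- mesh_clean(m, tol = tol)
  m
}

#' @export
print.rm_mesh <- function(x, ...) {
  wt <- tryCatch(mesh_is_watertight(x), error = function(e) NA)
  cat(sprintf("rm_mesh: %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(wt)) ", watertight" else "",
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Merge coincident vertices and drop degenerate faces
#'
#' Vertices within `tol` mm (on a snapped grid) are merged; faces with
#' repeated vertices or area below `area_tol` are removed. Raw STL stores
#' vertices per facet, so merging is required before any watertight
#' analysis.
#'
#' @param mesh an `rm_mesh`.
#' @param tol merge tolerance mm.
#' @param area_tol minimum face area mm^2.
#' @return cleaned `rm_mesh`.
#' @export
mesh_clean <- function(mesh, tol = 1e-6, area_tol = 1e-12) {
  V <- mesh$vertices
  F <- mesh$faces
  if (nrow(V) == 0L || nrow(F) == 0L)
    stop("mesh is empty")
  key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
  first <- !duplicated(key)
  newid <- match(key, key[first])
  V2 <- V[first, , drop = FALSE]
  F2 <- matrix(newid[F], ncol = 3)
  # drop faces with repeated vertices
  ok <- F2[, 1] != F2[, 2] & F2[, 2] != F2[, 3] & F2[, 1] != F2[, 3]
  F2 <- F2[ok, , drop = FALSE]
  if (nrow(F2) > 0L) {
    a <- V2[F2[, 2], ] - V2[F2[, 1], ]
    b <- V2[F2[, 3], ] - V2[F2[, 1], ]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area <- 0.5 * sqrt(rowSums(cr^2))
    F2 <- F2[area > area_tol, , drop = FALSE]
  }
  if (nrow(F2) == 0L) stop("mesh is empty after cleaning")
  used <- sort(unique(as.vector(F2)))
  remap <- integer(nrow(V2)); remap[used] <- seq_along(used)
  mesh$vertices <- V2[used, , drop = FALSE]
  mesh$faces <- matrix(as.integer(remap[F2]), ncol = 3)
  mesh
}

#' Watertightness check
#'
#' A mesh is watertight when every edge is shared by exactly two faces with
#' opposite direction (consistent outward orientation).
#'
#' @param mesh an `rm_mesh`.
#' @return logical; attribute `open_edges` carries the number of offending
#'   (boundary or non-manifold) edges.
#' @export
mesh_is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0L) return(structure(FALSE, open_edges = NA_integer_))
  he_from <- c(F[, 1], F[, 2], F[, 3])
  he_to   <- c(F[, 2], F[, 3], F[, 1])
  dir_key <- paste(he_from, he_to)
  opp_key <- paste(he_to, he_from)
  # every directed edge must be unique and have exactly one opposite partner
  bad <- sum(duplicated(dir_key)) + sum(!(dir_key %in% opp_key))
  structure(bad == 0L, open_edges = as.integer(bad))
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume: the sum of signed tetrahedron volumes of each
#' face against the origin. Positive for consistent outward orientation.
#'
#' @param mesh watertight `rm_mesh`.
#' @param check validate watertightness first (default TRUE).
#' @return volume in mm^3 (signed; negative indicates inward orientation).
#' @export
mesh_volume <- function(mesh, check = TRUE) {
  if (check) {
    wt <- mesh_is_watertight(mesh)
    if (!wt)
      stop(sprintf("mesh is not watertight (%d open/non-manifold edges)",
                   attr(wt, "open_edges")))
  }
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det) / 6
}

#' Per-vertex outward normals (area weighted)
#' @param mesh an `rm_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  N <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    for (j in 1:3) {
      s <- rowsum(fn[, j], F[, k])
      idx <- as.integer(rownames(s))
      N[idx, j] <- N[idx, j] + s
    }
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}

#' Plane through three points
#'
#' Three unordered points do not define a signed normal; when `toward` is
#' given (e.g. the occlusal cusp landmark) the normal is oriented so that
#' side counts as "above".
#'
#' @param p1,p2,p3 3D points (mm).
#' @param toward optional reference point the normal should face.
#' @return object of class `rm_plane` with `point` and unit `normal`.
#' @export
plane_from_points <- function(p1, p2, p3, toward = NULL) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  n <- cross3(p2 - p1, p3 - p1)
  area <- 0.5 * sqrt(sum(n^2))
  if (area <= 1e-9) stop("points are collinear: no unique plane")
  n <- n / sqrt(sum(n^2))
  if (!is.null(toward) && sum((as.numeric(toward) - p1) * n) < 0) n <- -n
  new_plane(p1, n)
}

#' Plane from a point and a normal
#' @param point point on the plane (mm).
#' @param normal plane normal (normalized internally).
#' @return `rm_plane`.
#' @export
new_plane <- function(point, normal) {
  normal <- as.numeric(normal)
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) stop("zero-length plane normal")
  structure(list(point = as.numeric(point), normal = normal / len),
            class = "rm_plane")
}

#' @export
print.rm_plane <- function(x, ...) {
  cat(sprintf("rm_plane: point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed distance of points to a plane
#' @param points n x 3 matrix or length-3 vector.
#' @param plane `rm_plane`.
#' @return numeric vector, positive on the normal side.
#' @export
plane_distance <- function(points, plane) {
  P <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  drop((P - matrix(plane$point, nrow(P), 3, byrow = TRUE)) %*% plane$normal)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Cut a mesh by a plane
#'
#' Splits crossing triangles exactly at the plane and keeps the requested
#' half-space. With `cap = TRUE` every cut boundary loop is triangulated by
#' a fan from its centroid (one fan per loop; multi-rooted teeth cut through
#' the furcation yield several loops), so a watertight input produces a
#' watertight output. Volume is conserved: the two capped halves sum to the
#' original volume.
#'
#' @param mesh watertight `rm_mesh`.
#' @param plane `rm_plane`.
#' @param keep `"above"` (positive normal side) or `"below"`.
#' @param cap triangulate the cut boundary (default TRUE).
#' @return `rm_mesh`; may be empty (0 faces) if the plane misses the mesh,
#'   in which case an `rm_mesh` with zero faces is returned.
#' @export
cut_mesh <- function(mesh, plane, keep = c("above", "below"), cap = TRUE) {
  keep <- match.arg(keep)
  V <- mesh$vertices; F <- mesh$faces
  d <- plane_distance(V, plane)
  if (keep == "below") d <- -d
  scale <- max(abs(range(V))) + 1
  eps <- 1e-9 * scale
  d[abs(d) < eps] <- 0
  inside <- d >= 0
  f_in <- inside[F[, 1]] & inside[F[, 2]] & inside[F[, 3]]
  f_out <- !inside[F[, 1]] & !inside[F[, 2]] & !inside[F[, 3]]
  if (all(f_in))
    return(mesh3(V, F, provenance = mesh$provenance, clean = FALSE))
  if (all(f_out))
    return(structure(list(vertices = matrix(0, 0, 3),
                          faces = matrix(0L, 0, 3),
                          provenance = mesh$provenance), class = "rm_mesh"))
  keep_faces <- F[f_in, , drop = FALSE]
  cross_faces <- which(!f_in & !f_out)

  # split crossing faces by Sutherland-Hodgman clipping against d >= 0
  nv <- nrow(V)
  new_pts <- list(); new_key <- character(0)
  extra_faces <- list()
  get_cut_vertex <- function(i, j) {
    key <- if (i < j) paste(i, j) else paste(j, i)
    hit <- match(key, new_key)
    if (!is.na(hit)) return(nv + hit)
    t <- d[i] / (d[i] - d[j])
    p <- V[i, ] + t * (V[j, ] - V[i, ])
    new_pts[[length(new_pts) + 1L]] <<- p
    new_key[length(new_key) + 1L] <<- key
    nv + length(new_pts)
  }
  for (fi in cross_faces) {
    tri <- F[fi, ]
    poly <- integer(0)
    for (e in 1:3) {
      i <- tri[e]; j <- tri[if (e == 3) 1 else e + 1]
      if (inside[i]) poly <- c(poly, i)
      if (xor(inside[i], inside[j]) && d[i] != 0 && d[j] != 0)
        poly <- c(poly, get_cut_vertex(i, j))
    }
    poly <- poly[c(TRUE, poly[-1] != poly[-length(poly)])]
    if (length(poly) > 1 && poly[1] == poly[length(poly)])
      poly <- poly[-length(poly)]
    if (length(poly) < 3) next
    for (k in 2:(length(poly) - 1))
      extra_faces[[length(extra_faces) + 1L]] <- c(poly[1], poly[k], poly[k + 1])
  }
  V2 <- rbind(V, if (length(new_pts)) do.call(rbind, new_pts))
  F2 <- rbind(keep_faces,
              if (length(extra_faces)) do.call(rbind, extra_faces))
  if (cap) {
    # the cut boundary is exactly the open boundary of the kept surface;
    # capping each directed loop with reversed triangles pairs every open
    # edge and inherits the surface orientation
    be <- boundary_edges(F2)
    loops <- if (nrow(be)) chain_loops_directed(be) else list()
    for (loop in loops) {
      if (length(loop) < 3) next
      centroid <- colMeans(V2[loop, , drop = FALSE])
      V2 <- rbind(V2, centroid)
      ci <- nrow(V2)
      for (e in seq_along(loop)) {
        a <- loop[e]; b <- loop[if (e == length(loop)) 1 else e + 1]
        F2 <- rbind(F2, c(ci, b, a))
      }
    }
  }
  out <- structure(list(vertices = V2, faces = matrix(as.integer(F2), ncol = 3),
                        provenance = mesh$provenance), class = "rm_mesh")
  # merge coincident cut vertices; keep zero-area slivers (watertightness
  # matters more here than sliver hygiene)
  mesh_clean(out, tol = eps, area_tol = 0)
}

# Directed edges of F that lack an opposite partner (open boundary).
boundary_edges <- function(F) {
  from <- c(F[, 1], F[, 2], F[, 3])
  to   <- c(F[, 2], F[, 3], F[, 1])
  dir_key <- paste(from, to)
  opp_key <- paste(to, from)
  open <- !(dir_key %in% opp_key)
  cbind(from[open], to[open])
}

# Chain directed edges (m x 2, from -> to) into closed directed loops.
chain_loops_directed <- function(edges) {
  out_adj <- split(edges[, 2], edges[, 1])
  used <- new.env(hash = TRUE)
  ekey <- function(i, j) paste(i, j)
  loops <- list()
  for (r in seq_len(nrow(edges))) {
    i0 <- edges[r, 1]; j0 <- edges[r, 2]
    if (!is.null(used[[ekey(i0, j0)]])) next
    loop <- i0
    assign(ekey(i0, j0), TRUE, envir = used)
    cur <- j0
    ok <- TRUE
    while (cur != i0) {
      loop <- c(loop, cur)
      nxt <- NA
      for (cand in out_adj[[as.character(cur)]]) {
        if (is.null(used[[ekey(cur, cand)]])) { nxt <- cand; break }
      }
      if (is.na(nxt)) { ok <- FALSE; break }
      assign(ekey(cur, nxt), TRUE, envir = used)
      cur <- nxt
      if (length(loop) > nrow(edges) + 1) { ok <- FALSE; break }
    }
    if (ok) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Axis-aligned box mesh
#' @param min,max opposite corners (mm).
#' @return watertight `rm_mesh` (12 faces).
#' @export
mesh_box <- function(min = c(0, 0, 0), max = c(1, 1, 1)) {
  x <- c(min[1], max[1]); y <- c(min[2], max[2]); z <- c(min[3], max[3])
  V <- as.matrix(expand.grid(x = x, y = y, z = z))
  dimnames(V) <- NULL
  # vertex order: (x,y,z) fastest on x; faces wound outward
  F <- rbind(
    c(1, 5, 7), c(1, 7, 3),   # x = min
    c(2, 4, 8), c(2, 8, 6),   # x = max
    c(1, 2, 6), c(1, 6, 5),   # y = min
    c(3, 8, 4), c(3, 7, 8),   # y = max
    c(1, 3, 4), c(1, 4, 2),   # z = min
    c(5, 6, 8), c(5, 8, 7))   # z = max
  mesh3(V, F, provenance = "box", clean = FALSE)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere.
#'
#' @param radius sphere radius mm.
#' @param subdivisions number of 4-to-1 subdivisions (4 gives 5120 faces).
#' @param center sphere center.
#' @return watertight `rm_mesh`.
#' @export
mesh_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_env <- new.env(hash = TRUE)
    newV <- V
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_env[[key]]
      if (!is.null(hit)) return(hit)
      p <- (newV[i, ] + newV[j, ]) / 2
      newV <<- rbind(newV, p)
      idx <- nrow(newV)
      assign(key, idx, envir = mid_env)
      idx
    }
    newF <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c_ <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    V <- newV; F <- newF
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  V <- sweep(V, 2, center, "+")
  mesh3(V, F, provenance = "icosphere", clean = FALSE)
}
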