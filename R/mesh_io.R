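#' Read a surface mesh from STL or PLY
#'
#' STL is read in both binary and ASCII dialects (auto-detected). PLY is
#' read in the ASCII dialect. Because STL stores vertices per facet, the
#' mesh is cleaned on read: coincident vertices are merged within `tol` mm
#' and degenerate faces dropped. Units are assumed millimetres.
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"`, or `NULL` to infer from the extension.
#' @param tol vertex merge tolerance mm.
#' @return an [mesh3()] object.
#' @export
read_mesh <- function(path, format = NULL, tol = 1e-6) {
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "ply"))
  if (format == "stl") read_stl(path, tol = tol) else read_ply(path, tol = tol)
}

read_stl <- function(path, tol = 1e-6) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80)
  is_ascii <- FALSE
  if (length(header) >= 5 &&
      identical(rawToChar(header[1:5]), "solid")) {
    # could still be binary with a header starting "solid"; check the
    # declared triangle count against the file size
    ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    expected <- 84 + as.numeric(ntri) * 50
    if (length(ntri) == 0 || !is.finite(expected) ||
        abs(file.size(path) - expected) > 1)
      is_ascii <- TRUE
  }
  if (is_ascii) {
    close(con); on.exit()
    return(read_stl_ascii(path, tol = tol))
  }
  seek(con, 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (ntri <= 0) stop("empty or corrupt binary STL: ", path)
  raw <- readBin(con, "raw", n = ntri * 50)
  if (length(raw) < ntri * 50) stop("truncated binary STL: ", path)
  m <- matrix(raw, nrow = 50)
  coords <- readBin(as.vector(m[1:48, ]), "double", size = 4,
                    n = 12 * ntri, endian = "little")
  coords <- matrix(coords, ncol = 12, byrow = TRUE)   # normal + 3 vertices
  V <- rbind(coords[, 4:6, drop = FALSE],
             coords[, 7:9, drop = FALSE],
             coords[, 10:12, drop = FALSE])
  n <- nrow(coords)
  V <- V[as.vector(t(matrix(seq_len(3 * n), ncol = 3))), , drop = FALSE]
  F <- matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)
  mesh3(V, F, provenance = basename(path), clean = TRUE, tol = tol)
}

read_stl_ascii <- function(path, tol = 1e-6) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vx) == 0 || length(vx) %% 3 != 0)
    stop("corrupt ASCII STL (vertex count not a multiple of 3): ", path)
  nums <- lapply(strsplit(trimws(vx), "\\s+"), function(p) as.numeric(p[2:4]))
  V <- do.call(rbind, nums)
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  mesh3(V, F, provenance = basename(path), clean = TRUE, tol = tol)
}

#' Write a surface mesh to STL or PLY
#'
#' Binary STL by default. PLY output is ASCII; when per-vertex `scalars`
#' are supplied (e.g. signed deviations), they are encoded as vertex RGB
#' via [deviation_colormap()] so the file renders as the standard
#' blue/green/red deviation color map.
#'
#' @param mesh an [mesh3()] object.
#' @param path output path.
#' @param format `"stl"`, `"ply"`, or `NULL` to infer from the extension.
#' @param scalars optional per-vertex values (PLY only), one per vertex.
#' @param ascii write ASCII STL instead of binary.
#' @param tolerance,range passed to [deviation_colormap()] when colouring.
#' @return invisibly, the path.
#' @export
write_mesh <- function(mesh, path, format = NULL, scalars = NULL,
                       ascii = FALSE, tolerance = 0.3, range = 0.5) {
  if (nrow(mesh$faces) == 0L) stop("refusing to write an empty mesh")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("stl", "ply"))
  if (!is.null(scalars) && length(scalars) != nrow(mesh$vertices))
    stop("scalars must have one value per vertex")
  if (format == "stl") {
    if (ascii) write_stl_ascii(mesh, path) else write_stl_binary(mesh, path)
  } else {
    write_ply_ascii(mesh, path, scalars = scalars,
                    tolerance = tolerance, range = range)
  }
  invisible(path)
}

face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n / len
}

write_stl_binary <- function(mesh, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write STL: ", path))
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "rootmorph binary STL"))[1:80]
  writeBin(header, con)
  F <- mesh$faces; V <- mesh$vertices
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  N <- face_normals(mesh)
  # facet record: normal, v1, v2, v3 (12 float32) + uint16 attribute
  block <- cbind(N, V[F[, 1], , drop = FALSE], V[F[, 2], , drop = FALSE],
                 V[F[, 3], , drop = FALSE])
  flt <- writeBin(as.vector(t(block)), raw(), size = 4, endian = "little")
  flt <- matrix(flt, nrow = 48)
  rec <- rbind(flt, matrix(as.raw(0), 2, ncol(flt)))
  writeBin(as.vector(rec), con)
}

write_stl_ascii <- function(mesh, path) {
  F <- mesh$faces; V <- mesh$vertices
  N <- face_normals(mesh)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write STL: ", path))
  on.exit(close(con))
  writeLines("solid rootmorph", con)
  for (f in seq_len(nrow(F))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", N[f, 1], N[f, 2], N[f, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      v <- V[F[f, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid rootmorph", con)
}

write_ply_ascii <- function(mesh, path, scalars = NULL,
                            tolerance = 0.3, range = 0.5) {
  V <- mesh$vertices; F <- mesh$faces
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write PLY: ", path))
  on.exit(close(con))
  has_col <- !is.null(scalars)
  hdr <- c("ply", "format ascii 1.0",
           "comment rootmorph deviation export",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z")
  if (has_col)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue", "property float quality")
  hdr <- c(hdr, sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (has_col) {
    rgb <- deviation_colormap(scalars, tolerance = tolerance, range = range)
    writeLines(sprintf("%.9g %.9g %.9g %d %d %d %.9g",
                       V[, 1], V[, 2], V[, 3],
                       rgb[, 1], rgb[, 2], rgb[, 3], scalars), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  }
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}

read_ply <- function(path, tol = 1e-6) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("corrupt PLY (no end_header): ", path)
  hdr <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("corrupt PLY header: ", path)
  body <- lines[(end + 1):length(lines)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- t(vapply(fparts, function(p) as.integer(p[2:4]) + 1L, integer(3)))
  mesh3(V, F, provenance = basename(path), clean = TRUE, tol = tol)
}
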