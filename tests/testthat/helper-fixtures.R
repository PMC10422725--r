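# shared fixtures: all geometry is generated in code at test time

unit_tet_ascii_stl <- function(path) {
  # regular unit-edge tetrahedron is overkill; a corner tetrahedron is the
  # smallest closed mesh
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  lines <- c("solid tet")
  for (i in seq_len(nrow(f))) {
    lines <- c(lines, " facet normal 0 0 0", "  outer loop",
               sprintf("   vertex %g %g %g", v[f[i, ], 1], v[f[i, ], 2],
                       v[f[i, ], 3]),
               "  endloop", " endfacet")
  }
  writeLines(c(lines, "endsolid tet"), path)
  path
}

# a cube mesh stored the way raw STL does: one vertex triple per facet
exploded_cube <- function() {
  m <- mesh_box()
  V <- m$vertices[t(m$faces), ]
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

random_rigid <- function(max_rot = 30, max_trans = 10) {
  rigid_transform(rotation_about_axis(random_unit_vector(),
                                      runif(1, 0, max_rot)),
                  runif(3, -max_trans, max_trans) / sqrt(3))
}

expect_watertight <- function(mesh) {
  expect_true(as.logical(mesh_is_watertight(mesh)))
}
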