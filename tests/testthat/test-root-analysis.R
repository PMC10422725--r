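test_that("root length is the cusp-to-apex distance", {
  # a tiny synthetic 'root': tetrahedron with its apex 20 mm below the cusp
  V <- rbind(c(0.5, 0.5, -19), c(-0.5, 0.5, -19), c(0, -0.5, -19),
             c(0, 0, -20))
  F <- rbind(c(1, 2, 3), c(1, 4, 2), c(2, 4, 3), c(3, 4, 1))
  m <- mesh3(V, F)
  lm <- list(cusp_B = c(0, 0, 0), apex = c(0, 0, -20))
  expect_equal(root_length(lm, m, "P1"), 20)
  expect_equal(root_length(lm, m, "P1", mode = "landmark"), 20)
  expect_error(root_length(list(apex = c(0, 0, -20)), m, "P1"),
               "cusp")
})

test_that("root length is invariant under rigid motion of mesh + landmarks", {
  t <- generate_tooth(tooth_template("M1"), seed = 15)
  set.seed(15)
  tr <- random_rigid()
  l0 <- vapply(c("M1m", "M1d", "M1p"),
               function(r) root_length(t$landmarks, t$mesh, r), numeric(1))
  lm2 <- apply_transform(t$landmarks, tr)
  m2 <- apply_transform(t$mesh, tr)
  l1 <- vapply(c("M1m", "M1d", "M1p"),
               function(r) root_length(lm2, m2, r), numeric(1))
  expect_equal(l0, l1, tolerance = 1e-9)
})

test_that("the radicular template is a capped CEJ cut conserving volume", {
  t <- generate_tooth(tooth_template("P2"), seed = 16)
  tpl <- build_radicular_template(t$mesh, t$landmarks)
  expect_watertight(tpl$template)
  expect_lt(max(abs(plane_distance(rbind(t$landmarks$CEJB,
                                         t$landmarks$CEJL), tpl$plane))),
            1e-9)
  crown <- cut_mesh(t$mesh, tpl$plane, "above", cap = TRUE)
  expect_equal(mesh_volume(tpl$template) + mesh_volume(crown),
               mesh_volume(t$mesh), tolerance = 1e-6)
  # occlusal side is 'above': the cusp centroid has positive distance
  cusps <- do.call(rbind, t$landmarks[grep("^cusp", names(t$landmarks))])
  expect_true(all(plane_distance(cusps, tpl$plane) > 0))
  expect_error(cej_plane(list(CEJB = c(1, 0, 0), CEJL = c(1, 0, 0),
                              cusp_B = c(0, 0, 5), apex = c(0, 0, -10))),
               "coincide")
})

test_that("synchronized cuts of identical models give identical roots", {
  t <- generate_tooth(tooth_template("P1"), seed = 17)
  tpl <- build_radicular_template(t$mesh, t$landmarks)
  roots <- cut_roots_synchronized(t$mesh, t$mesh, tpl$plane)
  expect_equal(mesh_volume(roots$t0_root), mesh_volume(roots$t1_root))
  vc <- volume_change(roots$t0_root, roots$t1_root)
  expect_equal(vc$delta_v, 0, tolerance = 1e-9)
  expect_equal(vc$delta_v_pct, 0, tolerance = 1e-9)
})

test_that("volume change identities hold", {
  a <- mesh_box(c(0, 0, 0), c(10, 5, 2))        # 100 mm^3
  b <- mesh_box(c(0, 0, 0), c(10, 4.6, 2))      # 92 mm^3
  vc <- volume_change(a, b)
  expect_equal(vc$delta_v, 8)
  expect_equal(vc$delta_v_pct, 8)
  expect_equal(vc$v_t0 - vc$v_t1, vc$delta_v)
})

test_that("deviation of identical shells is zero with full matching", {
  r <- build_radicular_template(generate_tooth(tooth_template("P1"),
                                               seed = 18)$mesh,
                                generate_tooth(tooth_template("P1"),
                                               seed = 18)$landmarks)$template
  dev <- deviation_analysis(r, r)
  expect_equal(max(abs(dev$distance)), 0, tolerance = 1e-9)
  expect_equal(dev$matching_pct, 100)
})

test_that("concentric spheres give exact signed distances and matching", {
  outer <- mesh_icosphere(5, 3)
  # radial scaling keeps vertices exactly on the smaller sphere
  shrink <- function(f) {
    m <- outer; m$vertices <- m$vertices * f; m
  }
  d1 <- deviation_analysis(outer, shrink(4.8 / 5), tolerance = 0.3)
  expect_equal(unname(quantile(d1$distance, c(0, 1))), c(-0.2, -0.2),
               tolerance = 1e-6)
  expect_equal(d1$matching_pct, 100)
  d2 <- deviation_analysis(outer, shrink(4.5 / 5), tolerance = 0.3)
  expect_equal(mean(d2$distance), -0.5, tolerance = 1e-6)
  expect_equal(d2$matching_pct, 0)
  # growth is positive
  d3 <- deviation_analysis(outer, shrink(5.2 / 5), tolerance = 0.3)
  expect_gt(min(d3$distance), 0.19)
})

test_that("the sign convention matches an independent inside/outside oracle", {
  outer <- mesh_icosphere(5, 3)
  shrunk <- outer; shrunk$vertices <- outer$vertices * 0.9
  grown <- outer; grown$vertices <- outer$vertices * 1.1
  expect_equal(sign_convention_check(outer, shrunk)$agreement, 1)
  expect_equal(sign_convention_check(outer, grown)$agreement, 1)
  # mixed dilation: stretched along x, shrunk along y
  mixed <- outer; mixed$vertices <- outer$vertices %*% diag(c(1.1, 0.9, 1))
  chk <- sign_convention_check(outer, mixed)
  expect_gt(chk$n_checked, 100)
  expect_gt(chk$agreement, 0.99)
})

test_that("deviation colormap bands and saturation are correct", {
  cm <- deviation_colormap(c(0, 0.29, -0.29, -0.5, 0.5, -1, 1), 0.3, 0.5)
  expect_equal(cm[1, ], c(0, 200, 0))
  expect_equal(cm[2, ], c(0, 200, 0))
  expect_equal(cm[3, ], c(0, 200, 0))
  expect_equal(cm[4, ], c(0, 0, 255))     # saturated blue
  expect_equal(cm[5, ], c(255, 0, 0))     # saturated red
  expect_equal(cm[6, ], cm[4, ])          # clamped
  expect_equal(cm[7, ], cm[5, ])
  ramp <- seq(-0.5, -0.3, length.out = 20)
  blue <- deviation_colormap(ramp, 0.3, 0.5)[, 3]
  expect_true(all(diff(blue) <= 0))       # monotone along the ramp
})

test_that("matching percentage decreases with resorption depth", {
  t0 <- generate_tooth(tooth_template("P1"), seed = 19)
  sites <- default_lacuna_sites(t0)
  match <- vapply(c(0.1, 0.35, 0.7), function(depth) {
    s <- lapply(sites, function(x) { x$depth <- depth; x })
    res <- apply_resorption(t0, resorption_spec(lacunae = s))
    tpl <- build_radicular_template(t0$mesh, t0$landmarks)
    roots <- cut_roots_synchronized(t0$mesh, res$t1$mesh, tpl$plane)
    deviation_analysis(roots$t0_root, roots$t1_root)$matching_pct
  }, numeric(1))
  expect_true(all(diff(match) <= 0))
  expect_lt(match[3], match[1])
})
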