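test_that("generated teeth are watertight with the expected landmarks", {
  m1 <- generate_tooth(tooth_template("M1"), seed = 1)
  expect_watertight(m1$mesh)
  expect_gt(mesh_volume(m1$mesh), 0)
  expect_setequal(grep("^apex", names(m1$landmarks), value = TRUE),
                  c("apex_m", "apex_d", "apex_p"))
  expect_true(all(c("cusp_MB", "cusp_DB", "cusp_ML", "CEJB", "CEJL",
                    "reg_buccal", "reg_lingual", "reg_mesial", "reg_distal",
                    "reg_occlusal") %in% names(m1$landmarks)))
  p1 <- generate_tooth(tooth_template("P1"), seed = 2)
  expect_watertight(p1$mesh)
  expect_true(all(c("cusp_B", "apex") %in% names(p1$landmarks)))
})

test_that("tooth generation is deterministic under a fixed seed", {
  a <- generate_tooth(tooth_template("M1"), seed = 77)
  b <- generate_tooth(tooth_template("M1"), seed = 77)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$landmarks, b$landmarks)
  c_ <- generate_tooth(tooth_template("M1"), seed = 78)
  expect_false(identical(a$mesh$vertices, c_$mesh$vertices))
})

test_that("apex landmarks sit on the mesh and cusp-apex spans are anatomical", {
  t <- generate_tooth(tooth_template("P1"))
  cp <- closest_point_on_mesh(t$landmarks$apex, t$mesh)
  expect_lt(cp$distance, 0.05)
  len <- root_length(t$landmarks, t$mesh, "P1")
  expect_gt(len, 15); expect_lt(len, 26)   # premolar cusp-apex span
})

test_that("pure truncation changes length by construction and little volume", {
  t0 <- generate_tooth(tooth_template("P1"), seed = 10)
  res <- apply_resorption(t0, resorption_spec(truncation = list(P1 = 0.5)))
  gt <- res$ground_truth
  expect_equal(unname(gt$true_dlen["P1"]), 0.5, tolerance = 1e-6)
  expect_gt(gt$true_dv, 0)
  expect_lt(gt$true_dv, 3)
  expect_watertight(res$t1$mesh)
  # and the pipeline's length measurement sees exactly that change
  l0 <- root_length(t0$landmarks, t0$mesh, "P1")
  l1 <- root_length(res$t1$landmarks, res$t1$mesh, "P1")
  expect_equal(l0 - l1, 0.5, tolerance = 2e-3)
})

test_that("no resorption means identical meshes and zero ground truth", {
  t0 <- generate_tooth(tooth_template("P2"), seed = 11)
  res <- apply_resorption(t0, resorption_spec())
  expect_equal(res$t1$mesh$vertices, t0$mesh$vertices, tolerance = 1e-12)
  expect_equal(res$ground_truth$true_dv, 0, tolerance = 1e-9)
  expect_equal(unname(res$ground_truth$true_dlen["P2"]), 0,
               tolerance = 1e-9)
})

test_that("volume targets are achieved and measured truth matches meshes", {
  set.seed(12)
  for (tgt in c(5, 15)) {
    t0 <- generate_tooth(tooth_template("M1"), seed = 100 + tgt)
    res <- apply_resorption(t0, resorption_spec(
      truncation = list(M1m = 0.2, M1d = 0.2, M1p = 0.3),
      target_volume_loss = tgt))
    expect_equal(res$ground_truth$true_dv, tgt, tolerance = 0.05 * tgt)
    # ground truth must equal the mesh-measured radicular difference
    pl <- cej_plane(t0$landmarks)
    v0 <- mesh_volume(cut_mesh(t0$mesh, pl, "below"))
    v1 <- mesh_volume(cut_mesh(res$t1$mesh, pl, "below"))
    expect_equal(res$ground_truth$true_dv, v0 - v1, tolerance = 1e-9)
  }
})

test_that("excessive truncation is rejected", {
  t0 <- generate_tooth(tooth_template("P1"), seed = 13)
  expect_error(apply_resorption(t0, resorption_spec(
    truncation = list(P1 = 40))), "exceeds root length")
})

test_that("frame perturbation is rigid, seeded and bounded", {
  t0 <- generate_tooth(tooth_template("P2"), seed = 14)
  none <- perturb_frame(t0, 0, 0, seed = 1)
  expect_equal(none$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(none$transform$translation, c(0, 0, 0))
  pert <- perturb_frame(t0, 10, 5, seed = 2)
  expect_lte(rotation_angle_deg(pert$transform$rotation), 10)
  expect_lte(sqrt(sum(pert$transform$translation^2)), 5)
  d0 <- dist(do.call(rbind, t0$landmarks))
  d1 <- dist(do.call(rbind, pert$tooth$landmarks))
  expect_equal(as.vector(d0), as.vector(d1), tolerance = 1e-9)
  again <- perturb_frame(t0, 10, 5, seed = 2)
  expect_identical(pert$transform, again$transform)
})

test_that("effect draws reproduce the configured distributions", {
  spec <- cohort_spec(n_per_group = 2)
  set.seed(31)
  draws <- replicate(400, {
    e <- rootmorph:::draw_tooth_effects(spec, "TB", "upper", "M1",
                                        c("M1m", "M1d", "M1p"))
    c(e$dv, e$dlen)
  })
  expect_equal(mean(draws[1, ]), 26.21, tolerance = 26.21 * 0.05)
  expect_equal(sd(draws[1, ]), 10.03, tolerance = 10.03 * 0.12)
  expect_equal(mean(draws[4, ]), 0.56, tolerance = 0.56 * 0.05)
  # volume and length draws correlate through the latent factor
  expect_gt(cor(draws[1, ], draws[4, ]), 0.1)
  # control draws keep their sign (no truncation at zero)
  ctrl <- replicate(400, rootmorph:::draw_tooth_effects(
    spec, "TB", "lower", "P1", "P1")$dv)
  expect_gt(sum(ctrl < 0), 100)
})

test_that("cohort generation writes a complete, reproducible layout", {
  dir1 <- file.path(tempdir(), "cohort_a")
  dir2 <- file.path(tempdir(), "cohort_b")
  unlink(c(dir1, dir2), recursive = TRUE)
  spec <- cohort_spec(n_per_group = 1, classes = c("P1", "M1"))
  gen1 <- generate_cohort(spec, dir1, seed = 5)
  gen2 <- generate_cohort(spec, dir2, seed = 5)
  # 2 patients x 2 arches x 2 classes x 2 sides
  expect_equal(nrow(gen1$manifest), 16)
  stl <- list.files(dir1, pattern = "\\.stl$", recursive = TRUE)
  expect_equal(length(stl), 32)      # T0 + T1 per tooth
  lmk <- list.files(dir1, pattern = "_landmarks\\.json$", recursive = TRUE)
  expect_equal(length(lmk), 32)
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  expect_identical(readLines(file.path(dir1, "roots.csv")),
                   readLines(file.path(dir2, "roots.csv")))
  # ground truth in the manifest is self-consistent
  expect_true(all(abs(gen1$manifest$true_dv_pct -
                        100 * gen1$manifest$true_dv /
                        gen1$manifest$true_v0_root) < 1e-9))
})
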