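test_that("landmark alignment recovers exact correspondences", {
  set.seed(21)
  S <- matrix(rnorm(15, sd = 5), 5)
  t0 <- landmark_align(S, S)
  expect_equal(t0$rotation, diag(3), tolerance = 1e-12)
  expect_lt(attr(t0, "rms"), 1e-12)

  tr <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(1, 2, 3))
  fit <- landmark_align(S, apply_transform(S, tr))
  expect_equal(fit$rotation, tr$rotation, tolerance = 1e-9)
  expect_equal(fit$translation, tr$translation, tolerance = 1e-9)
  expect_lt(attr(fit, "rms"), 1e-9)
})

test_that("landmark alignment never returns a reflection and validates input", {
  set.seed(22)
  for (i in 1:20) {
    S <- matrix(rnorm(15, sd = 3), 5)
    T_ <- S + matrix(rnorm(15, sd = 1), 5)
    fit <- landmark_align(S, T_)
    expect_gt(det(fit$rotation), 0)
  }
  expect_error(landmark_align(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(landmark_align(line, line + 1), "collinear")
})

test_that("jittered five-point alignment stays within 2 degrees", {
  lm <- generate_tooth(tooth_template("P1"))$landmarks
  reg <- do.call(rbind, lm[grep("^reg_", names(lm))])
  set.seed(23)
  errs <- vapply(1:100, function(i) {
    tr <- random_rigid(max_rot = 20, max_trans = 8)
    target <- apply_transform(reg, tr)
    # 0.2 mm RMS positional jitter per landmark
    jit <- reg + matrix(rnorm(length(reg), sd = 0.2 / sqrt(3)), nrow(reg))
    fit <- landmark_align(jit, target)
    rotation_angle_deg(t(tr$rotation) %*% fit$rotation)
  }, numeric(1))
  # manual landmark picking at ~0.2 mm precision on a ~5 mm landmark
  # spread: typically under 2 degrees, occasional configurations above
  expect_lt(median(errs), 2)
  expect_gt(mean(errs < 2), 0.7)
})

test_that("rigid transforms preserve distances, compose and invert", {
  set.seed(24)
  tr <- random_rigid()
  P <- matrix(rnorm(30, sd = 4), 10)
  Q <- apply_transform(P, tr)
  expect_equal(as.vector(dist(P)), as.vector(dist(Q)), tolerance = 1e-9)
  roundtrip <- compose_transform(tr, invert_transform(tr))
  expect_equal(roundtrip$rotation, diag(3), tolerance = 1e-9)
  expect_equal(roundtrip$translation, c(0, 0, 0), tolerance = 1e-9)
  m <- mesh_icosphere(2, 3)
  expect_equal(mesh_volume(apply_transform(m, tr)), mesh_volume(m),
               tolerance = 1e-9)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant|reflection")
})

test_that("transform JSON serialization round-trips", {
  set.seed(25)
  tr <- random_rigid()
  path <- tempfile(fileext = ".json")
  write_transform_json(tr, path)
  back <- read_transform_json(path)
  expect_equal(back$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(back$translation, tr$translation, tolerance = 1e-12)
})

test_that("ICP refines a jittered initialization to exact superimposition", {
  tooth <- generate_tooth(tooth_template("P2"), seed = 5)
  reg <- do.call(rbind,
                 tooth$landmarks[grep("^reg_", names(tooth$landmarks))])
  set.seed(26)
  tr <- random_rigid(max_rot = 25, max_trans = 8)
  moved <- apply_transform(tooth$mesh, tr)
  jit <- apply_transform(reg, tr) + matrix(rnorm(length(reg), sd = 0.2),
                                           nrow(reg))
  init <- landmark_align(reg, jit)   # deliberately imperfect
  fit <- icp_register(tooth$mesh, moved, init = init)
  expect_lt(fit$report$final_rms, 1e-3)
  expect_lt(rotation_angle_deg(t(tr$rotation) %*% fit$transform$rotation),
            0.1)
  expect_lt(sqrt(sum((fit$transform$translation - tr$translation)^2)), 0.01)
  expect_true(fit$report$converged)
  expect_true(all(diff(fit$report$rms_trace) <= 1e-12))
})

test_that("registering a resorbed tooth leaves crown residuals tiny", {
  t0 <- generate_tooth(tooth_template("M1"), seed = 6)
  res <- apply_resorption(t0, resorption_spec(
    truncation = list(M1m = 0.4, M1d = 0.4, M1p = 0.5),
    target_volume_loss = 25))
  pert <- perturb_frame(res$t1, 12, 6, seed = 61)
  rn <- grep("^reg_", names(t0$landmarks), value = TRUE)
  init <- landmark_align(pert$tooth$landmarks[rn], t0$landmarks[rn])
  fit <- icp_register(pert$tooth$mesh, t0$mesh, init = init)
  t1r <- apply_transform(pert$tooth$mesh, fit$transform)
  crown <- t1r$vertices[t1r$vertices[, 3] > t0$spec$cej_z + 1, ]
  cp <- closest_point_on_mesh(crown, t0$mesh)
  expect_lt(sqrt(mean(cp$distance^2)), 0.05)
  expect_gt(fit$report$final_rms, 0)
})

test_that("hopeless initialization either converges or reports failure honestly", {
  m <- generate_tooth(tooth_template("P1"), seed = 9)$mesh
  far <- apply_transform(m, rigid_transform(
    rotation_about_axis(c(1, 0, 0), 170), c(60, 0, 0)))
  out <- tryCatch(icp_register(m, far, max_iter = 20),
                  rm_registration_failure = function(e) e$report)
  if (inherits(out, "list") && !is.null(out$transform)) {
    expect_true(is.logical(out$report$converged))
  } else {
    expect_false(out$converged)
  }
})
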