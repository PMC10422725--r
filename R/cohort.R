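#' Default cohort effect tables
#'
#' Per-group, per-tooth-class distributions (mean, SD) of the simulated
#' longitudinal changes: radicular volume loss (mm^3), cusp-apex length
#' loss per root (mm), and per-patient skeletal (PWE) and dento-alveolar
#' (DAE) expansion changes (mm, negative = wider arch at T1). Test teeth
#' are the upper arch; the lower arch is the near-zero control. Values are
#' the effect sizes of the tooth-borne (TB) versus bone-borne (BB) rapid
#' maxillary expansion comparison this package targets.
#'
#' @return list of three data.frames: `volume`, `length`, `expansion`.
#' @export
default_effect_tables <- function() {
  volume <- rbind(
    data.frame(group = "TB", arch = "upper",
               tooth_class = c("P1", "P2", "M1"),
               mean = c(9.74, 8.23, 26.21), sd = c(3.77, 3.11, 10.03)),
    data.frame(group = "BB", arch = "upper",
               tooth_class = c("P1", "P2", "M1"),
               mean = c(1.45, 1.68, 4.62), sd = c(0.64, 0.53, 3.12)),
    data.frame(group = "TB", arch = "lower",
               tooth_class = c("P1", "P2", "M1"),
               mean = c(-0.25, -0.06, 0.37), sd = c(0.94, 0.76, 1.34)),
    data.frame(group = "BB", arch = "lower",
               tooth_class = c("P1", "P2", "M1"),
               mean = c(-0.12, 0.05, 0.26), sd = c(0.76, 0.41, 1.21)))
  length <- rbind(
    data.frame(group = "TB", arch = "upper",
               root = c("P1", "P2", "M1m", "M1d", "M1p"),
               mean = c(0.51, 0.39, 0.37, 0.43, 0.56),
               sd = c(0.18, 0.14, 0.10, 0.14, 0.19)),
    data.frame(group = "BB", arch = "upper",
               root = c("P1", "P2", "M1m", "M1d", "M1p"),
               mean = c(0.08, 0.11, 0.10, 0.09, 0.15),
               sd = c(0.03, 0.02, 0.04, 0.02, 0.04)),
    # lower-control length changes; the lower M1 palatal entry is a
    # near-zero assumption (not reported for the control arch)
    data.frame(group = "TB", arch = "lower",
               root = c("P1", "P2", "M1m", "M1d", "M1p"),
               mean = c(0.02, -0.06, 0.09, 0.01, 0.02),
               sd = c(0.21, 0.13, 0.48, 0.52, 0.30)),
    data.frame(group = "BB", arch = "lower",
               root = c("P1", "P2", "M1m", "M1d", "M1p"),
               mean = c(-0.05, 0.04, 0.03, 0.04, 0.02),
               sd = c(0.30, 0.11, 0.35, 0.55, 0.30)))
  expansion <- rbind(
    data.frame(group = "TB", level = c("P1", "P2", "M1"), kind = "PWE",
               mean = c(-1.83, -1.60, -1.54), sd = c(0.64, 0.51, 0.48)),
    data.frame(group = "BB", level = c("P1", "P2", "M1"), kind = "PWE",
               mean = c(-2.62, -2.29, -2.22), sd = c(1.22, 1.15, 1.13)),
    data.frame(group = "TB", level = c("P1", "P2", "M1"), kind = "DAE",
               mean = c(-5.04, -4.73, -5.59), sd = c(1.79, 1.81, 1.68)),
    data.frame(group = "BB", level = c("P1", "P2", "M1"), kind = "DAE",
               mean = c(-4.14, -3.99, -4.38), sd = c(1.92, 1.50, 1.57)))
  list(volume = volume, length = length, expansion = expansion)
}

#' Cohort simulation specification
#'
#' @param n_per_group patients per treatment group (TB, BB).
#' @param effects effect tables as in [default_effect_tables()].
#' @param arches arches to simulate (`"upper"` test, `"lower"` control).
#' @param classes tooth classes per arch.
#' @param rho latent correlation between a tooth's volume and length
#'   changes (an assumption; not an observed quantity).
#' @param truncate_at_zero truncate negative test-arch draws at 0 (control
#'   draws keep their sign).
#' @param mesh_resolution target mesh edge length mm.
#' @param max_rotation,max_translation per-timepoint frame perturbation
#'   bounds (degrees, mm).
#' @param p_male probability a simulated patient is male.
#' @param age_mean,age_sd named per-group age distributions (years).
#' @return object of class `rm_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20, effects = default_effect_tables(),
                        arches = c("upper", "lower"),
                        classes = c("P1", "P2", "M1"),
                        rho = 0.5, truncate_at_zero = TRUE,
                        mesh_resolution = 1.0,
                        max_rotation = 10, max_translation = 5,
                        p_male = 0.425,
                        age_mean = c(TB = 13.1, BB = 14.5),
                        age_sd = c(TB = 1.08, BB = 1.11)) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (any(effects$volume$sd < 0) || any(effects$length$sd < 0))
    stop("effect SDs must be non-negative")
  structure(list(n_per_group = n_per_group, effects = effects,
                 arches = match.arg(arches, c("upper", "lower"),
                                    several.ok = TRUE),
                 classes = match.arg(classes, c("P1", "P2", "M1"),
                                     several.ok = TRUE),
                 rho = rho, truncate_at_zero = truncate_at_zero,
                 mesh_resolution = mesh_resolution,
                 max_rotation = max_rotation,
                 max_translation = max_translation,
                 p_male = p_male, age_mean = age_mean, age_sd = age_sd),
            class = "rm_cohort_spec")
}

# deterministic stream of sub-seeds below 2^31
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# baseline arch widths (mm) at T0; typical adolescent maxilla
baseline_widths <- function() {
  list(PW = c(P1 = 26, P2 = 30, M1 = 33),
       DAW = c(P1 = 38, P2 = 44, M1 = 50))
}

#' Generate a synthetic two-group cohort on disk
#'
#' For every patient and tooth, draws the volume and length changes from
#' the group's effect distributions (jointly, with latent correlation
#' `rho`), realizes them as apical truncation plus buccal lacunae on a
#' synthetic tooth, perturbs the T1 coordinate frame, and writes
#' per-tooth T0/T1 STL meshes, landmark JSON files, per-patient arch
#' landmark files and ground-truth manifests.
#'
#' Output layout: `<dir>/<patient>/<class>_<side>_<arch>_<T0|T1>.stl` (+
#' `*_landmarks.json`), `<dir>/<patient>/arch_<T0|T1>.json`,
#' `<dir>/manifest.csv` (per tooth), `<dir>/roots.csv` (per root),
#' `<dir>/patients.csv`.
#'
#' @param spec an [cohort_spec()].
#' @param dir output directory (created).
#' @param seed integer master seed; every per-tooth seed derives from it.
#' @return invisibly, a list with `manifest`, `roots`, `patients`, `dir`.
#' @export
generate_cohort <- function(spec = cohort_spec(), dir, seed = 1) {
  stopifnot(inherits(spec, "rm_cohort_spec"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  n_pat <- 2L * spec$n_per_group
  n_teeth_per_pat <- length(spec$arches) * length(spec$classes) * 2L
  seeds <- derive_seeds(seed, n_pat * (n_teeth_per_pat + 1L))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }
  manifest <- list(); roots <- list(); patients <- list()
  bw <- baseline_widths()
  for (p in seq_len(n_pat)) {
    group <- if (p <= spec$n_per_group) "TB" else "BB"
    pid <- sprintf("pt%03d", p)
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    set.seed(next_seed())
    gender <- if (runif(1) < spec$p_male) "M" else "F"
    age <- rnorm(1, spec$age_mean[[group]], spec$age_sd[[group]])
    # arch landmarks: symmetric pairs, T1 widened by the drawn expansion
    exp_tab <- spec$effects$expansion
    arch0 <- list(); arch1 <- list()
    exp_draws <- list()
    for (lv in c("P1", "P2", "M1")) {
      y <- c(P1 = 8, P2 = 16, M1 = 24)[[lv]]
      for (kind in c("PW", "DAW")) {
        kk <- if (kind == "PW") "PWE" else "DAE"
        row <- exp_tab[exp_tab$group == group & exp_tab$level == lv &
                         exp_tab$kind == kk, ]
        change <- rnorm(1, row$mean, row$sd)
        w0 <- bw[[kind]][[lv]] + rnorm(1, 0, 1.5)
        w1 <- w0 - change
        z <- if (kind == "PW") 12 else 2
        arch0[[paste(kind, lv, "L", sep = "_")]] <- c(-w0 / 2, y, z)
        arch0[[paste(kind, lv, "R", sep = "_")]] <- c(w0 / 2, y, z)
        arch1[[paste(kind, lv, "L", sep = "_")]] <- c(-w1 / 2, y, z)
        arch1[[paste(kind, lv, "R", sep = "_")]] <- c(w1 / 2, y, z)
        exp_draws[[paste(kk, lv, sep = "_")]] <- change
      }
    }
    write_landmarks_json(arch0, file.path(pdir, "arch_T0.json"))
    write_landmarks_json(arch1, file.path(pdir, "arch_T1.json"))
    patients[[p]] <- data.frame(patient = pid, group = group,
                                gender = gender, age = age,
                                as.list(unlist(exp_draws)))
    for (arch in spec$arches) for (cls in spec$classes) for (side in c("L", "R")) {
      tooth_seed <- next_seed()
      rec <- simulate_tooth_pair(spec, group, arch, cls, side, pid, pdir,
                                 tooth_seed)
      manifest[[length(manifest) + 1L]] <- rec$tooth
      roots[[length(roots) + 1L]] <- rec$roots
    }
  }
  manifest <- do.call(rbind, manifest)
  roots <- do.call(rbind, roots)
  patients <- do.call(rbind, patients)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(roots, file.path(dir, "roots.csv"), row.names = FALSE)
  write.csv(patients, file.path(dir, "patients.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, roots = roots, patients = patients,
                 dir = dir))
}

# one joint draw of (volume loss, per-root length loss) for a tooth;
# latent factor gives correlation rho between the quantities
draw_tooth_effects <- function(spec, group, arch, cls, root_labels) {
  vt <- spec$effects$volume
  lt <- spec$effects$length
  vrow <- vt[vt$group == group & vt$arch == arch & vt$tooth_class == cls, ]
  z <- rnorm(1)                        # latent per-tooth severity
  mix <- function(mu, sd) mu + sd * (spec$rho * z +
                                     sqrt(1 - spec$rho^2) * rnorm(1))
  dv <- mix(vrow$mean, vrow$sd)
  dlen <- vapply(root_labels, function(r) {
    lrow <- lt[lt$group == group & lt$arch == arch & lt$root == r, ]
    mix(lrow$mean, lrow$sd)
  }, numeric(1))
  if (spec$truncate_at_zero && arch == "upper") {
    dv <- max(dv, 0); dlen <- pmax(dlen, 0)
  }
  list(dv = dv, dlen = dlen)
}

simulate_tooth_pair <- function(spec, group, arch, cls, side, pid, pdir, seed) {
  set.seed(seed)
  tooth_id <- paste(cls, side, arch, sep = "_")
  t0 <- generate_tooth(tooth_template(cls,
                                      mesh_resolution = spec$mesh_resolution),
                       seed = seed)
  rl <- t0$root_labels
  eff <- draw_tooth_effects(spec, group, arch, cls, rl)
  dv <- eff$dv; dlen <- eff$dlen
  res <- apply_resorption(t0, resorption_spec(
    truncation = setNames(as.list(dlen), rl),
    target_volume_loss = dv))
  pert <- perturb_frame(res$t1, spec$max_rotation, spec$max_translation)
  t1 <- pert$tooth
  f0 <- file.path(pdir, paste0(tooth_id, "_T0.stl"))
  f1 <- file.path(pdir, paste0(tooth_id, "_T1.stl"))
  write_mesh(t0$mesh, f0, "stl")
  write_mesh(t1$mesh, f1, "stl")
  l0 <- file.path(pdir, paste0(tooth_id, "_T0_landmarks.json"))
  l1 <- file.path(pdir, paste0(tooth_id, "_T1_landmarks.json"))
  write_landmarks_json(t0$landmarks, l0)
  write_landmarks_json(t1$landmarks, l1)
  gt <- res$ground_truth
  list(
    tooth = data.frame(patient = pid, group = group, arch = arch,
                       tooth_class = cls, side = side, tooth_id = tooth_id,
                       seed = seed,
                       true_dv = gt$true_dv, true_v0_root = gt$true_v0_root,
                       true_dv_pct = gt$true_dv_pct,
                       target_dv = dv),
    roots = data.frame(patient = pid, group = group, arch = arch,
                       tooth_class = cls, side = side, tooth_id = tooth_id,
                       root = rl, true_dlen = unname(gt$true_dlen),
                       target_dlen = unname(dlen)))
}

#' Read / write landmark JSON files
#'
#' Landmarks are stored as a JSON object mapping landmark names to
#' `[x, y, z]` millimetre coordinates.
#'
#' @param landmarks named list of 3D points.
#' @param path file path.
#' @return `read_landmarks_json` returns the named list.
#' @export
write_landmarks_json <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, function(p) round(as.numeric(p), 9)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, as.numeric)
}
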