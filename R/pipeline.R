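#' Analyze one T0/T1 tooth pair
#'
#' The full per-tooth measurement protocol: landmark pre-alignment of T1
#' onto T0 (five registration points), best-fit ICP refinement, CEJ
#' radicular template from the T0 landmarks, synchronized crown cut of
#' both models at the template plane, radicular volume change, per-root
#' cusp-apex lengths at both timepoints, and signed deviation analysis
#' with matching percentage. All downstream quantities live in the T0
#' frame.
#'
#' @param t0,t1 `rm_mesh` tooth models (T1 in its own scanner frame).
#' @param landmarks_t0,landmarks_t1 named landmark lists.
#' @param tooth_class `"P1"`, `"P2"` or `"M1"` (names the roots).
#' @param tolerance deviation tolerance band mm.
#' @param icp list of [icp_register()] arguments.
#' @param length_mode apex mode for [root_length()].
#' @return list of class `rm_tooth_analysis`: `volume`
#'   (`rm_volume_change`), `lengths` (data.frame root, length_t0,
#'   length_t1, delta_length), `deviation` (`rm_deviation`),
#'   `registration` (report), `transform`, `plane`, `roots` (the cut
#'   radicular meshes).
#' @export
analyze_tooth_pair <- function(t0, t1, landmarks_t0, landmarks_t1,
                               tooth_class = "P1", tolerance = 0.3,
                               icp = list(), length_mode = "vertex") {
  reg_names <- grep("^reg_", names(landmarks_t0), value = TRUE)
  if (length(reg_names) < 3)
    stop("need at least 3 matched registration landmarks (reg_*)")
  init <- landmark_align(landmarks_t1[reg_names], landmarks_t0[reg_names])
  fit <- do.call(icp_register,
                 c(list(source = t1, target = t0, init = init), icp))
  t1r <- apply_transform(t1, fit$transform)
  lm1r <- apply_transform(landmarks_t1, fit$transform)
  tpl <- build_radicular_template(t0, landmarks_t0)
  roots <- cut_roots_synchronized(t0, t1r, tpl$plane)
  vol <- volume_change(roots$t0_root, roots$t1_root)
  labels <- root_labels_for_class(tooth_class)
  lengths <- do.call(rbind, lapply(labels, function(lab) {
    l0 <- root_length(landmarks_t0, t0, lab, mode = length_mode)
    l1 <- root_length(lm1r, t1r, lab, mode = length_mode)
    data.frame(root = lab, length_t0 = l0, length_t1 = l1,
               delta_length = l0 - l1)
  }))
  dev <- deviation_analysis(roots$t0_root, roots$t1_root,
                            tolerance = tolerance)
  structure(list(volume = vol, lengths = lengths, deviation = dev,
                 registration = fit$report, transform = fit$transform,
                 plane = tpl$plane, roots = roots),
            class = "rm_tooth_analysis")
}

root_labels_for_class <- function(cls) {
  if (cls == "M1") c("M1m", "M1d", "M1p") else cls
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir run directory (created; holds `data/`, `results/`,
#'   `manifest.json`).
#' @param seed master seed for cohort generation.
#' @param cohort an [cohort_spec()]; ignored when `data_dir` points at an
#'   existing cohort.
#' @param data_dir optional pre-existing cohort directory (skips the
#'   generation stage).
#' @param tolerance deviation tolerance band mm.
#' @param icp list of [icp_register()] options.
#' @return list of class `rm_run_config`.
#' @export
run_config <- function(out_dir, seed = 1, cohort = cohort_spec(),
                       data_dir = NULL, tolerance = 0.3, icp = list()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 data_dir = data_dir, tolerance = tolerance, icp = icp),
            class = "rm_run_config")
}

#' Run the full resorption-quantification pipeline
#'
#' Executes generate (optional) -> register -> isolate -> measure ->
#' deviate -> expand -> stats as one reproducible run: generates (or
#' loads) the cohort, analyzes every tooth pair, measures arch expansion,
#' joins the ground truth into a recovery report, writes the report
#' tables, and records a deterministic run manifest with content hashes
#' of every output. Identical seed and configuration reproduce identical
#' outputs byte for byte.
#'
#' @param config an [run_config()].
#' @param verbose print stage progress.
#' @return object of class `rm_run`: `measurements` (per tooth),
#'   `lengths` (per root), `expansion` (per patient x level),
#'   `patients`, `recovery` (estimate vs truth), `report` (file paths),
#'   `manifest_path`.
#' @export
run_all <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "rm_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res_dir <- file.path(config$out_dir, "results")
  dir.create(res_dir, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  # stage: generate or load
  if (is.null(config$data_dir)) {
    say("stage generate: %d patients/group", config$cohort$n_per_group)
    data_dir <- file.path(config$out_dir, "data")
    gen <- withCallingHandlers(
      generate_cohort(config$cohort, data_dir, seed = config$seed),
      error = function(e) stop("stage generate failed: ",
                               conditionMessage(e)))
  } else {
    data_dir <- config$data_dir
    gen <- list(
      manifest = read.csv(file.path(data_dir, "manifest.csv")),
      roots = read.csv(file.path(data_dir, "roots.csv")),
      patients = read.csv(file.path(data_dir, "patients.csv")))
  }
  manifest <- gen$manifest

  # stage: per-tooth registration + measurement
  meas <- list(); lens <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    pdir <- file.path(data_dir, row$patient)
    say("stage analyze: %s %s (%d/%d)", row$patient, row$tooth_id, i,
        nrow(manifest))
    ana <- tryCatch({
      t0 <- read_mesh(file.path(pdir, paste0(row$tooth_id, "_T0.stl")))
      t1 <- read_mesh(file.path(pdir, paste0(row$tooth_id, "_T1.stl")))
      l0 <- read_landmarks_json(file.path(pdir,
              paste0(row$tooth_id, "_T0_landmarks.json")))
      l1 <- read_landmarks_json(file.path(pdir,
              paste0(row$tooth_id, "_T1_landmarks.json")))
      analyze_tooth_pair(t0, t1, l0, l1, tooth_class = row$tooth_class,
                         tolerance = config$tolerance, icp = config$icp)
    }, error = function(e)
      stop(sprintf("stage analyze failed for %s/%s: %s", row$patient,
                   row$tooth_id, conditionMessage(e)), call. = FALSE))
    meas[[i]] <- data.frame(
      patient = row$patient, group = row$group, arch = row$arch,
      tooth_class = row$tooth_class, side = row$side,
      tooth_id = row$tooth_id,
      v_t0 = ana$volume$v_t0, v_t1 = ana$volume$v_t1,
      delta_v = ana$volume$delta_v, delta_v_pct = ana$volume$delta_v_pct,
      matching_pct = ana$deviation$matching_pct,
      icp_rms = ana$registration$final_rms,
      icp_iterations = ana$registration$iterations)
    lens[[i]] <- data.frame(
      patient = row$patient, group = row$group, arch = row$arch,
      tooth_class = row$tooth_class, side = row$side,
      tooth_id = row$tooth_id, ana$lengths)
  }
  measurements <- do.call(rbind, meas)
  lengths <- do.call(rbind, lens)

  # stage: arch expansion
  say("stage expand")
  expansion <- do.call(rbind, lapply(unique(manifest$patient), function(pid) {
    a0 <- file.path(data_dir, pid, "arch_T0.json")
    if (!file.exists(a0)) return(NULL)
    e <- expansion_change(read_landmarks_json(a0),
                          read_landmarks_json(file.path(data_dir, pid,
                                                        "arch_T1.json")))
    cbind(patient = pid,
          group = manifest$group[match(pid, manifest$patient)], e)
  }))

  # stage: recovery (estimate vs ground truth)
  recovery <- NULL
  if (all(c("true_dv", "true_dv_pct") %in% names(manifest))) {
    recovery <- merge(measurements,
                      manifest[, c("patient", "tooth_id", "true_dv",
                                   "true_v0_root", "true_dv_pct")],
                      by = c("patient", "tooth_id"))
    recovery$dv_error <- recovery$delta_v - recovery$true_dv
    recovery$dv_pct_error <- recovery$delta_v_pct - recovery$true_dv_pct
    rr <- merge(lengths,
                gen$roots[, c("patient", "tooth_id", "root", "true_dlen")],
                by = c("patient", "tooth_id", "root"))
    rr$dlen_error <- rr$delta_length - rr$true_dlen
    recovery <- list(volume = recovery, length = rr)
  }

  # stage: stats + report
  say("stage report")
  report <- make_report(measurements, lengths, expansion, gen$patients,
                        recovery = recovery, out_dir = res_dir)

  write.csv(measurements, file.path(res_dir, "measurements.csv"),
            row.names = FALSE)
  write.csv(lengths, file.path(res_dir, "lengths.csv"), row.names = FALSE)
  if (!is.null(expansion))
    write.csv(expansion, file.path(res_dir, "expansion.csv"),
              row.names = FALSE)

  # run manifest: deterministic content hashes of every output file
  files <- sort(list.files(res_dir, full.names = TRUE, recursive = TRUE))
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- sub(paste0("^", config$out_dir, "/?"), "", files)
  man <- list(package = "rootmorph",
              version = as.character(utils::packageVersion("rootmorph")),
              seed = config$seed,
              tolerance = config$tolerance,
              stages = c("generate", "analyze", "expand", "report"),
              status = "ok",
              outputs = hashes)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  structure(list(measurements = measurements, lengths = lengths,
                 expansion = expansion, patients = gen$patients,
                 recovery = recovery, report = report,
                 manifest_path = manifest_path, out_dir = config$out_dir),
            class = "rm_run")
}

#' @export
print.rm_run <- function(x, ...) {
  cat(sprintf("rm_run: %d teeth, %d patients; results in %s\n",
              nrow(x$measurements), length(unique(x$measurements$patient)),
              x$out_dir))
  if (!is.null(x$recovery))
    cat(sprintf("  volume recovery: mean |error| %.3f mm^3 (%.3f %%-points)\n",
                mean(abs(x$recovery$volume$dv_error)),
                mean(abs(x$recovery$volume$dv_pct_error))))
  invisible(x)
}

#' @export
summary.rm_run <- function(object, ...) {
  up <- object$measurements[object$measurements$arch == "upper", ]
  agg <- aggregate(cbind(delta_v, delta_v_pct, matching_pct) ~
                     group + tooth_class, up, function(v)
                       c(mean = mean(v), sd = sd(v)))
  print(agg)
  invisible(agg)
}

fmt_mean_sd <- function(x) sprintf("%.2f (%.2f)", mean(x), sd(x))

#' Build the cohort report tables
#'
#' Writes the standard report set of a two-group resorption study:
#' demographics, radicular volume changes, radicular length changes,
#' matching percentages, arch expansion, and the per-class regression of
#' resorption on expander type and expansion — each as a CSV plus a
#' human-readable summary. All values are computed by the stats layer
#' functions of this package.
#'
#' @param measurements per-tooth table (from [run_all()]).
#' @param lengths per-root table.
#' @param expansion per-patient x level expansion table (or NULL).
#' @param patients per-patient table with `group`, `gender`, `age` (or
#'   NULL).
#' @param recovery optional recovery list (estimate vs truth).
#' @param out_dir directory for the report files.
#' @param alpha significance level used in the text summary.
#' @return named list of written file paths.
#' @export
make_report <- function(measurements, lengths, expansion = NULL,
                        patients = NULL, recovery = NULL, out_dir,
                        alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  txt <- c("Cohort analysis report", "======================", "")

  # demographics
  if (!is.null(patients) && all(c("gender", "age") %in% names(patients))) {
    counts <- table(factor(patients$group),
                    factor(patients$gender, levels = c("M", "F")))
    chi <- tryCatch(chi_square_gender(counts), error = function(e) NULL)
    aget <- tryCatch(two_sample_t(patients, "age", "group"),
                     error = function(e) list(p = NA_real_))
    t1 <- data.frame(
      group = rownames(counts),
      male = counts[, "M"],
      female = counts[, "F"],
      age_mean = tapply(patients$age, patients$group, mean)[rownames(counts)],
      age_sd = tapply(patients$age, patients$group, sd)[rownames(counts)],
      gender_chisq_p = if (is.null(chi)) NA else chi$p,
      age_t_p = aget$p)
    paths$demographics <- file.path(out_dir, "table1_demographics.csv")
    write.csv(t1, paths$demographics, row.names = FALSE)
    txt <- c(txt, "Demographics:",
             sprintf("  gender chi-square p = %s, age t-test p = %s",
                     fmt_p(if (is.null(chi)) NA else chi$p), fmt_p(aget$p)), "")
  }

  # per-tooth volume / percentage / matching tables
  paths$volume <- write_group_table(measurements, "delta_v",
                                    file.path(out_dir, "table2_volume.csv"))
  paths$volume_pct <- write_group_table(measurements, "delta_v_pct",
                                        file.path(out_dir,
                                                  "table2b_volume_pct.csv"))
  paths$matching <- write_group_table(
    measurements[measurements$arch == "upper", ], "matching_pct",
    file.path(out_dir, "table4_matching.csv"))

  # per-root length table
  lt <- lengths
  lt$tooth_class <- lt$root
  paths$length <- write_group_table(lt, "delta_length",
                                    file.path(out_dir, "table3_length.csv"))

  for (v in c("delta_v", "delta_v_pct")) {
    up <- measurements[measurements$arch == "upper", ]
    tb <- anova_bonferroni(up[up$group == "TB", ], v, "tooth_class")
    bb <- anova_bonferroni(up[up$group == "BB", ], v, "tooth_class")
    txt <- c(txt, sprintf("Upper-arch %s: intra-group ANOVA p (TB) = %s, (BB) = %s",
                          v, fmt_p(tb$p), fmt_p(bb$p)))
  }
  txt <- c(txt, "")

  # expansion
  if (!is.null(expansion) && nrow(expansion)) {
    rows <- list()
    for (lv in unique(expansion$level)) {
      sub <- expansion[expansion$level == lv, ]
      for (kind in c("pwe", "dae")) {
        tt <- tryCatch(two_sample_t(sub, kind, "group"),
                       error = function(e) list(p = NA_real_))
        for (g in unique(sub$group))
          rows[[length(rows) + 1L]] <- data.frame(
            level = lv, kind = toupper(kind), group = g,
            mean = mean(sub[[kind]][sub$group == g]),
            sd = sd(sub[[kind]][sub$group == g]),
            t_p = tt$p)
      }
    }
    t5 <- do.call(rbind, rows)
    paths$expansion <- file.path(out_dir, "table5_expansion.csv")
    write.csv(t5, paths$expansion, row.names = FALSE)
  }

  # regression per tooth class (upper arch), outcome delta_v
  if (!is.null(expansion) && nrow(expansion)) {
    up <- measurements[measurements$arch == "upper", ]
    regs <- list()
    for (cls in unique(up$tooth_class)) {
      sub <- up[up$tooth_class == cls, ]
      exp_sub <- expansion[expansion$level == cls, ]
      sub <- merge(sub, exp_sub[, c("patient", "pwe", "dae")], by = "patient")
      sub$expander <- ifelse(sub$group == "BB", 1, 0)
      fit <- tryCatch(err_regression(sub, "delta_v",
                                     c("expander", "pwe", "dae")),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        co <- fit$coefficients
        co$tooth_class <- cls
        co$r_squared <- fit$r_squared
        regs[[cls]] <- co
      }
    }
    if (length(regs)) {
      t6 <- do.call(rbind, regs)
      paths$regression <- file.path(out_dir, "table6_regression.csv")
      write.csv(t6, paths$regression, row.names = FALSE)
    }
  }

  # side pooling pre-test (logged, per protocol)
  sp <- tryCatch(side_pooling_pretest(
    measurements[measurements$arch == "upper", ], "delta_v"),
    error = function(e) NULL)
  if (!is.null(sp))
    txt <- c(txt, "Side pooling pre-test (upper, delta_v):",
             sprintf("  %s: p = %s (%s)", sp$stratum, fmt_p(sp$p),
                     ifelse(sp$poolable, "poolable", "NOT poolable")), "")

  # recovery
  if (!is.null(recovery)) {
    paths$recovery <- file.path(out_dir, "recovery_volume.csv")
    write.csv(recovery$volume, paths$recovery, row.names = FALSE)
    paths$recovery_length <- file.path(out_dir, "recovery_length.csv")
    write.csv(recovery$length, paths$recovery_length, row.names = FALSE)
    txt <- c(txt, sprintf(
      "Ground-truth recovery: mean |dV error| = %.4f mm^3, mean |dV%% error| = %.4f points, mean |dL error| = %.4f mm",
      mean(abs(recovery$volume$dv_error)),
      mean(abs(recovery$volume$dv_pct_error)),
      mean(abs(recovery$length$dlen_error))), "")
  }

  paths$summary <- file.path(out_dir, "report.txt")
  writeLines(txt, paths$summary)
  paths
}

fmt_p <- function(p) {
  ifelse(!is.finite(p), "NA",
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

# mean/SD by group x arch x class plus inter-group t and intra-group
# ANOVA p values for one measurement column
write_group_table <- function(table, variable, path) {
  rows <- list()
  for (arch in unique(table$arch)) {
    sub_a <- table[table$arch == arch, ]
    for (cls in unique(sub_a$tooth_class)) {
      sub <- sub_a[sub_a$tooth_class == cls, ]
      tt <- tryCatch(two_sample_t(sub, variable, "group"),
                     error = function(e) list(p = NA))
      for (g in unique(sub$group)) {
        x <- sub[[variable]][sub$group == g]
        an <- tryCatch(
          anova_bonferroni(sub_a[sub_a$group == g, ], variable,
                           "tooth_class")$p,
          error = function(e) NA)
        rows[[length(rows) + 1L]] <- data.frame(
          arch = arch, tooth_class = cls, group = g, n = length(x),
          mean = mean(x), sd = sd(x), anova_p = an, t_p = tt$p)
      }
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  path
}
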