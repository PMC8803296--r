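# Config-driven orchestration of the synthetic cohort study: N patients x 4
# plan archetypes x {SECT, DLCT} chains x {proton, helium, carbon},
# emitting range-shift records, ROI SPR tables, gamma pass rates and
# DVH/coverage tables.

#' Four plan archetypes on the synthetic head
#'
#' Template geometries parameterized on the head phantom (mm, head-centered
#' coordinates; beam angles are travel azimuths in the axial plane):
#'
#' * `A` — larger target mostly in brain, three beams;
#' * `B` — smaller skull-base target, two nearly opposing lateral beams
#'   traversing the bone-heavy skull base;
#' * `C` — target as in A but two beams separated by 60 degrees;
#' * `D` — centrally located target, two nearly opposing fields.
#'
#' @return Named list of archetypes with `plan_id`, `target_center`,
#'   `target_semi`, `angles`.
#' @export
plan_archetypes <- function() {
  list(
    A = list(plan_id = "A", target_center = c(24, 6, 14),
             target_semi = c(16, 16, 14), angles = c(180, 120, 240)),
    B = list(plan_id = "B", target_center = c(0, 10, -48),
             target_semi = c(10, 12, 7), angles = c(0, 184)),
    C = list(plan_id = "C", target_center = c(24, 6, 14),
             target_semi = c(15, 15, 13), angles = c(180, 240)),
    D = list(plan_id = "D", target_center = c(0, -12, 8),
             target_semi = c(12, 12, 12), angles = c(0, 184))
  )
}

#' Study configuration
#'
#' Defaults reproduce the study design: a cohort of synthetic patients,
#' four plan archetypes, both CT chains and three ion species.
#'
#' @param n_patients Cohort size (default 6).
#' @param spacing Voxel spacing in mm (default 2).
#' @param scanner A [scanner_model()]; its biases/noise are the imposed
#'   modality discrepancy (default: none).
#' @param stoich Truth scanner spectrum, a [stoich_params()].
#' @param ions Character vector of ion species to plan.
#' @param plans Archetype ids to run (default all four).
#' @param calibration `"interpolating"` (conversion curves exact on the
#'   phantom materials, isolating the imposed modality discrepancy from
#'   calibration residuals) or `"fitted"` (segment-fit EAN-to-I model and
#'   ten-segment HLUT).
#' @param calib_noise_sd HU noise SD on the synthetic insert readings used
#'   for the stoichiometric fit (default 0).
#' @param n_profiles Line-dose profiles per beam (default 5).
#' @param prescribed_dose Plan dose in Gy (RBE) at the SOBP plateau
#'   (default 54, a total treatment dose).
#' @param evaluate_dose Compute dose volumes, gamma, DVH/OAR tables
#'   (default TRUE); range-shift profiles are always computed.
#' @param gamma A [gamma_config()].
#' @param oar_threshold Flag threshold for OAR dose differences in Gy
#'   (default 0.5).
#' @param ray_spacing Lateral ray lattice spacing in mm for dose volumes.
#' @param profile_step Ray sampling step in mm for line-dose profiles
#'   (default 0.25).
#' @param anatomy_jitter Per-patient uniform half-range of the anatomy
#'   scale factors (default 0.03).
#' @param seed Master seed; every random sub-stream derives from it.
#' @return A `study_config` object.
#' @export
study_config <- function(n_patients = 6, spacing = 2,
                         scanner = scanner_model(),
                         stoich = default_stoich_params(),
                         ions = c("proton", "helium", "carbon"),
                         plans = c("A", "B", "C", "D"),
                         calibration = c("interpolating", "fitted"),
                         calib_noise_sd = 0,
                         n_profiles = 5, prescribed_dose = 54,
                         evaluate_dose = TRUE,
                         gamma = gamma_config(),
                         oar_threshold = 0.5,
                         ray_spacing = 4, profile_step = 0.25,
                         anatomy_jitter = 0.03, seed = 1L) {
  calibration <- match.arg(calibration)
  ions <- vapply(ions, function(i) match.arg(i, names(.ION_DEFAULTS)), "")
  structure(list(n_patients = n_patients, spacing = spacing,
                 scanner = scanner, stoich = stoich, ions = unname(ions),
                 plans = plans, calibration = calibration,
                 calib_noise_sd = calib_noise_sd, n_profiles = n_profiles,
                 prescribed_dose = prescribed_dose,
                 evaluate_dose = evaluate_dose, gamma = gamma,
                 oar_threshold = oar_threshold, ray_spacing = ray_spacing,
                 profile_step = profile_step,
                 anatomy_jitter = anatomy_jitter, seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Scalar fields of [study_config()] may be given in a YAML mapping;
#' `scanner` and `gamma` as nested mappings of their constructor arguments.
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scanner)) y$scanner <- do.call(scanner_model, y$scanner)
  if (!is.null(y$gamma)) y$gamma <- do.call(gamma_config, y$gamma)
  if (!is.null(y$stoich)) y$stoich <- do.call(stoich_params, y$stoich)
  do.call(study_config, y)
}

# ellipsoid mask on a volume grid
.ellipsoid_mask <- function(vol, center, semi) {
  ax <- vol_axes(vol)
  d <- dim(vol$data)
  X <- rep(ax$x, times = d[2] * d[3])
  Y <- rep(rep(ax$y, each = d[1]), times = d[3])
  Z <- rep(ax$z, each = d[1] * d[2])
  m <- ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
  array(m, dim = d)
}

# geometric entry/exit depths of a ray through an ellipsoid, relative to
# the ray origin; NULL if missed
.ray_ellipsoid <- function(origin, direction, center, semi) {
  o <- (origin - center) / semi
  dd <- direction / semi
  a <- sum(dd^2); b <- 2 * sum(o * dd); cc <- sum(o^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(NULL)
  sq <- sqrt(disc)
  sort(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
}

# build the beams of one plan archetype for one ion, with SOBP intervals
# set from WEPL on the planning (SECT) SPR map -- fixed beam parameters,
# recalculation without reoptimization on the other map
.make_beams <- function(arch, ion, spr_plan, cfg, margin_mm = 3) {
  n_beams <- length(arch$angles)
  lapply(arch$angles, function(ang) {
    dir <- beam_direction(ang)
    origin <- arch$target_center - 250 * dir
    tr <- trace_wepl(spr_plan, origin, dir, step = cfg$profile_step)
    if (!nrow(tr)) stop("plan ", arch$plan_id, ": beam misses the volume")
    hits <- .ray_ellipsoid(origin, dir, arch$target_center, arch$target_semi)
    if (is.null(hits)) stop("plan ", arch$plan_id, ": beam misses the target")
    t_entry <- attr(tr, "t_entry")
    w_in <- stats::approx(tr$depth, tr$wepl, xout = hits[1] - t_entry,
                          rule = 2)$y
    w_out <- stats::approx(tr$depth, tr$wepl, xout = hits[2] - t_entry,
                           rule = 2)$y
    sob <- build_sobp(ion, max(w_in - margin_mm, 5), w_out + margin_mm)
    rbe <- if (ion == "proton") 1.1 else 1.0
    # lateral field: u spans the axial plane, v the z axis
    fe <- c(2 * max(arch$target_semi[1:2]) + 8, 2 * arch$target_semi[3] + 8)
    beam_spec(ion, dir, arch$target_center, sob,
              field_extent = fe, ray_spacing = cfg$ray_spacing,
              prescribed_dose = cfg$prescribed_dose / rbe / n_beams)
  })
}

# synthetic organ-at-risk stand-ins (head-centered mm)
.default_oars <- function() {
  list(brainstem_analogue = list(center = c(0, -25, -38), semi = c(9, 9, 12)),
       chiasm_analogue = list(center = c(0, 26, -30), semi = c(6, 6, 5)))
}

#' Run the synthetic cohort study end-to-end
#'
#' For each synthetic patient: head phantom, simulated DLCT and SECT
#' acquisitions, the two SPR prediction chains (calibrated once per
#' scanner), per-plan beams fixed on the SECT map and recalculated on the
#' DLCT map, per-profile R90/R80 range-shift records, and (optionally)
#' dose volumes with 3D gamma, DVH metrics and organ-at-risk flags.
#'
#' @param cfg A [study_config()].
#' @param verbose Print per-stage progress (default FALSE).
#' @return A list of result tables: `records`, `roi_tables` (per patient),
#'   `roi_cohort`, `summary_by_plan`, `summary_by_patient`, `variability`,
#'   `paired_tests` (per patient, R90 SECT vs DLCT over all profiles),
#'   `gamma_summary`, `ptv_d99`, `oar_flags`, and `manifest` (config,
#'   seeds, package version).
#' @export
run_study <- function(cfg = study_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  tissues <- reference_tissues()

  # --- calibration (once per scanner) -------------------------------------
  inserts <- synthetic_inserts()
  if (cfg$calib_noise_sd > 0) set.seed(.sub_seed(cfg$seed, 17L))
  readings <- lapply(inserts, function(cc) {
    hu <- predict_hu(cc, cfg$stoich)
    if (cfg$calib_noise_sd > 0) hu <- hu + stats::rnorm(1, 0, cfg$calib_noise_sd)
    insert_reading(cc, hu)
  })
  fitted_sp <- fit_stoichiometric(readings)
  if (cfg$calibration == "interpolating") {
    lut <- build_hlut(fitted_sp, tissues, method = "interpolate")
    eim <- fit_ean_i_model(tissues, method = "interpolate")
  } else {
    lut <- build_hlut(fitted_sp, hlut_reference_tissues())
    eim <- fit_ean_i_model(hlut_reference_tissues())
  }
  say("calibration done (k1 = %.3g, k2 = %.3g)", fitted_sp$k1, fitted_sp$k2)

  archs <- plan_archetypes()[cfg$plans]
  records <- list(); roi_tables <- list(); gamma_rows <- list()
  d99_rows <- list(); flag_rows <- list()

  for (i in seq_len(cfg$n_patients)) {
    set.seed(.sub_seed(cfg$seed, 100L + i))
    scale <- 1 + stats::runif(3, -cfg$anatomy_jitter, cfg$anatomy_jitter)
    phantom <- build_head_phantom(head_geometry(scale), tissues,
                                  spacing = cfg$spacing)
    scanner <- cfg$scanner
    scanner$seed <- .sub_seed(cfg$seed, 200L + i)
    dl <- simulate_dlct(phantom, scanner)
    hu <- simulate_sect(phantom, cfg$stoich, scanner)
    spr_d <- predict_spr_dlct(dl$ed, dl$ean, eim)
    spr_s <- apply_hlut(hu, lut)
    say("patient %d: phantom %s, SPR maps done", i,
        paste(dim(hu$data), collapse = "x"))

    roi_tables[[i]] <- roi_spr_table(spr_s, spr_d, roi_masks(phantom))

    oars <- .default_oars()
    for (arch in archs) {
      for (ion in cfg$ions) {
        beams <- .make_beams(arch, ion, spr_s, cfg)
        plan <- list(patient_id = sprintf("P%02d", i),
                     plan_id = arch$plan_id, beams = beams,
                     target_center = arch$target_center,
                     target_semi = arch$target_semi)
        records[[length(records) + 1L]] <-
          range_shift_records(spr_s, spr_d, plan,
                              n_profiles = cfg$n_profiles,
                              step = cfg$profile_step)
        if (cfg$evaluate_dose) {
          dose_s <- plan_dose_volume(spr_s, beams, step = cfg$profile_step)
          dose_d <- plan_dose_volume(spr_d, beams, step = cfg$profile_step)
          g <- gamma_3d(dose_s, dose_d, cfg$gamma)
          gamma_rows[[length(gamma_rows) + 1L]] <- data.frame(
            patient_id = plan$patient_id, plan_id = arch$plan_id, ion = ion,
            pass_rate = g$pass_rate, n_analyzed = g$n_analyzed)
          ptv <- .ellipsoid_mask(spr_s, arch$target_center, arch$target_semi)
          masks <- c(list(ptv = ptv),
                     lapply(oars, function(o)
                       .ellipsoid_mask(spr_s, o$center, o$semi)))
          dv_s <- lapply(masks, function(m) dvh(dose_s, m))
          dv_d <- lapply(masks, function(m) dvh(dose_d, m))
          d99_rows[[length(d99_rows) + 1L]] <- data.frame(
            patient_id = plan$patient_id, plan_id = arch$plan_id, ion = ion,
            d99_sect = dv_s$ptv$d99, d99_dlct = dv_d$ptv$d99,
            delta_d99 = dv_s$ptv$d99 - dv_d$ptv$d99)
          fl <- oar_dose_flags(dv_s[-1], dv_d[-1],
                               threshold = cfg$oar_threshold)
          fl$patient_id <- plan$patient_id
          fl$plan_id <- arch$plan_id
          fl$ion <- ion
          flag_rows[[length(flag_rows) + 1L]] <- fl
        }
      }
      say("patient %d plan %s done", i, arch$plan_id)
    }
  }

  records <- do.call(rbind, records)
  paired <- lapply(split(records[!records$excluded, ],
                         records$patient_id[!records$excluded]),
                   function(g) paired_t_ci(g$r90_sect - g$r90_dlct))
  out <- list(
    records = records,
    roi_tables = roi_tables,
    roi_cohort = cohort_roi_summary(roi_tables),
    summary_by_plan = range_shift_summary(records, "plan_id"),
    summary_by_patient = range_shift_summary(records, "patient_id"),
    variability = if (cfg$n_patients >= 2) variability(records),
    paired_tests = paired,
    gamma_summary = if (length(gamma_rows)) do.call(rbind, gamma_rows),
    ptv_d99 = if (length(d99_rows)) do.call(rbind, d99_rows),
    oar_flags = if (length(flag_rows)) do.call(rbind, flag_rows),
    manifest = list(config = unclass(cfg), seed = cfg$seed,
                    package_version = as.character(utils::packageVersion("sprct")),
                    timestamp = format(Sys.time(), tz = "UTC"))
  )
  class(out) <- "study_result"
  out
}

#' Write study result tables to a directory
#'
#' CSV tables analogous to the published evaluation: per-ROI SPR
#' differences, range-shift percentile summaries, PTV D99 coverage, gamma
#' pass rates and OAR flags, plus a JSON manifest.
#'
#' @param result A `study_result` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$roi_cohort,
                   file.path(dir, "table1_roi_spr.csv"), row.names = FALSE)
  utils::write.csv(result$summary_by_plan,
                   file.path(dir, "table2_range_percentiles.csv"),
                   row.names = FALSE)
  utils::write.csv(result$records,
                   file.path(dir, "range_shift_records.csv"),
                   row.names = FALSE)
  if (!is.null(result$ptv_d99))
    utils::write.csv(result$ptv_d99, file.path(dir, "table3_ptv_d99.csv"),
                     row.names = FALSE)
  if (!is.null(result$gamma_summary))
    utils::write.csv(result$gamma_summary,
                     file.path(dir, "gamma_summary.csv"), row.names = FALSE)
  if (!is.null(result$oar_flags))
    utils::write.csv(result$oar_flags, file.path(dir, "oar_flags.csv"),
                     row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
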