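# Evaluation layer: ROI SPR statistics with paired tests, range-shift
# summaries and variabilities, local 3D gamma analysis, DVH metrics and
# organ-at-risk dose flags.
#
# Conventions (stated because several are ambiguous in common usage):
# percentiles use linear interpolation between order statistics (type 7),
# standard deviations use the n-1 denominator, SEM = SD/sqrt(n).

#' Circular ROI specifications for the homogeneous-tissue SPR comparison
#'
#' Per-structure circular regions of interest: approximate disc area (mm^2)
#' and number of consecutive axial slices, mirroring a typical head
#' protocol: brain 100 mm^2 x 10 slices, eyes 100 x 5, lateral ventricles
#' 50 x 5, cranial bone 50 x 10, skull base 25 x 10.
#'
#' @return Data frame with columns `roi`, `structures`, `area_mm2`,
#'   `n_slices`.
#' @export
default_roi_specs <- function() {
  data.frame(
    roi = c("brain", "eyes", "ventricles", "cranial_bone", "skull_base"),
    structures = I(list("brain", c("eye_l", "eye_r"),
                        c("ventricle_l", "ventricle_r"),
                        "cranium", "skull_base")),
    area_mm2 = c(100, 100, 50, 50, 25),
    n_slices = c(10, 5, 5, 10, 10)
  )
}

#' Place circular ROI masks on a labeled phantom
#'
#' For each ROI spec, discs of the requested area are centered on the
#' centroid of the named structure(s) over the requested number of
#' consecutive axial slices, intersected with the structure so the ROI
#' stays in-tissue (automatic seeding replaces manual placement).
#'
#' @param phantom A `labeled_phantom`.
#' @param specs Data frame as returned by [default_roi_specs()].
#' @return Named list of logical arrays on the phantom grid.
#' @export
roi_masks <- function(phantom, specs = default_roi_specs()) {
  d <- dim(phantom$labels$data)
  ax <- vol_axes(phantom$labels)
  out <- list()
  for (i in seq_len(nrow(specs))) {
    radius <- sqrt(specs$area_mm2[i] / pi)
    mask <- array(FALSE, d)
    for (sname in specs$structures[[i]]) {
      smask <- structure_mask(phantom, sname)
      if (!any(smask)) stop("structure '", sname, "' is empty")
      # per-slice disc at the slice centroid; keep the slices where the
      # disc is best covered by the structure (shell-like structures are
      # only locally disc-shaped, e.g. the calvaria cap)
      kset <- which(apply(smask, 3, any))
      cover <- numeric(length(kset))
      discs <- vector("list", length(kset))
      for (j in seq_along(kset)) {
        sl <- smask[, , kset[j]]
        idx <- which(sl, arr.ind = TRUE)
        cx <- ax$x[round(mean(idx[, 1]))]
        cy <- ax$y[round(mean(idx[, 2]))]
        disc <- outer((ax$x - cx)^2, (ax$y - cy)^2, `+`) <= radius^2
        discs[[j]] <- disc & sl
        cover[j] <- sum(discs[[j]]) / max(sum(disc), 1L)
      }
      take <- order(cover, decreasing = TRUE)[seq_len(min(specs$n_slices[i],
                                                          length(kset)))]
      for (j in take) if (any(discs[[j]]))
        mask[, , kset[j]] <- mask[, , kset[j]] | discs[[j]]
    }
    if (!any(mask)) stop("ROI '", specs$roi[i], "' is empty")
    out[[specs$roi[i]]] <- mask
  }
  out
}

#' Per-ROI SPR difference table
#'
#' For each ROI the relative SPR difference between the two modality maps
#' is computed per axial slice from the slice means,
#' \eqn{\delta = 100 (\bar{SPR}_{DLCT} - \bar{SPR}_{SECT}) / \bar{SPR}_{SECT}},
#' then summarized as mean and SD over the slices.
#'
#' @param spr_sect,spr_dlct SPR `scalar_volume`s on one grid.
#' @param masks Named list of logical ROI arrays (see [roi_masks()]).
#' @return Data frame with one row per ROI: `mean_sect`, `mean_dlct`,
#'   `delta_pct` (mean over slices), `delta_sd_pct`, `n_slices`, `n_voxels`.
#' @export
roi_spr_table <- function(spr_sect, spr_dlct, masks) {
  if (!same_grid(spr_sect, spr_dlct)) stop("volumes on different grids")
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!any(m)) stop("empty ROI mask: ", nm)
    slices <- which(apply(m, 3, any))
    delta <- vapply(slices, function(k) {
      ms <- mean(spr_sect$data[, , k][m[, , k]])
      md <- mean(spr_dlct$data[, , k][m[, , k]])
      100 * (md - ms) / ms
    }, 0)
    data.frame(roi = nm,
               mean_sect = mean(spr_sect$data[m]),
               mean_dlct = mean(spr_dlct$data[m]),
               delta_pct = mean(delta),
               delta_sd_pct = if (length(delta) > 1) stats::sd(delta) else 0,
               n_slices = length(slices), n_voxels = sum(m))
  })
  do.call(rbind, rows)
}

#' Cohort summary of per-patient ROI differences
#'
#' Median, mean and standard error of the mean (SD/sqrt(n)) of the
#' per-patient ROI mean differences.
#'
#' @param tables List of per-patient data frames from [roi_spr_table()].
#' @return Data frame, one row per ROI.
#' @export
cohort_roi_summary <- function(tables) {
  all <- do.call(rbind, Map(function(tb, i) transform(tb, patient = i),
                            tables, seq_along(tables)))
  rows <- lapply(split(all, all$roi), function(g) {
    data.frame(roi = g$roi[1], n_patients = nrow(g),
               median_delta_pct = stats::median(g$delta_pct),
               mean_delta_pct = mean(g$delta_pct),
               sem_delta_pct = stats::sd(g$delta_pct) / sqrt(nrow(g)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired t-test with confidence interval on per-unit differences
#'
#' Two-sided one-sample t-test of the differences against zero with the
#' (1 - alpha) confidence interval mean +/- t_{1-alpha/2, n-1} SD/sqrt(n).
#' Zero-variance input is reported with a degenerate flag (p = 0 for a
#' nonzero common difference, p = 1 for all-zero differences) and a
#' point-mass interval.
#'
#' @param differences Numeric vector of paired differences (n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return List with `t`, `df`, `p`, `ci` (length 2), `mean`, `sd`,
#'   `degenerate`.
#' @export
paired_t_ci <- function(differences, alpha = 0.05) {
  n <- length(differences)
  if (n < 2) stop("need at least 2 paired differences")
  m <- mean(differences); s <- stats::sd(differences)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else Inf * sign(m), df = n - 1,
                p = if (m == 0) 1 else 0, ci = c(m, m), mean = m, sd = 0,
                degenerate = TRUE))
  }
  ht <- stats::t.test(differences, conf.level = 1 - alpha)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, ci = as.numeric(ht$conf.int), mean = m, sd = s,
       degenerate = FALSE)
}

# type-7 percentiles + box-plot statistics of one numeric vector
.summary_row <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  data.frame(n = length(x), mean = mean(x),
             sd = if (length(x) > 1) stats::sd(x) else 0,
             p25 = q[1], p50 = q[2], p75 = q[3], p100 = q[4],
             whisker_low = min(x[inside]), whisker_high = max(x[inside]),
             n_outliers = sum(!inside))
}

#' Grouped summary of range-shift records
#'
#' Mean, SD, quartiles (linear interpolation), maximum and 1.5 IQR box-plot
#' whiskers of a range-shift column, grouped by plan, patient or any record
#' column.
#'
#' @param records Data frame from [range_shift_records()] (excluded rows are
#'   dropped).
#' @param group_by Grouping column name (e.g. `"plan_id"`, `"patient_id"`),
#'   or `NULL` for a single overall group.
#' @param value Value column (default `"rel_dr90"`).
#' @param absolute Summarize absolute values (default TRUE, as for
#'   box-plotted range-shift magnitudes).
#' @return Data frame, one row per group.
#' @export
range_shift_summary <- function(records, group_by = "plan_id",
                                value = "rel_dr90", absolute = TRUE) {
  records <- records[!records$excluded, , drop = FALSE]
  if (!nrow(records)) stop("no usable records")
  x <- records[[value]]
  if (absolute) x <- abs(x)
  grp <- if (is.null(group_by)) rep("all", nrow(records))
         else as.character(records[[group_by]])
  rows <- lapply(split(x, grp), .summary_row)
  out <- do.call(rbind, rows)
  out <- cbind(group = names(rows), out)
  rownames(out) <- NULL
  out
}

#' Intra- and inter-patient variability of range shifts
#'
#' Intrapatient variability is the mean over patients of the per-patient SD
#' of shifts; interpatient variability is the SD over patients of the
#' per-patient mean shift.
#'
#' @param records Data frame with a `patient_id` column.
#' @param value Value column (default `"rel_dr90"`).
#' @param absolute Use absolute values (default TRUE).
#' @return List with `intrapatient`, `interpatient`, `n_patients`,
#'   `flagged` (TRUE when some patient has a single record so its SD is
#'   undefined and dropped from the intrapatient mean).
#' @export
variability <- function(records, value = "rel_dr90", absolute = TRUE) {
  records <- records[!records$excluded, , drop = FALSE]
  x <- records[[value]]
  if (absolute) x <- abs(x)
  per <- split(x, records$patient_id)
  if (length(per) < 2) stop("need records from at least 2 patients")
  sds <- vapply(per, function(v) if (length(v) > 1) stats::sd(v) else NA_real_, 0)
  means <- vapply(per, mean, 0)
  list(intrapatient = mean(sds, na.rm = TRUE),
       interpatient = stats::sd(means),
       n_patients = length(per), flagged = anyNA(sds))
}

#' Gamma analysis configuration
#'
#' @param dose_criterion Dose-difference criterion as a fraction (default
#'   0.01 = 1%).
#' @param dta Distance-to-agreement criterion in mm (default 1).
#' @param normalization `"local"` (criterion times the local reference
#'   dose) or `"global"` (criterion times the reference maximum).
#' @param low_dose_cutoff Reference voxels below this fraction of the
#'   reference maximum are excluded (default 0.05).
#' @param search_radius Candidate search radius in units of `dta`
#'   (default 3).
#' @param lattice_step Candidate lattice step in units of `dta`
#'   (default 0.1).
#' @return A `gamma_config` object.
#' @export
gamma_config <- function(dose_criterion = 0.01, dta = 1,
                         normalization = c("local", "global"),
                         low_dose_cutoff = 0.05, search_radius = 3,
                         lattice_step = 0.1) {
  normalization <- match.arg(normalization)
  stopifnot(dose_criterion > 0, dta > 0, low_dose_cutoff >= 0,
            low_dose_cutoff < 1, search_radius > 0, lattice_step > 0)
  structure(list(dose_criterion = dose_criterion, dta = dta,
                 normalization = normalization,
                 low_dose_cutoff = low_dose_cutoff,
                 search_radius = search_radius, lattice_step = lattice_step),
            class = "gamma_config")
}

#' 3D gamma analysis
#'
#' For every reference voxel above the low-dose cutoff,
#' \deqn{\gamma = \min_r \sqrt{ \|\Delta r\|^2 / dta^2 +
#'   (D_{eval}(r) - D_{ref})^2 / \Delta D^2 }}
#' with \eqn{\Delta D} the dose criterion times the local reference dose
#' (local mode) or times the global reference maximum. Candidate offsets
#' live on a `lattice_step * dta` lattice inside a `search_radius * dta`
#' sphere, visited in order of increasing distance with per-voxel early
#' exit once no closer candidate can improve the running minimum; the
#' evaluated distribution is trilinearly interpolated at sub-voxel offsets.
#'
#' @param ref,eval `scalar_volume`s of reference and evaluated dose on one
#'   grid.
#' @param config A [gamma_config()].
#' @return List with `pass_rate` (percent of analyzed voxels with gamma <=
#'   1), `gamma` (a `scalar_volume`, `NA` below cutoff), `n_analyzed`.
#' @export
gamma_3d <- function(ref, eval, config = gamma_config()) {
  if (!same_grid(ref, eval)) stop("dose volumes on different grids")
  cfg <- config
  dmax <- max(ref$data)
  cut <- cfg$low_dose_cutoff * dmax
  sel <- which(ref$data > cut)
  if (!length(sel)) stop("all reference voxels below the low-dose cutoff")
  dref <- ref$data[sel]
  denom <- if (cfg$normalization == "local") cfg$dose_criterion * dref
           else rep(cfg$dose_criterion * dmax, length(dref))
  pts <- voxel_centers(ref)[sel, , drop = FALSE]

  # zero-offset dose term
  g2 <- ((eval$data[sel] - dref) / denom)^2
  # candidate offsets sorted by radius
  h <- cfg$lattice_step * cfg$dta
  rmax <- cfg$search_radius * cfg$dta
  k <- seq(-floor(rmax / h), floor(rmax / h))
  off <- as.matrix(expand.grid(x = k * h, y = k * h, z = k * h))
  r2 <- rowSums(off^2)
  keep <- r2 <= rmax^2 & r2 > 0
  off <- off[keep, , drop = FALSE]
  r2 <- r2[keep]
  o <- order(r2)
  off <- off[o, , drop = FALSE]
  r2 <- r2[o]
  dta2 <- cfg$dta^2

  active <- which(g2 > 1)
  for (j in seq_len(nrow(off))) {
    if (!length(active)) break
    dist_term <- r2[j] / dta2
    # drop voxels whose current minimum cannot be improved at this radius
    done <- g2[active] <= dist_term
    if (any(done)) {
      active <- active[!done]
      if (!length(active)) break
    }
    p <- pts[active, , drop = FALSE]
    p[, 1] <- p[, 1] + off[j, 1]
    p[, 2] <- p[, 2] + off[j, 2]
    p[, 3] <- p[, 3] + off[j, 3]
    dv <- interp_trilinear(eval, p)
    cand <- dist_term + ((dv - dref[active]) / denom[active])^2
    better <- !is.na(cand) & cand < g2[active]
    if (any(better)) g2[active[better]] <- cand[better]
    active <- active[g2[active] > 1]
  }
  gam <- sqrt(g2)
  out <- array(NA_real_, dim = dim(ref$data))
  out[sel] <- gam
  # the boundary gamma = 1 counts as passing; allow float rounding there
  list(pass_rate = 100 * mean(gam <= 1 + 1e-9),
       gamma = vol_like(ref, out), n_analyzed = length(sel))
}

#' Dose-volume histogram metrics for a structure
#'
#' Cumulative DVH on a dose grid plus the summary metrics: `dmean` (the
#' arithmetic voxel mean), `d_003cc` (minimum dose of the hottest
#' ceiling(0.03 cc / voxel volume) voxels, the near-maximum), and `d99`
#' (dose received by at least 99% of the volume, read off the order
#' statistics with linear interpolation).
#'
#' @param dose A `scalar_volume` of dose.
#' @param mask Logical array on the dose grid (non-empty).
#' @param n_bins Number of DVH dose bins (default 200).
#' @return An object of class `dvh_metrics`: `structure` fields `dmean`,
#'   `d_003cc`, `d99`, `v_cc`, `flag_small`, and `curve` (data frame
#'   `dose`, `volume_fraction`, non-increasing).
#' @export
dvh <- function(dose, mask, n_bins = 200) {
  stopifnot(inherits(dose, "scalar_volume"))
  if (!any(mask)) stop("empty structure mask")
  vv_cc <- prod(dose$spacing) / 1000
  x <- dose$data[mask]
  n <- length(x)
  k <- ceiling(0.03 / vv_cc)
  flag_small <- k > n
  if (flag_small) k <- 1L   # structure smaller than 0.03 cc: fall back to max
  srt <- sort(x, decreasing = TRUE)
  grid <- seq(0, max(x) * 1.001 + 1e-9, length.out = n_bins)
  vol_frac <- vapply(grid, function(g) mean(x >= g), 0)
  structure(list(
    dmean = mean(x),
    d_003cc = srt[k],
    d99 = stats::quantile(x, 0.01, type = 7, names = FALSE),
    v_cc = n * vv_cc,
    flag_small = flag_small,
    curve = data.frame(dose = grid, volume_fraction = vol_frac)
  ), class = "dvh_metrics")
}

#' Flag organ-at-risk dose differences between two plans
#'
#' Per structure, the absolute differences in mean dose and near-maximum
#' dose (D 0.03 cc); a structure is flagged when either exceeds the
#' threshold (strictly greater). The signed coverage difference
#' `d99_sect - d99_dlct` is also reported for target-type structures.
#'
#' @param dvh_sect,dvh_dlct Named lists of `dvh_metrics` (matching names).
#' @param threshold Flag threshold in Gy (default 0.5).
#' @return Data frame with one row per structure present on both sides
#'   (missing structures are skipped with a warning).
#' @export
oar_dose_flags <- function(dvh_sect, dvh_dlct, threshold = 0.5) {
  common <- intersect(names(dvh_sect), names(dvh_dlct))
  missing <- union(setdiff(names(dvh_sect), common),
                   setdiff(names(dvh_dlct), common))
  if (length(missing))
    warning("structure(s) missing on one side, skipped: ",
            paste(missing, collapse = ", "))
  rows <- lapply(common, function(nm) {
    a <- dvh_sect[[nm]]; b <- dvh_dlct[[nm]]
    ddm <- abs(a$dmean - b$dmean)
    ddx <- abs(a$d_003cc - b$d_003cc)
    data.frame(structure = nm,
               delta_dmean = ddm, delta_d003cc = ddx,
               delta_d99 = a$d99 - b$d99,
               flagged = ddm > threshold | ddx > threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
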