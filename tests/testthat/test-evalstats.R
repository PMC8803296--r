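# Evaluation statistics: ROI tables, paired tests, summaries, gamma, DVH.

test_that("ROI SPR tables report per-slice relative differences", {
  dims <- c(10, 10, 6)
  base <- scalar_volume(array(1, dims), c(2, 2, 2))
  mask <- array(FALSE, dims); mask[3:6, 3:6, 2:5] <- TRUE
  # identical volumes: zero everywhere
  t0 <- roi_spr_table(base, base, list(brain = mask))
  expect_equal(t0$delta_pct, 0)
  expect_equal(t0$delta_sd_pct, 0)
  # constant-ratio construction: dlct = 1.011 x sect -> 1.10%
  dlct <- vol_like(base, base$data * 1.011)
  t1 <- roi_spr_table(base, dlct, list(brain = mask))
  expect_equal(t1$delta_pct, 1.1, tolerance = 1e-9)
  expect_equal(t1$n_slices, 4)
  expect_error(roi_spr_table(base, dlct, list(empty = array(FALSE, dims))),
               "empty")
})

test_that("cohort ROI summary computes the SEM by definition", {
  mk <- function(delta) data.frame(roi = "brain", mean_sect = 1,
                                   mean_dlct = 1 + delta / 100,
                                   delta_pct = delta, delta_sd_pct = 0,
                                   n_slices = 10, n_voxels = 100)
  deltas <- c(0.8, 1.0, 1.2, 0.9, 1.1, 1.0, 0.7, 1.3)
  out <- cohort_roi_summary(lapply(deltas, mk))
  expect_equal(out$mean_delta_pct, mean(deltas))
  expect_equal(out$sem_delta_pct, sd(deltas) / sqrt(8))
  expect_equal(out$median_delta_pct, median(deltas))
})

test_that("paired t statistics match the closed form", {
  res <- paired_t_ci(c(1, 2, 3))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$t, 3.464, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-sqrt(12), df = 2), tolerance = 1e-9)
  expect_false(res$degenerate)
  # negation flips t, keeps p
  neg <- paired_t_ci(-c(1, 2, 3))
  expect_equal(neg$t, -res$t)
  expect_equal(neg$p, res$p)
  # degenerate constant differences
  dg <- paired_t_ci(c(0.5, 0.5, 0.5))
  expect_true(dg$degenerate)
  expect_equal(dg$ci, c(0.5, 0.5))
  expect_equal(dg$p, 0)
  dg0 <- paired_t_ci(c(0, 0))
  expect_equal(dg0$p, 1)
  expect_error(paired_t_ci(1), "at least 2")
})

test_that("range-shift summaries use interpolated percentiles and IQR whiskers", {
  rec <- data.frame(patient_id = "P1", plan_id = "A",
                    rel_dr90 = c(0.2, 0.4, 0.6, 0.8), excluded = FALSE)
  s <- range_shift_summary(rec, group_by = NULL)
  expect_equal(s$p25, 0.35)
  expect_equal(s$p50, 0.5)
  expect_equal(s$p75, 0.65)
  expect_equal(s$p100, 0.8)
  # duplicating every record leaves the quartile structure intact
  s2 <- range_shift_summary(rbind(rec, rec), group_by = NULL)
  expect_equal(s2$p50, s$p50)
  expect_equal(s2$p25, 0.35, tolerance = 0.06)
  # constant records collapse
  recc <- data.frame(patient_id = "P1", plan_id = "A",
                     rel_dr90 = rep(0.5, 6), excluded = FALSE)
  sc <- range_shift_summary(recc, group_by = "plan_id")
  expect_equal(sc$sd, 0)
  expect_equal(sc$p25, 0.5); expect_equal(sc$p100, 0.5)
  expect_equal(sc$n_outliers, 0)
})

test_that("variabilities follow the mean-of-SD / SD-of-mean definitions", {
  rec <- data.frame(patient_id = rep(c("A", "B"), each = 2),
                    rel_dr90 = c(1, 3, 2, 2), excluded = FALSE)
  v <- variability(rec, absolute = FALSE)
  expect_equal(v$intrapatient, sd(c(1, 3)) / 2 + sd(c(2, 2)) / 2)
  expect_equal(v$intrapatient, 0.707, tolerance = 1e-3)
  expect_equal(v$interpatient, 0)
  # identical per-patient sets: interpatient 0
  rec2 <- data.frame(patient_id = rep(c("A", "B", "C"), each = 3),
                     rel_dr90 = rep(c(1, 2, 3), 3), excluded = FALSE)
  expect_equal(variability(rec2, absolute = FALSE)$interpatient, 0)
  # homogeneity: scaling shifts scales both variabilities
  rec3 <- transform(rec, rel_dr90 = 2 * rel_dr90)
  v3 <- variability(rec3, absolute = FALSE)
  expect_equal(v3$intrapatient, 2 * v$intrapatient)
  # single-record patients get flagged
  rec4 <- data.frame(patient_id = c("A", "A", "B"),
                     rel_dr90 = c(1, 2, 5), excluded = FALSE)
  expect_true(variability(rec4)$flagged)
})

test_that("gamma analysis: identity, uniform offsets and brute-force parity", {
  v <- random_dose_volume(c(8, 8, 8), seed = 2)
  # identical volumes: gamma identically zero
  g0 <- gamma_3d(v, v)
  expect_equal(g0$pass_rate, 100)
  expect_equal(max(g0$gamma$data, na.rm = TRUE), 0)
  # +1% uniform scaling passes everywhere under a 1% local criterion
  v101 <- vol_like(v, v$data * 1.01)
  g1 <- gamma_3d(v, v101)
  expect_equal(g1$pass_rate, 100)
  # parity with the exhaustive search on a random pair
  ve <- vol_like(v, v$data * (1 + 0.012 * sin(seq_len(length(v$data)) / 40)))
  opt <- gamma_3d(v, ve)$pass_rate
  brute <- gamma_pass_rate_brute(v, ve)
  expect_lt(abs(opt - brute), 0.5)
  # all voxels below cutoff errors
  zero <- vol_like(v, array(0, dim(v$data)))
  expect_error(gamma_3d(zero, zero))
})

test_that("local gamma normalizes by the local reference dose", {
  dims <- c(6, 6, 6)
  ref <- scalar_volume(array(rep(c(1, 2), each = prod(dims) / 2), dims),
                       c(5, 5, 5))   # spacing >> dta: distance term cannot help
  ev <- vol_like(ref, ref$data * 1.015)
  g_loc <- gamma_3d(ref, ev, gamma_config(dose_criterion = 0.01, dta = 1))
  expect_lt(g_loc$pass_rate, 100)    # 1.5% > 1% local everywhere
  g_glob <- gamma_3d(ref, ev, gamma_config(dose_criterion = 0.01, dta = 1,
                                           normalization = "global"))
  # against the global max (2), the low-dose half differs by 0.75% only
  expect_gt(g_glob$pass_rate, g_loc$pass_rate)
})

test_that("DVH metrics match hand-computed toy cases", {
  dims <- c(10, 10, 10)
  vol <- scalar_volume(array(2, dims), c(10, 10, 10))  # 1 cc voxels
  mask <- array(TRUE, dims)
  m <- dvh(vol, mask)
  expect_equal(m$dmean, 2); expect_equal(m$d99, 2); expect_equal(m$d_003cc, 2)
  expect_true(all(diff(m$curve$volume_fraction) <= 0))
  # half at 2 Gy, half at 0
  arr <- array(0, dims); arr[1:5, , ] <- 2
  vol2 <- vol_like(vol, arr)
  m2 <- dvh(vol2, mask)
  expect_equal(m2$dmean, 1)
  expect_equal(m2$d99, 0)
  # 1000 voxels of 0.01 cc at 1..1000 mGy: hottest-3 rule
  sp <- rep((0.01 * 1000)^(1 / 3), 3)     # mm spacing for 0.01 cc voxels
  vol3 <- scalar_volume(array(1:1000 / 1000, dims), sp)
  m3 <- dvh(vol3, mask)
  expect_equal(m3$d_003cc, 0.998)
  # dmean equals the mask mean to machine precision
  expect_equal(m3$dmean, mean(vol3$data), tolerance = 1e-15)
  # tiny structures fall back to the maximum with a flag
  tiny <- array(FALSE, dims); tiny[1, 1, 1:2] <- TRUE
  vol4 <- scalar_volume(array(1:1000 / 1000, dims), c(1, 1, 1))
  m4 <- dvh(vol4, tiny)
  expect_true(m4$flag_small)
  expect_equal(m4$d_003cc, max(vol4$data[tiny]))
  expect_error(dvh(vol, array(FALSE, dims)), "empty")
})

test_that("OAR flags use a strict threshold and signed coverage deltas", {
  mk <- function(dmean, dmax, d99) structure(
    list(dmean = dmean, d_003cc = dmax, d99 = d99, v_cc = 1,
         flag_small = FALSE, curve = NULL), class = "dvh_metrics")
  a <- list(oar1 = mk(10, 12, 8), ptv = mk(60, 62, 60.0))
  b <- list(oar1 = mk(10.5, 12, 8), ptv = mk(60, 62, 59.5))
  fl <- oar_dose_flags(a, b)
  # difference of exactly 0.5 is not flagged (strict >)
  expect_false(fl$flagged[fl$structure == "oar1"])
  expect_equal(fl$delta_d99[fl$structure == "ptv"], 0.5)
  # identical plans: nothing flagged
  fl0 <- oar_dose_flags(a, a)
  expect_false(any(fl0$flagged))
  # above threshold flags
  cc <- list(oar1 = mk(10.51, 12, 8))
  expect_true(oar_dose_flags(cc, list(oar1 = mk(10, 12, 8)))$flagged)
  # missing structures are skipped with a warning
  expect_warning(oar_dose_flags(a, b[1]), "skipped")
})
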