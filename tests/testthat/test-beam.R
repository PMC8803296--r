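# Depth-dose models, WEPL tracing, range extraction and shift records.

test_that("pristine Bragg peaks anchor R80 at R0 with the right sharpness order", {
  for (ion in c("proton", "helium", "carbon")) {
    p <- pristine_bragg(ion, 150)
    prof <- data.frame(depth = p$depth, dose = p$dose)
    r80 <- extract_range(prof, 0.8, reference = max(p$dose))
    expect_lt(abs(r80 - 150), 0.15)
    expect_true(all(p$dose >= 0))
    # unimodal beyond the entrance: a single maximum region
    expect_lt(which.max(p$dose) * 0.1, 150)
  }
  expect_gt(straggling_sigma("proton", 150), straggling_sigma("helium", 150))
  expect_gt(straggling_sigma("helium", 150), straggling_sigma("carbon", 150))
  expect_error(pristine_bragg("proton", -5), "R0")
})

test_that("SOBP solves flat plateaus and single peaks degenerate cleanly", {
  s <- build_sobp("proton", 100, 150, n_peaks = 12)
  expect_lte(s$ripple, 0.02)
  prof <- data.frame(depth = s$depth, dose = s$dose)
  r90 <- extract_range(prof, 0.9, reference = 100)
  sg <- s$sigma
  expect_gt(r90, 150 - 3 * sg); expect_lt(r90, 150 + 3 * sg)
  # single-peak request returns the pristine peak (peak-normalized)
  s1 <- build_sobp("proton", 100, 150, n_peaks = 1)
  p <- pristine_bragg("proton", 150)
  expect_equal(max(s1$dose), 100)
  expect_equal(s1$dose / 100, p$dose / max(p$dose), tolerance = 1e-9)
  expect_error(build_sobp("proton", 150, 100), "d_dist")
})

test_that("WEPL tracing is exact in uniform media and additive", {
  vol <- make_uniform_volume(1)
  tr <- trace_wepl(vol, c(-400, 0, 0), c(1, 0, 0), step = 1)
  expect_equal(tr$wepl, tr$depth, tolerance = 1e-12)
  vol2 <- make_uniform_volume(1.05)
  tr2 <- trace_wepl(vol2, c(-400, 0, 0), c(1, 0, 0), step = 1)
  expect_equal(tr2$wepl, 1.05 * tr2$depth, tolerance = 1e-12)
  expect_true(all(diff(tr$wepl) >= 0))
  # missing the volume returns an empty trace
  miss <- trace_wepl(vol, c(0, 1e4, 0), c(1, 0, 0))
  expect_equal(nrow(miss), 0)
  # additivity: a trace started mid-way reproduces the tail (within a step)
  set.seed(4)
  arr <- array(runif(40 * 24 * 24, 0.8, 1.6), dim = c(40, 24, 24))
  v3 <- scalar_volume(arr, c(4, 4, 4), -c(39, 23, 23) / 2 * 4)
  full <- trace_wepl(v3, c(-300, 1, 2), c(1, 0, 0), step = 0.5)
  mid_o <- c(-300, 1, 2) + (attr(full, "t_entry") + 40) * c(1, 0, 0)
  tail <- trace_wepl(v3, mid_o, c(1, 0, 0), step = 0.5)
  w_full <- approx(full$depth, full$wepl, xout = 40 + tail$depth)$y
  w_head <- approx(full$depth, full$wepl, xout = 40)$y
  ok <- !is.na(w_full)
  expect_lt(max(abs((w_full - w_head) - tail$wepl[ok])), 0.8)
})

test_that("half-space WEPL matches the piecewise closed form", {
  arr <- array(1, c(100, 20, 20)); arr[51:100, , ] <- 1.5
  v <- scalar_volume(arr, c(1, 4, 4), c(0.5, 0, 0))
  tr <- trace_wepl(v, c(-50, 30, 30), c(1, 0, 0), step = 0.5)
  expect_equal(approx(tr$depth, tr$wepl, xout = 80)$y, 95, tolerance = 0.5)
})

test_that("range extraction interpolates the distal crossing exactly", {
  # linear fall-off 100% -> 0% between 100 and 110 mm
  prof <- data.frame(depth = c(0, 50, 100, 110), dose = c(100, 100, 100, 0))
  expect_equal(extract_range(prof, 0.9, reference = 100), 101)
  expect_equal(extract_range(prof, 0.8, reference = 100), 102)
  # translation equivariance
  prof2 <- transform(prof, depth = depth + 2)
  expect_equal(extract_range(prof2, 0.9, reference = 100), 103)
  # R80 is always distal to R90 on a monotone edge
  s <- build_sobp("proton", 80, 120)
  p <- data.frame(depth = s$depth, dose = s$dose)
  expect_gte(extract_range(p, 0.8, reference = 100),
             extract_range(p, 0.9, reference = 100))
  # no crossing -> flagged NA
  flat <- data.frame(depth = 0:10, dose = rep(50, 11))
  expect_true(is.na(extract_range(flat, 0.9, reference = 100)))
  expect_match(attr(extract_range(flat, 0.9, reference = 100), "reason"),
               "never reaches")
})

test_that("range extraction agrees with a dense-resampling search", {
  set.seed(11)
  for (k in 1:8) {
    dd <- runif(1, 120, 180)
    s <- build_sobp(sample(c("proton", "helium", "carbon"), 1),
                    dd - runif(1, 20, 60), dd)
    prof <- data.frame(depth = s$depth, dose = s$dose)
    for (lv in c(0.9, 0.8)) {
      fast <- extract_range(prof, lv, reference = 100)
      dense <- extract_range_dense(prof, lv, reference = 100)
      expect_lt(abs(fast - dense), 0.05)
    }
  }
})

test_that("line-dose profiles reproduce the SOBP in water and shift with SPR", {
  s <- build_sobp("proton", 100, 150)
  vol <- make_uniform_volume(1)
  beam <- beam_spec("proton", c(1, 0, 0), c(0, 0, 0), s, prescribed_dose = 2)
  prof <- line_dose_profile(vol, beam, origin = c(-400, 0, 0), step = 0.25)
  ref <- attr(prof, "reference_dose")
  expect_equal(ref, 2 * 1.1)
  # inside the plateau the profile equals the SOBP curve in geometric depth
  sel <- prof$depth > 105 & prof$depth < 145
  expect_equal(prof$dose[sel], s$fun(prof$depth[sel]) * ref / 100,
               tolerance = 1e-9)
  # determinism
  prof2 <- line_dose_profile(vol, beam, origin = c(-400, 0, 0), step = 0.25)
  expect_identical(prof$dose, prof2$dose)
  # 1% denser medium pulls the distal edge proximally by ~ R/101
  vol101 <- make_uniform_volume(1.01)
  p101 <- line_dose_profile(vol101, beam, origin = c(-400, 0, 0), step = 0.25)
  r0 <- extract_range(prof, 0.9); r1 <- extract_range(p101, 0.9)
  expect_equal(r1 - r0, -0.01 / 1.01 * r0, tolerance = 0.05)
})

test_that("range-shift records: identity, uniform scaling and swap symmetry", {
  s <- build_sobp("proton", 90, 130)
  vol <- make_uniform_volume(1, dims = c(50, 30, 30), spacing = 4)
  beam <- beam_spec("proton", c(1, 0, 0), c(20, 0, 0), s, prescribed_dose = 2)
  plan <- list(patient_id = "P1", plan_id = "T", beams = list(beam),
               target_center = c(20, 0, 0), target_semi = c(15, 15, 15))
  # identical volumes: all shifts vanish
  rec0 <- range_shift_records(vol, vol, plan, n_profiles = 5, step = 0.25)
  expect_equal(nrow(rec0), 5)
  expect_equal(max(rec0$dr90), 0)
  expect_equal(max(abs(rec0$rel_dr80)), 0)
  # uniform 1% scaling: every profile shifts by ~1%; the SECT map is denser
  # so its range is shorter and the signed relative shift is -0.99%
  vol_s <- make_uniform_volume(1.01, dims = c(50, 30, 30), spacing = 4)
  rec <- range_shift_records(vol_s, vol, plan, n_profiles = 5, step = 0.25)
  expect_true(all(abs(rec$rel_dr90 * 100 + 0.99) < 0.1))
  # swapping the maps preserves |dR| and flips the sign of the relative shift
  rec_sw <- range_shift_records(vol, vol_s, plan, n_profiles = 5, step = 0.25)
  expect_equal(rec_sw$dr90, rec$dr90, tolerance = 1e-9)
  expect_true(all(sign(rec_sw$rel_dr90) == -sign(rec$rel_dr90)))
  expect_lt(max(abs(rec_sw$rel_dr90 + rec$rel_dr90)), 1e-3)
  # mismatched grids are rejected
  expect_error(range_shift_records(vol, make_uniform_volume(1), plan),
               "different grids")
})

test_that("beam dose volumes deposit the SOBP along the field", {
  s <- build_sobp("proton", 60, 100)
  vol <- make_uniform_volume(1, dims = c(40, 20, 20), spacing = 4)
  beam <- beam_spec("proton", c(1, 0, 0), c(10, 0, 0), s,
                    field_extent = c(24, 24), ray_spacing = 4,
                    prescribed_dose = 2)
  dv <- beam_dose_volume(vol, beam, step = 1)
  expect_s3_class(dv, "scalar_volume")
  ref <- 2 * 1.1
  # plateau voxel on the central axis
  ax <- vol_axes(vol)
  i <- which.min(abs(ax$x - 2)); j <- which.min(abs(ax$y)); k <- which.min(abs(ax$z))
  d_geom <- ax$x[i] + 78  # entry at x = -78
  expect_equal(dv$data[i, j, k], s$fun(d_geom) * ref / 100, tolerance = 0.02 * ref)
  # outside the field no dose
  expect_equal(max(dv$data[, c(1, 20), ]), 0)
  # plan dose sums beams
  pv <- plan_dose_volume(vol, list(beam, beam), step = 1)
  expect_equal(pv$data, 2 * dv$data, tolerance = 1e-12)
})
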