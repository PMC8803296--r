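# The spectral (DLCT) SPR chain: kinematics, Bethe formula, EAN and I-value
# models, composition oracles.

test_that("beta squared follows relativistic kinematics", {
  # closed form 1 - (1 + E/Mc2)^-2 at 100 MeV proton
  expect_equal(beta_squared(bethe_params(100)),
               1 - (1 + 100 / 938.272)^-2, tolerance = 1e-12)
  expect_equal(beta_squared(bethe_params(100)), 0.1833514, tolerance = 1e-6)
  # vanishes with energy
  expect_lt(beta_squared(bethe_params(1e-6)), 1e-8)
  # depends only on E / Mc^2
  expect_equal(beta_squared(bethe_params(100, particle_rest_energy = 938.272)),
               beta_squared(bethe_params(400, particle_rest_energy = 4 * 938.272)))
  expect_error(bethe_params(-5), "kinetic_energy")
})

test_that("Bethe SPR obeys the water identity, linearity and monotonicity", {
  expect_equal(spr_bethe(1, 78.73), 1, tolerance = 1e-15)
  expect_equal(spr_bethe(1.05, 78.73), 1.05, tolerance = 1e-15)
  expect_gt(spr_bethe(1, 70), spr_bethe(1, 90))
  # linear in ED at fixed I
  expect_equal(spr_bethe(2, 100), 2 * spr_bethe(1, 100))
  expect_equal(spr_bethe(0, 100), 0)
  expect_error(spr_bethe(1, 1e9), "non-physical")
  expect_error(spr_bethe(-0.1, 78.73), "ed")
})

test_that("EAN from composition is an electron-weighted power mean", {
  o2 <- tissue_composition("oxygen", 1.4, c(O = 1))
  expect_equal(ean_from_composition(o2, 2.94), 8)
  expect_equal(ean_from_composition(o2, 1.5), 8)
  w <- water_composition()
  lam <- electron_fractions(w)
  expect_equal(ean_from_composition(w, 2.94),
               (lam[["H"]] * 1 + lam[["O"]] * 8^2.94)^(1 / 2.94))
  expect_equal(ean_from_composition(w, 2.94), 7.4167, tolerance = 1e-4)
  # adding calcium raises EAN
  tis <- reference_tissues()
  mixed <- tissue_mixture(tis$soft_tissue, tis$cortical_bone, 0.2)
  expect_gt(ean_from_composition(mixed), ean_from_composition(tis$soft_tissue))
})

test_that("Bragg-additivity I-value behaves as a log-average", {
  o2 <- tissue_composition("oxygen", 1.4, c(O = 1))
  expect_equal(ivalue_from_composition(o2),
               element_table()[element_table()$symbol == "O", "I_eV"])
  w <- water_composition()
  iw <- ivalue_from_composition(w)
  # Bragg additivity is approximate for water; residual against the adopted
  # 78.73 eV stays below 10 eV
  expect_lt(abs(iw - 78.73), 10)
  # bounded by the elemental extremes (convexity of the log-average)
  tis <- reference_tissues()
  for (t in tis) {
    ivals <- element_table()[match(names(t$fractions),
                                   element_table()$symbol), "I_eV"]
    iv <- ivalue_from_composition(t)
    expect_gte(iv, min(ivals)); expect_lte(iv, max(ivals))
  }
})

test_that("ground-truth SPR is water-normalized and density-linear", {
  w <- water_composition()
  expect_equal(ground_truth_spr(w), 1, tolerance = 1e-15)
  tis <- reference_tissues()
  for (t in tis[setdiff(names(tis), "air")]) {
    spr <- ground_truth_spr(t)
    ed <- relative_electron_density(t)
    expect_lt(abs(spr - ed) / ed, 0.3)   # L-ratio stays near 1 for tissue
    t2 <- tissue_composition(t$name, 2 * t$density, t$fractions)
    expect_equal(ground_truth_spr(t2), 2 * spr, tolerance = 1e-12)
  }
})

test_that("effective I-value reconciles Bragg additivity with the water anchor", {
  w <- water_composition()
  expect_equal(effective_ivalue(w), 78.73, tolerance = 1e-9)
  # by construction the chain with I_eff reproduces the ground truth exactly
  tis <- reference_tissues()
  for (t in tis[c("brain", "adipose", "cortical_bone")]) {
    expect_equal(spr_bethe(relative_electron_density(t), effective_ivalue(t)),
                 ground_truth_spr(t), tolerance = 1e-12)
  }
})

test_that("EAN-to-I model: anchor, exact recovery, cross-validation", {
  tis <- hlut_reference_tissues()
  m <- fit_ean_i_model(tis)
  ean_w <- ean_from_composition(water_composition())
  expect_equal(ivalue_from_ean(m, ean_w), 78.73, tolerance = 1e-9)

  # consistent data: tissues whose (EAN, ln I_eff) lie exactly on the
  # interpolating polyline are recovered exactly by the interpolate method
  mi <- fit_ean_i_model(tis, method = "interpolate")
  for (t in tis[c("brain", "spongiosa", "cortical_bone")]) {
    expect_equal(ivalue_from_ean(mi, ean_from_composition(t)),
                 effective_ivalue(t), tolerance = 1e-9)
  }

  # leave-one-out residual on the embedded table stays below 5 eV
  loo <- vapply(names(tis)[names(tis) != "air"], function(nm) {
    mm <- fit_ean_i_model(tis[setdiff(names(tis), nm)])
    abs(ivalue_from_ean(mm, ean_from_composition(tis[[nm]])) -
          effective_ivalue(tis[[nm]]))
  }, 0)
  expect_lt(max(loo), 5)

  # too few points per segment errors out
  expect_error(fit_ean_i_model(tis[c("water", "brain", "muscle", "csf")],
                               knots = c(8, 9.5, 11, 12.5)),
               "underdetermined")
  # JSON round trip
  path <- tempfile(fileext = ".json")
  write_ean_i_model(m, path)
  m2 <- read_ean_i_model(path)
  expect_equal(m2$breakpoints$ln_i, m$breakpoints$ln_i, tolerance = 1e-12)
})

test_that("the DLCT volume chain is linear in ED and floors air", {
  m <- default_ean_i_model()
  ean_w <- ean_from_composition(water_composition())
  ed <- array(1, c(4, 4, 4))
  ean <- array(ean_w, c(4, 4, 4))
  expect_equal(max(abs(predict_spr_dlct(ed, ean, m) - 1)), 0, tolerance = 1e-12)
  # linearity in ED at fixed EAN
  s1 <- predict_spr_dlct(ed, ean, m)
  s2 <- predict_spr_dlct(1.01 * ed, ean, m)
  expect_equal(s2, 1.01 * s1, tolerance = 1e-12)
  # air floor
  ed[1, 1, 1] <- 0.001
  expect_equal(predict_spr_dlct(ed, ean, m)[1, 1, 1], 0.001)
  # grid mismatch errors
  va <- scalar_volume(ed, c(1, 1, 1)); vb <- scalar_volume(ean, c(2, 2, 2))
  expect_error(predict_spr_dlct(va, vb, m), "grid")
})

test_that("SPR is insensitive to the evaluation energy across 80-200 MeV", {
  tis <- reference_tissues()
  for (nm in setdiff(names(tis), "air")) {
    t <- tis[[nm]]
    rel <- abs(ground_truth_spr(t, bethe_params(80)) -
                 ground_truth_spr(t, bethe_params(200))) / ground_truth_spr(t)
    lim <- if (ean_from_composition(t) > 8.5) 0.006 else 0.002
    expect_lt(rel, lim)
  }
})
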