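p_ref <- spina_parameters()

test_that("SPINA estimators invert the generating gains at the healthy
           steady state", {
  ss <- ref_steady()
  expect_equal(spina_gbeta(ss$G_inf, ss$I_inf) * 1e12, 2.8,
               tolerance = 1e-9)
  expect_equal(spina_gr(ss$G_inf, ss$I_inf), 2.3, tolerance = 1e-9)
  expect_equal(spina_gbeta(4e-3, 0), 0)
})

test_that("SPINA estimators match direct evaluation of their formulas", {
  # independently computed by brute-force substitution of the defaults
  expect_equal(spina_gbeta(3e-3, 100e-12) * 1e12, 5.6667,
               tolerance = 1e-4)
  expect_equal(spina_gr(5e-3, 60e-12), 2.0185, tolerance = 1e-4)
  # at the open-loop glucose G1*P no insulin action is required
  G_open <- asia_gain(0.11, 7.1e-4) * 150e-6
  expect_equal(spina_gr(G_open, 60e-12), 0, tolerance = 1e-9)
})

test_that("round-trip recovery is exact across random parameter sets", {
  set.seed(41)
  for (i in 1:200) {
    p <- random_params()
    ss <- equifinal_state(p)
    expect_equal(spina_gbeta(ss$G_inf, ss$I_inf, p), p$Gbeta,
                 tolerance = 1e-9)
    expect_equal(spina_gr(ss$G_inf, ss$I_inf, p), p$GR,
                 tolerance = 1e-9)
  }
})

test_that("SPINA-GBeta rises with insulin and falls with glucose;
           SPINA-GR falls with insulin", {
  g <- seq(2e-3, 10e-3, length.out = 50)
  i <- seq(10e-12, 500e-12, length.out = 50)
  expect_true(all(diff(spina_gbeta(4e-3, i)) > 0))
  expect_true(all(diff(spina_gbeta(g, 60e-12)) < 0))
  expect_true(all(diff(spina_gr(4e-3, i)) < 0))
})

test_that("scalar domain violations raise errors, vector ones yield NA", {
  expect_error(spina_gbeta(0, 60e-12), "G > 0")
  expect_error(spina_gr(4e-3, 0), "I > 0")
  v <- spina_gbeta(c(4e-3, 0, 5e-3), c(60e-12, 60e-12, 60e-12))
  expect_true(is.na(v[2]) && !anyNA(v[c(1, 3)]))
})

test_that("comparator indices match their conventional formulas", {
  expect_equal(homa_ir(5, 10), 2.2222, tolerance = 1e-4)
  expect_equal(homa_ir(22.5, 1), 1)
  expect_equal(homa_ir(4.5, 5), 1)
  expect_equal(homa_beta(5, 10), 133.33, tolerance = 1e-4)
  expect_equal(quicki(90.09, 10), 0.33847, tolerance = 1e-4)
  expect_equal(quicki(10, 10), 0.5)
  expect_lt(quicki(90.09, 20), quicki(90.09, 10))
})

test_that("HOMA-Beta has a blind zone at low glucose where SPINA-GBeta
           stays defined", {
  expect_error(homa_beta(3.5, 10), class = "spina_blind_zone_error")
  expect_error(homa_beta(3.0, 50), class = "spina_blind_zone_error")
  # vectorised: flagged as NA, never a negative value presented as valid
  v <- homa_beta(c(5, 3.4, 2.8), c(10, 10, 50))
  expect_false(is.na(v[1]))
  expect_true(all(is.na(v[2:3])))
  # the same low-glucose sample has a finite SPINA-GBeta
  expect_true(is.finite(spina_gbeta(3.0e-3, 50 * 6 * 1e-12)))
})

test_that("compute_panel reproduces the round-trip fixture and flags
           blind-zone rows", {
  coh <- data.frame(subject_id = c("a", "b"), visit = c(1L, 1L),
                    glucose = c(4.3378, 3.0), insulin = c(63.02, 50))
  panel <- compute_panel(coh, glucose_unit = "mmol/L",
                         insulin_unit = "pmol/L")
  expect_equal(panel$spina_gbeta_pmol_s[1], 2.80, tolerance = 1e-3)
  expect_equal(panel$spina_gr_mol_s[1], 2.30, tolerance = 1e-3)
  expect_equal(panel$flag_homa_beta, c("ok", "blind_zone"))
  expect_true(is.na(panel$homa_beta[2]))
  expect_true(is.finite(panel$spina_gbeta_pmol_s[2]))
})

test_that("compute_panel propagates missing values and requires units", {
  coh <- data.frame(subject_id = c("a", "b"), visit = c(1L, 1L),
                    glucose = c(5, NA), insulin = c(60, 60))
  panel <- compute_panel(coh, glucose_unit = "mmol/L",
                         insulin_unit = "pmol/L")
  expect_true(is.na(panel$spina_gbeta_pmol_s[2]))
  expect_equal(panel$flag_spina_gbeta[2], "missing_input")

  empty <- coh[0, ]
  ep <- compute_panel(empty, glucose_unit = "mmol/L",
                      insulin_unit = "pmol/L")
  expect_equal(nrow(ep), 0)

  expect_error(compute_panel(coh), "unit")
})

test_that("compute_panel flags negative receptor-gain estimates without
           clipping them", {
  # glucose above the open-loop value is inconsistent with the model
  coh <- data.frame(subject_id = "x", visit = 1L,
                    glucose = 30, insulin = 60)
  panel <- compute_panel(coh, glucose_unit = "mmol/L",
                         insulin_unit = "pmol/L")
  expect_lt(panel$spina_gr_mol_s, 0)
  expect_equal(panel$flag_spina_gr, "negative")
})
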