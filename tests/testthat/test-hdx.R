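test_that("percent exchange computes the centroid-normalised uptake", {
  r <- percent_exchange(c(10, 60, 180), c(1000, 1004, 1010),
                        m_0 = 1000, m_f = 1010, start_res = 820, end_res = 830)
  expect_equal(unname(r$percent), c(0, 40, 100))
  expect_equal(r$median_residue, 825)
  expect_error(percent_exchange(10, 1000, 1000, 1000), "degenerate")
  # replicate aggregation: mean and SD across rows
  m <- rbind(c(1004, 1008), c(1006, 1010))
  r2 <- percent_exchange(c(10, 60), m, 1000, 1010)
  expect_equal(unname(r2$percent), c(50, 90))
  expect_equal(unname(r2$sd), c(sd(c(40, 60)), sd(c(80, 100))))
})

test_that("percent exchange is invariant to adding a constant to all masses", {
  set.seed(5)
  for (shift in c(-100, 3.7, 500)) {
    m0 <- 1200; mf <- 1212; mt <- runif(4, m0, mf)
    a <- percent_exchange(c(10, 60, 180, 600), mt, m0, mf)
    b <- percent_exchange(c(10, 60, 180, 600), mt + shift, m0 + shift, mf + shift)
    expect_equal(a$percent, b$percent, tolerance = 1e-9)
  }
})

test_that("theoretical fully-deuterated mass follows the amide-count convention", {
  # length 10, one proline after position 1 -> 8 exchangeable amides
  expect_identical(exchangeable_amides("LPGAEEKEYH"), 8L)
  # N-terminal proline does not subtract
  expect_identical(exchangeable_amides("PLGAEEKEYH"), 9L)
  expect_equal(theoretical_mf("LPGAEEKEYH", 1000), 1000 + 0.95 * 8 * 1.00628)
})

test_that("residue mapping prefers the shortest then most C-terminal peptide", {
  # shortest wins: 821-827 over 820-830
  recs <- list(make_record(820, 830, 50), make_record(821, 827, 70))
  m <- map_to_residues(recs)
  expect_equal(m$percent[m$residue == 825], 70)
  # outside the short peptide the long one is used
  expect_equal(m$percent[m$residue == 829], 50)
  # equal-length tie: C-terminal retention picks 821-828
  recs2 <- list(make_record(820, 827, 40), make_record(821, 828, 60))
  m2 <- map_to_residues(recs2)
  expect_equal(m2$percent[m2$residue == 824], 60)
  # single peptide covering a residue
  m3 <- map_to_residues(list(make_record(900, 905, 33)))
  expect_true(all(m3$percent == 33))
  # uncovered residues flagged, not interpolated
  m4 <- map_to_residues(list(make_record(820, 822, 10), make_record(826, 828, 20)))
  expect_false(m4$covered[m4$residue == 824])
  expect_true(is.na(m4$percent[m4$residue == 824]))
  # permutation invariance
  expect_identical(map_to_residues(recs2), map_to_residues(rev(recs2)))
  # empty input
  expect_identical(nrow(map_to_residues(list())), 0L)
})

test_that("envelope deconvolution selects components and recovers fractions", {
  # pure single Gaussian -> one component
  env1 <- mixture_envelope(1100, 0.5, 1)
  f1 <- fit_envelope(env1$mz, env1$intensity)
  expect_identical(f1$n_components, 1L)
  expect_identical(f1$regime, "unimodal")
  expect_equal(f1$means, 1100, tolerance = 1e-3)
  # well-separated mixture (4/charge Th at z=1, equal widths 0.5)
  set.seed(21)
  env2 <- mixture_envelope(c(1100, 1104), c(0.5, 0.5), c(0.6, 0.4))
  noisy <- env2$intensity * (1 + rnorm(length(env2$intensity), 0, 0.01))
  noisy[noisy < 0] <- 0
  f2 <- fit_envelope(env2$mz, noisy)
  expect_identical(f2$n_components, 2L)
  expect_identical(f2$regime, "bimodal")
  expect_lt(abs(f2$folded_fraction - 0.6), 0.05)
  expect_lt(abs(f2$unfolded_fraction - 0.4), 0.05)
  expect_lt(f2$means[1], f2$means[2])
  # overlapping mixture: separation < 1.5x width -> fused-bimodal
  env3 <- mixture_envelope(c(1100, 1100.6), c(0.5, 0.5), c(0.5, 0.5))
  f3 <- fit_envelope(env3$mz, env3$intensity)
  expect_true(f3$regime %in% c("fused-bimodal", "unimodal"))
  expect_error(fit_envelope(1:5, rep(1, 5)), "10")
})

test_that("fraction recovery stays within 0.05 when separation >= 2x width", {
  set.seed(31)
  for (sep_mult in c(2, 3, 4)) {
    for (frac in c(0.25, 0.5, 0.75)) {
      w <- 0.5
      env <- mixture_envelope(c(1200, 1200 + sep_mult * w), c(w, w),
                              c(frac, 1 - frac))
      noisy <- pmax(env$intensity * (1 + rnorm(length(env$mz), 0, 0.01)), 0)
      f <- fit_envelope(env$mz, noisy)
      expect_identical(f$n_components, 2L,
                       label = sprintf("sep %gx frac %g", sep_mult, frac))
      expect_lt(abs(f$folded_fraction - frac), 0.05)
    }
  }
})

test_that("regime classification recovers generator truth", {
  # EX1: fixed means, folded fraction decaying
  fits_ex1 <- lapply(c(0.8, 0.5, 0.2), function(f) {
    env <- mixture_envelope(c(1100, 1105), c(0.5, 0.5), c(f, 1 - f))
    fit_envelope(env$mz, env$intensity)
  })
  expect_identical(classify_exchange_regime(fits_ex1), "EX1")
  # EX2: single component, centroid drifting up
  fits_ex2 <- lapply(c(1100, 1102, 1104), function(m) {
    env <- mixture_envelope(m, 0.8, 1)
    fit_envelope(env$mz, env$intensity)
  })
  expect_identical(classify_exchange_regime(fits_ex2), "EX2")
  # fused: persistent unresolved two-component envelopes
  fits_fused <- lapply(c(0.7, 0.4), function(f) {
    env <- mixture_envelope(c(1100, 1100.5), c(0.5, 0.5), c(f, 1 - f))
    fit_envelope(env$mz, env$intensity)
  })
  expect_true(classify_exchange_regime(fits_fused) %in%
                c("fused-bimodal", "EX2"))
  expect_error(classify_exchange_regime(fits_ex1[1]), "2 timepoints")
})

test_that("regime recovery is exact on generated series with good separation", {
  # end-to-end: generator -> envelope fits -> regime, across seeds
  for (seed in 1:3) {
    ex1 <- gen_hdx_series(hdx_scenario("HRDLAARNVLV", 835, 845, charge = 1L,
                                       m0 = 1200, k_open = 0.01,
                                       envelope_width = 0.8,
                                       noise_sd = 0.005, seed = seed))
    fits <- lapply(ex1$envelopes, function(e) fit_envelope(e$mz, e$intensity))
    expect_identical(classify_exchange_regime(fits), "EX1",
                     label = sprintf("EX1 seed %d", seed))
    ex2 <- gen_hdx_series(hdx_scenario("HRDLAARNVLV", 835, 845, charge = 1L,
                                       m0 = 1200, k_ex = 0.005,
                                       envelope_width = 2.5,
                                       noise_sd = 0.005, seed = seed))
    fits2 <- lapply(ex2$envelopes, function(e) fit_envelope(e$mz, e$intensity))
    expect_identical(classify_exchange_regime(fits2), "EX2",
                     label = sprintf("EX2 seed %d", seed))
  }
})

test_that("differential exchange flags variants outside the wild-type band", {
  wt <- list(make_record(820, 830, 50), make_record(840, 850, 30))
  # identical inputs: all zero, no flags
  d0 <- differential_exchange(wt, wt)
  expect_true(all(d0$delta_percent == 0))
  expect_false(any(d0$outside_band))
  # +10% shift against SD 2% -> flagged; within-band shift -> not
  var <- list(make_record(820, 830, 60), make_record(840, 850, 30.5))
  var[[1]]$sd <- 2
  wt[[1]]$sd <- 2; wt[[2]]$sd <- 1
  d1 <- differential_exchange(var, wt)
  expect_true(d1$outside_band[d1$start_res == 820])
  expect_false(d1$outside_band[d1$start_res == 840])
  # unmatched peptides excluded with a message
  expect_message(
    d2 <- differential_exchange(list(make_record(900, 910, 10)), wt),
    "no wild-type match")
  expect_identical(nrow(d2), 0L)
})

test_that("ligand occupancy solves the exact binding quadratic", {
  # HDX labelling conditions: 0.39 uM TKD, 0.78 uM erlotinib, Kd 5 nM
  occ <- ligand_occupancy(0.39, 0.78, 0.005)
  expect_equal(occ, 0.987, tolerance = 1e-3)
  expect_gt(occ, 0.90)
  # saturation limit and zero-ligand limit
  expect_equal(ligand_occupancy(0.1, 1e6, 0.01), 1, tolerance = 1e-4)
  expect_identical(ligand_occupancy(0.1, 0, 0.01), 0)
  # conservation: bound fraction never exceeds ligand/protein ratio
  expect_lte(ligand_occupancy(1, 0.5, 1e-9) * 1, 0.5 + 1e-9)
})
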