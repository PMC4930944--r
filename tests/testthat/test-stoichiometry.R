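test_that("mass to carbon-mole conversion follows the registry", {
  expect_equal(to_cmol(60.052, "acetate"), 2, tolerance = 1e-9)
  expect_equal(to_cmol(30.974, "ortho-p"), 1, tolerance = 1e-9)
  expect_equal(to_cmol(0, "propionate"), 0)
  expect_equal(to_cmol(74.079, "propionate"), 3, tolerance = 1e-9)
  expect_error(to_cmol(1, "caviar"), "unknown compound")
})

test_that("noise-free cycles reproduce the end-member stoichiometry", {
  r_pao <- transformation_ratios(generate_cycle(cycle_spec(f_pao = 1)))
  expect_equal(r_pao$p_vfa, 0.5, tolerance = 1e-9)
  expect_equal(r_pao$gly_vfa, 0.5, tolerance = 1e-9)
  expect_equal(r_pao$phb_vfa, 1.33, tolerance = 1e-9)
  expect_equal(r_pao$phv_vfa, 0, tolerance = 1e-9)
  r_gao <- transformation_ratios(generate_cycle(cycle_spec(f_pao = 0)))
  expect_equal(r_gao$p_vfa, 0, tolerance = 1e-9)
  expect_equal(r_gao$gly_vfa, 1.12, tolerance = 1e-9)
  expect_equal(r_gao$phb_vfa, 1.36, tolerance = 1e-9)
  expect_equal(r_gao$phv_vfa, 0.46, tolerance = 1e-9)
  # half-and-half mixture: linear mixing
  r_mix <- transformation_ratios(generate_cycle(cycle_spec(f_pao = 0.5)))
  expect_equal(r_mix$p_vfa, 0.25, tolerance = 1e-9)
})

test_that("cycle series respect the configured phase structure and feed split", {
  s <- cycle_spec(f_pao = 0.6)
  cyc <- generate_cycle(s)
  expect_true(all(diff(cyc$time_min) > 0))
  expect_true(all(cyc$phase %in% c("anaerobic", "aerobic")))
  an <- cyc[cyc$phase == "anaerobic", ]
  expect_equal(an$hac_cmmol[1] / (an$hac_cmmol[1] + an$hpr_cmmol[1]), 0.75)
  expect_equal(an$hac_cmmol[nrow(an)], 0, tolerance = 1e-9)
  # aerobic: PHA drains, glycogen replenishes, P drops below its start
  ae <- cyc[cyc$phase == "aerobic", ]
  expect_lt(ae$phb_cmmol[nrow(ae)], max(cyc$phb_cmmol))
  expect_equal(ae$gly_cmmol[nrow(ae)], an$gly_cmmol[1], tolerance = 1e-9)
  expect_lt(ae$po4_pmmol[nrow(ae)], an$po4_pmmol[1])
  # determinism with noise
  s2 <- cycle_spec(f_pao = 0.6, noise_sd_rel = 0.02, seed = 5)
  expect_identical(generate_cycle(s2), generate_cycle(s2))
  f <- tempfile(fileext = ".csv")
  write_cycle(cyc, f)
  expect_equal(read_cycle(f)$po4_pmmol, cyc$po4_pmmol, tolerance = 1e-9)
})

test_that("ratios are scale invariant and reject uptake-free series", {
  cyc <- generate_cycle(cycle_spec(f_pao = 0.4))
  r1 <- transformation_ratios(cyc)
  cyc2 <- cyc
  conc <- c("hac_cmmol", "hpr_cmmol", "po4_pmmol", "gly_cmmol",
            "phb_cmmol", "phv_cmmol")
  cyc2[conc] <- lapply(cyc2[conc], function(v) 2 * v)
  r2 <- transformation_ratios(cyc2)
  for (k in c("p_vfa", "gly_vfa", "pha_vfa", "phb_vfa", "phv_vfa")) {
    expect_equal(r2[[k]], r1[[k]], tolerance = 1e-9)
  }
  flat <- cyc
  flat$hac_cmmol <- 1; flat$hpr_cmmol <- 1
  expect_error(transformation_ratios(flat), "no anaerobic uptake")
  expect_error(transformation_ratios(cyc[cyc$phase == "aerobic", ]),
               "anaerobic phase")
})

test_that("rate-based ratios agree with endpoint ratios on linear cycles", {
  cyc <- generate_cycle(cycle_spec(f_pao = 0.7))
  re <- transformation_ratios(cyc)
  rr <- transformation_ratios(cyc, method = "rate", rate_window_min = 60)
  expect_equal(rr$p_vfa, re$p_vfa, tolerance = 1e-6)
  expect_equal(rr$gly_vfa, re$gly_vfa, tolerance = 1e-6)
})

test_that("mixing estimator inverts the linear model and clips out-of-range", {
  expect_equal(pao_fraction(ratio_set(0.3, 0.59, 1.16, 0.56))$f_pao, 0.6,
               tolerance = 1e-12)
  obs_pao <- ratio_set(0.5, 0.5, 1.33, 0)
  expect_equal(pao_fraction(obs_pao)$f_pao, 1)
  expect_warning(est <- pao_fraction(ratio_set(0.6, 0.5, 1.3, 0)), "clipped")
  expect_equal(est$f_pao, 1)
  expect_true(est$clipped)
  same <- reference_stoichiometry("GAO", 0.5, 1, 1.8, 1.4, 0.4)
  expect_error(pao_fraction(ratio_set(0.3, 0.5, 1, 0.2), gao_ref = same),
               "distinct")
})

test_that("mixing estimate is strictly increasing in the observed P/VFA", {
  f <- vapply(seq(0.01, 0.49, by = 0.04), function(p) {
    pao_fraction(ratio_set(p, 0.8, 1.3, 0.2))$f_pao
  }, 0)
  expect_true(all(diff(f) > 0))
})

test_that("least-squares basis recovers mixtures from full ratio sets", {
  for (f in c(0.2, 0.5, 0.8)) {
    obs <- transformation_ratios(generate_cycle(cycle_spec(f_pao = f)))
    est <- pao_fraction(obs, basis = "least_squares")
    expect_equal(est$f_pao, f, tolerance = 1e-9)
    expect_true(all(abs(est$residuals$residual) < 1e-9))
  }
})

test_that("parameter recovery: 1% noise, nine mixtures, 100 seeds each", {
  for (f in seq(0.1, 0.9, by = 0.1)) {
    est <- vapply(1:100, function(s) {
      cyc <- generate_cycle(cycle_spec(f_pao = f, noise_sd_rel = 0.01,
                                       seed = s))
      pao_fraction(transformation_ratios(cyc))$f_pao
    }, 0)
    expect_lt(abs(mean(est) - f), 0.05)
    expect_lt(stats::sd(est), 0.05)
  }
})

test_that("betweenness check reports each ratio against the reference span", {
  obs <- ratio_set(0.3, 0.59, 1.16, 0.56)
  bc <- betweenness_check(obs)
  expect_equal(bc$status[bc$ratio == "p_vfa"], "inside")
  # PHV/VFA 0.56 exceeds the GAO end member 0.46
  expect_equal(bc$status[bc$ratio == "phv_vfa"], "above")
  mid <- ratio_set(0.25, 0.81, 1.345, 0.23)
  expect_true(all(betweenness_check(mid)$status == "inside"))
})

test_that("the side-by-side report shows both conventions without forcing agreement", {
  rep <- pao_fraction_report(ratio_set(0.3, 0.59, 1.16, 0.56),
                             rate_based_pct = 58)
  expect_equal(rep$f_pao_pct[rep$method == "endpoint_p_vfa"], 60)
  expect_equal(rep$f_pao_pct[rep$method == "rate_based"], 58)
  expect_equal(attr(rep, "difference_pp"), 2)
})
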