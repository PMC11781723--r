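test_that("arterial diameter matches independent evaluation of the regression", {
  # oracle: hand-computed regression at the reference cohort means
  bmi <- 63.80 / (158.1 / 100)^2
  expected <- -0.258 + 0.029 * 158.1 + 0.006 * 40.35 + 0.036 * bmi
  expect_equal(artery_diameter(table3_means), expected, tolerance = 1e-12)
  expect_equal(artery_diameter(table3_means), 5.488, tolerance = 1e-3)
})

test_that("diameter grows with age and weight", {
  base <- table3_means
  older <- base; older$age_years <- base$age_years + 10
  heavier <- base; heavier$weight_kg <- base$weight_kg + 10
  expect_gt(artery_diameter(older), artery_diameter(base))
  expect_gt(artery_diameter(heavier), artery_diameter(base))
})

test_that("wall thickness matches independent evaluation and its limit", {
  bmi <- 63.80 / (158.1 / 100)^2
  expected <- 0.25 + 0.005 * 40.35 + 0.005 * bmi
  expect_equal(wall_thickness(table3_means), expected, tolerance = 1e-12)
  expect_equal(wall_thickness(table3_means), 0.5794, tolerance = 1e-3)
  # intercept limit as age and mass vanish
  tiny <- suppressWarnings(wall_thickness(
    data.frame(height_cm = 170, weight_kg = 1e-6, age_years = 1e-6)))
  expect_equal(tiny, 0.25, tolerance = 1e-6)
  older <- table3_means; older$age_years <- 60
  expect_gt(wall_thickness(older), wall_thickness(table3_means))
})

test_that("fixed-variant parameters are the literature constants", {
  par <- build_parameters("fixed")
  expect_equal(par$L_m, 0.2)
  expect_equal(par$D_s, 0.01)
  expect_equal(par$D_d, 0.01)
  expect_equal(par$h, 0.001)
})

test_that("demographic parameters compose geometry with the regressions", {
  geom <- vessel_length_difference(800, 350, 250, 160)  # L = 20 cm
  par <- build_parameters("demographic", demo = table3_means, geometry = geom)
  expect_equal(par$L_m, 0.20)
  expect_equal(par$D_d, artery_diameter(table3_means))
  expect_equal(par$h, wall_thickness(table3_means))
  expect_error(build_parameters("demographic", demo = table3_means),
               "requires both")
})

test_that("pressure-model round trip is exact for both variants and branches", {
  geom <- vessel_length_difference(800, 350, 250, 160)
  variants <- list(
    fixed = build_parameters("fixed"),
    demographic = build_parameters("demographic", demo = table3_means,
                                   geometry = geom))
  for (par in variants) {
    for (bp in c(85, 120, 202)) {
      for (branch in c("systolic", "diastolic")) {
        ptt <- invert_ptt(bp, par, branch)
        est <- estimate_bp(list(ptt_s = ptt, ptt_d = ptt), par)
        got <- if (branch == "systolic") est$sbp_mmHg else est$dbp_mmHg
        expect_lt(abs(got - bp), 1e-9)
      }
    }
  }
})

test_that("the wave-speed consistency identity holds for every estimate", {
  k <- model_constants()
  geom <- vessel_length_difference(812, 355, 247, 161.5)
  par <- build_parameters("demographic", demo = table3_means, geometry = geom)
  for (bp in seq(85, 200, by = 23)) {
    ptt <- invert_ptt(bp, par, "systolic")
    est <- estimate_bp(list(ptt_s = ptt, ptt_d = ptt), par)
    lhs <- est$pwv_s^2 * k$rho * est$D_s
    rhs <- est$h * k$E0 * exp(k$alpha * est$sbp_mmHg)
    expect_lt(abs(lhs - rhs) / rhs, 1e-9)
  }
})

test_that("pressure is monotone decreasing in transit time", {
  par <- build_parameters("fixed")
  ptts <- seq(0.1, 0.5, by = 0.05)
  sbp <- estimate_bp(list(ptt_s = ptts, ptt_d = ptts), par)$sbp_mmHg
  expect_true(all(diff(sbp) < 0))
})

test_that("doubling the path length raises pressure by (2/alpha) log 2", {
  k <- model_constants()
  par1 <- build_parameters("fixed")
  par2 <- par1; par2$L_m <- 2 * par1$L_m
  b1 <- estimate_bp(list(ptt_s = 0.25, ptt_d = 0.25), par1)$sbp_mmHg
  b2 <- estimate_bp(list(ptt_s = 0.25, ptt_d = 0.25), par2)$sbp_mmHg
  expect_equal(b2 - b1, (2 / k$alpha) * log(2), tolerance = 1e-10)
})

test_that("the inversion is decreasing in pressure and linear in length", {
  par <- build_parameters("fixed")
  p1 <- invert_ptt(c(85, 120, 202), par, "systolic")
  expect_true(all(diff(p1) < 0))
  par2 <- par; par2$L_m <- 3 * par$L_m
  expect_equal(invert_ptt(120, par2, "systolic"),
               3 * invert_ptt(120, par, "systolic"))
})

test_that("degenerate model inputs are rejected", {
  par <- build_parameters("fixed")
  expect_error(estimate_bp(list(ptt_s = 0, ptt_d = 0.2), par), "PTT <= 0")
  expect_error(estimate_bp(list(ptt_s = -1, ptt_d = 0.2), par), "PTT <= 0")
  expect_error(build_parameters("demographic", demo = table3_means,
                                geometry = -5), "L <= 0")
})

test_that("variant divergence follows the closed-form identity at equal PTT", {
  k <- model_constants()
  geom <- vessel_length_difference(800, 350, 250, 160)
  par_d <- build_parameters("demographic", demo = table3_means, geometry = geom)
  par_f <- build_parameters("fixed")
  ptt <- 0.22
  bd <- estimate_bp(list(ptt_s = ptt, ptt_d = ptt), par_d)$sbp_mmHg
  bf <- estimate_bp(list(ptt_s = ptt, ptt_d = ptt), par_f)$sbp_mmHg
  predicted <- (1 / k$alpha) *
    log((par_d$L_m^2 * par_d$D_s / par_d$h) / (par_f$L_m^2 * par_f$D_s / par_f$h))
  expect_equal(bd - bf, predicted, tolerance = 1e-9)
})

test_that("physiologically inconsistent estimates carry quality flags", {
  par <- build_parameters("fixed")
  ptt_s <- invert_ptt(80, par, "systolic")   # lower SBP than DBP below
  ptt_d <- invert_ptt(120, par, "diastolic")
  est <- estimate_bp(list(ptt_s = ptt_s, ptt_d = ptt_d), par)
  expect_true(any(grepl("SBP <= DBP", attr(est, "qc"))))
})
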