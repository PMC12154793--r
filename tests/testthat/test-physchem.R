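# Closed-form encoding physics and electrochemistry.

test_that("b-value matches an SI dimensional-analysis oracle and printed pairs", {
  # independent oracle: compute in SI from first principles, convert at the end
  b_si_oracle <- function(tau_ms, g) {
    gamma <- 2.6752218744e8 # rad/s/T
    tau <- tau_ms / 1000    # s
    b <- (2 / 3) * gamma^2 * g^2 * tau^3 # s/m^2
    b * (1e3 / 1e12)        # ms/um^2
  }
  for (tau in c(0.05, 0.2, 0.593, 0.735, 1.4)) {
    expect_equal(b_value(tau, 15.3), b_si_oracle(tau, 15.3),
                 tolerance = 1e-12)
  }
  # printed encoding pairs at g = 15.3 T/m, to their printed precision
  expect_equal(round(b_value(0.200, 15.3), 3), 0.089)
  expect_equal(round(b_value(0.735, 15.3), 3), 4.435)
  expect_equal(round(b_value(0.593, 15.3), 3), 2.329)
  expect_equal(round(b_value(0.580, 15.3), 3), 2.179)
  # monotone in tau, zero at tau = 0, domain error below 0
  expect_equal(b_value(0, 15.3), 0)
  expect_true(all(diff(b_value(seq(0, 2, 0.1), 15.3)) >= 0))
  expect_error(b_value(-1, 15.3), ">= 0")
})

test_that("length scales reproduce the strong- and clinical-gradient anchors", {
  expect_equal(length_scales(2.15, 15.3)$l_g, 0.8, tolerance = 0.01)
  expect_equal(length_scales(2.15, 0.3)$l_g, 3, tolerance = 0.01)
  expect_equal(length_scales(2.15, 15.3, tau_ms = 0)$l_d, 0)
  # l_g ~ g^(-1/3)
  lg <- function(g) length_scales(2.15, g)$l_g
  expect_equal(lg(1) / lg(8), 2, tolerance = 1e-10)
  expect_error(length_scales(-1, 15.3), "> 0")
  expect_error(length_scales(2.15, 0), "> 0")
})

test_that("van't Hoff pressure is linear and of the right magnitude", {
  expect_equal(vant_hoff_pressure(0, 298), 0)
  # direct arithmetic oracle: 100 mol/m^3 * R * 298 K in kPa
  expect_equal(vant_hoff_pressure(100, 298),
               100 * 8.314462618 * 298 / 1000, tolerance = 1e-12)
  # tens-of-mM impermeants (plus counter-ions) exert ~100 kPa
  p40 <- vant_hoff_pressure(40, 298)
  expect_gt(p40, 50)
  expect_lt(p40, 200)
  expect_equal(vant_hoff_pressure(2, 298), 2 * vant_hoff_pressure(1, 298))
})

test_that("chloride partition ratio hits the -48/-10 mV anchors and exp symmetry", {
  expect_equal(round(chloride_partition_ratio(-48, 298), 2), 0.15)
  expect_equal(round(chloride_partition_ratio(-10, 298), 2), 0.68)
  expect_equal(chloride_partition_ratio(0, 298), 1)
  for (V in c(-120, -48, -10, 3, 25, 90)) {
    expect_equal(chloride_partition_ratio(V, 298) *
                   chloride_partition_ratio(-V, 298), 1, tolerance = 1e-12)
  }
  # strictly increasing in V
  V <- seq(-100, 100, by = 5)
  expect_true(all(diff(chloride_partition_ratio(V, 298)) > 0))
})

test_that("steady-state cell volume follows the Nernst-partition closed form", {
  # derived oracle: plug the partition ratio into the formula directly
  r <- chloride_partition_ratio(-48, 298)
  expect_equal(steady_state_cell_volume(1, -1, 264, 132, -48, 298),
               2 / (264 - 264 * r), tolerance = 1e-12)
  expect_equal(steady_state_cell_volume(0, -1, 264, 132, -48), 0)
  expect_equal(steady_state_cell_volume(2, -1, 264, 132, -48),
               2 * steady_state_cell_volume(1, -1, 264, 132, -48))
  # unit-scale invariance: scaling x scales w, ratios unchanged
  w1 <- steady_state_cell_volume(1, -1, 264, 132, -48)
  w2 <- steady_state_cell_volume(1000, -1, 264, 132, -48)
  expect_equal(w2 / w1, 1000, tolerance = 1e-12)
  # depolarized enough that the denominator closes -> no stable volume
  expect_error(steady_state_cell_volume(1, -1, 264, 132, 10), "no stable volume")
})

test_that("recovery osmolarity reproduces 138 mOsm and is antisymmetric", {
  expect_equal(round(recovery_osmolarity(132, -48, -10, 298)), 138)
  expect_equal(recovery_osmolarity(132, -48, -48, 298), 0)
  expect_equal(recovery_osmolarity(66, -48, -10, 298),
               recovery_osmolarity(132, -48, -10, 298) / 2, tolerance = 1e-12)
  for (pair in list(c(-48, -10), c(-80, -5), c(-20, -60))) {
    expect_equal(recovery_osmolarity(132, pair[1], pair[2], 298),
                 -recovery_osmolarity(132, pair[2], pair[1], 298),
                 tolerance = 1e-12)
  }
})

test_that("media composition enforces electroneutrality and osmolarity", {
  m <- media_normal()
  expect_equal(media_osmolarity(m), 264)
  expect_equal(media_osmolarity(m, s_extra = 100), 364)
  expect_error(media_composition(128, 4, 100), "electroneutral")
  expect_error(media_composition(-1, 4, 3), ">= 0")
  # gluconate replacement balances with the impermeant anion
  g <- media_composition(128, 4, 4, g_o = 128)
  expect_equal(media_osmolarity(g), 264)
})
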