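p <- model_parameters()

test_that("PAR schedule follows the photoperiod", {
  expect_equal(par_intensity(c(0, 10, 100), light_regime("CL75")),
               c(75, 75, 75))
  ld <- light_regime("LD130")
  expect_equal(par_intensity(20, ld), 0)     # dark phase of the first cycle
  expect_equal(par_intensity(15.9, ld), 130) # still in the light phase
  # light fraction of each 24 h cycle is 16/24
  tt <- seq(0, 24, by = 0.01)[-1]
  expect_equal(mean(par_intensity(tt, ld) > 0), 2 / 3, tolerance = 1e-3)
})

test_that("cumulative light is the closed-form schedule integral", {
  expect_equal(cumulative_light(0, light_regime("CL75")), 0)
  expect_equal(cumulative_light(1, light_regime("CL75")), 75)
  expect_equal(cumulative_light(24, light_regime("LD75")), 75 * 16)
  # additive over abutting intervals and non-decreasing
  ld <- light_regime("LD130")
  tt <- sort(runif(50, 0, 200))
  cl <- cumulative_light(tt, ld)
  expect_true(all(diff(cl) >= 0))
  expect_equal(cumulative_light(100, ld),
               cumulative_light(37.3, ld) +
                 (cumulative_light(100, ld) - cumulative_light(37.3, ld)))
  # agrees with numerical quadrature of the piecewise schedule
  quad <- integrate(function(s) par_intensity(s, ld), 0, 50,
                    subdivisions = 2000, stop.on.error = FALSE)$value
  expect_equal(cumulative_light(50, ld), quad, tolerance = 1e-4)
})

test_that("phytochrome signal: white value, 30-min half-life, 30% plateau", {
  rg <- light_regime("CL75")  # FR onset day 4 -> t = 96 h
  expect_equal(phytochrome_signal(50, rg, p), 1)
  expect_equal(phytochrome_signal(96.5, rg, p), 0.5)   # half-life 30 min
  expect_equal(phytochrome_signal(120, rg, p), 0.3)    # epsilon plateau
  # continuity at onset (I_fr_max = 1) and at the decay-plateau transition
  expect_equal(phytochrome_signal(96, rg, p), 1)
  s_star <- -log2(p$epsilon) / 2
  expect_equal(phytochrome_signal(96 + s_star, rg, p),
               p$epsilon, tolerance = 1e-12)
  # non-increasing after onset
  tt <- seq(96, 110, by = 0.05)
  expect_true(all(diff(phytochrome_signal(tt, rg, p)) <= 0))
  # white treatment never drops
  expect_equal(phytochrome_signal(c(10, 100, 140),
                                  with_treatment(rg, "white"), p),
               c(1, 1, 1))
})

test_that("production modifier rises when far red dilutes the signal", {
  rg <- light_regime("CL75")
  # S2 argument at the translational value -> alpha = 1
  p1 <- model_parameters(beta = 0.5, u_fr = 0.5)
  expect_equal(production_modifier(10, rg, p1), 1)
  # alpha under the FR plateau exceeds alpha in white light when
  # u_fr < beta * epsilon < beta
  p2 <- model_parameters(beta = 2, u_fr = 0.5, epsilon = 0.3)
  a_white <- production_modifier(10, rg, p2)
  a_fr <- production_modifier(140, rg, p2)
  expect_gt(a_fr, a_white)
  expect_true(all(c(a_white, a_fr) >= 0 & c(a_white, a_fr) <= 1))
})
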