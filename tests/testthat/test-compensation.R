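test_that("targets are deterministic and scale with joint conductance scaling", {
  m <- make_stg()
  t1 <- make_targets(m)
  t2 <- make_targets(m)
  expect_equal(t1[c("gs_th", "gs_osc", "gu_th", "istatic_th", "v_th", "v_osc")],
               t2[c("gs_th", "gs_osc", "gu_th", "istatic_th", "v_th", "v_osc")])
  expect_gt(t1$gs_th, 0)  # slow positive feedback at threshold
  # joint scaling of every density, the leak and I_app scales the preserved
  # quantities linearly (homogeneity of the conductance-based equations),
  # markers and calcium reference held at the reference cell's
  c <- 1.35
  m2 <- m
  for (nm in names(m$currents))
    m2 <- dicurves:::set_gbar(m2, nm, c * m$currents[[nm]]$gbar)
  m2$leak$g <- c * m$leak$g
  m2$i_app <- c * m$i_app
  q1 <- dicurves:::eval_quantities(m, t1, t1$ca_ref)
  q2 <- dicurves:::eval_quantities(m2, t1, t1$ca_ref)
  expect_equal(q2, c * q1, tolerance = 1e-10)
})

test_that("the unperturbed problem returns the reference parameters", {
  m <- make_stg()
  tg <- make_targets(m)
  r <- compensate(m, "CaS", m$currents$CaS$gbar, tg)
  expect_equal(unname(r$x),
               c(m$i_app, m$currents$Kd$gbar, m$currents$A$gbar,
                 m$currents$KCa$gbar),
               tolerance = 1e-9)
  expect_lt(max(abs(r$residuals)), 1e-10)
  expect_false(r$nonphysiological)
})

test_that("compensated models reproduce the four targets exactly", {
  m <- make_stg()
  tg <- make_targets(m)
  for (mult in c(0.5, 2, 5)) {
    r <- compensate(m, "CaS", 4 * mult, tg)
    expect_lt(max(abs(r$residuals)), 1e-8)
    expect_lt(r$condition, 1e10)
    # the frozen-calcium convention's own error is reported, not hidden
    expect_true(is.finite(max(abs(r$residuals_full))))
  }
})

test_that("solution components are affine in the perturbed density", {
  m <- make_stg()
  tg <- make_targets(m)
  pth <- compensation_path(m, "CaS", c(2, 5, 8), tg)
  for (comp in c("i_app", "Kd", "A", "KCa")) {
    x <- pth[[comp]]
    pred <- x[1] + (x[3] - x[1]) * (5 - 2) / (8 - 2)
    expect_lt(abs(pred - x[2]) / max(abs(x), 1e-9), 1e-9)
  }
  # path through the reference density passes through the reference solution
  pref <- compensation_path(m, "CaS", c(3, 4, 5), tg)
  expect_equal(unname(unlist(pref[2, c("i_app", "Kd", "A", "KCa")])),
               c(0, 70, 50, 40), tolerance = 1e-9)
})

test_that("potassium densities co-vary with slow calcium as predicted", {
  m <- make_stg()
  tg <- make_targets(m)
  pth <- compensation_path(m, "CaS", c(2, 4, 8), tg)
  expect_true(all(diff(pth$KCa) > 0))  # K,Ca rises with Ca,S
  expect_true(all(diff(pth$Kd) < 0))   # K,d falls with Ca,S
})

test_that("a fourfold calcium loss drives the A-type conductance negative", {
  m <- make_stg()
  tg <- make_targets(m)
  r <- compensate(m, "CaS", m$currents$CaS$gbar / 4, tg)
  expect_lt(r$x[["A"]], 0)
  expect_true(r$nonphysiological)
  expect_lt(max(abs(r$residuals)), 1e-8)
})

test_that("the three-unknown variant drops the static row", {
  m <- make_stg()
  tg <- make_targets(m)
  r <- compensate(m, "CaS", 8, tg, use_iapp = FALSE)
  expect_named(r$x, c("Kd", "A", "KCa"))
  expect_lt(max(abs(r$residuals[c("gs_th", "gs_osc", "gu_th")])), 1e-8)
})
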