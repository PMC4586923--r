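test_that("a conductance-free model has identically zero curves", {
  m <- make_stg(gbar = c(Na = 0, CaT = 0, CaS = 0, A = 0, KCa = 0, Kd = 0))
  d <- dic_curves(m, seq(-80, 50, by = 1))
  expect_true(all(d$g_f == 0 & d$g_s == 0 & d$g_u == 0 & d$g_total == 0))
})

test_that("a purely fast current reproduces its closed-form conductance", {
  m <- make_toy("fast_pair", gbar_dep = 5, erev_dep = 50, half_dep = -40,
                gbar_rep = 3, erev_rep = -80, half_rep = -30,
                tau_dep = 0.5, tau_rep = 20)
  v <- seq(-75, 30, by = 0.5)
  d <- dic_curves(m, v)
  # dep: tau_x = tau_f everywhere -> whole pathway in the fast curve
  gf_expected <- -5 * (v - 50) * dboltz(v, -40, 8)
  expect_equal(d$per_channel$dep[, "f"], gf_expected, tolerance = 1e-6)
  expect_equal(d$per_channel$dep[, "s"], rep(0, length(v)))
  # rep: tau_x = tau_s everywhere -> whole pathway in the slow curve
  gs_expected <- -3 * (v + 80) * dboltz(v, -30, 8)
  expect_equal(d$per_channel$rep[, "s"], gs_expected, tolerance = 1e-6)
  expect_equal(d$per_channel$rep[, "f"], rep(0, length(v)))
  # leak contributes to no curve
  expect_equal(d$g_total, gf_expected + gs_expected, tolerance = 1e-6)
})

test_that("the fast/slow/ultraslow curves sum to the static conductance", {
  for (m in list(make_stg(), make_hh(), make_toy("fast_pair"))) {
    d <- dic_curves(m)
    expect_lt(max(abs(d$g_f + d$g_s + d$g_u - d$g_total)), 1e-10)
    per_sum <- Reduce(`+`, lapply(d$per_channel, rowSums))
    expect_equal(per_sum, d$g_total, tolerance = 1e-10)
  }
})

test_that("the decomposition superposes over single-channel submodels", {
  m <- make_stg()
  v <- seq(-80, 50, by = 2.5)
  tri <- reference_timescales(m)
  ca_ref <- function(vv) ca_steady(m, vv)
  full <- dic_curves(m, v, triplet = tri, ca_ref = ca_ref)
  acc <- 0
  for (nm in names(m$currents)) {
    solo <- m
    for (other in setdiff(names(m$currents), nm))
      solo <- dicurves:::set_gbar(solo, other, 0)
    d1 <- dic_curves(solo, v, triplet = tri, ca_ref = ca_ref)
    expect_equal(d1$per_channel[[nm]], full$per_channel[[nm]],
                 tolerance = 1e-10)
    acc <- acc + d1$g_total
  }
  expect_equal(acc, full$g_total, tolerance = 1e-10)
})

test_that("single-point evaluation agrees with the grid curves", {
  m <- make_stg()
  v <- seq(-80, 50, by = 10)
  d <- dic_curves(m, v)
  for (k in c(2, 7, 12)) {
    at <- dic_at(m, v[k])
    expect_equal(unname(at),
                 c(d$g_f[k], d$g_s[k], d$g_u[k], d$g_total[k]),
                 tolerance = 1e-12)
  }
})

test_that("the STG curves show the bursting signature", {
  m <- make_stg()
  d <- dic_curves(m, seq(-80, 50, by = 0.25))
  mk <- voltage_markers(m)
  # fast conductance mostly positive (regenerative upstroke pathway)
  expect_gt(mean(d$g_f > -1e-9), 0.6)
  expect_gt(max(d$g_f), 1)
  # slow conductance mostly negative, with its (negative) peak at
  # depolarized potentials and a small positive-feedback area at threshold
  expect_lt(min(d$g_s), -10)
  expect_gt(d$v[which.min(d$g_s)], -20)
  at_th <- dic_at(m, mk$v_th)
  expect_gt(at_th[["g_s"]], 0)
  # ultraslow conductance mostly negative below the up-state (restorative
  # adaptation), wherever it is appreciable; its positive region sits at
  # suprathreshold potentials
  sub <- d$v < mk$v_osc - 2
  appreciable <- sub & abs(d$g_u) > 0.01
  expect_gt(mean(d$g_u[appreciable] < 0), 0.8)
  expect_lt(min(d$g_u[sub]), -5)
  expect_gt(d$v[which.max(d$g_u)], mk$v_osc)
})
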