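test_that("sensitivity curves do not depend on the channel's own density", {
  m <- make_stg()
  v <- seq(-80, 50, by = 5)
  ca_ref <- function(vv) ca_steady(m, vv)
  for (nm in c("Na", "CaS", "KCa")) {
    s1 <- sensitivity_curves(m, nm, v, ca_ref = ca_ref)
    s2 <- sensitivity_curves(dicurves:::set_gbar(m, nm, 2 * m$currents[[nm]]$gbar),
                             nm, v, ca_ref = ca_ref)
    expect_equal(s1, s2, tolerance = 1e-12)
  }
  expect_error(sensitivity_curves(m, "nope", v), "unknown current")
})

test_that("analytic sensitivities match finite differences of the curves", {
  m <- make_stg()
  v <- seq(-78, 48, by = 2)
  tri <- reference_timescales(m)
  ca_ref <- function(vv) ca_steady(m, vv)
  for (nm in names(m$currents)) {
    s <- sensitivity_curves(m, nm, v, tri, ca_ref)
    g0 <- m$currents[[nm]]$gbar
    dg <- max(g0, 1) * 0.05
    dp <- dic_curves(dicurves:::set_gbar(m, nm, g0 + dg), v, tri, ca_ref)
    dm <- dic_curves(dicurves:::set_gbar(m, nm, g0 - dg), v, tri, ca_ref)
    for (j in c("f", "s", "u")) {
      gj <- paste0("g_", j)
      fd <- (dp[[gj]] - dm[[gj]]) / (2 * dg)
      scale <- max(abs(s[[j]]), 1e-6)
      expect_lt(max(abs(fd - s[[j]])) / scale, 1e-6)
    }
    # timescale-sum rule: the three curves telescope to the static one
    fd_tot <- (dp$g_total - dm$g_total) / (2 * dg)
    expect_lt(max(abs(fd_tot - (s$f + s$s + s$u))) /
                max(abs(fd_tot), 1e-6), 1e-6)
  }
})

test_that("slow calcium channels stay out of the fast timescale", {
  m <- make_stg()
  v <- seq(-80, 50, by = 0.5)
  s <- sensitivity_curves(m, "CaS", v)
  expect_lt(max(abs(s$f)), 1e-4)
  expect_gt(max(abs(s$s)), 0.01)
})

test_that("marker-point sensitivities reproduce the dominance rankings", {
  m <- make_stg()
  sm <- sensitivity_at_markers(m)
  at <- sm$at_markers
  val <- function(cur, ts, col) at[at$current == cur & at$timescale == ts, col]
  # at threshold, calcium channels' slow contribution dwarfs the potassium
  expect_gt(min(val("CaS", "s", "at_v_th"), val("CaT", "s", "at_v_th")),
            10 * max(abs(val("Kd", "s", "at_v_th")),
                     abs(val("KCa", "s", "at_v_th"))))
  # at up-state, the delayed rectifier dominates every other slow entry
  others <- vapply(c("Na", "CaT", "CaS", "A"), function(nm)
    abs(val(nm, "s", "at_v_osc")), numeric(1))
  expect_gt(abs(val("Kd", "s", "at_v_osc")), max(others))
  # localization curves are normalized to unit peak
  loc <- sm$localization
  for (nm in c("Na", "Kd", "CaS"))
    expect_equal(max(abs(loc$normalized[loc$current == nm &
                                        loc$timescale == "s"])), 1)
})

test_that("activation shifts translate the gate and nothing else", {
  m <- make_stg()
  expect_equal(dic_at(shift_activation(m, "A", "activation", 0), -45),
               dic_at(m, -45))
  m2 <- shift_activation(m, "A", "activation", 4.5)
  g <- m2$currents$A$activation
  # half-activation moved by exactly the shift
  expect_equal(g$inf(-27.2 + 4.5), 0.5, tolerance = 1e-12)
  expect_equal(g$tau(-30 + 4.5), m$currents$A$activation$tau(-30))
  # original model untouched
  expect_equal(m$currents$A$activation$inf(-27.2), 0.5, tolerance = 1e-12)
  expect_error(shift_activation(m, "Kd", "inactivation", 1), "no inactivation")
})

test_that("A-type/slow-calcium colocalization degrades under a right shift", {
  m <- make_stg()
  v <- seq(-80, 50, by = 0.5)
  ref_cas <- overlap_score(m, "A", "CaS", "s", v)
  ref_cat <- overlap_score(m, "A", "CaT", "s", v)
  expect_gt(ref_cas, ref_cat)
  m2 <- shift_activation(m, "A", "activation", 4.5)
  expect_lt(overlap_score(m2, "A", "CaS", "s", v), ref_cas)
  expect_gt(overlap_score(m2, "A", "CaT", "s", v), ref_cat)
})
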