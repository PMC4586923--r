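test_that("steady state is bounded, idempotent, and matches gate midpoints", {
  m <- make_stg()
  for (v in c(-80, -55, -30, 0, 40)) {
    st <- steady_state(m, v)
    gates <- st[names(st) != "Ca"]
    expect_true(all(gates >= 0 & gates <= 1))
    expect_true(st[["Ca"]] >= 0)
    # idempotence: a steady state regenerated at the same potential is itself
    expect_identical(st, steady_state(m, v))
  }
  # sodium nearly deactivated far below its half-activation
  expect_lt(steady_state(m, -80)[["Na.m"]], 0.05)
  # a Boltzmann gate evaluated at its half-activation gives exactly 1/2
  toy <- make_toy("one_gate", half = -40, slope = 10)
  expect_equal(steady_state(toy, -40)[["X.m"]], 0.5, tolerance = 1e-12)
  expect_error(steady_state(m, 100), "working range")
})

test_that("leak-only models have trivial steady state and I/V", {
  p <- make_toy("passive", g_leak = 0.2, e_leak = -55)
  expect_length(steady_state(p, -60), 0)
  v <- seq(-80, 0, by = 0.5)
  expect_equal(static_iv(p, v), 0.2 * (v + 55))
  expect_equal(find_upstate(p), -55, tolerance = 1e-6)
})

test_that("static I/V is exactly linear in every maximal conductance", {
  m <- make_stg()
  v <- seq(-80, 50, by = 2.5)
  base <- static_iv(m, v, per_channel = TRUE)
  set.seed(42)
  for (rep in 1:5) {
    sc <- stats::runif(length(m$currents), 0, 3)
    names(sc) <- names(m$currents)
    m2 <- m
    for (nm in names(sc))
      m2 <- dicurves:::set_gbar(m2, nm, sc[nm] * m$currents[[nm]]$gbar)
    # freeze the calcium reference so KCa's column stays comparable
    ca_ref <- function(vv) ca_steady(m, vv)
    pc <- static_iv(m2, v, calcium = ca_ref, per_channel = TRUE)
    pc0 <- static_iv(m, v, calcium = ca_ref, per_channel = TRUE)
    for (nm in names(sc))
      expect_equal(pc[, nm], sc[[nm]] * pc0[, nm], tolerance = 1e-12)
  }
  expect_error(static_iv(m, numeric(0)), "empty")
})

test_that("passive membrane relaxes to the leak reversal", {
  p <- make_toy("passive", g_leak = 0.1, e_leak = -50)
  tr <- simulate_model(p, 500, v0 = -40, dt_out = 1)
  expect_equal(tr$v[nrow(tr)], -50, tolerance = 1e-4)
})

test_that("the HH fixture rests at the canonical potential and spikes", {
  m <- make_hh()
  # independent oracle: root of the independently-coded steady current
  v_rest <- uniroot(hh_oracle_current, c(-80, -50), tol = 1e-10)$root
  tr <- simulate_model(m, 300, v0 = -65, dt_out = 0.5)
  expect_equal(tr$v[nrow(tr)], v_rest, tolerance = 0.01)
  # suprathreshold step current elicits repetitive spiking
  tr2 <- simulate_model(m, 400, i_app = 15, v0 = v_rest, dt_out = 0.1)
  st <- trace_statistics(tr2, discard = 50)
  expect_gt(length(st$spike_times), 5)
})

test_that("spike and burst statistics follow their definitions", {
  # constant trace: no spikes, empty result rather than an error
  flat <- data.frame(time = 0:100, v = rep(-60, 101))
  expect_length(trace_statistics(flat)$spike_times, 0)
  # forced example: two bursts with ISIs {10, 10} and {10}
  tr <- synthetic_spike_trace(c(100, 110, 120, 500, 510), 600)
  st <- trace_statistics(tr, burst_gap = 100)
  expect_equal(st$n_bursts, 2L)
  expect_equal(st$spikes_per_burst, c(3L, 2L))
  expect_equal(st$burst_isis[[1]], c(10, 10), tolerance = 1e-6)
  expect_equal(st$burst_isis[[2]], 10, tolerance = 1e-6)
})

test_that("clamped gating relaxes monotonically toward its steady state", {
  m <- make_stg()
  init <- steady_state(m, -70)
  tr <- dicurves:::simulate_clamped(m, -40, seq(0, 400, by = 0.5), init)
  target <- steady_state(m, -40)
  for (nm in c("Na.h", "Kd.m", "CaS.m")) {
    x <- tr[[nm]]
    dir <- sign(target[[nm]] - init[[nm]])
    expect_true(all(dir * diff(x) > -1e-9))
    expect_equal(x[length(x)], target[[nm]], tolerance = 1e-4)
  }
})
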