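test_that("a leak-only membrane gives a flat step response and zero DICs", {
  p <- make_toy("passive", g_leak = 0.2, e_leak = -55)
  pr <- clamp_protocol(v_holds = c(-60, -45), step_duration = 1500)
  tr <- run_clamp_step(p, -60, 1, pr)
  expect_lt(diff(range(tr$i_total)), 1e-12)
  e <- extract_clamp(tr, pr)
  expect_equal(c(e$di_f, e$di_s, e$di_u, e$di_static), c(0, 0, 0, 0))
  md <- measure_dics(p, pr, timescales = 3)
  expect_equal(unlist(md[, c("g_f", "g_s", "g_u", "g_total")]),
               rep(0, 8), ignore_attr = TRUE)
})

test_that("a one-gate model relaxes with its closed-form exponential", {
  tau <- 50
  m <- make_toy("one_gate", tau = tau, gbar = 2, erev = 0, half = -40,
                slope = 10, g_leak = 0.1, e_leak = -50)
  pr <- clamp_protocol(v_holds = -45, step_duration = 1200)
  v0 <- -45; v1 <- -44
  tr <- run_clamp_step(m, v0, 1, pr)
  m_inf0 <- boltz(v0, -40, 10)
  m_inf1 <- boltz(v1, -40, 10)
  m_t <- m_inf1 + (m_inf0 - m_inf1) * exp(-tr$time / tau)
  i_t <- 2 * m_t * (v1 - 0) + 0.1 * (v1 + 50)
  expect_equal(tr$i_total, i_t, tolerance = 1e-7)
})

test_that("window extraction recovers three separated exponential currents", {
  # closed-form trace: three inward relaxations with separated time scales
  a <- c(-5, -2, -1); taus <- c(0.5, 30, 3000); i0 <- 4
  tt <- unique(c(seq(0, 10, by = 0.05), seq(10, 5000, by = 1)))
  itrace <- i0 + (a[1] * (1 - exp(-tt / taus[1])) +
                  a[2] * (1 - exp(-tt / taus[2])) +
                  a[3] * (1 - exp(-tt / taus[3])))
  e <- extract_clamp(data.frame(time = tt, i_total = itrace))
  closed <- function(t) i0 + sum(a * (1 - exp(-t / taus)))
  # the window picks are exactly the closed form at the window extrema
  expect_equal(e$i0, closed(0))
  expect_equal(e$i_f, closed(2))
  expect_equal(e$i_s, closed(100))
  expect_equal(e$i_u, closed(5000))
  # and the dynamic currents recover the amplitudes to the slack the closed
  # form itself allows at those windows (cross-timescale leakage)
  slack <- function(di, target) abs(di - target)
  expect_lt(slack(closed(2) - closed(0), a[1]), 0.05)
  expect_lt(slack(closed(100) - closed(2), a[2]), 0.15)
  expect_lt(slack(closed(5000) - closed(100), a[3]), 0.25)
  expect_equal(e$di_f, closed(2) - closed(0))
  expect_equal(e$di_s, closed(100) - closed(2))
  expect_equal(e$di_u, closed(5000) - closed(100))
  expect_equal(e$di_f + e$di_s + e$di_u, e$di_static)
})

test_that("a rising slow window falls back to the 10 ms amplitude", {
  tt <- unique(c(seq(0, 10, by = 0.05), seq(10, 1500, by = 1)))
  itrace <- 1 - 5 * (1 - exp(-tt / 0.5)) + 3 * (1 - exp(-tt / 300))
  e <- extract_clamp(data.frame(time = tt, i_total = itrace))
  expect_true("i_s_fallback_10ms" %in% e$flags)
  expect_equal(e$i_s, itrace[tt == 10])
  expect_error(extract_clamp(data.frame(time = 0:500, i_total = rep(1, 501))),
               "window")
})

test_that("the telescoping identity holds on a real extraction", {
  m <- make_stg()
  pr <- clamp_protocol(v_holds = -55)
  tr <- run_clamp_step(m, -55, 1, pr)
  e <- extract_clamp(tr, pr)
  expect_identical(e$di_f + e$di_s + e$di_u, e$di_static)
})

test_that("halving the step size changes measured values only at O(dV)", {
  m <- make_stg()
  pr1 <- clamp_protocol(v_holds = -60, delta_v = 1)
  pr2 <- clamp_protocol(v_holds = -60, delta_v = 0.5)
  g1 <- measure_dics(m, pr1)
  g2 <- measure_dics(m, pr2)
  for (j in c("g_f", "g_s", "g_u", "g_total"))
    expect_lt(abs(g1[[j]] - g2[[j]]), max(0.02, 0.05 * abs(g1[[j]])))
})

test_that("two-timescale measurement leaves no ultraslow component", {
  md <- measure_dics(make_hh(), clamp_protocol(v_holds = c(-80, -75)))
  expect_equal(md$g_u, c(0, 0))
  expect_true(all(grepl("two_timescale", md$flags)))
})
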