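test_that("reference timescales resolve to the expected gates", {
  tri <- reference_timescales(make_stg())
  expect_equal(unname(tri$provenance[c("fast", "slow", "ultraslow")]),
               c("Na.m", "Kd.m", "CaS.h"))
  tri_hh <- reference_timescales(make_hh())
  expect_equal(unname(tri_hh$provenance[c("fast", "slow")]),
               c("Na.m", "K.m"))
  expect_null(tri_hh$tau_u)
  # auto mode needs both a gated depolarizing and a repolarizing current
  expect_error(reference_timescales(make_toy("one_gate"),
                                    designation = "auto"),
               "designation")
  # the STG designations also emerge from auto mode
  tri_auto <- reference_timescales(make_stg(), designation = "auto")
  expect_equal(unname(tri_auto$provenance[c("fast", "slow", "ultraslow")]),
               c("Na.m", "Kd.m", "CaS.h"))
})

test_that("a violated tau ordering fails loudly instead of reordering", {
  expect_error(
    reference_timescales(make_stg(),
                         designation = list(fast = "Kd.m", slow = "Na.m",
                                            ultraslow = "CaS.h")),
    "ordering")
})

test_that("weights respect boundaries and the log-linear midpoint", {
  w <- dic_weights(1, 1, 10, 100)     # tau_x = tau_f
  expect_identical(c(w$w_fs, w$w_su), c(1, 1))
  w <- dic_weights(10, 1, 10, 100)    # tau_x = tau_s
  expect_identical(c(w$w_fs, w$w_su), c(0, 1))
  w <- dic_weights(100, 1, 10, 100)   # tau_x = tau_u
  expect_identical(c(w$w_fs, w$w_su), c(0, 0))
  # geometric midpoint of (tau_f, tau_s) sits at exactly one half
  w <- dic_weights(sqrt(10), 1, 10, 100)
  expect_equal(w$w_fs, 0.5, tolerance = 1e-12)
  expect_equal(w$w_su, 1, tolerance = 1e-12)
  expect_error(dic_weights(-1, 1, 10, 100), "positive")
})

test_that("weights are a partition of unity, monotone in tau_x", {
  set.seed(7)
  for (i in 1:500) {
    taus <- sort(exp(stats::runif(3, log(0.05), log(500))))
    tx <- exp(stats::runif(1, log(0.01), log(1000)))
    w <- dic_weights(tx, taus[1], taus[2], taus[3])
    expect_true(w$w_fs >= 0 && w$w_fs <= w$w_su && w$w_su <= 1)
    shares <- c(w$w_fs, w$w_su - w$w_fs, 1 - w$w_su)
    expect_equal(sum(shares), 1, tolerance = 1e-12)
    # monotonicity: a slower variable never gets more fast/slow weight
    w2 <- dic_weights(tx * 1.5, taus[1], taus[2], taus[3])
    expect_lte(w2$w_fs, w$w_fs + 1e-12)
    expect_lte(w2$w_su, w$w_su + 1e-12)
  }
})

test_that("two-timescale degeneration sends all ultraslow weight to slow", {
  w <- dic_weights(c(0.1, 5, 50, 1000), 0.5, 8, NULL)
  expect_identical(w$w_su, rep(1, 4))
  d <- dic_curves(make_hh(), seq(-80, 40, by = 1))
  expect_identical(d$g_u, rep(0, length(d$v)))
})

test_that("the weight table covers every state variable", {
  m <- make_stg()
  wt <- weight_table(m, c(-60, -40))
  expect_setequal(unique(wt$variable),
                  c("Na.m", "Na.h", "CaT.m", "CaT.h", "CaS.m", "CaS.h",
                    "A.m", "A.h", "KCa.m", "Kd.m", "Ca"))
  # intracellular calcium acts (almost) wholly in the ultraslow timescale
  ca_w <- wt[wt$variable == "Ca", ]
  expect_true(all(ca_w$w_su < 0.2))
})
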