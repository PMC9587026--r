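p_ref <- spina_parameters()

test_that("protocols conserve the administered dose", {
  ogtt <- make_protocol("ogtt")  # 75 g, f = 0.8
  # numerical integral of the absorption profile
  tt <- seq(0, 10 * 1800, by = 1)
  absorbed <- sum(ogtt$W_fun(tt)) * 1
  expect_equal(absorbed, 0.8 * 75 / 180.18, tolerance = 1e-3)

  # zero dose degenerates to fasting
  none <- make_protocol("ogtt", dose = 0)
  expect_equal(none$W_fun(c(0, 100, 1000)), c(0, 0, 0))
  expect_error(make_protocol("ogtt", dose = -1), "non-negative")

  iv <- make_protocol("ivgtt", dose = 21)
  expect_equal(iv$bolus$amount_mol, 21 / 180.18)
})

test_that("a trajectory started at the equifinal state stays there", {
  traj <- simulate_homeostasis(p_ref, t_end = 7200, dt = 10)
  ss <- ref_steady()
  expect_lt(max(abs(traj$G / ss$G_inf - 1)), 1e-9)
  expect_lt(max(abs(traj$I / ss$I_inf - 1)), 1e-9)
  expect_true(all(diff(traj$t) > 0))
  expect_equal(traj$R, traj$W + traj$Q)
  expect_equal(traj$N, p_ref$GE * traj$M)
})

test_that("fasting runs converge to the analytic steady state from
           varied initial conditions", {
  ss <- ref_steady()
  for (G0 in c(0.1e-3, 10e-3, 20e-3)) {
    for (I0 in c(0, 1000e-12)) {
      traj <- simulate_homeostasis(p_ref, t_end = 50000, dt = 10,
                                   initial = c(G0, I0))
      last <- traj[nrow(traj), ]
      expect_equal(last$G, ss$G_inf, tolerance = 1e-3)
      expect_equal(last$I, ss$I_inf, tolerance = 1e-3)
      expect_true(all(traj$G >= 0) && all(traj$I >= 0))
    }
  }
})

test_that("halving the step barely changes the terminal state", {
  t1 <- simulate_homeostasis(p_ref, t_end = 20000, dt = 20,
                             initial = c(10e-3, 0))
  t2 <- simulate_homeostasis(p_ref, t_end = 20000, dt = 10,
                             initial = c(10e-3, 0))
  expect_equal(t1$G[nrow(t1)], t2$G[nrow(t2)], tolerance = 1e-4)
})

test_that("an intravenous bolus raises glucose by exactly dose times
           alphaG", {
  iv <- make_protocol("ivgtt", dose = 21)
  traj <- simulate_homeostasis(p_ref, iv, t_end = 600, dt = 10)
  ss <- ref_steady()
  expect_equal(traj$G[1], ss$G_inf + 21 / 180.18 * p_ref$alphaG,
               tolerance = 1e-12)
  # glucose then decays back towards baseline
  expect_lt(traj$G[nrow(traj)], traj$G[1])

  # a delayed bolus jumps at the event step, not before
  iv2 <- make_protocol("ivgtt", dose = 21, bolus_time = 300)
  tr2 <- simulate_homeostasis(p_ref, iv2, t_end = 600, dt = 10)
  before <- tr2$G[tr2$t == 290]
  after <- tr2$G[tr2$t == 310]
  expect_equal(before, ss$G_inf, tolerance = 1e-6)
  expect_gt(after, ss$G_inf + 0.9 * 21 / 180.18 * p_ref$alphaG)
})

test_that("with negligible insulin feedback glucose approaches the
           open-loop value G1*P", {
  p_open <- spina_parameters(Gbeta = 1e-30)  # secretion effectively off
  traj <- simulate_homeostasis(p_open, t_end = 50000, dt = 10,
                               initial = c(5e-3, 0))
  expect_equal(traj$G[nrow(traj)] * 1e3, 23.239, tolerance = 1e-3)
})

test_that("oral glucose raises the 2-hour value above fasting", {
  traj <- simulate_homeostasis(p_ref, make_protocol("ogtt"),
                               t_end = 10800, dt = 30)
  s <- summarize_trajectory(traj)
  ss <- ref_steady()
  expect_gt(s$G_120min, ss$G_inf)
  expect_gt(s$G_peak, s$G_120min)
  expect_gt(s$t_peak, 0)
})

test_that("trajectory summaries report settling behaviour", {
  flat <- simulate_homeostasis(p_ref, t_end = 3600, dt = 60)
  s <- summarize_trajectory(flat)
  expect_equal(s$settling_time, 0)
  expect_equal(s$G_peak, ref_steady()$G_inf, tolerance = 1e-9)

  relax <- simulate_homeostasis(p_ref, t_end = 50000, dt = 10,
                                initial = c(10e-3, 0))
  s2 <- summarize_trajectory(relax)
  expect_lte(s2$settling_time, 10 / p_ref$betaG)
  expect_error(summarize_trajectory(data.frame()), "trajectory")
})

test_that("integration guards reject invalid steps and states", {
  expect_error(simulate_homeostasis(p_ref, dt = 0), "dt")
  expect_error(simulate_homeostasis(p_ref, dt = 120), "dt")
  expect_error(simulate_homeostasis(p_ref, t_end = -1), "t_end")
  expect_error(simulate_homeostasis(p_ref, initial = c(-1e-3, 0)),
               "initial")
})

test_that("trajectory CSV export round-trips and writes a sidecar", {
  traj <- simulate_homeostasis(p_ref, t_end = 600, dt = 60)
  tmp <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(names(back), c("t", "G", "I", "S", "M", "N", "Q", "R", "W"))
  expect_equal(back$G, traj$G, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(meta$integrator, "rk4")
  expect_equal(meta$params$Gbeta, 2.8)
})
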