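test_that("gate update has the correct fixed point and step response", {
  g <- hh_gate(1, vhalf = -40, k = 5, tau_min = 1, tau_amp = 4)
  V <- -35
  minf <- gate_inf(g, V)
  m <- 0.1
  for (i in 1:4000) m <- gate_advance(g, m, V, dt = 1)
  expect_equal(m, minf, tolerance = 1e-9)

  tau <- gate_tau(g, V)
  tf <- 2
  m1 <- gate_advance(g, 0, V, dt = tau / tf, temp_factor = tf)
  expect_equal(m1, minf * (1 - exp(-1)), tolerance = 1e-12)
})

test_that("gate trajectory matches dense ODE integration for varying V", {
  skip_if_not_installed("deSolve")
  g <- hh_gate(2, vhalf = -45, k = 6, tau_min = 0.5, tau_amp = 3,
               tau_vhalf = -50, tau_ka = 12, tau_kb = 18)
  vfun <- function(t) -60 + 25 * sin(2 * pi * t / 13) + 10 * sin(2 * pi * t / 3.7)
  # fine-step reference at dt = 1e-4 ms
  rhs <- function(t, y, p) {
    V <- vfun(t)
    list((gate_inf(g, V) - y) / gate_tau(g, V))
  }
  ref <- deSolve::ode(y = c(m = 0.2), times = seq(0, 50, by = 0.025),
                      func = rhs, parms = NULL, method = "ode45",
                      atol = 1e-10, rtol = 1e-10)
  m <- 0.2
  dev <- 0
  for (i in seq(2, nrow(ref))) {
    # exponential integrator with V held at the step midpoint
    V <- vfun(ref[i - 1, "time"] + 0.0125)
    m <- gate_advance(g, m, V, dt = 0.025)
    dev <- max(dev, abs(m - ref[i, "m"]))
  }
  expect_lt(dev, 1e-3)
})

test_that("Markov propagation preserves probability and matches closed forms", {
  # zero generator: state unchanged
  ch0 <- markov_channel("null", 2, 2,
                        data.frame(from = 1, to = 2, base = 0, vhalf = 0,
                                   kv = 0, ca_pow = 0), erev = 0)
  p <- c(0.3, 0.7)
  expect_equal(markov_advance(ch0, p, V = -60, dt = 0.5), p, tolerance = 1e-12)

  # two-state channel with constant rates: analytic exponential relaxation
  a <- 0.4; b <- 0.1
  ch2 <- markov_channel("twostate", 2, 2,
                        data.frame(from = c(1, 2), to = c(2, 1),
                                   base = c(a, b), vhalf = 0, kv = 0,
                                   ca_pow = 0), erev = 0)
  p <- c(1, 0)
  t_tot <- 20; dt <- 0.001
  for (i in seq_len(t_tot / dt)) p <- markov_advance(ch2, p, -60, dt = dt)
  p_inf <- a / (a + b)
  p2_analytic <- p_inf + (0 - p_inf) * exp(-(a + b) * t_tot)
  expect_equal(p[2], p2_analytic, tolerance = 1e-6)
  expect_equal(sum(p), 1, tolerance = 1e-9)

  # 6-state scheme vs matrix-exponential oracle over 10 ms
  set.seed(42)
  tr <- data.frame(from = c(1, 2, 2, 3, 3, 4, 4, 5, 5, 6),
                   to   = c(2, 1, 3, 2, 4, 3, 5, 4, 6, 5),
                   base = runif(10, 0.05, 0.8), vhalf = 0, kv = 0, ca_pow = 0)
  ch6 <- markov_channel("six", 6, 6, tr, erev = 0)
  Q <- golgicell:::markov_Q(ch6, V = -60)
  p_exact <- as.numeric(Matrix::expm(Matrix::Matrix(t(Q) * 10)) %*%
                          c(1, rep(0, 5)))
  p <- c(1, rep(0, 5))
  for (i in seq_len(10 / 0.0005)) p <- markov_advance(ch6, p, -60, dt = 5e-4)
  expect_lt(max(abs(p - p_exact)), 1e-5)
})

test_that("Markov probabilities stay normalized over long driven trajectories", {
  nav <- default_channels()$Nav1.6
  p <- channel_steady_state(nav, -70)
  set.seed(1)
  V <- -70
  for (i in 1:20000) { # 2 s at dt 0.1 with a wandering voltage
    V <- max(min(V + rnorm(1, 0, 2), 30), -90)
    p <- markov_advance(nav, p, V, dt = 0.1)
    if (i %% 4000 == 0) {
      expect_equal(sum(p), 1, tolerance = 1e-9)
      expect_true(all(p >= 0 & p <= 1))
    }
  }
})

test_that("channel currents vanish at the reversal potential", {
  chans <- default_channels()
  for (ch in chans) {
    st <- channel_steady_state(ch, -30, ca = 1e-3)
    expect_equal(channel_current(ch, st, V = ch$erev, gmax = 0.01), 0)
  }
})

test_that("fully open sodium current follows Ohmic arithmetic", {
  nav <- default_channels()$Nav1.6
  # force the open state: g = 0.149 S/cm2, V = -10, E = +60 -> i = 0.149 * -70
  p <- rep(0, nav$n_states); p[4] <- 1
  expect_equal(channel_current(nav, p, V = -10, gmax = 0.149),
               0.149 * (-70), tolerance = 1e-12)
  p0 <- rep(0, nav$n_states); p0[1] <- 1
  expect_equal(channel_current(nav, p0, V = -10, gmax = 0.149), 0)
})

test_that("Q10 factors follow the power law", {
  expect_equal(q10_factor(3, 42, 32), 3)
  expect_equal(q10_factor(3, 25, 25), 1)
  expect_equal(q10_factor(2.4, 32, 22), 2.4)
})

test_that("calcium shell rests at equilibrium and relaxes after a pulse", {
  sh <- calcium_shell()
  st <- shell_rest_state(sh)
  st2 <- st
  for (i in 1:2000) st2 <- calcium_step(sh, st2, 0, area_cm2 = 1e-6, dt = 0.025)
  expect_equal(st2$ca, st$ca, tolerance = 1e-6)

  # constant influx pulse, then release: returns to rest (soma-like pump)
  sh2 <- calcium_shell(pump_density = 1e-7)
  st3 <- shell_rest_state(sh2)
  for (i in 1:400) st3 <- calcium_step(sh2, st3, -0.01, 1e-6, 0.025)
  expect_gt(st3$ca, st$ca)
  for (i in 1:80000) st3 <- calcium_step(sh2, st3, 0, 1e-6, 0.025)
  expect_lt(abs(st3$ca - st$ca) / st$ca, 0.05)
  expect_gt(min(st3$ca, st3$bound), 0)
})

test_that("calcium step matches a fine-step ODE oracle", {
  sh <- calcium_shell()
  st_ref <- st <- shell_rest_state(sh)
  i_ca <- -0.005
  # fine-step explicit reference at dt = 1e-4 ms using the shared derivative
  for (i in seq_len(10 / 1e-4)) {
    d <- golgicell:::shell_deriv(sh, st_ref, i_ca, 1e-6)
    st_ref$ca <- st_ref$ca + d$dca * 1e-4
    st_ref$bound <- st_ref$bound + d$dbound * 1e-4
  }
  for (i in seq_len(10 / 0.025)) st <- calcium_step(sh, st, i_ca, 1e-6, 0.025)
  expect_lt(abs(st$ca - st_ref$ca) / st_ref$ca, 1e-3)
})

test_that("the default registry matches the published placement map", {
  reg <- default_channel_registry()
  expect_false(any(grepl("AMPA|NMDA|GABA", reg$channel)))
  cav23 <- reg[reg$channel == "Cav2.3", ]
  expect_equal(cav23$section, "apical_dendrite")
  expect_equal(cav23$gmax, 0.0012)
  expect_equal(reg$gmax[reg$channel == "Kv7.x" & reg$section == "AIS"], 2e-4)
  expect_equal(reg$gmax[reg$channel == "Nav1.6" & reg$section == "soma"], 0.149)
  # Nav everywhere, graded; reversal potentials as printed
  expect_setequal(reg$section[reg$channel == "Nav1.6"],
                  c("soma", "AIS", "axon", "basal_dendrite", "apical_dendrite"))
  chans <- default_channels()
  expect_equal(chans$Nav1.6$erev, 60)
  expect_equal(chans$Kv3.4$erev, -80)
  expect_equal(chans$HCN1$erev, -20)
  expect_equal(chans$Cav2.2$erev, 137.5)
  # pump densities follow the methods text (apical lightest)
  pd <- default_pump_densities()
  expect_equal(unname(pd["apical_dendrite"]), 2e-9)
  expect_equal(unname(pd["basal_dendrite"]), 5e-9)
  expect_equal(unname(pd["soma"]), 1e-7)
})
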