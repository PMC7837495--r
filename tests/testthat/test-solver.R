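test_that("a passive isopotential compartment follows the RC closed form", {
  mod <- passive_sphere(e_leak = -70)
  sim <- simulate_cell(mod,
                       electrodes = list(current_step(0.01, onset = 0,
                                                      duration = 500)),
                       t_stop = 500, settle = 0, record_dt = 0.025,
                       recordings = list(record("V", "soma", name = "v")))
  tr <- sim$traces
  tau <- 1 / 3e-5 / 1000 # Cm/GL in ms = 33.33
  v_inf <- 0.01 / (3e-5 * 1e-4 * 1e9) * 1e3 # nA / nS -> mV
  v_pred <- -70 + v_inf * (1 - exp(-tr$time / tau))
  expect_lt(max(abs(tr$v - v_pred)) / v_inf, 0.002)
})

test_that("with zero conductances and no current the voltage is constant", {
  mod <- passive_sphere(e_leak = -70)
  mod$passive$gl <- 0
  pd <- golgicell::default_pump_densities()
  pd[] <- NA_real_
  mod$pump_densities <- pd
  sim <- simulate_cell(mod, t_stop = 100, settle = 0, v_init = -53.7,
                       recordings = list(record("V", "soma", name = "v")))
  expect_true(all(sim$traces$v == -53.7))
})

test_that("the tree solve equals a dense linear solve on a branched tree", {
  m <- discretize(make_surrogate(params = surrogate_params(n_basal = 2,
                                                           n_apical = 1,
                                                           n_branch = 1),
                                 seed = 3), 60)
  mod <- cell_model(m, registry = default_channel_registry()[0, ])
  ws <- golgicell:::assemble(mod)
  n <- length(ws$parent)
  expect_lte(n, 50)
  dt <- 0.025
  v0 <- rep(-70, n)
  A <- matrix(0, n, n); b <- numeric(n)
  for (i in seq_len(n)) {
    A[i, i] <- ws$cap_nF[i] / dt + ws$gl_uS[i]
    b[i] <- ws$cap_nF[i] / dt * v0[i] + ws$gl_uS[i] * ws$e_leak[i]
  }
  b[1] <- b[1] + 0.1
  for (i in seq_len(n)) {
    p <- ws$parent[i] + 1
    if (p > 0) {
      g <- ws$g_axial_uS[i]
      A[i, i] <- A[i, i] + g; A[p, p] <- A[p, p] + g
      A[i, p] <- A[i, p] - g; A[p, i] <- A[p, i] - g
    }
  }
  v_dense <- solve(A, b)
  cc <- current_clamp(comp = m$compartments$comp_id[1], times = 0, values = 0.1)
  recs <- lapply(m$compartments$comp_id,
                 function(i) record("V", i, name = paste0("v", i)))
  sim <- simulate_cell(mod, electrodes = list(cc), recordings = recs,
                       t_stop = dt, dt = dt, settle = 0)
  v_tree <- as.numeric(sim$traces[2, -1])
  expect_lt(max(abs(v_tree - v_dense)), 1e-10)
})

test_that("simulations are bit-reproducible and t_stop = 0 yields no samples", {
  mod <- exemplar_model()
  s1 <- simulate_cell(mod, t_stop = 200, settle = 100, record_dt = 0.1,
                      recordings = list(record("V", "soma", name = "v")))
  s2 <- simulate_cell(mod, t_stop = 200, settle = 100, record_dt = 0.1,
                      recordings = list(record("V", "soma", name = "v")))
  expect_identical(s1$traces, s2$traces)

  s0 <- simulate_cell(mod, t_stop = 0, settle = 0,
                      recordings = list(record("V", "soma", name = "v")))
  expect_equal(nrow(s0$traces), 0)
})

test_that("input resistance matches the analytic value and scaling law", {
  mod <- passive_sphere()
  rin <- input_resistance(mod)
  expect_equal(rin, 1 / (3e-5 * 1e-4) / 1e6, tolerance = 0.002) # 333.3 MOhm
  # doubling the membrane area halves Rin
  big <- passive_sphere()
  ct <- big$morphology$compartments
  big$morphology$compartments$area_cm2 <- ct$area_cm2 * 2
  expect_equal(input_resistance(big), rin / 2, tolerance = 0.002)
})

test_that("injected charge balances membrane current at steady state", {
  mod <- passive_sphere(e_leak = -70)
  sim <- simulate_cell(mod,
                       electrodes = list(current_step(0.02, onset = 0,
                                                      duration = 400)),
                       t_stop = 400, settle = 400, record_dt = 0.1,
                       recordings = list(record("V", "soma", name = "v")))
  v_ss <- utils::tail(sim$traces$v, 1)
  i_leak <- 3e-5 * 1e-4 * (v_ss - (-70)) * 1e6 # S * mV -> nA
  expect_lt(abs(i_leak - 0.02) / 0.02, 1e-5)
})

test_that("refining the time step preserves spikes and shifts times slightly", {
  mod <- exemplar_model()
  run <- function(dt) {
    simulate_cell(mod, t_stop = 1500, settle = 300, dt = dt,
                  record_dt = 0.025,
                  recordings = list(record("V", "soma", name = "v")))
  }
  s1 <- run(0.025)
  s2 <- run(0.005)
  t1 <- spike_times(s1, "v")
  t2 <- spike_times(s2, "v")
  # no spike creation or deletion, and the pacemaker period drifts by < 2%
  expect_equal(length(t1), length(t2))
  expect_gt(length(t1), 3)
  expect_lt(max(abs(diff(t1) - diff(t2)) / diff(t2)), 0.02)
  expect_lt(abs(t1[1] - t2[1]), 5)
})

test_that("a missing recording target fails before the simulation starts", {
  mod <- exemplar_model()
  expect_error(
    simulate_cell(mod, recordings = list(record("I_syn", index = 1)),
                  t_stop = 10),
    "recording target missing")
  expect_error(
    simulate_cell(mod, recordings = list(record("I_channel", "axon",
                                                channel = "HCN1")),
                  t_stop = 10),
    "recording target missing")
})
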