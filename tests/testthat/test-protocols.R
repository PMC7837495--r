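test_that("spike detection handles flat traces, thresholds and known peaks", {
  t <- seq(0, 100, by = 0.1)
  flat <- rep(-70, length(t))
  expect_length(detect_spikes(t, flat), 0)
  # three synthetic spikes with known peak times
  v <- rep(-65, length(t))
  for (pk in c(20, 50, 80)) {
    v <- v + 80 * exp(-((t - pk) / 0.6)^2)
  }
  spk <- detect_spikes(t, v)
  expect_length(spk, 3)
  expect_true(all(abs(spk - c(20, 50, 80)) <= 0.1))
  expect_length(detect_spikes(t, v, threshold = max(v) + 1), 0)
})

test_that("feature extraction follows hand arithmetic and stays consistent", {
  # perfectly periodic spike train: ISI CV = 0
  t <- seq(0, 300, by = 0.05)
  v <- rep(-65, length(t))
  for (pk in seq(20, 280, by = 20)) v <- v + 85 * exp(-((t - pk) / 0.5)^2)
  ft <- extract_features(t, v)
  expect_equal(ft$isi_cv, 0, tolerance = 1e-6)
  expect_equal(ft$spike_count, length(detect_spikes(t, v)))

  # ISIs {10, 20}: mean 15, sd 5 (population would be 5; sd() uses n-1)
  v2 <- rep(-65, length(t))
  for (pk in c(50, 60, 80)) v2 <- v2 + 85 * exp(-((t - pk) / 0.5)^2)
  ft2 <- extract_features(t, v2)
  expect_equal(ft2$isi_cv, stats::sd(c(10, 20)) / 15, tolerance = 1e-6)

  # fewer than two spikes: frequency and CV absent, not zero
  v3 <- rep(-65, length(t)); v3 <- v3 + 85 * exp(-((t - 50) / 0.5)^2)
  ft3 <- extract_features(t, v3)
  expect_true(is.na(ft3$isi_cv))
  expect_true(is.na(ft3$mean_frequency))
  expect_equal(ft3$spike_count, 1)
})

test_that("the exemplar model paces regularly in the validated range", {
  sim <- exemplar_spontaneous()
  spk <- spike_times(sim, "v")
  rate <- 1000 * length(spk) / 3000
  expect_gte(rate, 2); expect_lte(rate, 15)
  cv <- stats::sd(diff(spk)) / mean(diff(spk))
  expect_lt(cv, 0.3)
})

test_that("the f-I curve is monotone and close to linear when driven", {
  fi <- fixture("fi_curve", function() {
    run_fi(exemplar_model(), amplitudes = c(0.1, 0.2, 0.3, 0.4, 0.5),
           duration = 1500)
  })
  expect_true(all(diff(fi$frequency_hz) >= 0))
  expect_false(any(fi$depol_block))
  fit <- stats::lm(frequency_hz ~ amplitude_nA, data = fi)
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_gt(fi$frequency_hz[1], 0) # driven above the spontaneous rate
})

test_that("sag is HCN-borne: absent passively and under HCN block", {
  expect_lt(measure_sag(passive_surrogate()), 0.1)
  sag <- fixture("sag_exemplar", function() measure_sag(exemplar_model()))
  expect_gte(sag, 4.4); expect_lte(sag, 10)
  blocked <- switch_off(switch_off(exemplar_model(), "HCN1", block = 1),
                        "HCN2", block = 1)
  expect_lt(measure_sag(blocked), 0.5)
})

test_that("release from hyperpolarization accelerates firing transiently", {
  reb <- measure_rebound(exemplar_model())
  expect_gt(reb$rebound_hz, reb$baseline_hz)
})

test_that("a triggered spike resets the pacemaker cycle", {
  # pause is zero without a stimulus by definition
  none <- measure_phase_reset(exemplar_model(), amp = 0)
  expect_equal(none$pause_ms, 0)
  # a suprathreshold pulse delivered outside the deep-AHP third of the
  # cycle triggers a spike, and the cycle restarts from that spike: the
  # following interval matches the baseline period regardless of the
  # phase at which the pulse arrived
  spont <- exemplar_spontaneous()
  spk0 <- spike_times(spont, "v")
  isi0 <- mean(diff(spk0))
  anchor <- spk0[spk0 > 1500][1]
  for (phase in c(0.55, 0.8)) {
    tp <- anchor + phase * isi0
    sim <- simulate_cell(exemplar_model(),
                         electrodes = list(current_clamp("soma",
                                                         c(0, tp, tp + 5),
                                                         c(0, 1, 0))),
                         t_stop = tp + 600, settle = 500, record_dt = 0.1,
                         recordings = list(record("V", "soma", name = "v")))
    spk <- spike_times(sim, "v")
    post <- spk[spk > tp]
    expect_lt(post[1] - tp, 15)              # the pulse triggers a spike
    expect_lt(abs((post[2] - post[1]) - isi0) / isi0, 0.3) # cycle restarts
  }
})

test_that("the spike output resonates at low repetition frequencies", {
  res <- fixture("resonance", function() {
    measure_resonance(exemplar_model(), freqs = c(1, 2, 4, 8, 12))
  })
  peak <- res$rep_freq_hz[which.max(res$output_hz)]
  expect_lte(peak, 4)
})

test_that("switch-off with zero block leaves the model bit-identical", {
  mod <- exemplar_model()
  m0 <- switch_off(mod, "Cav2.2", block = 0)
  s1 <- simulate_cell(mod, t_stop = 300, settle = 100,
                      recordings = list(record("V", "soma", name = "v")))
  s2 <- simulate_cell(m0, t_stop = 300, settle = 100,
                      recordings = list(record("V", "soma", name = "v")))
  expect_identical(s1$traces$v, s2$traces$v)
  expect_error(switch_off(mod, "Kv9.9"), "no placement")
})

test_that("blocking the main dendritic calcium current uncovers slow firing", {
  blocked <- switch_off(exemplar_model(), "Cav2.2", block = 0.9)
  sim <- simulate_cell(blocked, t_stop = 4000, settle = 500, record_dt = 0.2,
                       recordings = list(record("V", "soma", name = "v")))
  spk <- spike_times(sim, "v")
  rate <- 1000 * length(spk) / 4000
  expect_gt(rate, 0)       # not silent, not plateau-locked
  expect_lte(rate, 5)      # slow oscillatory firing
  # and it stays off the depolarized plateau
  expect_lt(mean(sim$traces$v), -40)
})

test_that("spikes originate in the AIS and backpropagate asymmetrically", {
  sim <- fixture("bprop", function() {
    simulate_cell(exemplar_model(), t_stop = 700, settle = 400,
                  record_dt = 0.025,
                  recordings = list(
                    record("V", "AIS", name = "ais"),
                    record("V", "soma", name = "soma"),
                    record("V", "basal_dendrite:distal", name = "basal"),
                    record("V", "apical_dendrite:distal", name = "apical")))
  })
  tr <- sim$traces
  pk <- which.max(tr$ais)
  w <- max(1, pk - 200):min(nrow(tr), pk + 300)
  base <- function(x) stats::quantile(x[1:50], 0.1)
  amp <- function(x) max(x[w]) - base(x[w])
  a_ais <- amp(tr$ais); a_b <- amp(tr$basal); a_p <- amp(tr$apical)
  # AIS crosses threshold before the soma on the spontaneous spike
  t_ais <- tr$time[w][which(tr$ais[w] > -20)[1]]
  t_soma <- tr$time[w][which(tr$soma[w] > -20)[1]]
  expect_lte(t_ais, t_soma)
  # basal invasion is strong (50-80% of AIS), apical severely attenuated
  expect_gt(a_b / a_ais, a_p / a_ais)
  expect_gte(a_b / a_ais, 0.5); expect_lte(a_b / a_ais, 0.85)
  expect_lte(a_p / a_ais, 0.2)
})

test_that("synaptic thresholds search monotonically from a silenced cell", {
  m10 <- fixture("m10", function() discretize(make_surrogate(seed = 1), 10))
  mod <- place_synapses(cell_model(m10), counts = c(MF = 20), seed = 2)
  hold <- fixture("hold", function() silencing_current(mod))
  expect_lt(hold, 0)
  # no synapse, no spike at the holding current
  sim <- simulate_cell(mod,
                       electrodes = list(current_clamp("soma", 0, 1.3 * hold)),
                       t_stop = 600, settle = 500, record_dt = 0.1,
                       recordings = list(record("V", "soma", name = "v")))
  expect_length(spike_times(sim, "v"), 0)
  thr <- synapse_threshold(mod, "MF", hold = 1.3 * hold)
  expect_true(is.finite(thr))
  expect_gte(thr, 1)
  # monotonicity at the threshold: n-1 synapses do not spike, n do
  if (thr > 1) {
    mod2 <- mod
    rows <- which(mod$synapses$pathway == "MF")
    mod2$synapses <- mod$synapses[rows[seq_len(thr - 1)], ]
    sim2 <- simulate_cell(mod2,
                          electrodes = list(current_clamp("soma", 0,
                                                          1.3 * hold)),
                          stimuli = list(list(pathway = "MF", times = 30)),
                          t_stop = 80, settle = 600, record_dt = 0.1,
                          recordings = list(record("V", "soma", name = "v")))
    expect_length(spike_times(sim2, "v"), 0)
  }
})

test_that("synaptic bursts produce a spike burst followed by a pause", {
  mod10 <- fixture("mod10", function() {
    cell_model(fixture("m10", function() discretize(make_surrogate(seed = 1),
                                                    10)))
  })
  exc <- fixture("psth_exc", function() {
    run_psth(mod10, counts = c(MF = 20, AA = 20, PF = 89, INH = 0),
             n_trials = 2, seed = 10)
  })
  expect_gte(exc$summary$burst_spikes, 1)
  # the response is time-locked: the stimulus window reaches the global
  # maximum of the PSTH
  in_win <- exc$psth$bin_start_ms >= 495 & exc$psth$bin_start_ms <= 565
  expect_gte(max(exc$psth$count[in_win]), max(exc$psth$count[!in_win]))
  # the burst is followed by a pause much longer than the pacemaker cycle
  expect_gt(exc$summary$pause_ms, exc$summary$baseline_isi_ms)
  inh <- fixture("psth_inh", function() {
    run_psth(mod10, counts = c(MF = 20, AA = 20, PF = 89, INH = 20),
             inh_lag_ms = 10, n_trials = 2, seed = 10)
  })
  expect_lte(inh$summary$burst_spikes, exc$summary$burst_spikes)
  # pause length is insensitive to the excitation/inhibition lag in +/-10 ms
  lagm <- fixture("psth_lagm", function() {
    run_psth(mod10, counts = c(MF = 20, AA = 20, PF = 89, INH = 20),
             inh_lag_ms = -10, n_trials = 2, seed = 10)
  })
  pauses <- c(inh$summary$pause_ms, lagm$summary$pause_ms)
  expect_lt(diff(range(pauses)) / mean(pauses), 0.2)
})
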