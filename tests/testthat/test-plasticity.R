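test_that("the transfer function crosses zero exactly at the inversion point", {
  spec <- omega_spec()
  expect_identical(omega(0.75, spec), 0)
  expect_equal(omega(100, spec), 50, tolerance = 1e-6)
  expect_equal(omega(0, spec), -2 * 50 * (0.5 - stats::plogis(-7.5)),
               tolerance = 1e-9)
  ca <- seq(0, 2, by = 0.01)
  expect_true(all(diff(omega(ca, spec)) > 0))
  expect_true(all(abs(omega(ca, spec)) <= 50))
  # antisymmetric about theta in the sigmoid argument
  expect_equal(omega(0.75 + 0.3, spec), -omega(0.75 - 0.3, spec),
               tolerance = 1e-12)
})

test_that("NMDA calcium requires the NMDA conductance", {
  m10 <- fixture("m10", function() discretize(make_surrogate(seed = 1), 10))
  mod <- cell_model(m10)
  ca_on <- fixture("ca_on", function() {
    nmda_ca_transient(cell_model(fixture("m10", function()
      discretize(make_surrogate(seed = 1), 10))), dt_ms = 10, n_pf = 61)
  })
  pw <- synapse_defaults()
  pw$MF$receptors[[2]]$g_max_pS <- 1e-9
  ca_off <- nmda_ca_transient(mod, dt_ms = 10, n_pf = 61, pathways = pw)
  expect_gt(ca_on, 0.2)
  expect_lt(ca_off, 1e-6)
})

test_that("coincidence timing orders the calcium transients as in the model's
          LTP/LTD assignment", {
  m10 <- fixture("m10", function() discretize(make_surrogate(seed = 1), 10))
  mod <- cell_model(m10)
  ca_pos <- fixture("ca_on", function() nmda_ca_transient(mod, dt_ms = 10,
                                                           n_pf = 61))
  ca_neg <- fixture("ca_neg", function() nmda_ca_transient(mod, dt_ms = -10,
                                                           n_pf = 61))
  ca_alone <- fixture("ca_alone", function() nmda_ca_transient(mod,
                                                               dt_ms = 10,
                                                               n_pf = 0))
  # MF-before-bAP (positive dt) carries more calcium than bAP-before-MF
  expect_gt(ca_pos, ca_neg)
  # MF alone, without backpropagation, stays below the inversion point
  expect_lt(ca_alone, 0.75)
  # and the coincident case crosses into the LTP region
  expect_gt(ca_pos, 0.75)
  expect_gt(omega(ca_pos), 0)
  expect_lt(omega(ca_neg), 0)
})
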