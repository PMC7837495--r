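# Spike-timing dependent plasticity prediction at mossy fiber synapses:
# NMDA-receptor calcium transients evaluated through the calcium-control
# transfer function (LTD below, LTP above the inversion point).

#' Calcium-to-weight-change transfer function
#'
#' The sigmoidal transfer function of the calcium-control hypothesis:
#' `dW% = 2 * amplitude * (sigma(rate * (ca - theta)) - 1/2)`, which crosses
#' zero exactly at `theta`, saturates at plus/minus `amplitude`, and is
#' monotone increasing in calcium.
#'
#' @param theta LTP/LTD inversion point (uM), default 0.75.
#' @param rate Steepness (1/uM), default 10.
#' @param amplitude Maximal absolute weight change (%), default 50.
#' @return A `goc_omega_spec`.
#' @export
omega_spec <- function(theta = 0.75, rate = 10, amplitude = 50) {
  stopifnot(theta > 0, rate > 0, amplitude > 0)
  structure(list(theta = theta, rate = rate, amplitude = amplitude),
            class = "goc_omega_spec")
}

#' @rdname omega_spec
#' @param ca Peak calcium transient(s) above rest (uM).
#' @param spec An [omega_spec()].
#' @return Weight change(s) in percent, in `[-amplitude, +amplitude]`.
#' @export
omega <- function(ca, spec = omega_spec()) {
  stopifnot(all(ca >= 0))
  2 * spec$amplitude * (stats::plogis(spec$rate * (ca - spec$theta)) - 0.5)
}

# Integrate an NMDA calcium current (nA, inward negative) through the local
# synaptic calcium domain; returns peak Ca above rest in uM. The domain is a
# rapidly equilibrating microdomain: endogenous buffering (binding ratio
# `kappa`) attenuates the free-calcium increment and a first-order clearance
# with time constant `tau_dom` lumps extrusion and diffusion out of the
# domain. The peak therefore tracks the instantaneous NMDA influx rate (the
# coincidence signal) rather than its long time-integral. No store
# amplification is applied here.
nmda_shell_peak <- function(time, i_ca_nA, area_cm2, shell, pump_density,
                            kappa = 8, tau_dom = 2) {
  sh <- shell
  dt <- stats::median(diff(time))
  vol_L <- area_cm2 * sh$depth_um * 1e-4 * 1e-3
  peak <- 0
  ca <- sh$ca_rest
  for (i in seq_along(i_ca_nA)) {
    influx <- -i_ca_nA[i] * 1e-12 / (2 * 96485) / vol_L * 1e3 # mM/ms
    ca <- max(ca + (influx / (1 + kappa) - (ca - sh$ca_rest) / tau_dom) * dt,
              1e-9)
    if (ca > peak) peak <- ca
  }
  (peak - sh$ca_rest) * 1e3
}

#' NMDA calcium transient at a mossy fiber synapse
#'
#' Simulates the conjunction of mossy fiber activation with a parallel
#' fiber burst (5 impulses at 100 Hz by default), records the NMDA calcium
#' influx at one MF synapse, integrates it through the local submembrane
#' shell and applies the store amplification factor (3 by default). The
#' result is the peak calcium elevation above rest that drives the
#' plasticity transfer function.
#'
#' @param model A `goc_cell_model` (placement is done internally).
#' @param dt_ms PF burst onset minus MF event time (ms); positive means the
#'   MF event leads.
#' @param n_pf Number of parallel fiber synapses.
#' @param n_mf Number of mossy fiber synapses (the probe is the first).
#' @param n_inh Inhibitory synapses co-activated with the PF burst.
#' @param mf_burst If `TRUE` the mossy fibers also receive the 5-impulse
#'   burst; otherwise a single MF event (the timing-curve convention).
#' @param amplification Calcium-store amplification factor applied to the
#'   shell transient.
#' @param seed Placement seed.
#' @param pacemaking If `FALSE`, a holding current silences spontaneous
#'   spiking so only the PF-driven depolarization backpropagates.
#' @param pathways Pathway definitions ([synapse_defaults()]).
#' @return Peak calcium elevation (uM, amplified).
#' @export
nmda_ca_transient <- function(model, dt_ms = 10, n_pf = 61, n_mf = 11,
                              n_inh = 0, mf_burst = FALSE,
                              amplification = 3, seed = 1,
                              pacemaking = FALSE,
                              pathways = synapse_defaults()) {
  counts <- c(MF = n_mf, PF = n_pf)
  if (n_inh > 0) counts <- c(counts, INH = n_inh)
  mod <- place_synapses(model, counts = counts, seed = seed,
                        pathways = pathways)
  t0 <- 200
  burst <- t0 + dt_ms + (0:4) * 10
  mf_times <- if (mf_burst) t0 + (0:4) * 10 else t0
  stim <- list(list(pathway = "MF", times = mf_times))
  if (n_pf > 0) stim <- c(stim, list(list(pathway = "PF", times = burst)))
  if (n_inh > 0) stim <- c(stim, list(list(pathway = "INH", times = burst)))
  electrodes <- list()
  if (!pacemaking) {
    electrodes <- list(current_clamp("soma", 0, -0.022))
  }
  # NMDA instance of the first MF synapse: synapse entries are ordered by
  # stimulus block, MF first, receptors AMPA then NMDA per synapse
  nmda_index <- 2L
  sim <- simulate_cell(mod, electrodes = electrodes, stimuli = stim,
                       t_stop = 450, settle = 400, record_dt = 0.05,
                       recordings = list(record("I_syn", index = nmda_index,
                                                name = "i_nmda")))
  probe_comp <- mod$synapses$comp_id[mod$synapses$pathway == "MF"][1]
  area <- mod$morphology$compartments$area_cm2[probe_comp]
  ca_frac <- mod$pathways$MF$receptors[[2]]$ca_frac
  tr <- sim$traces
  keep <- tr$time >= t0 - 5
  peak <- nmda_shell_peak(tr$time[keep], ca_frac * tr$i_nmda[keep], area,
                          model$shell,
                          model$pump_densities[["basal_dendrite"]])
  amplification * peak
}

#' Spike-timing dependent plasticity curve
#'
#' One point per timing offset: the NMDA calcium transient at the probed
#' mossy fiber synapse is evaluated through the calcium-control transfer
#' function. Positive `dt` means the MF event precedes the PF-burst-driven
#' backpropagating depolarization.
#'
#' @param model A `goc_cell_model`.
#' @param dt_grid Timing offsets (ms), default -100..100 in 20 ms steps.
#' @param n_pf Parallel fiber count.
#' @param spec The [omega_spec()] transfer function.
#' @param ... Passed to [nmda_ca_transient()].
#' @return Tibble: `dt_ms`, `peak_ca_um`, `dw_percent`.
#' @export
stdp_curve <- function(model, dt_grid = seq(-100, 100, by = 20), n_pf = 61,
                       spec = omega_spec(), ...) {
  rows <- lapply(dt_grid, function(d) {
    ca <- nmda_ca_transient(model, dt_ms = d, n_pf = n_pf, ...)
    tibble(dt_ms = d, peak_ca_um = ca, dw_percent = omega(ca, spec))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("goc_stdp", class(out))
  out
}

#' Synaptic input-output surface
#'
#' Output firing frequency during the response window for combined
#' activation of mossy fibers (basal dendrites) and parallel fibers (apical
#' dendrites), each with a 5-impulse 100 Hz burst.
#'
#' @param model A `goc_cell_model`.
#' @param n_mf_grid,n_pf_grid Synapse-count grids.
#' @param n_inh Inhibitory synapses co-activated with the burst.
#' @param seed Placement seed.
#' @return Tibble: `n_mf`, `n_pf`, `output_hz`.
#' @export
io_surface <- function(model, n_mf_grid = c(0, 10, 20),
                       n_pf_grid = c(0, 30, 60), n_inh = 0, seed = 1) {
  t0 <- 300; win <- 80
  rows <- list()
  for (nm in n_mf_grid) {
    for (np in n_pf_grid) {
      counts <- c(MF = max(nm, 1), PF = max(np, 1))
      if (n_inh > 0) counts <- c(counts, INH = n_inh)
      mod <- place_synapses(model, counts = counts, seed = seed)
      burst <- t0 + (0:4) * 10
      stim <- list()
      if (nm > 0) stim <- c(stim, list(list(pathway = "MF", times = burst)))
      if (np > 0) stim <- c(stim, list(list(pathway = "PF", times = burst)))
      if (n_inh > 0) stim <- c(stim, list(list(pathway = "INH", times = burst)))
      sim <- simulate_cell(mod, stimuli = stim, t_stop = t0 + win + 50,
                           settle = 500, record_dt = 0.1,
                           recordings = list(record("V", "soma", name = "v")))
      spk <- spike_times(sim, "v")
      n_out <- sum(spk >= t0 & spk <= t0 + win)
      rows[[length(rows) + 1]] <- tibble(n_mf = nm, n_pf = np,
                                         output_hz = 1000 * n_out / win)
    }
  }
  dplyr::bind_rows(rows)
}
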