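# The stimulation/measurement battery: spike detection, scalar feature
# extraction, frequency-intensity curves, sag, rebound, phase reset,
# resonance, synaptic thresholds and PSTH burst-pause analysis.

#' Detect spikes in a voltage trace
#'
#' Upward crossings of `threshold` (default -20 mV); one event per crossing,
#' reported at the local peak time.
#'
#' @param time,v Uniformly sampled time (ms) and voltage (mV) vectors, or a
#'   `goc_sim` trace tibble via [spike_times()].
#' @param threshold Crossing threshold (mV).
#' @return Numeric vector of spike peak times (ms).
#' @export
detect_spikes <- function(time, v, threshold = -20) {
  stopifnot(length(time) == length(v))
  up <- which(diff(v > threshold) == 1) + 1
  vapply(up, function(i) {
    j <- i
    while (j < length(v) && v[j + 1] >= v[j]) j <- j + 1
    time[j]
  }, numeric(1))
}

#' @rdname detect_spikes
#' @param sim A `goc_sim`.
#' @param trace Trace column name (default the first non-time column).
#' @export
spike_times <- function(sim, trace = NULL, threshold = -20) {
  stopifnot(inherits(sim, "goc_sim"))
  trace <- trace %||% setdiff(names(sim$traces), "time")[1]
  detect_spikes(sim$traces$time, sim$traces[[trace]], threshold)
}

#' Extract scalar electrophysiological features from a voltage trace
#'
#' The six features used as the optimization template: action potential
#' width at half height (ms), AP height (peak minus threshold-crossing
#' voltage, mV), AHP depth (threshold-crossing voltage minus post-spike
#' minimum, mV), ISI coefficient of variation, mean firing frequency (Hz)
#' and spike count. Frequency and ISI CV require at least two spikes and are
#' reported as `NA` otherwise (absent, not zero).
#'
#' @param time,v Uniform time (ms) / voltage (mV) samples.
#' @param window Analysis window `c(t0, t1)` in ms (default whole trace).
#' @param threshold Spike detection threshold (mV).
#' @return A one-row tibble: `ap_width`, `ap_height`, `ahp_depth`, `isi_cv`,
#'   `mean_frequency`, `spike_count`.
#' @export
extract_features <- function(time, v, window = range(time), threshold = -20) {
  keep <- time >= window[1] & time <= window[2]
  time <- time[keep]; v <- v[keep]
  spk <- detect_spikes(time, v, threshold)
  n <- length(spk)
  widths <- heights <- ahps <- numeric(0)
  for (t0 in spk) {
    i <- which.min(abs(time - t0))
    lo <- max(1, i - 200); hi <- min(length(v), i + 400)
    # threshold-crossing voltage before the peak
    seg <- lo:i
    cross <- which(v[seg] > threshold)[1]
    if (is.na(cross)) next
    v_thr <- threshold
    peak <- v[i]
    half <- (peak + v_thr) / 2
    # sub-sample width at half height by linear interpolation around the peak
    j1 <- i
    while (j1 > lo && v[j1 - 1] >= half) j1 <- j1 - 1
    j2 <- i
    while (j2 < hi && v[j2 + 1] >= half) j2 <- j2 + 1
    if (j1 > lo && j2 < hi) {
      t_up <- time[j1 - 1] + (half - v[j1 - 1]) / (v[j1] - v[j1 - 1]) *
        (time[j1] - time[j1 - 1])
      t_dn <- time[j2] + (half - v[j2]) / (v[j2 + 1] - v[j2]) *
        (time[j2 + 1] - time[j2])
      widths <- c(widths, t_dn - t_up)
    }
    heights <- c(heights, peak - v_thr)
    # AHP: minimum between this spike and the next (or 25 ms)
    nxt <- spk[spk > t0][1]
    t_end <- if (is.na(nxt)) t0 + 25 else nxt
    post <- v[time > t0 & time <= t_end]
    if (length(post) > 0) ahps <- c(ahps, v_thr - min(post))
  }
  isi <- diff(spk)
  tibble(
    ap_width = if (length(widths)) mean(widths) else NA_real_,
    ap_height = if (length(heights)) mean(heights) else NA_real_,
    ahp_depth = if (length(ahps)) mean(ahps) else NA_real_,
    isi_cv = if (n >= 2) stats::sd(isi) / mean(isi) else NA_real_,
    mean_frequency = if (n >= 2) 1000 * n / diff(window) else NA_real_,
    spike_count = n
  )
}

# standard settled spontaneous run used by several protocols
run_spontaneous <- function(model, t_stop = 2000, settle = 500) {
  simulate_cell(model, t_stop = t_stop, settle = settle, record_dt = 0.1,
                recordings = list(record("V", "soma", name = "v")))
}

#' Spontaneous firing rate and regularity
#'
#' @param model A `goc_cell_model`.
#' @param t_stop Observation window (ms).
#' @param settle Settling time (ms).
#' @return Tibble with `rate_hz` and `isi_cv`.
#' @export
spontaneous_rate <- function(model, t_stop = 2000, settle = 500) {
  sim <- run_spontaneous(model, t_stop, settle)
  spk <- spike_times(sim, "v")
  isi <- diff(spk)
  tibble(rate_hz = 1000 * length(spk) / t_stop,
         isi_cv = if (length(isi) >= 2) stats::sd(isi) / mean(isi) else NA_real_)
}

#' Frequency-intensity curve
#'
#' Two-second somatic current steps; firing frequency from the spike count
#' in the step window. Depolarization block (spikes ceasing in the second
#' half of the step despite spikes in the first half) is flagged.
#'
#' @param model A `goc_cell_model`.
#' @param amplitudes Step amplitudes (nA).
#' @param duration Step duration (ms), default 2000 as in the validation
#'   protocol.
#' @return Tibble: `amplitude_nA`, `frequency_hz`, `depol_block`.
#' @export
run_fi <- function(model, amplitudes = seq(0.1, 0.6, by = 0.1),
                   duration = 2000) {
  rows <- lapply(amplitudes, function(a) {
    sim <- simulate_cell(model,
                         electrodes = list(current_step(a, onset = 0,
                                                        duration = duration)),
                         t_stop = duration, settle = 500, record_dt = 0.1,
                         recordings = list(record("V", "soma", name = "v")))
    spk <- spike_times(sim, "v")
    block <- length(spk) > 0 && max(spk) < duration / 2 && a > 0
    tibble(amplitude_nA = a, frequency_hz = 1000 * length(spk) / duration,
           depol_block = block)
  })
  dplyr::bind_rows(rows)
}

#' Sag during a hyperpolarizing current step
#'
#' Injects `amp` (negative, default -0.2 nA) for `dur` ms and reports the
#' sag depth: steady-state voltage in the last decile of the step minus the
#' hyperpolarization peak.
#'
#' @param model A `goc_cell_model`.
#' @param amp Step amplitude (nA), must be negative.
#' @param dur Step duration (ms), default 1000.
#' @return Sag depth (mV, non-negative).
#' @export
measure_sag <- function(model, amp = -0.2, dur = 1000) {
  stopifnot(amp < 0)
  onset <- 200
  sim <- simulate_cell(model,
                       electrodes = list(current_step(amp, onset = onset,
                                                      duration = dur)),
                       t_stop = onset + dur + 200, settle = 500,
                       record_dt = 0.1,
                       recordings = list(record("V", "soma", name = "v")))
  tr <- sim$traces
  instep <- tr$time > onset & tr$time <= onset + dur
  v_min <- min(tr$v[instep])
  tail_w <- tr$time > onset + 0.85 * dur & tr$time <= onset + 0.98 * dur
  v_ss <- mean(tr$v[tail_w])
  max(v_ss - v_min, 0)
}

#' Rebound firing after release from hyperpolarization
#'
#' Releases the cell from a hyperpolarizing step and compares the first
#' post-release instantaneous frequency with the spontaneous rate.
#'
#' @param model A `goc_cell_model`.
#' @param amp,dur Hyperpolarizing step (nA, ms).
#' @return Tibble: `rebound_hz` (first post-release instantaneous
#'   frequency), `baseline_hz`.
#' @export
measure_rebound <- function(model, amp = -0.2, dur = 1000) {
  stopifnot(amp < 0)
  onset <- 500
  sim <- simulate_cell(model,
                       electrodes = list(current_step(amp, onset = onset,
                                                      duration = dur)),
                       t_stop = onset + dur + 1000, settle = 500,
                       record_dt = 0.1,
                       recordings = list(record("V", "soma", name = "v")))
  spk <- spike_times(sim, "v")
  base <- spk[spk < onset]
  post <- spk[spk > onset + dur]
  base_hz <- if (length(base) >= 2) 1000 / mean(diff(base)) else
    1000 * length(base) / onset
  reb_hz <- if (length(post) >= 2) 1000 / diff(post)[1] else 0
  tibble(rebound_hz = reb_hz, baseline_hz = base_hz)
}

#' Phase reset by a brief depolarizing pulse
#'
#' Delivers a short current pulse during pacemaking and reports the pause:
#' the first post-pulse interspike interval minus the mean baseline ISI
#' (0 when no stimulus is applied).
#'
#' @param model A `goc_cell_model`.
#' @param amp Pulse amplitude (nA); 0 measures the control case.
#' @param width Pulse width (ms).
#' @return Tibble: `pause_ms`, `baseline_isi_ms`.
#' @export
measure_phase_reset <- function(model, amp = 0.2, width = 5) {
  t_pulse <- 2000
  sim <- simulate_cell(model,
                       electrodes = list(current_step(amp, onset = t_pulse,
                                                      duration = width)),
                       t_stop = 3500, settle = 500, record_dt = 0.1,
                       recordings = list(record("V", "soma", name = "v")))
  spk <- spike_times(sim, "v")
  base <- spk[spk < t_pulse]
  if (length(base) < 3) {
    rlang::abort("phase-reset undefined: no baseline pacemaking")
  }
  base_isi <- mean(diff(base))
  if (amp == 0) return(tibble(pause_ms = 0, baseline_isi_ms = base_isi))
  post <- spk[spk > t_pulse]
  first_isi <- if (length(post) >= 2) diff(post)[1] else Inf
  tibble(pause_ms = max(first_isi - base_isi, 0), baseline_isi_ms = base_isi)
}

#' Resonance of the spike output to repetitive current steps
#'
#' Eight cycles of square current steps (50% duty) at each repetition
#' frequency; the output measure is the mean intra-burst instantaneous
#' frequency over the ON phases (0 when no ON phase contains at least two
#' spikes). The resonance frequency is the repetition frequency maximizing
#' the output.
#'
#' @param model A `goc_cell_model`.
#' @param freqs Repetition frequencies to probe (Hz).
#' @param amp Step amplitude (nA).
#' @param n_cycles Cycles per frequency.
#' @return Tibble: `rep_freq_hz`, `output_hz`; the resonance peak is
#'   `rep_freq_hz[which.max(output_hz)]`.
#' @export
measure_resonance <- function(model, freqs = c(1, 2, 3, 4, 6, 8, 10, 15),
                              amp = 0.1, n_cycles = 8) {
  rows <- lapply(freqs, function(f) {
    per <- 1000 / f
    times <- c(0, as.vector(rbind((0:(n_cycles - 1)) * per,
                                  (0:(n_cycles - 1)) * per + per / 2)))
    vals <- c(0, rep(c(amp, 0), n_cycles))
    o <- order(times)
    sim <- simulate_cell(model,
                         electrodes = list(current_clamp("soma", times[o], vals[o])),
                         t_stop = n_cycles * per, settle = 500, record_dt = 0.1,
                         recordings = list(record("V", "soma", name = "v")))
    spk <- spike_times(sim, "v")
    isis <- c()
    for (k in 0:(n_cycles - 1)) {
      s <- spk[spk >= k * per & spk < (k + 0.5) * per]
      if (length(s) > 1) isis <- c(isis, diff(s))
    }
    tibble(rep_freq_hz = f,
           output_hz = if (length(isis)) 1000 / mean(isis) else 0)
  })
  dplyr::bind_rows(rows)
}

#' Resonance peak frequency
#'
#' @inheritParams measure_resonance
#' @return The repetition frequency (Hz) with maximal output.
#' @export
resonance_peak <- function(model, freqs = c(1, 2, 3, 4, 6, 8, 10, 15),
                           amp = 0.1, n_cycles = 8) {
  curve <- measure_resonance(model, freqs, amp, n_cycles)
  curve$rep_freq_hz[which.max(curve$output_hz)]
}

#' Minimal holding current that silences pacemaking
#'
#' Bisection on the (negative) somatic holding current until spontaneous
#' spiking stops; used to poise the cell just below threshold for the
#' synaptic-threshold protocol.
#'
#' @param model A `goc_cell_model`.
#' @param lo,hi Bracketing currents (nA); `lo` must silence.
#' @param tol Bisection tolerance (nA).
#' @return Holding current (nA, negative).
#' @export
silencing_current <- function(model, lo = -0.1, hi = 0, tol = 0.002) {
  silent <- function(h) {
    sim <- simulate_cell(model, electrodes = list(current_clamp("soma", 0, h)),
                         t_stop = 1500, settle = 500, record_dt = 0.1,
                         recordings = list(record("V", "soma", name = "v")))
    length(spike_times(sim, "v")) == 0
  }
  if (!silent(lo)) rlang::abort("bracketing current does not silence the cell")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (silent(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Number of synchronous synapses needed to elicit a spike
#'
#' With pacemaking suppressed by a small negative holding current, an
#' increasing number of synapses of one pathway is activated with a single
#' synchronous stimulus until at least one spike occurs within 50 ms
#' (monotone search).
#'
#' @param model A placed model ([place_synapses()]).
#' @param pathway `"MF"`, `"AA"`, `"PF"` or `"INH"`.
#' @param hold Holding current (nA); default 1.3 times the minimal
#'   silencing current.
#' @param n_max Search limit (capacity of the pathway by default).
#' @return Integer threshold count, or `Inf` if no spike up to `n_max`
#'   (reported as "greater than capacity").
#' @export
synapse_threshold <- function(model, pathway = "MF", hold = NULL,
                              n_max = NULL) {
  if (is.null(model$synapses)) rlang::abort("place synapses first")
  rows <- which(model$synapses$pathway == pathway)
  if (length(rows) == 0) rlang::abort(paste0("no ", pathway, " synapses placed"))
  if (is.null(n_max)) n_max <- length(rows)
  if (is.null(hold)) hold <- 1.3 * silencing_current(model)
  one <- function(n) {
    mod2 <- model
    mod2$synapses <- model$synapses[rows[seq_len(n)], ]
    sim <- simulate_cell(mod2,
                         electrodes = list(current_clamp("soma", 0, hold)),
                         stimuli = list(list(pathway = pathway, times = 30)),
                         t_stop = 80, settle = 600, record_dt = 0.1,
                         recordings = list(record("V", "soma", name = "v")))
    any(spike_times(sim, "v") > 30)
  }
  for (n in seq_len(n_max)) if (one(n)) return(n)
  Inf
}

#' Peristimulus time histogram of the response to synaptic bursts
#'
#' Delivers a short train (default 5 impulses at 100 Hz) through the
#' excitatory pathways (and optionally inhibition at a lag) over `n_trials`
#' placement seeds, and summarizes the response burst and the subsequent
#' pause.
#'
#' @param model An unplaced `goc_cell_model` (placement is redrawn per
#'   trial).
#' @param counts Synapse counts per pathway.
#' @param inh_lag_ms Lag of the inhibitory train relative to excitation
#'   (ms); ignored when no INH synapses are requested.
#' @param n_impulses,rate_hz Burst shape.
#' @param n_trials Number of placement seeds.
#' @param seed Base seed; trial k uses `seed + k`.
#' @param bin_ms PSTH bin width.
#' @param t_stim Stimulus onset (ms) within the 1-second observation.
#' @return A list: `psth` tibble (`bin_start_ms`, `count`, `rate_hz`) and
#'   `summary` tibble (`burst_spikes` per trial mean, `pause_ms`,
#'   `baseline_isi_ms`).
#' @export
run_psth <- function(model, counts = c(MF = 20, AA = 20, PF = 89, INH = 0),
                     inh_lag_ms = 10, n_impulses = 5, rate_hz = 100,
                     n_trials = 5, seed = 1, bin_ms = 5, t_stim = 500) {
  train <- t_stim + (0:(n_impulses - 1)) * 1000 / rate_hz
  all_spk <- list()
  burst_n <- pause <- base_isi <- numeric(n_trials)
  t_stop <- 1800
  for (k in seq_len(n_trials)) {
    mk <- place_synapses(model, counts = counts, seed = seed + k)
    stim <- list(list(pathway = "MF", times = train),
                 list(pathway = "AA", times = train),
                 list(pathway = "PF", times = train))
    if ("INH" %in% names(counts) && counts[["INH"]] > 0) {
      stim <- c(stim, list(list(pathway = "INH", times = train + inh_lag_ms)))
    }
    sim <- simulate_cell(mk, stimuli = stim, t_stop = t_stop, settle = 500,
                         record_dt = 0.1,
                         recordings = list(record("V", "soma", name = "v")))
    spk <- spike_times(sim, "v")
    all_spk[[k]] <- spk
    base <- spk[spk < t_stim]
    base_isi[k] <- if (length(base) >= 2) mean(diff(base)) else NA_real_
    burst_end <- max(train) + 25
    burst_n[k] <- sum(spk >= t_stim & spk <= burst_end)
    post <- spk[spk > burst_end]
    last_in <- if (any(spk <= burst_end)) max(spk[spk <= burst_end]) else burst_end
    pause[k] <- if (length(post) >= 1) post[1] - last_in else t_stop - last_in
  }
  spk <- unlist(all_spk)
  breaks <- seq(0, t_stop, by = bin_ms)
  h <- graphics::hist(spk, breaks = breaks, plot = FALSE)
  list(
    psth = tibble(bin_start_ms = utils::head(breaks, -1), count = h$counts,
                  rate_hz = 1000 * h$counts / (bin_ms * n_trials)),
    summary = tibble(burst_spikes = mean(burst_n), pause_ms = mean(pause),
                     baseline_isi_ms = mean(base_isi, na.rm = TRUE))
  )
}

#' Scan burst/pause against inhibition count and excitation/inhibition lag
#'
#' @param model An unplaced model.
#' @param inh_counts Numbers of inhibitory synapses to test.
#' @param lags_ms Inhibition lags relative to excitation (ms).
#' @param ... Passed to [run_psth()].
#' @return Tibble: `n_inh`, `lag_ms`, `burst_spikes`, `pause_ms`.
#' @export
scan_inhibition <- function(model, inh_counts = c(0, 10, 20),
                            lags_ms = c(-10, 0, 10), ...) {
  rows <- list()
  for (ni in inh_counts) {
    for (lag in (if (ni == 0) 0 else lags_ms)) {
      r <- run_psth(model,
                    counts = c(MF = 20, AA = 20, PF = 89, INH = ni),
                    inh_lag_ms = lag, ...)
      rows[[length(rows) + 1]] <- tibble(n_inh = ni, lag_ms = lag,
                                         burst_spikes = r$summary$burst_spikes,
                                         pause_ms = r$summary$pause_ms)
    }
  }
  dplyr::bind_rows(rows)
}
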