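# Cell model assembly and the simulation front end over the compiled
# implicit cable solver.

#' Passive membrane parameters
#'
#' Defaults of the Golgi cell models: axial resistance 122 Ohm cm everywhere;
#' specific capacitance 1 uF/cm^2 except 2.5 uF/cm^2 in dendrites; leak
#' 3e-5 S/cm^2 except 1e-6 S/cm^2 in the axon; leak reversal -55 mV (set to
#' sustain the correct pacemaker frequency).
#'
#' @param ra Axial resistivity (Ohm cm).
#' @param cm,cm_dendrite Specific capacitance (uF/cm^2).
#' @param gl,gl_axon Leak conductance density (S/cm^2).
#' @param e_leak Leak reversal potential (mV).
#' @return Named list of passive parameters.
#' @export
passive_defaults <- function(ra = 122, cm = 1, cm_dendrite = 2.5,
                             gl = 3e-5, gl_axon = 1e-6, e_leak = -55) {
  list(ra = ra, cm = cm, cm_dendrite = cm_dendrite, gl = gl,
       gl_axon = gl_axon, e_leak = e_leak)
}

#' Build a conductance-based cell model
#'
#' Combines a discretized morphology with a channel placement registry,
#' channel kinetic definitions, passive parameters and calcium shell
#' settings into a simulatable model. The registry's `gmax` column is the
#' genome of the model: [optimize_conductances()] searches within
#' `[bound_lo, bound_hi]`.
#'
#' @param morphology A `goc_morphology` (discretized with [discretize()];
#'   discretized automatically at 20 um otherwise).
#' @param registry Channel placement tibble, see [default_channel_registry()].
#' @param channels Named list of channel definitions
#'   ([default_channels()]).
#' @param passive Passive parameters ([passive_defaults()]).
#' @param temperature Working temperature, degrees C (default 32, as in the
#'   slice recordings the kinetics are normalized to).
#' @param shell Calcium shell settings ([calcium_shell()]); pump density is
#'   overridden per section by `pump_densities`.
#' @param pump_densities Named vector of pump surface densities per section
#'   label (mol/cm^2), see [default_pump_densities()].
#' @return A `goc_cell_model`.
#' @export
cell_model <- function(morphology, registry = default_channel_registry(),
                       channels = default_channels(),
                       passive = passive_defaults(), temperature = 32,
                       shell = calcium_shell(),
                       pump_densities = default_pump_densities()) {
  stopifnot(inherits(morphology, "goc_morphology"))
  if (is.null(morphology$compartments)) morphology <- discretize(morphology, 20)
  keys <- sprintf("%s@%s", registry$channel, registry$section)
  keys[!(keys %in% names(channels))] <- registry$channel[!(keys %in% names(channels))]
  missing_ch <- setdiff(unique(keys), names(channels))
  if (length(missing_ch) > 0) {
    rlang::abort(paste0("registry places unknown channel: ", missing_ch[1]))
  }
  bad <- registry$gmax < registry$bound_lo - 1e-12 |
    registry$gmax > registry$bound_hi + 1e-12
  if (any(bad)) {
    rlang::warn(paste0("gmax outside optimization bounds for ",
                       registry$channel[bad][1], "/", registry$section[bad][1]))
  }
  structure(list(morphology = morphology, registry = registry,
                 channels = channels, passive = passive,
                 temperature = temperature, shell = shell,
                 pump_densities = pump_densities,
                 synapses = NULL),
            class = "goc_cell_model")
}

#' @export
print.goc_cell_model <- function(x, ...) {
  cat("<goc_cell_model> ", nrow(x$morphology$compartments), " compartments, ",
      nrow(x$registry), " channel placements, T = ", x$temperature, " C\n",
      sep = "")
  invisible(x)
}

#' Scale a channel conductance to mimic pharmacological blockade
#'
#' Multiplies the maximum conductance of `channel` in the given sections by
#' `1 - block`; everything else is untouched.
#'
#' @param model A `goc_cell_model`.
#' @param channel Channel name.
#' @param section Section label(s); default all sections carrying the
#'   channel.
#' @param block Blocked fraction in `[0, 1]` (0.9 = 90% block).
#' @return The modified model.
#' @export
switch_off <- function(model, channel, section = NULL, block = 0.9) {
  stopifnot(inherits(model, "goc_cell_model"), block >= 0, block <= 1)
  reg <- model$registry
  hit <- reg$channel == channel
  if (!is.null(section)) hit <- hit & reg$section %in% section
  if (!any(hit)) {
    rlang::abort(paste0("no placement of ", channel, " in ",
                        paste(section, collapse = "/")))
  }
  reg$gmax[hit] <- reg$gmax[hit] * (1 - block)
  reg$free[hit] <- FALSE
  model$registry <- reg
  model
}

# resolve a compartment reference: integer id, or a section label meaning the
# middle compartment of that label, or "<label>:distal" for the most distal
resolve_comp <- function(model, where) {
  ct <- model$morphology$compartments
  if (is.numeric(where)) {
    if (!(where %in% ct$comp_id)) rlang::abort("unknown compartment id")
    return(as.integer(where))
  }
  parts <- strsplit(where, ":", fixed = TRUE)[[1]]
  lab <- parts[1]
  pos <- if (length(parts) > 1) parts[2] else "mid"
  rows <- which(ct$label == lab)
  if (length(rows) == 0) rlang::abort(paste0("no compartment with label ", lab))
  sel <- switch(pos,
    mid = rows[which.min(abs(ct$path_dist_um[rows] -
                               stats::median(ct$path_dist_um[rows])))],
    distal = rows[which.max(ct$path_dist_um[rows])],
    proximal = rows[which.min(ct$path_dist_um[rows])],
    rlang::abort("position must be mid, distal or proximal"))
  ct$comp_id[sel]
}

#' Electrodes
#'
#' `current_clamp()` injects a piecewise-constant current waveform;
#' `current_step()` is a convenience for a single step on a baseline;
#' `voltage_clamp()` holds the target compartment at a piecewise-constant
#' command potential through a series resistance (default 0.01 MOhm,
#' effectively ideal).
#'
#' @param comp Compartment id or section label (see Details in
#'   [simulate_cell()]).
#' @param times Non-decreasing waveform switch times (ms).
#' @param values Current (nA) or command potential (mV) from each switch
#'   time onward.
#' @param rs_mohm Series resistance for voltage clamp (MOhm).
#' @return An electrode specification.
#' @export
current_clamp <- function(comp = "soma", times, values) {
  stopifnot(length(times) == length(values), !is.unsorted(times))
  structure(list(mode = 0L, comp = comp, t = as.numeric(times),
                 val = as.numeric(values), rs_mohm = 0),
            class = "gc_electrode")
}

#' @rdname current_clamp
#' @param amp Step amplitude (nA).
#' @param onset,duration Step timing (ms).
#' @param baseline Holding current outside the step (nA).
#' @export
current_step <- function(amp, onset = 100, duration = 2000, comp = "soma",
                         baseline = 0) {
  current_clamp(comp, c(0, onset, onset + duration),
                c(baseline, baseline + amp, baseline))
}

#' @rdname current_clamp
#' @export
voltage_clamp <- function(comp = "soma", times, values, rs_mohm = 0.01) {
  stopifnot(length(times) == length(values), !is.unsorted(times), rs_mohm >= 0)
  structure(list(mode = 1L, comp = comp, t = as.numeric(times),
                 val = as.numeric(values),
                 rs_mohm = max(rs_mohm, 1e-4)),
            class = "gc_electrode")
}

#' Recording specification
#'
#' @param var One of `"V"` (membrane potential, mV), `"Ca"` (shell calcium,
#'   mM), `"I_syn"` (synaptic current, nA; `index` = synapse row),
#'   `"I_clamp"` (electrode current, nA; `index` = electrode position) or
#'   `"I_channel"` (channel current, nA; give `channel` and a compartment).
#' @param comp Compartment id or section label.
#' @param index Synapse/electrode index for `I_syn` / `I_clamp`.
#' @param channel Channel name for `I_channel`.
#' @param name Trace name; autogenerated when `NULL`.
#' @return A recording specification.
#' @export
record <- function(var = "V", comp = "soma", index = 1L, channel = NULL,
                   name = NULL) {
  var <- match.arg(var, c("V", "Ca", "I_syn", "I_clamp", "I_channel"))
  structure(list(var = var, comp = comp, index = as.integer(index),
                 channel = channel, name = name),
            class = "gc_recording")
}

# ---------------------------------------------------------------------------

gate_to_c <- function(g) {
  if (g$kind == "v") {
    c(kind = 0, exponent = g$exponent, vhalf = g$vhalf, k = g$k,
      tau_min = g$tau_min, tau_amp = g$tau_amp, tau_vhalf = g$tau_vhalf,
      tau_ka = g$tau_ka, tau_kb = g$tau_kb, n = 0, kd = 0, tau = 0)
  } else {
    c(kind = 1, exponent = g$exponent, vhalf = 0, k = 1, tau_min = 0,
      tau_amp = 0, tau_vhalf = 0, tau_ka = 1, tau_kb = 1,
      n = g$n, kd = g$kd, tau = g$tau)
  }
}

# build the solver workspace from a model (Hines-ordered arrays)
assemble <- function(model, stimuli = NULL, extra_synapses = NULL) {
  ct <- model$morphology$compartments
  n <- nrow(ct)
  if (any(is.na(ct$parent_comp) & ct$comp_id != ct$comp_id[1])) {
    first_na <- which(is.na(ct$parent_comp))
    if (length(first_na) != 1) rlang::abort("assembly error: disconnected compartment")
  }
  pas <- model$passive
  cm <- ifelse(ct$label %in% c("basal_dendrite", "apical_dendrite"),
               pas$cm_dendrite, pas$cm)
  gl <- ifelse(ct$label == "axon", pas$gl_axon, pas$gl)
  g_axial <- ifelse(is.na(ct$parent_comp), 0, 100 / (pas$ra * ct$ri_geom))
  reg <- model$registry
  chans <- list()
  for (r in seq_len(nrow(reg))) {
    key <- sprintf("%s@%s", reg$channel[r], reg$section[r])
    def <- model$channels[[key]] %||% model$channels[[reg$channel[r]]]
    comps <- which(ct$label == reg$section[r])
    if (length(comps) == 0) next
    tf <- q10_factor(def$q10, model$temperature, def$ref_temp)
    entry <- list(kind = if (def$kind == "hh") 0L else 1L,
                  comps = as.integer(comps - 1L),
                  gbar_uS = reg$gmax[r] * ct$area_cm2[comps] * 1e6,
                  erev = def$erev, is_ca = isTRUE(def$is_calcium), tf = tf,
                  name = def$name, section = reg$section[r])
    if (def$kind == "hh") {
      entry$gates <- lapply(def$gates, gate_to_c)
    } else {
      entry$n_states <- def$n_states
      entry$open_states <- as.integer(def$open_states - 1L)
      tr <- def$transitions
      entry$trans <- cbind(tr$from - 1, tr$to - 1, tr$base, tr$vhalf, tr$kv,
                           tr$ca_pow)
    }
    chans[[length(chans) + 1]] <- entry
  }
  # calcium shells: one per compartment of every section with a pump density
  sh <- model$shell
  shells <- list(); shell_of <- rep(-1L, n)
  for (i in seq_len(n)) {
    dens <- model$pump_densities[[ct$label[i]]]
    if (is.null(dens) || is.na(dens)) next
    area <- ct$area_cm2[i]
    vol_L <- area * sh$depth_um * 1e-4 * 1e-3
    shells[[length(shells) + 1]] <- list(
      ca_rest = sh$ca_rest,
      pump_vmax = dens * sh$pump_turnover,
      pump_km = sh$pump_km,
      factor = 1e-12 / (2 * 96485) / vol_L * 1e3,
      surf_to_conc = area / vol_L * 1e3,
      b_tot = vapply(sh$buffers, `[[`, numeric(1), "total"),
      b_kon = vapply(sh$buffers, `[[`, numeric(1), "kon"),
      b_koff = vapply(sh$buffers, `[[`, numeric(1), "koff")
    )
    shell_of[i] <- length(shells) - 1L
  }
  syns <- build_synapse_ws(model, stimuli, extra_synapses)
  list(parent = as.integer(ifelse(is.na(ct$parent_comp), -1L,
                                  ct$parent_comp - 1L)),
       cap_nF = cm * ct$area_cm2 * 1e3,
       gl_uS = gl * ct$area_cm2 * 1e6,
       e_leak = rep(pas$e_leak, n),
       g_axial_uS = g_axial,
       area_cm2 = ct$area_cm2,
       channels = chans, shells = shells, shell_of = shell_of,
       synapses = syns)
}

#' Simulate a cell model
#'
#' Runs the implicit compartmental integration: one backward-Euler voltage
#' update per time step on the Hines-ordered tree, interleaved (staggered)
#' with exponential-integrator gate updates, implicit Markov updates,
#' calcium shell dynamics and synaptic state. Deterministic given model and
#' protocol. The model is first settled for `settle` ms (discarded) from
#' `v_init` with all waveforms held at their t = 0 value.
#'
#' Compartment references in electrodes and recordings may be an integer
#' compartment id or a section label (`"soma"`, `"AIS"`, `"axon"`,
#' `"basal_dendrite"`, `"apical_dendrite"`), optionally suffixed
#' `:mid` / `:distal` / `:proximal`.
#'
#' @param model A `goc_cell_model`.
#' @param electrodes List of [current_clamp()] / [voltage_clamp()]
#'   specifications.
#' @param recordings List of [record()] specifications.
#' @param t_stop Simulated time after settling (ms).
#' @param dt Fixed time step (ms), default 0.025.
#' @param v_init Initial potential (mV).
#' @param settle Settling time discarded before t = 0 (ms).
#' @param record_dt Sampling interval of recordings (ms), default `dt`.
#' @param stimuli Synaptic stimulation: a list of `list(pathway =, times =)`
#'   entries delivering presynaptic spike trains to all placed synapses of
#'   that pathway (see [place_synapses()]).
#' @param extra_synapses Ad-hoc synapses for calibration protocols: a list
#'   of `list(comp =, receptor = receptor_spec(), tm = tm_spec(), times =)`.
#' @return A `goc_sim` object: tibble `traces` (column `time` plus one
#'   column per recording) and the run metadata.
#' @export
simulate_cell <- function(model, electrodes = list(),
                          recordings = list(record("V", "soma")),
                          t_stop = 1000, dt = 0.025, v_init = -70,
                          settle = 100, record_dt = dt, stimuli = NULL,
                          extra_synapses = NULL) {
  stopifnot(inherits(model, "goc_cell_model"), dt > 0, t_stop >= 0)
  if (inherits(electrodes, "gc_electrode")) electrodes <- list(electrodes)
  if (inherits(recordings, "gc_recording")) recordings <- list(recordings)
  ws <- assemble(model, stimuli = stimuli, extra_synapses = extra_synapses)
  ws$electrodes <- lapply(electrodes, function(e) {
    list(mode = e$mode, comp = resolve_comp(model, e$comp) - 1L,
         t = e$t, val = e$val,
         g_clamp = if (e$mode == 1L) 1 / e$rs_mohm else 0)
  })
  spec <- matrix(0L, nrow = length(recordings), ncol = 3)
  nms <- character(length(recordings))
  for (i in seq_along(recordings)) {
    rc <- recordings[[i]]
    kind <- match(rc$var, c("V", "Ca", "I_syn", "I_clamp", "I_channel")) - 1L
    if (rc$var %in% c("V", "Ca")) {
      cmp <- resolve_comp(model, rc$comp)
      spec[i, ] <- c(kind, cmp - 1L, 0L)
      nms[i] <- rc$name %||% paste0(tolower(rc$var), "_", rc$comp)
    } else if (rc$var == "I_syn") {
      if (length(ws$synapses) < rc$index) {
        rlang::abort("recording target missing: synapse index out of range")
      }
      spec[i, ] <- c(kind, rc$index - 1L, 0L)
      nms[i] <- rc$name %||% paste0("i_syn_", rc$index)
    } else if (rc$var == "I_clamp") {
      if (length(ws$electrodes) < rc$index) {
        rlang::abort("recording target missing: electrode index out of range")
      }
      spec[i, ] <- c(kind, rc$index - 1L, 0L)
      nms[i] <- rc$name %||% paste0("i_clamp_", rc$index)
    } else {
      cmp <- resolve_comp(model, rc$comp)
      hit <- NULL
      for (ci in seq_along(ws$channels)) {
        ch <- ws$channels[[ci]]
        if (ch$name == rc$channel && (cmp - 1L) %in% ch$comps) {
          hit <- c(ci - 1L, which(ch$comps == cmp - 1L) - 1L)
          break
        }
      }
      if (is.null(hit)) {
        rlang::abort(paste0("recording target missing: channel ", rc$channel,
                            " not present in compartment"))
      }
      spec[i, ] <- c(4L, hit[1], hit[2])
      nms[i] <- rc$name %||% paste0("i_", rc$channel, "_", rc$comp)
    }
  }
  res <- sim_run(ws, t_stop, dt, v_init,
                 list(spec = spec), record_dt, settle)
  traces <- tibble::as_tibble(as.data.frame(res$traces, col.names = nms))
  names(traces) <- nms
  traces <- dplyr::bind_cols(tibble(time = as.numeric(res$time)), traces)
  structure(list(traces = traces, dt = dt, record_dt = record_dt,
                 t_stop = t_stop, v_init = v_init, settle = settle),
            class = "goc_sim")
}

#' @export
print.goc_sim <- function(x, ...) {
  cat("<goc_sim> ", x$t_stop, " ms at dt ", x$dt, " ms; traces: ",
      paste(setdiff(names(x$traces), "time"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Input resistance from a somatic voltage-clamp step
#'
#' Holds the soma at -70 mV and steps to -80 mV for 100 ms; the input
#' resistance is 10 mV over the steady-state current difference.
#'
#' @param model A `goc_cell_model`.
#' @param passive_only If `TRUE`, strip all active channels first (passive
#'   measurement).
#' @return Input resistance (MOhm).
#' @export
input_resistance <- function(model, passive_only = FALSE) {
  if (passive_only) model$registry <- model$registry[0, ]
  vc <- voltage_clamp("soma", c(0, 100, 200), c(-70, -80, -70))
  sim <- simulate_cell(model, electrodes = list(vc),
                       recordings = list(record("I_clamp", index = 1)),
                       t_stop = 200, settle = 300, v_init = -70)
  tr <- sim$traces
  i_base <- mean(tr$i_clamp_1[tr$time > 90 & tr$time <= 100])
  i_step <- mean(tr$i_clamp_1[tr$time > 190 & tr$time <= 200])
  d_i <- i_base - i_step
  if (!is.finite(d_i) || abs(d_i) < 1e-12) {
    rlang::abort("measurement error: clamp current did not reach steady state")
  }
  10 / abs(d_i)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
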