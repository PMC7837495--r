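# Dynamic synapses: Tsodyks-Markram presynaptic release, transmitter
# waveform, receptor kinetics (AMPA, NMDA-NR2B, GABA-A) and placement rules
# for the four input pathways (parallel fiber, ascending axon, mossy fiber,
# inhibitory).

#' Tsodyks-Markram release specification
#'
#' @param p Release probability (initial utilization), in (0, 1].
#' @param tau_rec Recovery time constant (ms).
#' @param tau_fac Facilitation time constant (ms).
#' @return A `gc_tm_spec`.
#' @export
tm_spec <- function(p, tau_rec, tau_fac) {
  stopifnot(p > 0, p <= 1, tau_rec > 0, tau_fac > 0)
  structure(list(p = p, tau_rec = tau_rec, tau_fac = tau_fac),
            class = "gc_tm_spec")
}

#' Event-driven Tsodyks-Markram release
#'
#' Closed-form recursion between presynaptic spikes: facilitation decays as
#' `u <- u * exp(-dt/tau_fac)` then jumps `u <- u + p * (1 - u)`; resources
#' recover as `R <- 1 - (1 - R * (1 - u_prev)) * exp(-dt/tau_rec)`. The
#' released fraction at each spike is `u * R`. The first spike releases
#' exactly `p`.
#'
#' @param spec A [tm_spec()].
#' @param spike_times Strictly increasing presynaptic spike times (ms).
#' @return Tibble with `time`, `u`, `R`, `release`.
#' @export
tm_release <- function(spec, spike_times) {
  stopifnot(inherits(spec, "gc_tm_spec"))
  n <- length(spike_times)
  if (n == 0) {
    return(tibble(time = numeric(), u = numeric(), R = numeric(),
                  release = numeric()))
  }
  if (n > 1 && any(diff(spike_times) <= 0)) {
    rlang::abort("spike times must be strictly increasing")
  }
  u <- numeric(n); R <- numeric(n)
  u_cur <- 0; R_cur <- 1
  t_prev <- -Inf
  for (k in seq_len(n)) {
    dt <- spike_times[k] - t_prev
    if (is.finite(dt)) {
      u_prev <- u_cur
      u_cur <- u_cur * exp(-dt / spec$tau_fac)
      R_cur <- 1 - (1 - R_cur * (1 - u_prev)) * exp(-dt / spec$tau_rec)
    }
    u_cur <- u_cur + spec$p * (1 - u_cur)
    u[k] <- u_cur; R[k] <- R_cur
    t_prev <- spike_times[k]
  }
  tibble(time = spike_times, u = u, R = R, release = u * R)
}

#' Paired-pulse ratio of a release specification
#'
#' Ratio of the second to the first released fraction for a spike pair.
#'
#' @param spec A [tm_spec()].
#' @param interval Inter-spike interval (ms); 20 ms corresponds to the 50 Hz
#'   pairs used to characterize the synapses.
#' @return Numeric PPR.
#' @export
paired_pulse_ratio <- function(spec, interval = 20) {
  rel <- tm_release(spec, c(0, interval))$release
  rel[2] / rel[1]
}

#' Transmitter concentration waveform
#'
#' Biexponential pulse `T(t) = release * t_max * (exp(-t/tau_decay) -
#' exp(-t/tau_rise)) / norm`, normalized so the peak equals
#' `release * t_max`. Successive events superpose linearly.
#'
#' @param release Released fraction(s) scaling the pulse.
#' @param t Time since the release event (ms), vectorized.
#' @param tau_rise,tau_decay Rise/decay time constants (ms).
#' @param t_max Peak concentration for a full release (mM).
#' @return Concentration (mM).
#' @export
transmitter_waveform <- function(release, t, tau_rise = 0.1, tau_decay = 1,
                                 t_max = 1) {
  stopifnot(all(t >= 0), tau_decay > tau_rise)
  tp <- log(tau_decay / tau_rise) * tau_decay * tau_rise / (tau_decay - tau_rise)
  norm <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  release * t_max * (exp(-t / tau_decay) - exp(-t / tau_rise)) / norm
}

#' Voltage-dependent magnesium unblock of the NMDA receptor
#'
#' Boltzmann form `1 / (1 + [Mg]/k1 * exp(-k2 * V))`: a monotone increasing
#' sigmoid of voltage, the coincidence-detection nonlinearity of the mossy
#' fiber synapse.
#'
#' @param V Membrane potential (mV), vectorized.
#' @param mg Extracellular magnesium (mM).
#' @param k1 Concentration scale (mM).
#' @param k2 Voltage sensitivity (1/mV).
#' @return Unblocked fraction in `[0, 1]`.
#' @export
mg_unblock <- function(V, mg = 1, k1 = 3.57, k2 = 0.072) {
  1 / (1 + mg / k1 * exp(-k2 * V))
}

#' Receptor specification
#'
#' A three-state kinetic scheme (closed, open, desensitized) driven by the
#' transmitter transient: binding `C -> O` at `rb * T`, unbinding `O -> C`
#' at `ru`, desensitization `O -> D` at `rd`, recovery `D -> C` at `rr`.
#' NMDA receptors additionally carry the magnesium unblock gate and convert
#' `ca_frac` of their current into calcium influx to the local shell.
#'
#' @param kind `"AMPA"`, `"NMDA"` or `"GABA"`.
#' @param g_max_pS Maximum conductance (pS).
#' @param erev Reversal potential (mV): 0 for AMPA/NMDA, -70 for GABA.
#' @param rb Binding rate (1/(mM ms)).
#' @param ru,rd,rr Unbinding, desensitization and recovery rates (1/ms).
#' @param tau_rise,tau_decay,t_max Transmitter waveform parameters
#'   ([transmitter_waveform()]).
#' @param mg,mg_k1,mg_k2 Magnesium unblock parameters ([mg_unblock()]).
#' @param ca_frac Fraction of current converted to calcium influx (NMDA).
#' @return A `gc_receptor_spec`.
#' @export
receptor_spec <- function(kind, g_max_pS, erev = if (kind == "GABA") -70 else 0,
                          rb = 2, ru = 1, rd = 0.3, rr = 0.05,
                          tau_rise = 0.1, tau_decay = 1, t_max = 1,
                          mg = 1, mg_k1 = 3.57, mg_k2 = 0.072,
                          ca_frac = if (kind == "NMDA") 0.1 else 0) {
  kind <- match.arg(kind, c("AMPA", "NMDA", "GABA"))
  stopifnot(g_max_pS > 0)
  structure(list(kind = kind, g_max_pS = g_max_pS, erev = erev, rb = rb,
                 ru = ru, rd = rd, rr = rr, tau_rise = tau_rise,
                 tau_decay = tau_decay, t_max = t_max, mg = mg,
                 mg_k1 = mg_k1, mg_k2 = mg_k2, ca_frac = ca_frac),
            class = "gc_receptor_spec")
}

#' Advance a receptor state by one time step (reference implementation)
#'
#' Implicit update of the open/desensitized pair given the transmitter
#' concentration; mirrors the compiled solver's kinetics and is used to
#' cross-check it.
#'
#' @param spec A [receptor_spec()].
#' @param state List with `O` and `D` occupancies.
#' @param transmitter Transmitter concentration (mM).
#' @param V Membrane potential (mV).
#' @param dt Time step (ms).
#' @return List with updated `state`, `current_pA` and `i_ca_pA`.
#' @export
receptor_step <- function(spec, state, transmitter, V, dt) {
  stopifnot(dt > 0)
  a11 <- 1 + dt * (spec$rb * transmitter + spec$ru + spec$rd)
  a12 <- dt * spec$rb * transmitter
  a21 <- -dt * spec$rd
  a22 <- 1 + dt * spec$rr
  b1 <- state$O + dt * spec$rb * transmitter
  b2 <- state$D
  det <- a11 * a22 - a12 * a21
  O <- max((b1 * a22 - a12 * b2) / det, 0)
  D <- max((a11 * b2 - a21 * b1) / det, 0)
  if (O + D > 1 + 1e-6) rlang::abort("receptor occupancy exceeded 1")
  unblock <- if (spec$kind == "NMDA") {
    mg_unblock(V, spec$mg, spec$mg_k1, spec$mg_k2)
  } else 1
  i_pA <- spec$g_max_pS * 1e-6 * O * unblock * (V - spec$erev) * 1e3
  list(state = list(O = O, D = D), current_pA = i_pA,
       i_ca_pA = spec$ca_frac * i_pA)
}

#' Synaptic pathway definitions
#'
#' Release dynamics and receptor complements of the four input pathways:
#' parallel fiber (PF) and ascending axon (AA) are facilitating
#' (p 0.4, tau_rec 35.1 ms, tau_fac 55 ms) with AMPA receptors (1200 pS);
#' mossy fiber (MF) is neither facilitating nor depressing (p 0.43, tau_rec
#' 5 ms, tau_fac 8 ms) with AMPA (1200 pS) plus NR2B-type NMDA (10000 pS,
#' 10% calcium current); inhibition (INH) is GABA-A (2600 pS, -70 mV) with
#' p 0.5, tau_rec 15 ms, tau_fac 4 ms.
#'
#' @return Named list per pathway with elements `tm` and `receptors`.
#' @export
synapse_defaults <- function() {
  ampa <- function() receptor_spec("AMPA", 1200, rb = 2.7, ru = 1.1, rd = 0.3,
                                   rr = 0.05)
  list(
    PF = list(tm = tm_spec(0.4, 35.1, 55), receptors = list(ampa())),
    AA = list(tm = tm_spec(0.4, 35.1, 55), receptors = list(ampa())),
    MF = list(tm = tm_spec(0.43, 5, 8),
              receptors = list(ampa(),
                               receptor_spec("NMDA", 10000, rb = 0.75,
                                             ru = 0.025, rd = 0.01,
                                             rr = 0.003, tau_decay = 1.5))),
    INH = list(tm = tm_spec(0.5, 15, 4),
               receptors = list(receptor_spec("GABA", 2600, rb = 0.28,
                                              ru = 0.15, rd = 0.05,
                                              rr = 0.01, tau_decay = 1.2)))
  )
}

#' Place synapses on a cell model
#'
#' Placement rules: PF synapses on apical-dendrite compartments, at most one
#' per compartment; AA synapses one per basal-dendrite section; MF synapses
#' on basal-dendrite compartments at least `mf_min_dist` um of path distance
#' from the soma; inhibitory synapses on compartments of both dendrite
#' classes. Deterministic for a fixed seed.
#'
#' @param model A `goc_cell_model`.
#' @param counts Named vector: `c(PF =, AA =, MF =, INH =)` (missing
#'   pathways get 0).
#' @param seed Integer seed for site sampling.
#' @param pathways Pathway definitions ([synapse_defaults()]).
#' @param mf_min_dist Minimum somatic path distance for MF sites (um).
#' @return The model with a `synapses` tibble (`syn_id`, `pathway`,
#'   `comp_id`, `section_id`, `path_dist_um`).
#' @export
place_synapses <- function(model, counts = c(PF = 89, AA = 20, MF = 20, INH = 20),
                           seed = 1, pathways = synapse_defaults(),
                           mf_min_dist = 20) {
  stopifnot(inherits(model, "goc_cell_model"))
  ct <- model$morphology$compartments
  rng <- local_rng(seed)
  pick <- function(pool, k, replace = FALSE) {
    if (k == 0) return(integer(0))
    if (!replace && k > length(pool)) {
      rlang::abort(sprintf(
        "placement error: requested %d synapses but only %d eligible sites",
        k, length(pool)))
    }
    idx <- order(rng$unif(length(pool)))
    if (replace) {
      pool[ceiling(rng$unif(k) * length(pool))]
    } else {
      pool[idx[seq_len(k)]]
    }
  }
  cnt <- function(p) if (p %in% names(counts)) as.integer(counts[[p]]) else 0L
  out <- list()
  apical <- ct$comp_id[ct$label == "apical_dendrite"]
  out$PF <- pick(apical, cnt("PF"))
  basal_secs <- unique(ct$section_id[ct$label == "basal_dendrite"])
  aa_secs <- pick(basal_secs, cnt("AA"))
  out$AA <- vapply(aa_secs, function(s) {
    comps <- ct$comp_id[ct$section_id == s]
    comps[ceiling(length(comps) / 2)]
  }, numeric(1))
  mf_pool <- ct$comp_id[ct$label == "basal_dendrite" &
                          ct$path_dist_um >= mf_min_dist]
  out$MF <- pick(mf_pool, cnt("MF"))
  inh_pool <- ct$comp_id[ct$label %in% c("basal_dendrite", "apical_dendrite")]
  out$INH <- pick(inh_pool, cnt("INH"), replace = cnt("INH") > length(inh_pool))
  tab <- dplyr::bind_rows(lapply(names(out), function(p) {
    if (length(out[[p]]) == 0) return(NULL)
    tibble(pathway = p, comp_id = as.integer(out[[p]]))
  }))
  if (is.null(tab) || nrow(tab) == 0) {
    tab <- tibble(pathway = character(), comp_id = integer())
  }
  tab <- dplyr::left_join(tab, ct[, c("comp_id", "section_id", "path_dist_um")],
                          by = "comp_id")
  tab$syn_id <- seq_len(nrow(tab))
  model$synapses <- tab[, c("syn_id", "pathway", "comp_id", "section_id",
                            "path_dist_um")]
  model$pathways <- pathways
  model
}

#' Audit synapse placement constraints
#'
#' Verifies the pathway placement rules on a placed model.
#'
#' @param model A model after [place_synapses()].
#' @param mf_min_dist Minimum MF path distance (um).
#' @return Invisibly `TRUE`; aborts on the first violated rule.
#' @export
audit_placement <- function(model, mf_min_dist = 20) {
  syn <- model$synapses
  if (is.null(syn)) rlang::abort("no synapses placed")
  ct <- model$morphology$compartments
  lab <- ct$label[match(syn$comp_id, ct$comp_id)]
  if (any(lab[syn$pathway == "PF"] != "apical_dendrite")) {
    rlang::abort("PF synapse off the apical dendrites")
  }
  pf <- syn$comp_id[syn$pathway == "PF"]
  if (anyDuplicated(pf)) rlang::abort("more than one PF synapse per compartment")
  if (any(lab[syn$pathway %in% c("AA", "MF")] != "basal_dendrite")) {
    rlang::abort("AA/MF synapse off the basal dendrites")
  }
  aa_secs <- syn$section_id[syn$pathway == "AA"]
  if (anyDuplicated(aa_secs)) rlang::abort("more than one AA synapse per section")
  if (any(syn$path_dist_um[syn$pathway == "MF"] < mf_min_dist)) {
    rlang::abort("MF synapse closer than the minimum somatic distance")
  }
  if (any(!lab[syn$pathway == "INH"] %in%
            c("basal_dendrite", "apical_dendrite"))) {
    rlang::abort("inhibitory synapse off the dendrites")
  }
  invisible(TRUE)
}

# Build per-receptor synapse entries for the solver workspace. `stimuli` is a
# list of list(pathway =, times =, jitter_sd = 0); every placed synapse of the
# pathway receives the train. `extra_synapses` allows protocol code to add
# ad-hoc synapses: list of list(comp, receptor = receptor_spec, tm = tm_spec,
# times).
build_synapse_ws <- function(model, stimuli = NULL, extra_synapses = NULL) {
  entries <- list()
  add_entry <- function(comp_id, rec, events) {
    entries[[length(entries) + 1]] <<- list(
      comp = as.integer(comp_id - 1L),
      receptor = match(rec$kind, c("AMPA", "NMDA", "GABA")) - 1L,
      gmax_uS = rec$g_max_pS * 1e-6,
      erev = rec$erev,
      tau_r = rec$tau_rise, tau_d = rec$tau_decay,
      rb = rec$rb * rec$t_max, ru = rec$ru, rd = rec$rd, rr = rec$rr,
      mg = rec$mg, mg_k1 = rec$mg_k1, mg_k2 = rec$mg_k2,
      ca_frac = rec$ca_frac,
      ev_t = as.numeric(events$time), ev_y = as.numeric(events$release))
  }
  if (!is.null(stimuli) && !is.null(model$synapses) && nrow(model$synapses) > 0) {
    for (st in stimuli) {
      rows <- which(model$synapses$pathway == st$pathway)
      if (length(rows) == 0) next
      pw <- model$pathways[[st$pathway]]
      for (r in rows) {
        times <- sort(st$times)
        ev <- tm_release(pw$tm, times)
        for (rec in pw$receptors) add_entry(model$synapses$comp_id[r], rec, ev)
      }
    }
  }
  if (!is.null(extra_synapses)) {
    for (xs in extra_synapses) {
      ev <- tm_release(xs$tm, sort(xs$times))
      add_entry(xs$comp, xs$receptor, ev)
    }
  }
  entries
}
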