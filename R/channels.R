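# Ion channel gating: Hodgkin-Huxley gates with parameterized steady-state /
# time-constant functions, and Markov schemes with exponential voltage- and
# calcium-dependent transition rates. These R implementations define the
# reference semantics; the compiled solver reimplements the same update rules
# for whole-cell simulation.

#' Define a Hodgkin-Huxley gating particle
#'
#' Steady state is a Boltzmann function of voltage,
#' `minf(V) = 1 / (1 + exp(-(V - vhalf)/k))` (negative `k` yields an
#' inactivation gate), and the time constant is a thermally scalable bell,
#' `tau(V) = tau_min + tau_amp / (exp((V - tau_vhalf)/tau_ka) +
#' exp(-(V - tau_vhalf)/tau_kb))`.
#'
#' @param exponent Integer power of the gate in the open fraction.
#' @param vhalf,k Boltzmann half-activation (mV) and slope (mV).
#' @param tau_min,tau_amp Floor and amplitude of the time constant (ms).
#' @param tau_vhalf,tau_ka,tau_kb Bell center (mV) and rise/fall slopes (mV).
#' @return A `gc_gate` object.
#' @export
hh_gate <- function(exponent = 1, vhalf, k, tau_min = 0.1, tau_amp = 1,
                    tau_vhalf = vhalf, tau_ka = 20, tau_kb = 20) {
  stopifnot(exponent >= 1, tau_min > 0 || tau_amp > 0, tau_ka > 0, tau_kb > 0)
  structure(list(kind = "v", exponent = as.integer(exponent), vhalf = vhalf,
                 k = k, tau_min = tau_min, tau_amp = tau_amp,
                 tau_vhalf = tau_vhalf, tau_ka = tau_ka, tau_kb = tau_kb),
            class = "gc_gate")
}

#' Define a calcium-activated gating particle
#'
#' Steady state is a Hill function of submembrane calcium,
#' `minf([Ca]) = Ca^n / (Ca^n + kd^n)`, with a fixed time constant.
#'
#' @param exponent Integer power of the gate.
#' @param n Hill coefficient.
#' @param kd Half-activation calcium concentration (mM).
#' @param tau Time constant (ms).
#' @return A `gc_gate` object.
#' @export
ca_gate <- function(exponent = 1, n = 4, kd = 5e-4, tau = 5) {
  stopifnot(exponent >= 1, n > 0, kd > 0, tau > 0)
  structure(list(kind = "ca", exponent = as.integer(exponent), n = n, kd = kd,
                 tau = tau),
            class = "gc_gate")
}

#' Steady state and time constant of a gate
#'
#' @param gate A `gc_gate`.
#' @param V Membrane potential (mV).
#' @param ca Submembrane calcium (mM), used by calcium-activated gates.
#' @return Numeric vector, recycled over `V`/`ca`.
#' @export
gate_inf <- function(gate, V, ca = 5e-5) {
  if (gate$kind == "ca") {
    can <- ca^gate$n
    can / (can + gate$kd^gate$n)
  } else {
    1 / (1 + exp(-(V - gate$vhalf) / gate$k))
  }
}

#' @rdname gate_inf
#' @export
gate_tau <- function(gate, V, ca = 5e-5) {
  if (gate$kind == "ca") {
    rep_len(gate$tau, max(length(V), length(ca)))
  } else {
    gate$tau_min + gate$tau_amp /
      (exp((V - gate$tau_vhalf) / gate$tau_ka) +
         exp(-(V - gate$tau_vhalf) / gate$tau_kb))
  }
}

#' Advance a Hodgkin-Huxley gate by one time step
#'
#' Exponential integrator, exact for constant voltage:
#' `m <- minf + (m - minf) * exp(-dt * temp_factor / tau)`.
#'
#' @param gate A `gc_gate`.
#' @param m Current gate value in `[0, 1]`.
#' @param V Membrane potential (mV).
#' @param dt Time step (ms), > 0.
#' @param temp_factor Q10 rate multiplier from [q10_factor()].
#' @param ca Submembrane calcium (mM).
#' @return Updated gate value.
#' @export
gate_advance <- function(gate, m, V, dt, temp_factor = 1, ca = 5e-5) {
  stopifnot(dt > 0)
  minf <- gate_inf(gate, V, ca)
  tau <- gate_tau(gate, V, ca)
  minf + (m - minf) * exp(-dt * temp_factor / tau)
}

#' Temperature scaling factor for kinetic rates
#'
#' `q10 ^ ((temp_C - ref_temp_C) / 10)`. All channel kinetics are normalized
#' to the working temperature of 32 degrees C used in the slice recordings
#' the models target.
#'
#' @param q10 Q10 coefficient (> 0).
#' @param temp_C Simulation temperature (degrees C).
#' @param ref_temp_C Reference temperature of the kinetics (degrees C).
#' @return Dimensionless rate multiplier.
#' @export
q10_factor <- function(q10, temp_C, ref_temp_C) {
  stopifnot(q10 > 0)
  q10^((temp_C - ref_temp_C) / 10)
}

#' Define a Hodgkin-Huxley channel
#'
#' @param name Channel name.
#' @param gates List of [hh_gate()] / [ca_gate()] particles.
#' @param erev Reversal potential (mV).
#' @param q10,ref_temp Temperature correction of the gating rates.
#' @param is_calcium Does this channel carry calcium into the submembrane
#'   shell?
#' @return A `gc_channel` of kind `"hh"`.
#' @export
hh_channel <- function(name, gates, erev, q10 = 3, ref_temp = 23,
                       is_calcium = FALSE) {
  stopifnot(length(gates) >= 1, all(vapply(gates, inherits, logical(1), "gc_gate")))
  structure(list(name = name, kind = "hh", gates = gates, erev = erev,
                 q10 = q10, ref_temp = ref_temp, is_calcium = is_calcium),
            class = "gc_channel")
}

#' Define a Markov channel
#'
#' Transition rates follow the exponential family
#' `r(V, Ca) = base * exp((V - vhalf)/kv) * Ca^ca_pow` (no voltage dependence
#' when `kv = 0`; no calcium dependence when `ca_pow = 0`; `Ca` in mM). The
#' exponent argument is clamped to `[-20, 20]` for numerical safety.
#'
#' @param name Channel name.
#' @param n_states Number of states.
#' @param open_states Integer indices of conducting states.
#' @param transitions Data frame with columns `from`, `to`, `base` (1/ms),
#'   `vhalf` (mV), `kv` (mV; 0 = voltage independent), `ca_pow`.
#' @param erev Reversal potential (mV).
#' @param q10,ref_temp Temperature correction.
#' @param is_calcium Does this channel carry calcium?
#' @param init_state Index of the state holding all probability at rest
#'   initialization (before equilibration).
#' @return A `gc_channel` of kind `"markov"`.
#' @export
markov_channel <- function(name, n_states, open_states, transitions, erev,
                           q10 = 3, ref_temp = 23, is_calcium = FALSE,
                           init_state = 1L) {
  tr <- as.data.frame(transitions)
  stopifnot(all(c("from", "to", "base", "vhalf", "kv", "ca_pow") %in% names(tr)),
            all(tr$from >= 1 & tr$from <= n_states),
            all(tr$to >= 1 & tr$to <= n_states),
            all(tr$base >= 0),
            all(open_states >= 1 & open_states <= n_states))
  structure(list(name = name, kind = "markov", n_states = as.integer(n_states),
                 open_states = as.integer(open_states), transitions = tr,
                 erev = erev, q10 = q10, ref_temp = ref_temp,
                 is_calcium = is_calcium, init_state = as.integer(init_state)),
            class = "gc_channel")
}

# generator matrix Q (n x n): Q[i,j] = rate i -> j for i != j; rows sum to 0
markov_Q <- function(chan, V, ca = 5e-5, temp_factor = 1) {
  n <- chan$n_states
  Q <- matrix(0, n, n)
  tr <- chan$transitions
  for (r in seq_len(nrow(tr))) {
    rate <- tr$base[r]
    if (tr$kv[r] != 0) {
      rate <- rate * exp(pmin(pmax((V - tr$vhalf[r]) / tr$kv[r], -20), 20))
    }
    if (tr$ca_pow[r] != 0) rate <- rate * ca^tr$ca_pow[r]
    Q[tr$from[r], tr$to[r]] <- Q[tr$from[r], tr$to[r]] + rate * temp_factor
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Advance a Markov channel state by one time step
#'
#' Implicit (backward Euler) propagation of the state-probability vector,
#' `p(t+dt) = solve(I - dt * t(Q)) p(t)`, which preserves the probability sum
#' to machine precision and is robust for stiff schemes.
#'
#' @param chan A Markov `gc_channel`.
#' @param probs State probability vector (sums to 1).
#' @param V Membrane potential (mV).
#' @param ca Submembrane calcium (mM).
#' @param dt Time step (ms).
#' @param temp_factor Q10 rate multiplier.
#' @return Updated probability vector.
#' @export
markov_advance <- function(chan, probs, V, ca = 5e-5, dt, temp_factor = 1) {
  stopifnot(chan$kind == "markov", length(probs) == chan$n_states, dt > 0)
  if (abs(sum(probs) - 1) > 1e-6) rlang::abort("state probabilities must sum to 1")
  Q <- markov_Q(chan, V, ca, temp_factor)
  A <- diag(chan$n_states) - dt * t(Q)
  p <- solve(A, probs)
  p <- p / sum(p)
  if (any(p < -1e-9)) {
    rlang::abort("negative state probability; reduce dt for this scheme")
  }
  pmax(p, 0)
}

#' Equilibrium state of a channel at fixed voltage and calcium
#'
#' @inheritParams markov_advance
#' @return For HH channels, the vector of gate steady states; for Markov
#'   channels, the stationary probability vector.
#' @export
channel_steady_state <- function(chan, V, ca = 5e-5) {
  if (chan$kind == "hh") {
    vapply(chan$gates, gate_inf, numeric(1), V = V, ca = ca)
  } else {
    Q <- markov_Q(chan, V, ca)
    # stationary distribution: solve t(Q) p = 0 with sum(p) = 1
    n <- chan$n_states
    A <- rbind(t(Q), rep(1, n))
    b <- c(rep(0, n), 1)
    p <- qr.solve(A, b)
    pmax(p, 0) / sum(pmax(p, 0))
  }
}

#' Open fraction of a channel given its state
#'
#' @param chan A `gc_channel`.
#' @param state Gate vector (HH) or probability vector (Markov).
#' @return Open fraction in `[0, 1]`.
#' @export
open_fraction <- function(chan, state) {
  if (chan$kind == "hh") {
    prod(vapply(seq_along(chan$gates), function(i) {
      state[i]^chan$gates[[i]]$exponent
    }, numeric(1)))
  } else {
    sum(state[chan$open_states])
  }
}

#' Membrane current density through a channel
#'
#' `i = gmax * open_fraction * (V - erev)`, outward positive, in mA/cm^2
#' when `gmax` is in S/cm^2 and `V` in mV.
#'
#' @param chan A `gc_channel`.
#' @param state Channel state (see [open_fraction()]).
#' @param V Membrane potential (mV).
#' @param gmax Maximum conductance density (S/cm^2).
#' @return Current density (mA/cm^2).
#' @export
channel_current <- function(chan, state, V, gmax) {
  gmax * open_fraction(chan, state) * (V - chan$erev)
}

# ---------------------------------------------------------------------------
# Submembrane calcium shell

#' Define a submembrane calcium shell
#'
#' A single annulus of depth `depth_um` under the membrane. Calcium enters
#' from the calcium-carrying channel current, binds to parvalbumin and
#' calmodulin, and is extruded by a saturating membrane pump whose maximal
#' flux is `pump_density * pump_turnover`; the pump is balanced so that the
#' resting concentration is a true equilibrium.
#'
#' @param depth_um Shell depth (um).
#' @param ca_rest Resting free calcium (mM).
#' @param pump_density Pump surface density (mol/cm^2), per Table-of-channel
#'   conventions set per section at model build time.
#' @param pump_turnover Pump turnover rate (1/ms).
#' @param pump_km Pump Michaelis constant (mM).
#' @param buffers List of buffers, each `list(total, kon, koff)` with total
#'   concentration in mM, `kon` in 1/(mM ms), `koff` in 1/ms.
#' @return A `gc_ca_shell` object.
#' @export
calcium_shell <- function(depth_um = 0.2, ca_rest = 5e-5,
                          pump_density = 1e-9, pump_turnover = 8e-7,
                          pump_km = 5e-4,
                          buffers = list(
                            parvalbumin = list(total = 0.002, kon = 40, koff = 0.1),
                            calmodulin = list(total = 0.03, kon = 500, koff = 5)
                          )) {
  stopifnot(depth_um > 0, ca_rest > 0, pump_density >= 0)
  structure(list(depth_um = depth_um, ca_rest = ca_rest,
                 pump_density = pump_density, pump_turnover = pump_turnover,
                 pump_km = pump_km, buffers = buffers),
            class = "gc_ca_shell")
}

#' Initialize calcium shell state at rest
#'
#' Free calcium at the resting concentration and each buffer bound at its
#' equilibrium occupancy.
#'
#' @param shell A `gc_ca_shell`.
#' @return List with `ca` (mM) and `bound` (mM per buffer).
#' @export
shell_rest_state <- function(shell) {
  bound <- vapply(shell$buffers, function(b) {
    b$total * shell$ca_rest / (shell$ca_rest + b$koff / b$kon)
  }, numeric(1))
  list(ca = shell$ca_rest, bound = bound)
}

# time derivative of (ca, bound...) for a given calcium current; used by both
# calcium_step and the fine-step oracle in the tests
shell_deriv <- function(shell, state, i_ca_nA, area_cm2) {
  vol_L <- area_cm2 * shell$depth_um * 1e-4 * 1e-3 # cm^3 -> L
  influx <- -i_ca_nA * 1e-12 / (2 * 96485) / vol_L * 1e3 # mM/ms, inward I < 0
  sat <- function(ca) ca / (ca + shell$pump_km)
  pump_flux <- shell$pump_density * shell$pump_turnover *
    (sat(state$ca) - sat(shell$ca_rest)) # mol/cm^2/ms
  pump <- pump_flux * area_cm2 / vol_L * 1e3 # mM/ms
  dbound <- numeric(length(shell$buffers))
  dca_buf <- 0
  for (i in seq_along(shell$buffers)) {
    b <- shell$buffers[[i]]
    free_b <- b$total - state$bound[i]
    dbound[i] <- b$kon * state$ca * free_b - b$koff * state$bound[i]
    dca_buf <- dca_buf - dbound[i]
  }
  list(dca = influx - pump + dca_buf, dbound = dbound)
}

#' Advance the calcium shell by one time step
#'
#' Semi-implicit update: buffer kinetics and pump are advanced with an
#' explicit exponential-Euler-style step on the free calcium, which keeps
#' the concentration positive at the default step of 0.025 ms.
#'
#' @param shell A `gc_ca_shell`.
#' @param state Shell state from [shell_rest_state()].
#' @param i_ca_nA Total calcium current into the compartment membrane (nA,
#'   inward negative).
#' @param area_cm2 Compartment membrane area (cm^2).
#' @param dt Time step (ms).
#' @return Updated shell state.
#' @export
calcium_step <- function(shell, state, i_ca_nA, area_cm2, dt) {
  stopifnot(dt > 0)
  # two half steps improve accuracy for stiff buffer kinetics at default dt
  for (h in 1:2) {
    d <- shell_deriv(shell, state, i_ca_nA, area_cm2)
    state$ca <- max(state$ca + d$dca * dt / 2, 1e-9)
    state$bound <- pmin(pmax(state$bound + d$dbound * dt / 2, 0),
                        vapply(shell$buffers, `[[`, numeric(1), "total"))
  }
  state
}

# ---------------------------------------------------------------------------
# Channel scheme builders

# Markov scheme equivalent to coupled m^3 h activation/inactivation with an
# additional slow-inactivated state, using exponential voltage-dependent
# elementary rates. States are (m, h): 1..4 = h available with m = 0..3
# (state 4 = open), 5..8 = fast-inactivated, 9 = slow-inactivated. Slow
# inactivation is entered from the fully activated states (4, 8) during
# depolarized plateaus and recovers at rest; it terminates depolarization
# plateaus and produces spike-frequency adaptation and the slow bursting
# uncovered when SK channels or their calcium source are blocked.
nav_scheme <- function(am, vam, kam, bm, vbm, kbm, ah, vah, kah, bh, vbh, kbh,
                       as_ = 0.02, vas = -40, kas = 100,
                       ars = 0.004, vrs = -65, krs = 7) {
  tr <- list()
  add <- function(from, to, base, vh, kv) {
    tr[[length(tr) + 1]] <<- data.frame(from = from, to = to, base = base,
                                        vhalf = vh, kv = kv, ca_pow = 0)
  }
  for (h in 0:1) {
    off <- if (h == 1) 0L else 4L
    for (m in 0:2) {
      add(off + m + 1, off + m + 2, (3 - m) * am, vam, kam)   # m up
      add(off + m + 2, off + m + 1, (m + 1) * bm, vbm, -kbm)  # m down
    }
  }
  for (m in 0:3) {
    add(m + 1, m + 5, ah, vah, kah)        # inactivate (faster when depolarized)
    add(m + 5, m + 1, bh, vbh, -kbh)       # recover (faster when hyperpolarized)
  }
  add(4, 9, as_, vas, kas)                 # slow inactivation from open
  add(8, 9, as_, vas, kas)                 # and from the depolarized plateau
  add(3, 9, as_, vas, kas)                 # partially activated states are
  add(7, 9, as_, vas, kas)                 # also captured during plateaus
  add(9, 1, ars, vrs, -krs)                # slow recovery at rest
  do.call(rbind, tr)
}

# BK-type scheme: two sequential calcium bindings then a voltage-dependent
# opening step. States: 1 C0, 2 C1, 3 C2, 4 O.
kca11_scheme <- function(kon = 1000, koff = 5, aop = 10, kop = 25,
                         bcl = 0.1, kcl = 25) {
  data.frame(
    from = c(1, 2, 2, 3, 3, 4),
    to = c(2, 1, 3, 2, 4, 3),
    base = c(2 * kon, koff, kon, 2 * koff, aop, bcl),
    vhalf = c(0, 0, 0, 0, 0, 0),
    kv = c(0, 0, 0, 0, kop, -kcl),
    ca_pow = c(1, 0, 1, 0, 0, 0)
  )
}

# SK-type scheme: voltage-independent, successive calcium bindings gate the
# open transition. States: 1 C1, 2 C2, 3 C3, 4 O.
kca22_scheme <- function(kon = 90, koff = 0.5, aop = 0.6, bop = 0.3) {
  data.frame(
    from = c(1, 2, 2, 3, 3, 4),
    to = c(2, 1, 3, 2, 4, 3),
    base = c(2 * kon, koff, kon, 2 * koff, aop, bop),
    vhalf = 0, kv = 0,
    ca_pow = c(1, 0, 1, 0, 0, 0)
  )
}

#' Default channel definitions for the Golgi cell model
#'
#' Kinetic parameterizations for the channel set of the model: Nav1.6 (Markov
#' activation/inactivation scheme), delayed-rectifier and A-type potassium
#' channels, M-current, HCN1/HCN2, high- and low-threshold calcium channels
#' and the three calcium-activated potassium channels. The published model
#' cites its gating equations from earlier cerebellar models without printing
#' them; these defaults are calibrated so that the default conductance map
#' ([default_channel_registry()]) reproduces the validated cell-level
#' behaviours (pacemaking, sag, rebound, resonance, block-induced bursting).
#' Every parameter can be overridden by passing a modified list to
#' [cell_model()].
#'
#' @return Named list of `gc_channel` objects.
#' @export
default_channels <- function() {
  list(
    Nav1.6 = markov_channel(
      "Nav1.6", n_states = 9, open_states = 4,
      transitions = nav_scheme(am = 9, vam = -42, kam = 9,
                               bm = 9, vbm = -42, kbm = 9,
                               ah = 0.08, vah = -46, kah = 6,
                               bh = 0.08, vbh = -46, kbh = 6),
      erev = 60, q10 = 3, ref_temp = 32, init_state = 1
    ),
    # dendritic parameterization of the same conductance: faster onset of
    # fast inactivation, so slowly rising backpropagating depolarizations
    # inactivate the channels before they regenerate (apical spikelets are
    # small and slow, unlike the faithful basal backpropagation)
    `Nav1.6@apical_dendrite` = markov_channel(
      "Nav1.6", n_states = 9, open_states = 4,
      transitions = nav_scheme(am = 9, vam = -40, kam = 9,
                               bm = 9, vbm = -40, kbm = 9,
                               ah = 0.5, vah = -50, kah = 6,
                               bh = 0.08, vbh = -50, kbh = 6),
      erev = 60, q10 = 3, ref_temp = 32, init_state = 1
    ),
    Kv1.x = hh_channel("Kv1.x",
      gates = list(hh_gate(4, vhalf = -32, k = 8, tau_min = 1, tau_amp = 14,
                           tau_vhalf = -50, tau_ka = 25, tau_kb = 25)),
      erev = -80, ref_temp = 32),
    Kv3.4 = hh_channel("Kv3.4",
      gates = list(hh_gate(2, vhalf = -15, k = 7, tau_min = 0.3, tau_amp = 5,
                           tau_vhalf = -60, tau_ka = 10, tau_kb = 40)),
      erev = -80, ref_temp = 32),
    Kv4.3 = hh_channel("Kv4.3",
      gates = list(hh_gate(3, vhalf = -45, k = 8, tau_min = 0.8, tau_amp = 2,
                           tau_vhalf = -50, tau_ka = 20, tau_kb = 20),
                   hh_gate(1, vhalf = -69, k = -6, tau_min = 15, tau_amp = 30,
                           tau_vhalf = -70, tau_ka = 15, tau_kb = 15)),
      erev = -80, ref_temp = 32),
    Kv7.x = hh_channel("Kv7.x",
      gates = list(hh_gate(1, vhalf = -40, k = 7, tau_min = 60, tau_amp = 80,
                           tau_vhalf = -50, tau_ka = 25, tau_kb = 25)),
      erev = -80, ref_temp = 32),
    HCN1 = hh_channel("HCN1",
      gates = list(hh_gate(1, vhalf = -73, k = -8, tau_min = 80, tau_amp = 320,
                           tau_vhalf = -80, tau_ka = 20, tau_kb = 20)),
      erev = -20, ref_temp = 32),
    HCN2 = hh_channel("HCN2",
      gates = list(hh_gate(1, vhalf = -82, k = -8, tau_min = 300, tau_amp = 900,
                           tau_vhalf = -90, tau_ka = 20, tau_kb = 20)),
      erev = -20, ref_temp = 32),
    Cav2.2 = hh_channel("Cav2.2",
      gates = list(hh_gate(2, vhalf = -18, k = 7, tau_min = 0.4, tau_amp = 1.2,
                           tau_vhalf = -25, tau_ka = 18, tau_kb = 18)),
      erev = 137.5, ref_temp = 32, is_calcium = TRUE),
    Cav2.3 = hh_channel("Cav2.3",
      gates = list(hh_gate(2, vhalf = -15, k = 7, tau_min = 0.8, tau_amp = 2,
                           tau_vhalf = -20, tau_ka = 18, tau_kb = 18)),
      erev = 137.5, ref_temp = 32, is_calcium = TRUE),
    Cav3.1 = hh_channel("Cav3.1",
      gates = list(hh_gate(2, vhalf = -52, k = 5, tau_min = 2, tau_amp = 6,
                           tau_vhalf = -60, tau_ka = 15, tau_kb = 15),
                   hh_gate(1, vhalf = -72, k = -5, tau_min = 25, tau_amp = 60,
                           tau_vhalf = -80, tau_ka = 15, tau_kb = 15)),
      erev = 137.5, ref_temp = 32, is_calcium = TRUE),
    Kca1.1 = markov_channel("Kca1.1", n_states = 4, open_states = 4,
      transitions = kca11_scheme(), erev = -80, ref_temp = 32),
    Kca2.2 = markov_channel("Kca2.2", n_states = 4, open_states = 4,
      transitions = kca22_scheme(), erev = -80, ref_temp = 32),
    Kca3.1 = hh_channel("Kca3.1",
      gates = list(ca_gate(1, n = 4, kd = 1.5e-3, tau = 4)),
      erev = -80, ref_temp = 32)
  )
}

#' Default channel placement map and conductance bounds
#'
#' The per-section maximum conductance map of the validated Golgi cell model:
#' Nav1.6 in every section with graded density (AIS > soma > basal dendrite >
#' axon > apical dendrite), Kv1.x/Kv3.4/Kv4.3/Kca3.1/Cav2.2/Cav3.1 in the
#' soma, Kv3.4 in the axon, Kv7.x/HCN1/HCN2/Cav2.2/Kca1.1 in the AIS,
#' Cav2.2/Kca1.1/Kca2.2 in basal dendrites and Cav2.3/Cav3.1/Kca1.1/Kca2.2 in
#' apical dendrites. `gmax` holds the exemplar model's value (S/cm^2) and
#' `[bound_lo, bound_hi]` the optimization range explored across the model
#' family. Reversal potentials: Na +60, K -80, HCN -20, Ca +137.5 mV.
#'
#' @return A tibble with columns `channel`, `section`, `gmax`, `bound_lo`,
#'   `bound_hi`, `free`.
#' @export
default_channel_registry <- function() {
  tribble(
    ~channel, ~section, ~gmax, ~bound_lo, ~bound_hi,
    "Nav1.6", "apical_dendrite", 0.0049, 0.0024, 0.0068,
    "Nav1.6", "basal_dendrite", 0.008, 0.006, 0.0135,
    "Nav1.6", "soma", 0.149, 0.143, 0.24,
    "Nav1.6", "AIS", 0.172, 0.17, 0.2,
    "Nav1.6", "axon", 0.011, 0.0072, 0.025,
    "Kv1.x", "soma", 0.005, 0.004, 0.007,
    "Kv3.4", "soma", 0.149, 0.11, 0.195,
    "Kv3.4", "axon", 0.0091, 0.0021, 0.010,
    "Kv4.3", "soma", 0.004, 0.0035, 0.0085,
    "Kv7.x", "AIS", 0.0002, 0.0002, 0.0003,
    "Kca1.1", "apical_dendrite", 0.01, 0.008, 0.014,
    "Kca1.1", "basal_dendrite", 0.012, 0.009, 0.014,
    "Kca1.1", "soma", 0.017, 0.0145, 0.019,
    "Kca1.1", "AIS", 0.1, 0.09, 0.12,
    "Kca2.2", "apical_dendrite", 0.0024, 0.0018, 0.0045,
    "Kca2.2", "basal_dendrite", 0.016, 0.015, 0.019,
    "Kca3.1", "soma", 0.0101, 0.009, 0.015,
    "Cav2.2", "basal_dendrite", 0.0013, 0.00125, 0.0019,
    "Cav2.2", "soma", 0.0087, 0.0078, 0.0165,
    "Cav2.2", "AIS", 0.0059, 0.0045, 0.0075,
    "Cav2.3", "apical_dendrite", 0.0012, 0.0012, 0.0017,
    "Cav3.1", "apical_dendrite", 3.69e-5, 3.6e-5, 7.5e-5,
    "Cav3.1", "soma", 3.40e-5, 3e-5, 9.5e-5,
    "HCN1", "AIS", 0.00033, 0.0001, 0.00038,
    "HCN2", "AIS", 0.0003, 0.0003, 0.00035
  ) |>
    dplyr::mutate(free = TRUE)
}

#' Default calcium pump densities per section
#'
#' mol/cm^2; soma carries the densest extrusion, dendrites the lightest.
#'
#' @return Named numeric vector over section labels.
#' @export
default_pump_densities <- function() {
  c(soma = 1e-7, AIS = 1e-8, axon = 1e-8,
    basal_dendrite = 5e-9, apical_dendrite = 2e-9)
}
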