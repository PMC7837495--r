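# Evolutionary optimization of the per-section maximum conductances against
# a spike-feature template, and the staged validation pipeline.

FEATURES <- c("ap_width", "ap_height", "ahp_depth", "isi_cv",
              "mean_frequency", "spike_count")

#' Free-parameter bounds of a model's conductance genome
#'
#' The genome is the vector of maximum conductances of the registry rows
#' marked `free`, in registry order, bounded by `[bound_lo, bound_hi]`.
#'
#' @param model A `goc_cell_model`.
#' @return Tibble: `gene` (channel\@section), `value`, `lo`, `hi`.
#' @export
genome_bounds <- function(model) {
  reg <- model$registry
  free <- which(reg$free)
  tibble(gene = paste0(reg$channel[free], "@", reg$section[free]),
         value = reg$gmax[free], lo = reg$bound_lo[free],
         hi = reg$bound_hi[free])
}

# write a genome vector back into the model registry
apply_genome <- function(model, genome) {
  reg <- model$registry
  free <- which(reg$free)
  stopifnot(length(genome) == length(free))
  reg$gmax[free] <- as.numeric(genome)
  model$registry <- reg
  model
}

#' Feature targets for the optimization objective
#'
#' Targets are defined per stimulus amplitude for the six spike features.
#' The shipped default is an approximate template of Golgi cell discharge
#' during 2-second current steps, documented as replaceable: the
#' ground-truth-recovery tests build their objective from a reference
#' model's own features instead ([objective_from_model()]).
#'
#' @param amplitudes Step amplitudes (nA).
#' @param duration Step duration (ms).
#' @return A `goc_objective`: tibble with `amplitude_nA`, `feature`,
#'   `mean`, `sd`, plus attributes.
#' @export
default_objective <- function(amplitudes = c(0.2, 0.4, 0.6), duration = 2000) {
  base <- list(
    ap_width = c(1.0, 0.4), ap_height = c(45, 12), ahp_depth = c(20, 6),
    isi_cv = c(0.1, 0.15)
  )
  freq <- c(12, 20, 28)[match(amplitudes, c(0.2, 0.4, 0.6))]
  freq[is.na(freq)] <- 15
  rows <- list()
  for (i in seq_along(amplitudes)) {
    for (f in FEATURES) {
      ms <- switch(f,
        mean_frequency = c(freq[i], max(6, 0.35 * freq[i])),
        spike_count = c(freq[i] * duration / 1000,
                        max(8, 0.35 * freq[i] * duration / 1000)),
        base[[f]])
      rows[[length(rows) + 1]] <- tibble(amplitude_nA = amplitudes[i],
                                         feature = f, mean = ms[1], sd = ms[2])
    }
  }
  obj <- dplyr::bind_rows(rows)
  attr(obj, "duration") <- duration
  class(obj) <- c("goc_objective", class(obj))
  obj
}

# simulate the objective's steps and extract one FeatureSet per amplitude
eval_features <- function(model, amplitudes, duration, settle = 300) {
  rows <- lapply(amplitudes, function(a) {
    sim <- tryCatch(
      simulate_cell(model,
                    electrodes = list(current_step(a, onset = 0,
                                                   duration = duration)),
                    t_stop = duration, settle = settle, record_dt = 0.1,
                    recordings = list(record("V", "soma", name = "v"))),
      error = function(e) NULL)
    if (is.null(sim)) {
      return(tibble(amplitude_nA = a, ap_width = NA, ap_height = NA,
                    ahp_depth = NA, isi_cv = NA, mean_frequency = NA,
                    spike_count = NA, failed = TRUE))
    }
    ft <- extract_features(sim$traces$time, sim$traces$v)
    dplyr::bind_cols(tibble(amplitude_nA = a), ft, tibble(failed = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Build an objective from a reference model's own features
#'
#' Used for ground-truth recovery: the targets are the reference model's
#' feature values, with the given relative standard deviations.
#'
#' @param model The reference `goc_cell_model`.
#' @param amplitudes,duration Stimulus set.
#' @param rel_sd Relative sd per feature (floored at `min_sd`).
#' @param min_sd Absolute sd floor.
#' @return A `goc_objective`.
#' @export
objective_from_model <- function(model, amplitudes = c(0.2, 0.4, 0.6),
                                 duration = 2000, rel_sd = 0.2,
                                 min_sd = c(ap_width = 0.15, ap_height = 4,
                                            ahp_depth = 2, isi_cv = 0.08,
                                            mean_frequency = 2,
                                            spike_count = 4)) {
  ft <- eval_features(model, amplitudes, duration)
  rows <- list()
  for (i in seq_len(nrow(ft))) {
    for (f in FEATURES) {
      m <- ft[[f]][i]
      if (is.na(m)) next
      rows[[length(rows) + 1]] <- tibble(
        amplitude_nA = ft$amplitude_nA[i], feature = f, mean = m,
        sd = max(rel_sd * abs(m), min_sd[[f]]))
    }
  }
  obj <- dplyr::bind_rows(rows)
  attr(obj, "duration") <- duration
  class(obj) <- c("goc_objective", class(obj))
  obj
}

#' Score a genome against an objective
#'
#' Simulates the objective's current steps with the genome written into the
#' model's free conductances, extracts the six features per step, and
#' returns the per-feature z-errors `|feature - target| / sd`. A feature
#' that is undefined (for example no spikes) scores the documented penalty
#' of 10; a simulation failure scores the penalty on every feature rather
#' than raising an error.
#'
#' @param genome Numeric vector over the free genes ([genome_bounds()]).
#' @param objective A `goc_objective`.
#' @param model The model template.
#' @param penalty Z-error assigned to missing features.
#' @return Tibble: `amplitude_nA`, `feature`, `value`, `target`, `z`.
#' @export
score_genome <- function(genome, objective, model, penalty = 10) {
  model <- apply_genome(model, genome)
  duration <- attr(objective, "duration") %||% 2000
  amps <- unique(objective$amplitude_nA)
  ft <- eval_features(model, amps, duration)
  out <- objective
  out$value <- NA_real_
  out$z <- penalty
  for (i in seq_len(nrow(out))) {
    row <- ft[ft$amplitude_nA == out$amplitude_nA[i], ]
    if (nrow(row) == 0 || isTRUE(row$failed)) next
    v <- row[[out$feature[i]]]
    if (is.na(v)) next
    out$value[i] <- v
    out$z[i] <- abs(v - out$mean[i]) / out$sd[i]
  }
  tibble(amplitude_nA = out$amplitude_nA, feature = out$feature,
         value = out$value, target = out$mean, z = out$z)
}

#' Evolutionary optimization of maximum conductances
#'
#' A seeded, reproducible generational genetic algorithm over the free
#' conductances: tournament selection (size 2), uniform crossover, per-gene
#' Gaussian mutation with sigma = 10% of the gene's range, clamped to
#' bounds, with elitism. Fitness is the summed z-error over all features
#' and amplitudes. The shipped defaults (population 16, 6 generations) are
#' the desk-scale regime; the published optimizations used population 576
#' for 10 generations on an HPC system, which this implementation
#' reproduces in miniature.
#'
#' @param model The model template (free genes per its registry).
#' @param objective A `goc_objective`.
#' @param pop_size Population size (even, >= 4).
#' @param n_gen Number of generations (0 returns the seeded initial
#'   population evaluated but unchanged).
#' @param seed Integer seed.
#' @param mut_p,mut_sigma Mutation probability per gene and sigma as a
#'   fraction of the gene range.
#' @param cx_p Per-gene uniform crossover probability.
#' @param elite Number of elites copied unchanged.
#' @param seed_default Include the template's own genome in the initial
#'   population.
#' @return A `goc_ga` object: `best_genome`, `best_fitness`, `population`
#'   (matrix), `fitness`, `logbook` tibble, and the optimized model
#'   (`best_model`).
#' @export
optimize_conductances <- function(model, objective = default_objective(),
                                  pop_size = 16, n_gen = 6, seed = 1,
                                  mut_p = 0.3, mut_sigma = 0.1, cx_p = 0.5,
                                  elite = 2, seed_default = TRUE) {
  stopifnot(pop_size >= 4, pop_size %% 2 == 0, n_gen >= 0)
  gb <- genome_bounds(model)
  ng <- nrow(gb)
  rng <- local_rng(seed)
  pop <- matrix(rng$unif(pop_size * ng), nrow = pop_size)
  pop <- sweep(sweep(pop, 2, gb$hi - gb$lo, `*`), 2, gb$lo, `+`)
  if (seed_default) pop[1, ] <- gb$value
  fit_of <- function(g) sum(score_genome(g, objective, model)$z)
  fitness <- apply(pop, 1, fit_of)
  log_rows <- list(tibble(gen = 0L, best = min(fitness),
                          mean = mean(fitness), worst = max(fitness)))
  if (n_gen > 0) {
    for (gen in seq_len(n_gen)) {
      ord <- order(fitness)
      newpop <- pop[ord[seq_len(elite)], , drop = FALSE]
      while (nrow(newpop) < pop_size) {
        pick <- function() {
          cand <- ceiling(rng$unif(2) * pop_size)
          cand[which.min(fitness[cand])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        swap <- rng$unif(ng) < cx_p
        child <- ifelse(swap, p2, p1)
        mut <- rng$unif(ng) < mut_p
        child[mut] <- child[mut] +
          rng$norm(sum(mut)) * mut_sigma * (gb$hi - gb$lo)[mut]
        child <- pmin(pmax(child, gb$lo), gb$hi)
        newpop <- rbind(newpop, child)
      }
      keep_fit <- fitness[ord[seq_len(elite)]]
      new_fit <- apply(newpop[-seq_len(elite), , drop = FALSE], 1, fit_of)
      pop <- newpop
      fitness <- c(keep_fit, new_fit)
      log_rows[[length(log_rows) + 1]] <- tibble(
        gen = gen, best = min(fitness), mean = mean(fitness),
        worst = max(fitness))
    }
  }
  best <- which.min(fitness)
  structure(list(best_genome = stats::setNames(pop[best, ], gb$gene),
                 best_fitness = fitness[best],
                 population = pop, fitness = fitness,
                 logbook = dplyr::bind_rows(log_rows),
                 best_model = apply_genome(model, pop[best, ]),
                 bounds = gb, seed = seed),
            class = "goc_ga")
}

#' @export
print.goc_ga <- function(x, ...) {
  cat("<goc_ga> ", nrow(x$population), " individuals, ",
      max(x$logbook$gen), " generations; best fitness ",
      signif(x$best_fitness, 4), "\n", sep = "")
  invisible(x)
}

#' Validation thresholds
#'
#' The staged validation bounds: spontaneous rate 2-15 Hz with ISI CV < 0.3
#' and driven rates inside the experimental envelope (step 1), sag depth
#' 4.4-10 mV at -0.2 nA / 1000 ms (step 2), and slow oscillatory firing
#' (<= `burst_max_hz`) under 90% Cav2.2 block with the SK/BK sensitivity
#' checks (step 3). The frequency envelope defaults are approximate,
#' documented bounds on Golgi cell discharge.
#'
#' @param rate_range,isi_cv_max Step-1 spontaneous bounds.
#' @param fi_envelope Named list: amplitude (nA as character) -> c(lo, hi)
#'   Hz.
#' @param sag_range Step-2 sag bounds (mV).
#' @param burst_max_hz Step-3 maximum mean rate under Cav2.2 block.
#' @return A list of thresholds.
#' @export
validation_config <- function(rate_range = c(2, 15), isi_cv_max = 0.3,
                              fi_envelope = list(`0.4` = c(8, 80),
                                                 `0.6` = c(12, 110)),
                              sag_range = c(4.4, 10), burst_max_hz = 5) {
  list(rate_range = rate_range, isi_cv_max = isi_cv_max,
       fi_envelope = fi_envelope, sag_range = sag_range,
       burst_max_hz = burst_max_hz)
}

#' Staged validation of a model
#'
#' Step 1: spontaneous firing between 2 and 15 Hz with ISI CV < 0.3, and
#' driven rates at 0.4 and 0.6 nA inside the configured experimental
#' envelope. Step 2: sag depth between 4.4 and 10 mV for a -0.2 nA, 1000 ms
#' step. Step 3: 90% Cav2.2 block uncovers slow oscillatory firing (the
#' model keeps firing, below `burst_max_hz`, rather than locking into a
#' depolarized plateau or falling silent); the Kca2.2 and Kca1.1 reductions
#' are then assessed and reported. All steps are always evaluated; failures
#' are report entries, not errors.
#'
#' @param model A `goc_cell_model`.
#' @param config Thresholds from [validation_config()].
#' @return A `goc_validation` report: tibbles `step1`, `step2`, `step3` and
#'   the `overall` pass flag.
#' @export
validate_model <- function(model, config = validation_config()) {
  sp <- spontaneous_rate(model)
  fi <- run_fi(model, amplitudes = as.numeric(names(config$fi_envelope)))
  fi_ok <- all(vapply(seq_len(nrow(fi)), function(i) {
    env <- config$fi_envelope[[as.character(fi$amplitude_nA[i])]]
    fi$frequency_hz[i] >= env[1] && fi$frequency_hz[i] <= env[2]
  }, logical(1)))
  s1_pass <- !is.na(sp$rate_hz) && sp$rate_hz >= config$rate_range[1] &&
    sp$rate_hz <= config$rate_range[2] &&
    !is.na(sp$isi_cv) && sp$isi_cv < config$isi_cv_max && fi_ok
  step1 <- tibble(rate_hz = sp$rate_hz, isi_cv = sp$isi_cv, fi_pass = fi_ok,
                  pass = s1_pass)

  sag <- measure_sag(model, amp = -0.2, dur = 1000)
  s2_pass <- sag >= config$sag_range[1] && sag <= config$sag_range[2]
  step2 <- tibble(sag_mv = sag, pass = s2_pass)

  block_rate <- function(mod) {
    sim <- simulate_cell(mod, t_stop = 3000, settle = 500, record_dt = 0.2,
                         recordings = list(record("V", "soma", name = "v")))
    length(spike_times(sim, "v")) / 3
  }
  r_cav <- block_rate(switch_off(model, "Cav2.2", block = 0.9))
  s3_pass <- r_cav > 0 && r_cav <= config$burst_max_hz
  r_sk <- block_rate(switch_off(model, "Kca2.2", block = 0.9))
  r_bk <- block_rate(switch_off(model, "Kca1.1", block = 0.9))
  step3 <- tibble(cav22_block_hz = r_cav, kca22_block_hz = r_sk,
                  kca11_block_hz = r_bk, pass = s3_pass)

  structure(list(step1 = step1, step2 = step2, step3 = step3,
                 overall = s1_pass && s2_pass && s3_pass),
            class = "goc_validation")
}

#' @export
print.goc_validation <- function(x, ...) {
  cat("<goc_validation> overall:", if (x$overall) "PASS" else "FAIL", "\n")
  cat(sprintf("  step 1: rate %.2f Hz, ISI CV %.3f, f-I %s -> %s\n",
              x$step1$rate_hz, x$step1$isi_cv,
              if (x$step1$fi_pass) "in range" else "out of range",
              if (x$step1$pass) "pass" else "fail"))
  cat(sprintf("  step 2: sag %.2f mV -> %s\n", x$step2$sag_mv,
              if (x$step2$pass) "pass" else "fail"))
  cat(sprintf("  step 3: Cav2.2-block %.2f Hz -> %s\n",
              x$step3$cav22_block_hz, if (x$step3$pass) "pass" else "fail"))
  invisible(x)
}

#' Triage statistics over a set of validation reports
#'
#' @param reports List of `goc_validation` objects.
#' @return Tibble with the fraction passing steps 1-2 and the fraction
#'   passing all steps.
#' @export
triage_stats <- function(reports) {
  stopifnot(length(reports) >= 1)
  s12 <- vapply(reports, function(r) r$step1$pass && r$step2$pass, logical(1))
  all3 <- vapply(reports, function(r) isTRUE(r$overall), logical(1))
  tibble(n = length(reports), frac_steps_1_2 = mean(s12),
         frac_all_steps = mean(all3))
}
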