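# ggplot2 views of simulation results and broom-style tidiers.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 ggplot aes geom_line geom_point labs autoplot
#'   facet_wrap geom_col geom_hline geom_tile
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a simulation result into long format
#'
#' @param x A `goc_sim`.
#' @param ... Unused.
#' @return Tibble: `time`, `trace`, `value`.
#' @export
tidy.goc_sim <- function(x, ...) {
  tidyr::pivot_longer(x$traces, -"time", names_to = "trace",
                      values_to = "value")
}

#' @export
glance.goc_sim <- function(x, ...) {
  tibble(t_stop_ms = x$t_stop, dt_ms = x$dt, record_dt_ms = x$record_dt,
         n_traces = ncol(x$traces) - 1L, n_samples = nrow(x$traces))
}

#' @export
tidy.goc_ga <- function(x, ...) x$logbook

#' @export
glance.goc_ga <- function(x, ...) {
  tibble(pop_size = nrow(x$population), n_gen = max(x$logbook$gen),
         best_fitness = x$best_fitness, seed = x$seed)
}

#' @export
tidy.goc_validation <- function(x, ...) {
  dplyr::bind_rows(
    tibble(step = "step1", metric = c("rate_hz", "isi_cv"),
           value = c(x$step1$rate_hz, x$step1$isi_cv), pass = x$step1$pass),
    tibble(step = "step2", metric = "sag_mv", value = x$step2$sag_mv,
           pass = x$step2$pass),
    tibble(step = "step3", metric = c("cav22_block_hz", "kca22_block_hz",
                                      "kca11_block_hz"),
           value = c(x$step3$cav22_block_hz, x$step3$kca22_block_hz,
                     x$step3$kca11_block_hz), pass = x$step3$pass)
  )
}

#' @export
glance.goc_validation <- function(x, ...) {
  tibble(step1 = x$step1$pass, step2 = x$step2$pass, step3 = x$step3$pass,
         overall = x$overall)
}

#' @export
autoplot.goc_sim <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~.data$trace, scales = "free_y", ncol = 1) +
    labs(x = "time (ms)", y = NULL)
}

#' Plot an f-I curve
#'
#' @param fi Output of [run_fi()].
#' @return A ggplot.
#' @export
plot_fi <- function(fi) {
  ggplot(fi, aes(x = .data$amplitude_nA, y = .data$frequency_hz)) +
    geom_line() + geom_point() +
    labs(x = "injected current (nA)", y = "firing frequency (Hz)")
}

#' Plot a resonance curve
#'
#' @param res Output of [measure_resonance()].
#' @return A ggplot.
#' @export
plot_resonance <- function(res) {
  ggplot(res, aes(x = .data$rep_freq_hz, y = .data$output_hz)) +
    geom_line() + geom_point() +
    labs(x = "repetition frequency (Hz)", y = "intra-burst output (Hz)")
}

#' Plot an STDP curve
#'
#' @param curve Output of [stdp_curve()].
#' @return A ggplot.
#' @export
plot_stdp <- function(curve) {
  ggplot(curve, aes(x = .data$dt_ms, y = .data$dw_percent)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_line() + geom_point() +
    labs(x = "MF - PF timing offset (ms)", y = "weight change (%)")
}

#' @export
autoplot.goc_stdp <- function(object, ...) plot_stdp(object)

#' Plot a PSTH
#'
#' @param psth The `psth` tibble from [run_psth()].
#' @return A ggplot.
#' @export
plot_psth <- function(psth) {
  ggplot(psth, aes(x = .data$bin_start_ms, y = .data$rate_hz)) +
    geom_col(width = diff(psth$bin_start_ms)[1]) +
    labs(x = "time (ms)", y = "rate (Hz)")
}

#' Plot a synaptic input-output surface
#'
#' @param surface Output of [io_surface()].
#' @return A ggplot.
#' @export
plot_io_surface <- function(surface) {
  ggplot(surface, aes(x = .data$n_pf, y = .data$n_mf,
                      fill = .data$output_hz)) +
    geom_tile() +
    labs(x = "parallel fiber synapses", y = "mossy fiber synapses",
         fill = "output (Hz)")
}
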