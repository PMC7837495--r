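# Shared fixtures, built lazily and cached for the whole suite.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# surrogate morphology at the desk-scale 40 um grid
surrogate40 <- function() {
  fixture("surrogate40", function() discretize(make_surrogate(seed = 1), 40))
}

# the exemplar model: default Table-value conductances on the surrogate
exemplar_model <- function() {
  fixture("exemplar", function() cell_model(surrogate40()))
}

# an isopotential passive sphere of total area 1e-4 cm^2 (as a 2-point
# cylindrical soma with diameter = length)
passive_sphere <- function(e_leak = -70) {
  d <- sqrt(1e-4 / pi) * 1e4 # um
  swc <- tempfile(fileext = ".swc")
  writeLines(sprintf("%d 1 0 %g 0 %g %d", 1:2, c(0, d), d / 2, c(-1, 1)), swc)
  m <- discretize(read_swc(swc), 2 * d)
  cell_model(m, registry = default_channel_registry()[0, ],
             passive = passive_defaults(e_leak = e_leak))
}

# a passive model on the surrogate (no active channels)
passive_surrogate <- function() {
  fixture("passive_surrogate", function() {
    cell_model(surrogate40(), registry = default_channel_registry()[0, ])
  })
}

# cached 3-second spontaneous run of the exemplar
exemplar_spontaneous <- function() {
  fixture("exemplar_spont", function() {
    simulate_cell(exemplar_model(), t_stop = 3000, settle = 500,
                  record_dt = 0.1,
                  recordings = list(record("V", "soma", name = "v")))
  })
}

# write a morphology, return the path
write_swc_tmp <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}
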