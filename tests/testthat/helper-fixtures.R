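# Shared helpers: tiny fixtures built in code.

# A toggle-switch model with all regulation disabled (lambda = 1), i.e. two
# independent linear birth-death genes; used for closed-form checks.
unregulated_toggle_model <- function(seed = 7) {
  ts <- fixture_circuit("TS")
  m <- sample_model(ts, default_ranges(ts), seed = seed)
  m$LAMBDA[] <- 1
  list(circuit = ts, params = m)
}

# Write a topology file from text lines, return the path.
write_topo_lines <- function(lines) {
  path <- tempfile(fileext = ".tpo")
  writeLines(lines, path)
  path
}

# Lazily computed, shared across tests in a session: a quadrastable set
# from the documented quadrastable range configuration.
quad_cache <- new.env(parent = emptyenv())
get_quadrastable_fixture <- function() {
  if (is.null(quad_cache$qset)) {
    ts2 <- fixture_circuit("TS_SA2")
    ens <- sample_ensemble(ts2, quadrastable_ranges(ts2),
                           n_models = 1500, seed = 5)
    quad_cache$qset <- find_quadrastable(ens, n_ic = 100, seed = 6)
  }
  quad_cache$qset
}
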