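# Shared fixtures. Expensive simulations are memoised for the session so
# several test files can reuse one run.

small_params <- function(n = 32, ...) {
  tissue_params(grid_rows = n, grid_cols = n, ...)
}

# quick plane-wave movie + ground truth on a small grid
quick_wave <- function(cv = 50, apd80 = 75, n = 48, cl = 400, beats = 4,
                       polarity = "fluorescence_down") {
  plane_wave_movie(cv, apd80,
                   params = small_params(n),
                   protocol = pacing_protocol(cycle_lengths = cl,
                                              beats_per_cl = beats),
                   polarity = polarity)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# one control-phenotype simulation at CL 400, reused across files
sim_control_400 <- function() cached("sim_control_400", {
  simulate_tissue(phenotype_params("control", grid_rows = 48, grid_cols = 48),
                  pacing_protocol(cycle_lengths = 400, beats_per_cl = 3),
                  seed = 5)
})

# Kruskal-Wallis H computed from first principles (definition formula with
# tie correction), independent of stats::kruskal.test
kw_h_definition <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, idx, sum)^2 / sizes) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
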