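# Shared, lazily computed simulation fixtures. Full-protocol simulations
# (10 APs at 20 Hz) take a few seconds each, so they are memoised for the
# whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture_traj <- function(genotype = "wt") {
  key <- paste0("traj_", genotype)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulate_release(default_parameters(),
                                         genotype = genotype)
  .fixtures[[key]]
}

fixture_metrics <- function(genotype = "wt") {
  key <- paste0("met_", genotype)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- per_stimulus_metrics(fixture_traj(genotype))
  .fixtures[[key]]
}

# a transient pinned at resting calcium, for stationarity checks
constant_transient <- function(params, t_end = 1) {
  structure(list(
    ca = function(t) rep(params$ca_rest, length(t)),
    synchronous = function(t) numeric(length(t)),
    residual = function(t) numeric(length(t)),
    ap_onsets = 0, t_end = t_end, freq = 1, params = params),
    class = "vesikin_transient")
}

# minimal hand-built trajectory (flat occupancies) for metric edge cases
flat_trajectory <- function(params = default_parameters(), t_end = 0.5,
                            n = 501) {
  states <- enumerate_states()
  tr <- build_transient(params, n_aps = 10, freq = 20, t_end = t_end)
  ss <- steady_state(params, params$ca_rest)
  time <- seq(0, t_end, length.out = n)
  sites <- matrix(rep(unname(ss$sites), each = n), n,
                  dimnames = list(NULL, states$labels))
  syt7 <- matrix(rep(unname(ss$syt7), each = n), n,
                 dimnames = list(NULL, states$syt7_labels))
  structure(list(time = time, sites = sites, syt7 = syt7,
                 fused = rep(0, n),
                 docked = rowSums(sites[, states$docked]),
                 tethered = rowSums(sites[, states$tethered]),
                 empty = rowSums(sites[, states$empty]),
                 params = params, genotype = "wt", transient = tr,
                 states = states),
            class = "vesikin_trajectory")
}
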