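#' Specification for synthetic optical traces
#'
#' Collects every knob of the iGluSnFR-like trace generator with defaults
#' emulating the single-stimulus recording conditions: 100 Hz frames, a
#' 500 ms baseline before the first stimulus, events with an instant rise
#' (within one frame) and exponential decay, white Gaussian noise in dF/F0
#' units, and a 64:36 split between synchronous and asynchronous events.
#' Asynchronous latencies follow an exponential law with 20 ms mean
#' truncated to (10, 100] ms after the stimulus (capped one frame short of
#' the inter-stimulus interval in trains). The decay constant defaults to
#' 100 ms (medium-affinity sensor variant); use ~30 ms to emulate the
#' faster low-affinity variant used for trains.
#'
#' @param seed integer RNG seed; identical seed and spec give bit-identical
#'   output.
#' @param n_boutons number of boutons (traces).
#' @param frame_period frame interval, s.
#' @param baseline_s baseline length before the first stimulus, s.
#' @param n_stimuli,freq train protocol (1 stimulus by default).
#' @param tail_s recording time after the last stimulus, s.
#' @param p_sync,p_async per-stimulus, per-bouton probabilities of emitting
#'   one synchronous / one asynchronous event.
#' @param sync_amp,async_amp mean event amplitudes, dF/F0 units.
#' @param amp_cv coefficient of variation of the lognormal amplitude law.
#' @param latency_mean,latency_min,latency_max asynchronous latency law, s.
#' @param kernel_tau event decay constant, s.
#' @param noise_sd Gaussian noise SD in dF/F0 units.
#' @param f0_raw baseline raw intensity (arbitrary units).
#' @return a `vesikin_synthspec` list.
#' @export
synth_spec <- function(seed = 1, n_boutons = 60, frame_period = 0.01,
                       baseline_s = 0.5, n_stimuli = 1, freq = 10,
                       tail_s = 0.3, p_sync = 0.64, p_async = 0.36,
                       sync_amp = 1.2, async_amp = 0.8, amp_cv = 0.3,
                       latency_mean = 0.02, latency_min = 0.01,
                       latency_max = 0.1, kernel_tau = 0.1,
                       noise_sd = 0.05, f0_raw = 1000) {
  spec <- as.list(environment())
  stopifnot(n_boutons >= 1, frame_period > 0, baseline_s > 0,
            n_stimuli >= 1, freq > 0, p_sync >= 0, p_sync <= 1,
            p_async >= 0, p_async <= 1, kernel_tau > 0, noise_sd >= 0,
            latency_min < latency_max)
  structure(spec, class = "vesikin_synthspec")
}

# exponential latency truncated to (lo, hi], by inverse CDF
rtrunc_exp <- function(n, mean, lo, hi) {
  u <- stats::runif(n)
  elo <- exp(-lo / mean); ehi <- exp(-hi / mean)
  -mean * log(elo - u * (elo - ehi))
}

rlnorm_mean <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - s^2 / 2, sdlog = s)
}

# render a ground-truth event table into noiseless dF/F0 traces
render_events <- function(truth, times, n_boutons, kernel_tau) {
  clean <- matrix(0, length(times), n_boutons)
  for (i in seq_len(nrow(truth))) {
    b <- truth$bouton[i]
    on <- times >= truth$time_s[i] - 1e-12
    clean[on, b] <- clean[on, b] +
      truth$amplitude[i] * exp(-(times[on] - truth$time_s[i]) / kernel_tau)
  }
  clean
}

#' Generate synthetic fluorescence traces with ground truth
#'
#' Draws, per bouton and stimulus, at most one synchronous event (placed on
#' the first frame after the stimulus) and one asynchronous event (latency
#' drawn from the truncated-exponential law, snapped to the enclosing
#' frame), renders them with the instant-rise/exponential-decay kernel,
#' and adds Gaussian noise on top of a constant raw baseline. The returned
#' ground truth is mutually consistent with the traces: re-rendering it
#' with the same kernel and zero noise reproduces the noiseless dF/F0
#' exactly.
#'
#' @param spec a `vesikin_synthspec`.
#' @return list with `trace` (a [fluorescence_trace()] object), `truth`
#'   (data.frame: `bouton`, `stimulus`, `class`, `time_s`, `rel_ms`,
#'   `amplitude`), `clean_dff` (noiseless dF/F0 matrix),
#'   `stimulus_onsets`, `spec`.
#' @export
synth_iglu <- function(spec = synth_spec()) {
  set.seed(spec$seed)
  onsets <- spec$baseline_s + (seq_len(spec$n_stimuli) - 1) / spec$freq
  t_end <- max(onsets) + spec$tail_s
  times <- seq(0, t_end, by = spec$frame_period)
  lat_hi <- spec$latency_max
  if (spec$n_stimuli > 1)
    lat_hi <- min(lat_hi, 1 / spec$freq - spec$frame_period)
  rows <- list()
  for (b in seq_len(spec$n_boutons)) {
    for (k in seq_len(spec$n_stimuli)) {
      if (stats::runif(1) < spec$p_sync) {
        tev <- onsets[k] + spec$frame_period
        rows[[length(rows) + 1]] <- data.frame(
          bouton = b, stimulus = k, class = "synchronous", time_s = tev,
          rel_ms = (tev - onsets[k]) * 1e3,
          amplitude = rlnorm_mean(1, spec$sync_amp, spec$amp_cv))
      }
      if (stats::runif(1) < spec$p_async) {
        lat <- rtrunc_exp(1, spec$latency_mean, spec$latency_min, lat_hi)
        tev <- spec$frame_period *
          ceiling((onsets[k] + lat) / spec$frame_period - 1e-9)
        rows[[length(rows) + 1]] <- data.frame(
          bouton = b, stimulus = k, class = "asynchronous", time_s = tev,
          rel_ms = (tev - onsets[k]) * 1e3,
          amplitude = rlnorm_mean(1, spec$async_amp, spec$amp_cv))
      }
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bouton = integer(), stimulus = integer(), class = character(),
               time_s = numeric(), rel_ms = numeric(), amplitude = numeric())
  clean <- render_events(truth, times, spec$n_boutons, spec$kernel_tau)
  raw <- spec$f0_raw *
    (1 + clean + matrix(stats::rnorm(length(clean), 0, spec$noise_sd),
                        nrow(clean)))
  trace <- fluorescence_trace(raw, time = times,
                              baseline_window = spec$baseline_s)
  list(trace = trace, truth = truth, clean_dff = clean,
       stimulus_onsets = onsets, spec = spec)
}

#' Generate a synthetic evoked-current train with ground truth
#'
#' Builds a 20 Hz train of phasic inward currents (unitary biexponential
#' waveforms with per-stimulus amplitudes depressing geometrically to a
#' plateau) riding on a slowly accumulating tonic envelope plus Gaussian
#' noise. The analytic tonic charge — the trapezoid over the envelope
#' sampled at the same tail nodes that [tonic_charge()] uses — is returned
#' as ground truth.
#'
#' @param n_stimuli,freq train protocol.
#' @param fs sampling rate, Hz.
#' @param baseline_s,tail_s record before the first / after the last
#'   stimulus, s.
#' @param amp1 first phasic amplitude, pA (negative = inward).
#' @param amp_ss_frac plateau amplitude as a fraction of `amp1`.
#' @param depress_tau_stim depression time constant in units of stimuli.
#' @param tau_rise,tau_decay phasic waveform constants, s.
#' @param tonic_fun envelope as a function of time since the first
#'   stimulus, pA (negative = inward); default exponential build-up to
#'   -150 pA with a 0.5 s time constant.
#' @param baseline_pA holding current, pA.
#' @param noise_sd current noise SD, pA.
#' @param seed RNG seed.
#' @return list with `trace` (a [current_trace()] object), `truth` (list:
#'   `phasic_amplitudes`, `tonic_fun`, `tonic_charge` in pC, `tail_times`),
#'   and the generating arguments in `spec`.
#' @export
synth_epsc <- function(n_stimuli = 50, freq = 20, fs = 10e3,
                       baseline_s = 0.2, tail_s = 0.3, amp1 = -1500,
                       amp_ss_frac = 0.4, depress_tau_stim = 3,
                       tau_rise = 0.001, tau_decay = 0.004,
                       tonic_fun = NULL, baseline_pA = -20, noise_sd = 2,
                       seed = 1) {
  set.seed(seed)
  if (is.null(tonic_fun))
    tonic_fun <- function(t) -150 * (1 - exp(-t / 0.5)) * (t >= 0)
  onsets <- baseline_s + (seq_len(n_stimuli) - 1) / freq
  t_end <- max(onsets) + tail_s
  times <- seq(0, t_end, by = 1 / fs)
  amp_ss <- amp1 * amp_ss_frac
  amps <- amp_ss + (amp1 - amp_ss) * exp(-(seq_len(n_stimuli) - 1) /
                                           depress_tau_stim)
  # unitary waveform normalised to peak 1
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  pk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  cur <- rep(baseline_pA, length(times))
  for (k in seq_len(n_stimuli)) {
    dt <- times - onsets[k]
    on <- dt >= 0
    cur[on] <- cur[on] + amps[k] *
      (exp(-dt[on] / tau_decay) - exp(-dt[on] / tau_rise)) / pk
  }
  cur <- cur + tonic_fun(times - onsets[1])
  if (noise_sd > 0) cur <- cur + stats::rnorm(length(cur), 0, noise_sd)
  trace <- current_trace(times, cur, onsets)
  isi <- 1 / freq
  tail_t <- c(onsets[-1], onsets[n_stimuli] + isi) - 0.001
  nodes_t <- c(onsets[1], tail_t)
  nodes_v <- tonic_fun(nodes_t - onsets[1])
  gt_charge <- sum(diff(nodes_t) *
                     -(utils::head(nodes_v, -1) + utils::tail(nodes_v, -1)) / 2)
  list(trace = trace,
       truth = list(phasic_amplitudes = amps, tonic_fun = tonic_fun,
                    tonic_charge = gt_charge, tail_times = tail_t),
       spec = list(n_stimuli = n_stimuli, freq = freq, fs = fs,
                   baseline_s = baseline_s, tail_s = tail_s, amp1 = amp1,
                   amp_ss_frac = amp_ss_frac,
                   depress_tau_stim = depress_tau_stim,
                   tau_rise = tau_rise, tau_decay = tau_decay,
                   baseline_pA = baseline_pA, noise_sd = noise_sd,
                   seed = seed))
}

#' Synthetic single-sweep current from a known charge decomposition
#'
#' Generates the current whose cumulative charge is exactly
#' `Qf (1 - e^(-t/tau_f)) + Qs (1 - e^(-t/tau_s))`, for validating
#' [cumulative_charge_decomposition()] against known parameters.
#'
#' @param q_fast,q_slow component charges, pC.
#' @param tau_fast,tau_slow component time constants, s.
#' @param fs sampling rate, Hz.
#' @param baseline_s pre-stimulus record, s.
#' @param window post-stimulus record, s.
#' @param baseline_pA holding current, pA.
#' @param noise_sd current noise SD, pA.
#' @param seed RNG seed (used only if `noise_sd > 0`).
#' @return list with `trace` (a [current_trace()]) and `truth`.
#' @export
synth_biexp_current <- function(q_fast = 30, q_slow = 20, tau_fast = 0.006,
                                tau_slow = 0.09, fs = 20e3,
                                baseline_s = 0.1, window = 0.5,
                                baseline_pA = -20, noise_sd = 0, seed = 1) {
  set.seed(seed)
  times <- seq(0, baseline_s + window, by = 1 / fs)
  dt <- times - baseline_s
  on <- dt >= 0
  cur <- rep(baseline_pA, length(times))
  cur[on] <- cur[on] - (q_fast / tau_fast * exp(-dt[on] / tau_fast) +
                          q_slow / tau_slow * exp(-dt[on] / tau_slow))
  if (noise_sd > 0) cur <- cur + stats::rnorm(length(cur), 0, noise_sd)
  list(trace = current_trace(times, cur, baseline_s),
       truth = list(q_fast = q_fast, q_slow = q_slow, tau_fast = tau_fast,
                    tau_slow = tau_slow))
}

#' Model-driven synthetic fluorescence traces
#'
#' Closes the loop from the kinetic model to the optical measurement: a
#' simulated trajectory's per-stimulus synchronous and asynchronous fusion
#' counts set per-bouton event probabilities (`1 - exp(-gain * count)`),
#' asynchronous event latencies are drawn from the trajectory's own
#' release-time distribution within the asynchronous window, and events are
#' rendered and analysed exactly like [synth_iglu()] output.
#'
#' @param params a `vesikin_params`.
#' @param genotype genotype preset.
#' @param gain vesicles-to-event-probability conversion (per vesicle).
#' @param traj optionally, a precomputed `vesikin_trajectory` (its genotype
#'   wins over `genotype`).
#' @param n_boutons,frame_period,baseline_s,noise_sd,kernel_tau,amp,seed
#'   trace rendering controls; `amp` is the (fixed) event amplitude.
#' @return as [synth_iglu()].
#' @export
model_driven_synth <- function(params, genotype = "wt", gain = 0.04,
                               traj = NULL, n_boutons = 60,
                               frame_period = 0.01, baseline_s = 0.5,
                               noise_sd = 0.05, kernel_tau = 0.03,
                               amp = 1, seed = 1) {
  if (is.null(traj)) traj <- simulate_release(params, genotype = genotype)
  set.seed(seed)
  met <- per_stimulus_metrics(traj)$table
  n_stim <- nrow(met)
  freq <- traj$transient$freq
  isi <- 1 / freq
  onsets <- baseline_s + traj$transient$ap_onsets
  p_sync <- 1 - exp(-gain * met$sync_count)
  p_async <- 1 - exp(-gain * met$async_count)
  # asynchronous latency law per stimulus, from the model's own release
  lat_grid <- seq(0.005, isi, by = 0.001)
  times <- seq(0, max(onsets) + 0.3, by = frame_period)
  rows <- list()
  for (k in seq_len(n_stim)) {
    Fk <- interp_fused(traj, met$onset_s[k] + lat_grid)
    w <- pmax(diff(Fk), 0)
    for (b in seq_len(n_boutons)) {
      if (stats::runif(1) < p_sync[k]) {
        tev <- onsets[k] + frame_period
        rows[[length(rows) + 1]] <- data.frame(
          bouton = b, stimulus = k, class = "synchronous", time_s = tev,
          rel_ms = frame_period * 1e3, amplitude = amp)
      }
      if (stats::runif(1) < p_async[k] && sum(w) > 0) {
        lat <- lat_grid[sample.int(length(w), 1, prob = w)] +
          stats::runif(1, 0, 0.001)
        lat <- min(lat, isi - frame_period)
        tev <- frame_period * ceiling((onsets[k] + lat) / frame_period - 1e-9)
        rows[[length(rows) + 1]] <- data.frame(
          bouton = b, stimulus = k, class = "asynchronous", time_s = tev,
          rel_ms = (tev - onsets[k]) * 1e3, amplitude = amp)
      }
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bouton = integer(), stimulus = integer(), class = character(),
               time_s = numeric(), rel_ms = numeric(), amplitude = numeric())
  clean <- render_events(truth, times, n_boutons, kernel_tau)
  raw <- 1000 * (1 + clean + matrix(stats::rnorm(length(clean), 0, noise_sd),
                                    nrow(clean)))
  trace <- fluorescence_trace(raw, time = times, baseline_window = baseline_s)
  list(trace = trace, truth = truth, clean_dff = clean,
       stimulus_onsets = onsets, gain = gain, trajectory = traj)
}
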