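#' Fluorescence trace container
#'
#' Holds uniformly sampled per-bouton optical sensor recordings and their
#' normalised form. The baseline window (by default the first 500 ms,
#' before the first stimulus) defines F0 as the per-bouton mean raw
#' intensity; traces are expressed as dF/F0 = (F - F0)/F0, and the baseline
#' noise SD is estimated per bouton from the dF/F0 baseline samples.
#'
#' @param time frame times in seconds (uniform grid), or `NULL` to derive
#'   from `frame_period`.
#' @param raw numeric matrix (frames x boutons) or vector of raw
#'   intensities.
#' @param frame_period frame interval, s (default 10 ms).
#' @param baseline_window length of the baseline at the start of the
#'   record, s (default 0.5).
#' @param robust_noise if `TRUE`, use 1.4826 x median absolute deviation
#'   instead of the plain SD for the baseline noise estimate.
#' @return object of class `vesikin_fluor`: list with `time`, `raw`, `dff`,
#'   `f0`, `noise_sd`, `frame_period`, `baseline_window`.
#' @export
fluorescence_trace <- function(raw, time = NULL, frame_period = 0.01,
                               baseline_window = 0.5, robust_noise = FALSE) {
  raw <- as.matrix(raw)
  if (is.null(time)) time <- (seq_len(nrow(raw)) - 1) * frame_period
  if (length(time) != nrow(raw)) stop("time and raw lengths differ")
  if (nrow(raw) > 1) {
    dt <- diff(time)
    if (max(abs(dt - dt[1])) > 1e-9) stop("frames must be uniformly sampled")
    frame_period <- dt[1]
  }
  base_idx <- which(time < time[1] + baseline_window)
  if (length(base_idx) < 2)
    stop("need at least two baseline frames before the first stimulus")
  f0 <- colMeans(raw[base_idx, , drop = FALSE])
  if (any(f0 == 0)) stop("zero baseline intensity; cannot form dF/F0")
  dff <- sweep(sweep(raw, 2, f0, "-"), 2, f0, "/")
  noise <- apply(dff[base_idx, , drop = FALSE], 2,
                 if (robust_noise) function(x) stats::mad(x) else stats::sd)
  structure(list(time = time, raw = raw, dff = dff, f0 = f0,
                 noise_sd = noise, frame_period = frame_period,
                 baseline_window = baseline_window),
            class = "vesikin_fluor")
}

#' Detect release events in fluorescence traces
#'
#' A release event is a frame-to-frame intensity *change* (rise of dF/F0)
#' exceeding `threshold_sd` times the noise SD of the baseline changes —
#' thresholding the change rather than the absolute level keeps detection
#' robust while earlier events are still decaying. The event's time is the
#' frame in which the signal peaks (the frame the rise lands on, given the
#' within-one-frame rise of the sensor; plateau ties resolve to the
#' earliest frame). Each event is assigned to the latest stimulus at or
#' before its peak frame, binned into 10 ms bins from that stimulus's
#' onset, and classed synchronous if it falls in the first bin,
#' asynchronous otherwise. Dual peaks at one bouton after one stimulus
#' (synchronous then asynchronous) are reported as separate events. Events
#' before the first stimulus are discarded.
#'
#' @param trace a `vesikin_fluor` object.
#' @param stimulus_onsets stimulus times, s.
#' @param threshold_sd detection threshold as a multiple of the baseline
#'   noise SD of the differenced trace (default 5).
#' @param bin_width classification bin, s (default 10 ms).
#' @return object of class `vesikin_events`: data.frame with `bouton`,
#'   `time_s` (absolute peak time), `stimulus` (1-based index), `rel_ms`
#'   (peak time from stimulus onset), `bin` (1-based 10 ms bin),
#'   `class` (`"synchronous"`/`"asynchronous"`), `amplitude` (dF/F0 at the
#'   peak frame).
#' @export
detect_events <- function(trace, stimulus_onsets, threshold_sd = 5,
                          bin_width = 0.01) {
  if (!inherits(trace, "vesikin_fluor")) stop("need a vesikin_fluor object")
  if (!length(stimulus_onsets)) stop("need at least one stimulus onset")
  stimulus_onsets <- sort(stimulus_onsets)
  out <- list()
  nt <- length(trace$time)
  base_idx <- which(trace$time < trace$time[1] + trace$baseline_window)
  for (b in seq_len(ncol(trace$dff))) {
    x <- trace$dff[, b]
    rise <- diff(x)
    sd_rise <- stats::sd(rise[utils::head(base_idx, -1)])
    if (!is.finite(sd_rise)) stop("cannot estimate baseline change noise")
    thr <- threshold_sd * sd_rise
    peaks <- which(rise > thr) + 1L
    if (!length(peaks)) next
    tp <- trace$time[peaks]
    stim <- findInterval(tp + 1e-9, stimulus_onsets)
    keep <- stim >= 1
    if (!any(keep)) next
    tp <- tp[keep]; stim <- stim[keep]; amps <- x[peaks][keep]
    rel <- tp - stimulus_onsets[stim]
    bin <- pmax(1L, ceiling((rel - 1e-9) / bin_width))
    out[[b]] <- data.frame(bouton = b, time_s = tp, stimulus = stim,
                           rel_ms = rel * 1e3, bin = bin,
                           class = ifelse(bin == 1L, "synchronous",
                                          "asynchronous"),
                           amplitude = amps)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(bouton = integer(), time_s = numeric(), stimulus = integer(),
               rel_ms = numeric(), bin = integer(), class = character(),
               amplitude = numeric())
  rownames(res) <- NULL
  class(res) <- c("vesikin_events", "data.frame")
  res
}

#' Percentage of events classified asynchronous
#'
#' @param events a `vesikin_events` table.
#' @return 100 x (asynchronous events)/(all events).
#' @export
percent_asynchronous <- function(events) {
  if (!nrow(events)) stop("no events: percent asynchronous is undefined")
  100 * mean(events$class == "asynchronous")
}

#' Per-stimulus asynchronous release fraction in a train
#'
#' For every stimulus, the fraction of its events (peaks up to the next
#' stimulus) that fall after the first 10 ms bin. Stimuli with no events
#' give 0.
#'
#' @param events a `vesikin_events` table.
#' @param n_stimuli number of stimuli in the protocol.
#' @return numeric vector of length `n_stimuli`.
#' @export
train_ar_fraction <- function(events, n_stimuli) {
  vapply(seq_len(n_stimuli), function(k) {
    ev <- events[events$stimulus == k, ]
    if (!nrow(ev)) return(0)
    mean(ev$class == "asynchronous")
  }, 0)
}

#' Mean event amplitude per stimulus
#' @param events a `vesikin_events` table.
#' @param n_stimuli number of stimuli.
#' @param synchronous_only restrict to synchronous events (default TRUE,
#'   the convention for amplitude-based train metrics).
#' @return numeric vector (NA for stimuli without events).
#' @export
per_stimulus_amplitude <- function(events, n_stimuli,
                                   synchronous_only = TRUE) {
  if (synchronous_only) events <- events[events$class == "synchronous", ]
  vapply(seq_len(n_stimuli), function(k) {
    a <- events$amplitude[events$stimulus == k]
    if (!length(a)) NA_real_ else mean(a)
  }, 0)
}

#' Paired-pulse ratio
#'
#' Second response amplitude over the first; above one indicates
#' facilitation, below one depression.
#'
#' @param amplitudes per-stimulus mean amplitudes (length >= 2).
#' @return `amplitudes[2] / amplitudes[1]`.
#' @export
paired_pulse_ratio <- function(amplitudes) {
  if (length(amplitudes) < 2) stop("need at least two stimuli")
  if (is.na(amplitudes[1]) || amplitudes[1] == 0)
    stop("first amplitude is zero or undefined")
  amplitudes[2] / amplitudes[1]
}

#' Current trace container
#'
#' @param time sample times, s (uniform).
#' @param current membrane current, pA (inward negative).
#' @param stimulus_onsets stimulus times, s.
#' @return object of class `vesikin_current`: list with `time`, `current`,
#'   `stimulus_onsets`, `baseline` (mean current before the first
#'   stimulus, pA), `fs` (sampling rate, Hz).
#' @export
current_trace <- function(time, current, stimulus_onsets) {
  if (length(time) != length(current)) stop("time and current lengths differ")
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("sampling must be uniform")
  stimulus_onsets <- sort(stimulus_onsets)
  base_idx <- time < stimulus_onsets[1]
  if (!any(base_idx)) stop("no baseline samples before the first stimulus")
  structure(list(time = time, current = current,
                 stimulus_onsets = stimulus_onsets,
                 baseline = mean(current[base_idx]), fs = 1 / dt[1]),
            class = "vesikin_current")
}

# cumulative trapezoid of y over x, starting at 0
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Decompose the cumulative charge of a single evoked response
#'
#' Integrates the baseline-subtracted current over `window` seconds from
#' the stimulus (inward current counts as positive transferred charge;
#' pA x s = pC) and fits the double exponential
#' \deqn{Q(t) = Q_f (1 - e^{-t/\tau_f}) + Q_s (1 - e^{-t/\tau_s})}
#' by nonlinear least squares, multi-started over tau guesses with
#' log-transformed parameters so all four stay positive, and ordered so
#' `tau_fast < tau_slow`. The fast component reflects synchronous release,
#' the slow one asynchronous release.
#'
#' @param trace a `vesikin_current` with a single stimulus.
#' @param window integration window after the stimulus, s (default 0.4).
#' @param tau_starts initial decay-constant guesses, s.
#' @return list with `q_fast`, `q_slow` (pC), `tau_fast`, `tau_slow` (s),
#'   `amplitude` (peak baseline-subtracted inward current, pA),
#'   `total_charge` (pC), `degenerate` (TRUE when the fitted taus differ by
#'   less than 3x, i.e. the split is not identifiable), `fit` (the nls
#'   object), `t`, `q` (the fitted series).
#' @export
cumulative_charge_decomposition <- function(trace, window = 0.4,
                                            tau_starts = c(0.005, 0.1)) {
  on <- trace$stimulus_onsets[1]
  sel <- trace$time >= on & trace$time <= on + window
  if (sum(sel) < 10) stop("too few samples in the integration window")
  t <- trace$time[sel] - on
  q <- cumtrapz(t, -(trace$current[sel] - trace$baseline))  # pC, inward > 0
  q_tot <- q[length(q)]
  if (q_tot <= 0) stop("non-positive total charge; check current sign")
  model <- function(p, t)
    exp(p[1]) * (1 - exp(-t / exp(p[3]))) + exp(p[2]) * (1 - exp(-t / exp(p[4])))
  best <- NULL
  grid <- expand.grid(f = tau_starts, s = tau_starts)
  grid <- grid[grid$f <= grid$s, ]
  for (i in seq_len(nrow(grid))) {
    start <- c(lqf = log(0.7 * q_tot), lqs = log(max(0.3 * q_tot, 1e-6)),
               ltf = log(grid$f[i]), lts = log(grid$s[i]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start,
                         fn = function(p) q - model(p, t),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("biexponential fit failed to converge")
  p <- exp(best$par)
  names(p) <- c("q1", "q2", "tau1", "tau2")
  ord <- order(p[c("tau1", "tau2")])
  qs <- p[c("q1", "q2")][ord]; taus <- p[c("tau1", "tau2")][ord]
  amp <- max(-(trace$current[sel] - trace$baseline))
  list(q_fast = unname(qs[1]), q_slow = unname(qs[2]),
       tau_fast = unname(taus[1]), tau_slow = unname(taus[2]),
       amplitude = amp, total_charge = q_tot,
       degenerate = taus[2] / taus[1] < 3,
       fit = best, t = t, q = q)
}

#' Tonic charge of a stimulus train
#'
#' Quantifies the slow build-up of inward current during a train: tail
#' currents are sampled 1 ms before each stimulus from the second onward
#' and 1 ms before the would-be next stimulus after the last, the tonic
#' envelope is the piecewise-linear interpolation through these tails
#' anchored at the baseline at the first onset, and the tonic charge is the
#' integral of (baseline - envelope) over the train, so sustained inward
#' (negative) current gives positive charge in pC.
#'
#' @param trace a `vesikin_current` with a train of stimuli.
#' @param isi inter-stimulus interval, s; inferred from the onsets if
#'   omitted.
#' @param tail_offset how long before each stimulus the tail is read, s.
#' @return list with `charge` (pC), `tail_times`, `tail_values` (pA), and
#'   `envelope` (function of time).
#' @export
tonic_charge <- function(trace, isi = NULL, tail_offset = 0.001) {
  on <- trace$stimulus_onsets
  if (length(on) < 2) stop("tonic charge needs a train of stimuli")
  if (is.null(isi)) isi <- stats::median(diff(on))
  tail_t <- c(on[-1], on[length(on)] + isi) - tail_offset
  if (max(tail_t) > max(trace$time)) stop("tail sample outside the record")
  tail_v <- stats::approx(trace$time, trace$current, xout = tail_t)$y
  nodes_t <- c(on[1], tail_t)
  nodes_v <- c(trace$baseline, tail_v)
  env <- stats::approxfun(nodes_t, nodes_v)
  # trapezoid over the envelope nodes: exact for a piecewise-linear envelope
  charge <- sum(diff(nodes_t) *
                  (utils::head(trace$baseline - nodes_v, -1) +
                   utils::tail(trace$baseline - nodes_v, -1)) / 2)
  list(charge = charge, tail_times = tail_t, tail_values = tail_v,
       envelope = env)
}
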