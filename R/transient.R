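#' Build the free-calcium transient driving the model
#'
#' The transient for an action-potential (AP) train is the resting
#' concentration plus, for each AP, a sharp synchronous component and a slow
#' residual component. The synchronous component is a Gaussian bump peaking
#' `gauss_mean` ms after AP onset (sd `gauss_sd` ms), scaled so its peak
#' height equals `amplitude_ap`. The residual starts `t0_offset` ms after
#' onset and follows
#' \deqn{A e^{-(t - t_0)/\tau} \frac{t - t_0}{(t - t_0) + k_m}}
#' for t >= t0 (zero before), where the Michaelis-type factor smooths the
#' onset; residuals from successive APs add linearly. The returned object
#' evaluates the transient analytically at arbitrary times, so ODE solvers
#' can take any step.
#'
#' @param params a `vesikin_params` object.
#' @param n_aps number of APs (>= 1); defaults to the protocol in `params`.
#' @param freq stimulation frequency in Hz (> 0).
#' @param t_end end of the record in seconds; default extends 50 ms past the
#'   last AP onset.
#' @return an object of class `vesikin_transient`: list with `ca(t)` (total,
#'   uM), `synchronous(t)`, `residual(t)` (per-component sums over APs,
#'   excluding rest), `ap_onsets` (s), `t_end`, and the generating `params`.
#' @examples
#' tr <- build_transient(default_parameters(), n_aps = 10, freq = 20)
#' tr$ca(-0.001)      # resting 0.05 uM before the first AP
#' max(tr$synchronous(seq(0, 0.005, by = 1e-6)))   # ~30 uM peak
#' @export
build_transient <- function(params, n_aps = params$protocol$n_aps,
                            freq = params$protocol$freq, t_end = NULL) {
  if (!is.numeric(n_aps) || n_aps < 1 || n_aps != round(n_aps))
    stop("n_aps must be a positive integer")
  if (!is.numeric(freq) || freq <= 0) stop("freq must be > 0")
  onsets <- (seq_len(n_aps) - 1) / freq
  if (is.null(t_end)) t_end <- onsets[n_aps] + 0.05
  mu  <- params$gauss_mean / 1000   # s
  sd  <- params$gauss_sd / 1000
  t0  <- params$t0_offset / 1000
  km  <- params$km_smooth / 1000
  amp <- params$amplitude_ap
  A   <- params$amplitude_residual
  tau <- params$tau_residual

  synchronous <- function(t) {
    out <- numeric(length(t))
    for (o in onsets) out <- out + amp * exp(-((t - o - mu)^2) / (2 * sd^2))
    out
  }
  residual <- function(t) {
    out <- numeric(length(t))
    for (o in onsets) {
      dt <- t - o - t0
      on <- dt > 0
      out[on] <- out[on] + A * exp(-dt[on] / tau) * dt[on] / (dt[on] + km)
    }
    out
  }
  ca <- function(t) params$ca_rest + synchronous(t) + residual(t)

  structure(list(ca = ca, synchronous = synchronous, residual = residual,
                 ap_onsets = onsets, t_end = t_end, freq = freq,
                 params = params),
            class = "vesikin_transient")
}

#' @export
print.vesikin_transient <- function(x, ...) {
  cat(sprintf("Ca2+ transient: %d AP(s) at %g Hz, record 0-%g s\n",
              length(x$ap_onsets), x$freq, x$t_end))
  cat(sprintf("  peak %g uM synchronous + %g uM residual over %g uM rest\n",
              x$params$amplitude_ap, x$params$amplitude_residual,
              x$params$ca_rest))
  invisible(x)
}

#' @export
plot.vesikin_transient <- function(x, n = 5000, log = "", ...) {
  t <- seq(0, x$t_end, length.out = n)
  graphics::plot(t * 1e3, x$ca(t), type = "l", xlab = "time (ms)",
                 ylab = expression("[Ca"^"2+"*"] ("*mu*"M)"), log = log, ...)
  invisible(x)
}

#' Tabulate a transient on a uniform grid
#' @param transient a `vesikin_transient`.
#' @param fs sampling rate in Hz.
#' @return data.frame with `time_s` and `ca_uM`.
#' @export
sample_transient <- function(transient, fs = 50e3) {
  t <- seq(0, transient$t_end, by = 1 / fs)
  data.frame(time_s = t, ca_uM = transient$ca(t))
}
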