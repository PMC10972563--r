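#' Release-rate time series from a trajectory
#'
#' The cumulative fused-vesicle count is linearly interpolated onto a
#' uniform grid at `fs` and differenced forward, so `rate[i]` approximates
#' the instantaneous release rate on `[t_i, t_{i+1})` in vesicles/s.
#'
#' @param traj a `vesikin_trajectory`.
#' @param fs sampling rate, Hz (default 50 kHz).
#' @return data.frame with `time_s` and `rate` (the last grid point carries
#'   a zero-length interval and is dropped).
#' @export
release_rate_series <- function(traj, fs = 50e3) {
  if (fs <= 0) stop("fs must be > 0")
  t_end <- max(traj$time)
  if (t_end < 1 / fs) stop("trajectory shorter than one sample interval")
  grid <- seq(0, t_end, by = 1 / fs)
  Fg <- stats::approx(traj$time, traj$fused, xout = grid)$y
  data.frame(time_s = grid[-length(grid)], rate = diff(Fg) * fs)
}

# F interpolated at arbitrary times (rule 2 clamps at the record ends)
interp_fused <- function(traj, t) {
  stats::approx(traj$time, traj$fused, xout = t, rule = 2)$y
}

interp_docked <- function(traj, t) {
  stats::approx(traj$time, traj$docked, xout = t, rule = 2)$y
}

#' Per-stimulus model metrics
#'
#' For each AP with onset o_k and inter-stimulus interval ISI = 1/freq:
#' the peak release rate is the maximum of the 50 kHz release-rate series on
#' `[o_k, o_k + ISI)`; the asynchronous count is the release between
#' `o_k + 5 ms` and `o_k + ISI` (the synchronous window being the first
#' 5 ms); docked counts are read at +5, +11 and +15 ms after onset, and the
#' docking recovered between +5 and +15 ms is their difference. The
#' depression ratio is the last stimulus's peak rate over the first's.
#'
#' @param traj a `vesikin_trajectory`.
#' @param fs sampling rate for the rate series, Hz.
#' @param sync_window length of the synchronous window, s (default 5 ms).
#' @return an object of class `vesikin_metrics`: list with `table` (one row
#'   per stimulus: `stimulus`, `onset_s`, `peak_rate`, `sync_count`,
#'   `async_count`, `async_cumulative`, `docked_5ms`, `docked_11ms`,
#'   `docked_15ms`, `dock_recovery` (net docked change +5 to +15 ms),
#'   `dock_influx` (docking events +5 to +15 ms)), `depression_ratio`,
#'   `total_fused`,
#'   `genotype`.
#' @export
per_stimulus_metrics <- function(traj, fs = 50e3, sync_window = 0.005) {
  onsets <- traj$transient$ap_onsets
  isi <- 1 / traj$transient$freq
  rs <- release_rate_series(traj, fs)
  n <- length(onsets)
  peak <- sync_ct <- async_ct <- d5 <- d11 <- d15 <- influx <- numeric(n)
  for (k in seq_len(n)) {
    o <- onsets[k]
    in_win <- rs$time_s >= o & rs$time_s < o + isi
    peak[k] <- max(rs$rate[in_win])
    sync_ct[k] <- interp_fused(traj, o + sync_window) - interp_fused(traj, o)
    async_ct[k] <- interp_fused(traj, o + isi) - interp_fused(traj, o + sync_window)
    d5[k] <- interp_docked(traj, o + 0.005)
    d11[k] <- interp_docked(traj, o + 0.011)
    d15[k] <- interp_docked(traj, o + 0.015)
    influx[k] <- docking_influx(traj, o + 0.005, o + 0.015)
  }
  tab <- data.frame(stimulus = seq_len(n), onset_s = onsets,
                    peak_rate = peak, sync_count = sync_ct,
                    async_count = async_ct,
                    async_cumulative = cumsum(async_ct),
                    docked_5ms = d5, docked_11ms = d11, docked_15ms = d15,
                    dock_recovery = d15 - d5, dock_influx = influx)
  structure(list(table = tab, depression_ratio = peak[n] / peak[1],
                 total_fused = max(traj$fused), genotype = traj$genotype),
            class = "vesikin_metrics")
}

#' @export
print.vesikin_metrics <- function(x, ...) {
  cat(sprintf("Per-stimulus metrics (%s): %d stimuli\n", x$genotype,
              nrow(x$table)))
  print(format(x$table, digits = 4), row.names = FALSE)
  cat(sprintf("depression ratio (last/first peak): %.3f; total fused %.2f\n",
              x$depression_ratio, x$total_fused))
  invisible(x)
}

#' Vesicles docking in a window after one AP
#'
#' Two readings of "vesicles docking between +5 and +15 ms" are supported.
#' `"events"` (default) counts docking events: the integral of the docking
#' flux `k_docking * g(t) * tethered(t)` over the window, with `g` the syt7
#' catalytic factor — the measure that makes transient docking nearly
#' vanish when syt7 is removed. `"net"` is the change in the docked count
#' between the window ends, which confounds docking with the concurrent
#' undocking and fusion fluxes (and is zero on a flat trajectory).
#'
#' @param traj a `vesikin_trajectory`.
#' @param ap_index which stimulus (1-based).
#' @param window offsets after AP onset, s; default `c(0.005, 0.015)`.
#' @param measure `"events"` (gross docking influx) or `"net"` (docked
#'   count difference).
#' @return vesicles docking in the window (per the chosen measure).
#' @export
docking_recovery <- function(traj, ap_index = 1, window = c(0.005, 0.015),
                             measure = c("events", "net")) {
  measure <- match.arg(measure)
  onsets <- traj$transient$ap_onsets
  if (ap_index < 1 || ap_index > length(onsets)) stop("ap_index out of range")
  if (ap_index < length(onsets) &&
      window[2] > onsets[ap_index + 1] - onsets[ap_index])
    stop("window extends past the next stimulus onset")
  o <- onsets[ap_index]
  if (measure == "net")
    return(interp_docked(traj, o + window[2]) -
             interp_docked(traj, o + window[1]))
  docking_influx(traj, o + window[1], o + window[2])
}

# integral of the docking flux k_docking * g(t) * T(t) over [t1, t2]
docking_influx <- function(traj, t1, t2) {
  sel <- traj$time >= t1 & traj$time <= t2
  tt <- traj$time[sel]
  g <- as.vector(traj$syt7[sel, , drop = FALSE] %*%
                   traj$params$syt7$f^(0:2))
  flux <- traj$params$k_docking * g * traj$tethered[sel]
  sum(diff(tt) * (utils::head(flux, -1) + utils::tail(flux, -1)) / 2)
}

#' One-at-a-time parameter sweep
#'
#' Re-simulates the model with each named parameter scaled by each
#' multiplier (all other parameters at baseline) and records the four
#' headline metrics: vesicles docking 5-15 ms after the first AP
#' (`docking_5_15_ap1`, the events measure of [docking_recovery()]),
#' cumulative asynchronous release over the train
#' (`ar_total`), the first stimulus's peak release rate (`peak_rate_ap1`),
#' and the depression ratio of last to first peak rate
#' (`depression_ratio`). Failures of individual cells are recorded and the
#' sweep continues.
#'
#' @param params baseline `vesikin_params`.
#' @param names flat parameter keys to sweep (see [read_parameters()]).
#' @param multipliers sweep grid; default 13 log-spaced points from 0.1 to
#'   10.
#' @param genotype genotype preset applied to every cell.
#' @param ... passed to [simulate_release()].
#' @return data.frame in long format: `parameter`, `multiplier`, `metric`,
#'   `value`, `status`.
#' @export
parameter_sweep <- function(params, names,
                            multipliers = 10^seq(-1, 1, length.out = 13),
                            genotype = "wt", ...) {
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  rows <- list()
  metrics <- c("docking_5_15_ap1", "ar_total", "peak_rate_ap1",
               "depression_ratio")
  for (nm in names) {
    base_val <- get_parameter(params, nm)
    if (!is.numeric(base_val) || base_val <= 0)
      stop("swept parameter must be positive: ", nm)
    for (m in multipliers) {
      vals <- rep(NA_real_, 4)
      status <- "ok"
      res <- tryCatch({
        pm <- set_parameter(params, nm, base_val * m)
        traj <- simulate_release(pm, genotype = genotype, ...)
        met <- per_stimulus_metrics(traj)
        c(met$table$dock_influx[1],
          sum(met$table$async_count),
          met$table$peak_rate[1],
          met$depression_ratio)
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) status <- res else vals <- res
      rows[[length(rows) + 1]] <- data.frame(
        parameter = nm, multiplier = m, metric = metrics, value = vals,
        status = status)
    }
  }
  do.call(rbind, rows)
}
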