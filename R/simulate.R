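#' Simulate the release-site model over a calcium transient
#'
#' Integrates the 24 release-site occupancies, the 3-state syt7 occupancy
#' and the cumulative number of fused vesicles jointly, starting from the
#' steady state at resting calcium. The system is linear in the occupancies
#' at each instant — the generator is `A + ca(t) B + g(t) C` with `g` the
#' syt7 catalytic factor — and is driven by the analytic transient, so the
#' stiff solver can take arbitrary steps up to `hmax`. Defaults mirror a
#' stiff variable-order BDF run at relative/absolute tolerance 1e-5 and
#' maximum step 1e-5 s; output is returned on a uniform 50 kHz grid.
#'
#' Genotype presets: `"doc2_ko"` sets the Doc2alpha binding rate to zero,
#' `"syt7_ko"` sets the syt7 docking multiplier `f7` to one, `"dko"` both.
#'
#' @param params a `vesikin_params` object.
#' @param transient a `vesikin_transient`; built from `params`' protocol if
#'   omitted. Must cover the simulation window.
#' @param genotype `"wt"`, `"doc2_ko"`, `"syt7_ko"` or `"dko"`.
#' @param fs_out output sampling rate, Hz.
#' @param hmax maximum solver step, s.
#' @param rtol,atol solver tolerances.
#' @param method a [deSolve::ode()] method; `"lsoda"` by default.
#' @return an object of class `vesikin_trajectory`: list with `time` (s),
#'   `sites` (time x 24 occupancy matrix, labelled), `syt7` (time x 3
#'   fractions), `fused` (cumulative count), `docked`, `tethered`, `empty`
#'   (totals), plus `params` (post-genotype), `genotype`, `transient`,
#'   `states`.
#' @examples
#' \donttest{
#' p <- default_parameters()
#' tr <- build_transient(p, n_aps = 2, freq = 20)
#' traj <- simulate_release(p, tr)
#' max(traj$fused)
#' }
#' @export
simulate_release <- function(params, transient = NULL,
                             genotype = c("wt", "doc2_ko", "syt7_ko", "dko"),
                             fs_out = 50e3, hmax = 1e-5,
                             rtol = 1e-5, atol = 1e-5, method = "lsoda") {
  genotype <- match.arg(genotype)
  params <- apply_genotype(params, genotype)
  if (is.null(transient)) transient <- build_transient(params)
  states <- enumerate_states()
  qc <- q_components(params, states)
  tA <- t(qc$A); tB <- t(qc$B); tC <- t(qc$C)
  f7pow <- params$syt7$f^(0:2)
  k7p <- params$syt7$k_plus; k7m <- params$syt7$k_minus; b7 <- params$syt7$b
  S0m <- matrix(c(0,    k7m,      0,
                  0,   -k7m,  2 * b7 * k7m,
                  0,    0,   -2 * b7 * k7m), 3, 3, byrow = TRUE)
  S1m <- matrix(c(-2 * k7p,   0,    0,
                   2 * k7p, -k7p,   0,
                   0,         k7p,  0), 3, 3, byrow = TRUE)
  fvec <- numeric(24)
  dk <- which(states$docked)
  fvec[dk] <- fusion_rate(states$d2[dk], states$s1[dk], params)
  ca_fun <- transient$ca
  idx_x <- 1:24; idx_s <- 25:27
  rhs <- function(t, y, parms) {
    ca <- ca_fun(t)
    x <- y[idx_x]; S <- y[idx_s]
    g <- sum(S * f7pow)
    dx <- (tA + ca * tB + g * tC) %*% x
    dS <- (S0m + ca * S1m) %*% S
    list(c(dx, dS, sum(fvec * x)))
  }
  ss <- steady_state(params, params$ca_rest)
  y0 <- c(unname(ss$sites), unname(ss$syt7), 0)
  times <- seq(0, transient$t_end, by = 1 / fs_out)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, hmax = hmax, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed at t = ", max(sol[, 1]), " s")
  sites <- sol[, 1 + idx_x, drop = FALSE]
  colnames(sites) <- states$labels
  syt7 <- sol[, 1 + idx_s, drop = FALSE]
  colnames(syt7) <- states$syt7_labels
  structure(list(
    time = sol[, 1],
    sites = sites,
    syt7 = syt7,
    fused = sol[, 29],
    docked = rowSums(sites[, states$docked, drop = FALSE]),
    tethered = rowSums(sites[, states$tethered, drop = FALSE]),
    empty = rowSums(sites[, states$empty, drop = FALSE]),
    params = params, genotype = genotype, transient = transient,
    states = states
  ), class = "vesikin_trajectory")
}

#' @export
print.vesikin_trajectory <- function(x, ...) {
  cat(sprintf("Release-site trajectory (%s): %d APs at %g Hz, 0-%g s\n",
              x$genotype, length(x$transient$ap_onsets), x$transient$freq,
              max(x$time)))
  cat(sprintf("  %d output samples; %g vesicles fused; docked %0.1f -> %0.1f\n",
              length(x$time), max(x$fused), x$docked[1],
              x$docked[length(x$time)]))
  invisible(x)
}

#' @export
summary.vesikin_trajectory <- function(object, ...) {
  m <- per_stimulus_metrics(object)
  cat(sprintf("Trajectory summary (%s):\n", object$genotype))
  cat(sprintf("  total fused: %.2f (asynchronous: %.2f)\n",
              max(object$fused), sum(m$table$async_count)))
  cat(sprintf("  peak rate AP1: %.0f /s; depression peak_n/peak_1: %.3f\n",
              m$table$peak_rate[1], m$depression_ratio))
  invisible(m)
}

#' @export
plot.vesikin_trajectory <- function(x, what = c("docked", "rate", "fused", "calcium"),
                                    ...) {
  what <- match.arg(what)
  t_ms <- x$time * 1e3
  switch(what,
    docked = graphics::plot(t_ms, x$docked, type = "l", xlab = "time (ms)",
                            ylab = "docked vesicles", ...),
    fused = graphics::plot(t_ms, x$fused, type = "l", xlab = "time (ms)",
                           ylab = "cumulative fused vesicles", ...),
    rate = {
      rs <- release_rate_series(x)
      graphics::plot(rs$time_s * 1e3, rs$rate, type = "l",
                     xlab = "time (ms)", ylab = "release rate (ves/s)", ...)
    },
    calcium = graphics::plot(t_ms, x$transient$ca(x$time), type = "l",
                             xlab = "time (ms)",
                             ylab = expression("[Ca"^"2+"*"] ("*mu*"M)"), ...)
  )
  invisible(x)
}

#' Export a trajectory as a data frame
#' @param x a `vesikin_trajectory`.
#' @param row.names,optional,... passed on conventionally (unused).
#' @return data.frame with `time_s`, one column per state label, `S0..S2`,
#'   and `F_cumulative`.
#' @export
as.data.frame.vesikin_trajectory <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  df <- data.frame(time_s = x$time, x$sites, x$syt7, F_cumulative = x$fused,
                   check.names = FALSE)
  names(df) <- c("time_s", colnames(x$sites), "S0", "S1", "S2",
                 "F_cumulative")
  df
}
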