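#' Stochastic single-site simulation by thinning
#'
#' Simulates independent single release sites as a time-inhomogeneous
#' continuous-time Markov chain over the 24 site states, driven by the same
#' analytic calcium transient and the same (deterministic) syt7 catalytic
#' factor g(t) as the ODE model, and counts fusion events. Because sites
#' are independent and the driving signals are deterministic, the mean
#' cumulative fusion count over replicates times `n_sites` converges to the
#' ODE solution — this routine is the independent stochastic oracle for
#' [simulate_release()].
#'
#' Event times are drawn by thinning against a piecewise-constant majorant:
#' time is cut into cells of `cell_width` seconds, the calcium and g
#' maxima per cell bound the current state's total exit rate, and candidate
#' events are accepted with probability (actual rate)/(bound).
#'
#' @param params a `vesikin_params` object.
#' @param transient a `vesikin_transient`; built from `params`' protocol if
#'   omitted.
#' @param n_reps number of independent single-site replicates.
#' @param seed integer seed for the R random number generator.
#' @param genotype genotype preset.
#' @param cell_width majorant cell width, s.
#' @return list with `fused` (integer fusion count per replicate),
#'   `mean_total` (mean count scaled to `n_sites`), `se_total` (its
#'   standard error), `n_reps`, `t_end`.
#' @export
simulate_site_stochastic <- function(params, transient = NULL, n_reps = 1000,
                                     seed = 1,
                                     genotype = c("wt", "doc2_ko", "syt7_ko", "dko"),
                                     cell_width = 5e-4) {
  genotype <- match.arg(genotype)
  params <- apply_genotype(params, genotype)
  if (is.null(transient)) transient <- build_transient(params)
  set.seed(seed)
  states <- enumerate_states()
  tt <- transition_table(params, states)
  t_end <- transient$t_end

  # deterministic syt7 catalytic factor on a fine grid
  f7pow <- params$syt7$f^(0:2)
  k7p <- params$syt7$k_plus; k7m <- params$syt7$k_minus; b7 <- params$syt7$b
  s7_rhs <- function(t, S, parms) {
    ca <- transient$ca(t)
    list(c(k7m * S[2] - 2 * k7p * ca * S[1],
           2 * k7p * ca * S[1] + 2 * b7 * k7m * S[3] - (k7p * ca + k7m) * S[2],
           k7p * ca * S[2] - 2 * b7 * k7m * S[3]))
  }
  dt_g <- 2e-5
  tg <- seq(0, t_end + dt_g, by = dt_g)
  sol <- deSolve::ode(y = unname(syt7_steady_state(params, params$ca_rest)),
                      times = tg, func = s7_rhs, parms = NULL,
                      method = "lsoda", hmax = 1e-5, rtol = 1e-8, atol = 1e-10)
  g_grid <- as.vector(sol[, 2:4] %*% f7pow)
  g_at <- function(t) {       # manual linear interpolation, scalar t
    i <- floor(t / dt_g) + 1
    w <- t / dt_g - (i - 1)
    g_grid[i] * (1 - w) + g_grid[i + 1] * w
  }

  # per-cell bounds on ca and g (fine sampling plus a small safety factor)
  n_cells <- ceiling(t_end / cell_width)
  ca_max <- g_max <- numeric(n_cells)
  for (c_ in seq_len(n_cells)) {
    tt_fine <- seq((c_ - 1) * cell_width, min(c_ * cell_width, t_end),
                   by = 1e-6)
    ca_max[c_] <- max(transient$ca(tt_fine)) * 1.001
    gi <- which(tg >= (c_ - 1) * cell_width - dt_g &
                tg <= c_ * cell_width + dt_g)
    g_max[c_] <- max(g_grid[gi]) * 1.001
  }

  # exit-rate coefficients per state, and the transition lists by state
  n_st <- length(states$labels)
  by_state <- lapply(seq_len(n_st), function(i) which(tt$from == i))
  a_i <- vapply(by_state, function(ix) sum(tt$base[ix]), 0)
  b_i <- vapply(by_state, function(ix) sum(tt$ca_coef[ix]), 0)
  c_i <- vapply(by_state, function(ix) sum(tt$g_coef[ix]), 0)
  is_fusion <- tt$base > 0 & states$docked[tt$from] & states$empty[tt$to]

  p0 <- steady_state(params, params$ca_rest)$sites / params$n_sites
  init_states <- sample.int(n_st, n_reps, replace = TRUE, prob = p0)
  fused <- integer(n_reps)
  ca_fun <- transient$ca
  for (r in seq_len(n_reps)) {
    i <- init_states[r]; t <- 0; nf <- 0L
    cell <- 1L
    cell_end <- cell_width
    repeat {
      lam <- a_i[i] + ca_max[cell] * b_i[i] + g_max[cell] * c_i[i]
      t_cand <- t + stats::rexp(1, lam)
      if (t_cand >= cell_end) {
        t <- cell_end
        if (t >= t_end) break
        cell <- cell + 1L
        cell_end <- min(cell * cell_width, t_end)
        next
      }
      t <- t_cand
      ix <- by_state[[i]]
      ca <- ca_fun(t)
      rates <- tt$base[ix] + ca * tt$ca_coef[ix] + g_at(t) * tt$g_coef[ix]
      tot <- sum(rates)
      if (tot > lam * (1 + 1e-9))
        stop("thinning bound violated; decrease cell_width")
      if (stats::runif(1) * lam < tot) {
        m <- ix[which(stats::runif(1) * tot <= cumsum(rates))[1]]
        if (is_fusion[m]) nf <- nf + 1L
        i <- tt$to[m]
      }
    }
    fused[r] <- nf
  }
  list(fused = fused,
       mean_total = mean(fused) * params$n_sites,
       se_total = stats::sd(fused) / sqrt(n_reps) * params$n_sites,
       n_reps = n_reps, t_end = t_end)
}
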