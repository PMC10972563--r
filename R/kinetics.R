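#' Fusion rate of a docked vesicle
#'
#' Fusion is accelerated multiplicatively by every calcium ion bound to the
#' two fusion sensors: `l_plus * f1^s1 * f2^d2`, with `l_plus` the basal
#' (sensor-independent) fusion rate.
#'
#' @param d2 ions bound to Doc2alpha (0..2), vectorised.
#' @param s1 ions bound to syt1 (0..5), vectorised.
#' @param params a `vesikin_params` object.
#' @return fusion rate(s) in s^-1.
#' @examples
#' fusion_rate(0, 0, default_parameters())   # basal rate 3.5e-4 s^-1
#' @export
fusion_rate <- function(d2, s1, params) {
  if (any(d2 < 0 | d2 > params$doc2$n) || any(d2 != round(d2)))
    stop("d2 out of range 0..", params$doc2$n)
  if (any(s1 < 0 | s1 > params$syt1$n) || any(s1 != round(s1)))
    stop("s1 out of range 0..", params$syt1$n)
  params$l_plus * params$syt1$f^s1 * params$doc2$f^d2
}

# catalytic speed-up of docking/undocking given syt7 occupancy fractions
syt7_factor <- function(syt7_occupancy, params) {
  sum(syt7_occupancy * params$syt7$f^(seq_along(syt7_occupancy) - 1))
}

#' Docking and undocking rates under the current syt7 occupancy
#'
#' Calcium-bound syt7 catalyses the docking reaction: both the docking and
#' the undocking rate are multiplied by `sum(S[s7] * f7^s7)` over the
#' syt7 occupancy distribution, so syt7 accelerates equilibration without
#' shifting the docked/tethered equilibrium.
#'
#' @param syt7_occupancy fractions of sites with 0, 1, 2 ions on syt7;
#'   non-negative, summing to one.
#' @param params a `vesikin_params` object.
#' @return named numeric vector `c(docking =, undocking =)`, s^-1.
#' @examples
#' docking_rates(c(1, 0, 0), default_parameters())   # basal (5, 5)
#' @export
docking_rates <- function(syt7_occupancy, params) {
  if (length(syt7_occupancy) != 3 || any(syt7_occupancy < 0))
    stop("syt7_occupancy must be 3 non-negative fractions")
  if (abs(sum(syt7_occupancy) - 1) > 1e-6)
    stop("syt7_occupancy must sum to 1")
  g <- syt7_factor(syt7_occupancy, params)
  c(docking = params$k_docking * g, undocking = params$k_undocking * g)
}

#' Calcium binding and unbinding rates for one sensor
#'
#' On-rates are (available binding sites) x k_plus x calcium. Availability
#' reflects both the sensor's own capacity and, on docked vesicles, the
#' shared budget of five ions across syt1 and Doc2alpha: syt1 on a docked
#' vesicle can bind into `min(n1 - s1, 5 - (d2 + s1))` slots, Doc2alpha on a
#' docked vesicle into `min(n2 - d2, 5 - (d2 + s1))`; Doc2alpha on empty or
#' tethered sites, and syt7 always, use only their own free capacity. Off-
#' rates from m bound ions are `m * k_minus * b^(m-1)` (cooperative
#' destabilisation of later ions).
#'
#' @param sensor `"syt1"`, `"doc2"` or `"syt7"`.
#' @param occupied ions currently bound to this sensor.
#' @param ca free calcium, uM.
#' @param params a `vesikin_params` object.
#' @param context for sensors on a docked vesicle, the pair `c(d2, s1)`
#'   used for the shared-budget clamp; `NULL` (default) for syt7, or for
#'   Doc2alpha on empty/tethered sites.
#' @return named vector `c(on =, off =)`, s^-1.
#' @export
ca_binding_rates <- function(sensor = c("syt1", "doc2", "syt7"), occupied,
                             ca, params, context = NULL) {
  sensor <- match.arg(sensor)
  blk <- params[[sensor]]
  if (occupied < 0 || occupied > blk$n || occupied != round(occupied))
    stop("occupied out of range 0..", blk$n)
  if (ca < 0) stop("ca must be >= 0")
  if (sensor == "syt1" && is.null(context))
    stop("syt1 binds calcium only on docked vesicles; supply context = c(d2, s1)")
  slots <- blk$n - occupied
  if (!is.null(context)) {
    budget <- params$syt1$n   # shared cap across syt1 + Doc2alpha
    slots <- min(slots, max(0, budget - sum(context)))
  }
  on <- max(0, slots) * blk$k_plus * ca
  off <- if (occupied == 0) 0 else occupied * blk$k_minus * blk$b^(occupied - 1)
  c(on = on, off = off)
}

# All site-state transitions as a flat table. Each rate decomposes as
# base + ca * ca_coef + g * g_coef, where g is the syt7 catalytic factor;
# exactly one of the three coefficients is nonzero per transition.
transition_table <- function(params, states = enumerate_states()) {
  n1 <- params$syt1$n; n2 <- params$doc2$n
  budget <- n1
  k1p <- params$syt1$k_plus; k1m <- params$syt1$k_minus; b1 <- params$syt1$b
  k2p <- params$doc2$k_plus; k2m <- params$doc2$k_minus; b2 <- params$doc2$b
  from <- to <- integer(0); base <- cac <- gc <- numeric(0)
  add <- function(i, j, b = 0, ca = 0, g = 0) {
    from <<- c(from, i); to <<- c(to, j)
    base <<- c(base, b); cac <<- c(cac, ca); gc <<- c(gc, g)
  }
  idx <- states$index
  for (d2 in 0:2) {
    E <- idx[sprintf("E[%d]", d2)]; T_ <- idx[sprintf("T[%d]", d2)]
    add(E, T_, b = params$k_tet)
    add(T_, E, b = params$k_untet)
    add(T_, idx[sprintf("D[%d,0]", d2)], g = params$k_docking)
    # Doc2alpha on empty/tethered sites: own capacity only
    if (d2 < n2) {
      on <- (n2 - d2) * k2p
      add(E, idx[sprintf("E[%d]", d2 + 1)], ca = on)
      add(T_, idx[sprintf("T[%d]", d2 + 1)], ca = on)
    }
    if (d2 > 0) {
      off <- d2 * k2m * b2^(d2 - 1)
      add(E, idx[sprintf("E[%d]", d2 - 1)], b = off)
      add(T_, idx[sprintf("T[%d]", d2 - 1)], b = off)
    }
    for (s1 in 0:5) {
      D <- idx[sprintf("D[%d,%d]", d2, s1)]
      add(D, T_, g = params$k_undocking)
      add(D, E, b = fusion_rate(d2, s1, params))
      free <- max(0, budget - (d2 + s1))
      if (s1 < n1 && min(n1 - s1, free) > 0)
        add(D, idx[sprintf("D[%d,%d]", d2, s1 + 1)],
            ca = min(n1 - s1, free) * k1p)
      if (s1 > 0)
        add(D, idx[sprintf("D[%d,%d]", d2, s1 - 1)],
            b = s1 * k1m * b1^(s1 - 1))
      if (d2 < n2 && min(n2 - d2, free) > 0)
        add(D, idx[sprintf("D[%d,%d]", d2 + 1, s1)],
            ca = min(n2 - d2, free) * k2p)
      if (d2 > 0)
        add(D, idx[sprintf("D[%d,%d]", d2 - 1, s1)],
            b = d2 * k2m * b2^(d2 - 1))
    }
  }
  # budget-violating docked states receive no flux at all (not even from
  # each other); they can only drain, so they are transient and stay empty
  keep <- !states$forbidden[to]
  list(from = from[keep], to = to[keep], base = base[keep],
       ca_coef = cac[keep], g_coef = gc[keep], states = states)
}

# Dense 24x24 components: Q(ca, g) = A + ca*B + g*C (off-diagonals), with
# diagonals completing each to zero row sums so the sum is an intensity matrix.
q_components <- function(params, states = enumerate_states()) {
  tt <- transition_table(params, states)
  n <- length(states$labels)
  mk <- function(w) {
    M <- matrix(0, n, n)
    M[cbind(tt$from, tt$to)] <- M[cbind(tt$from, tt$to)] + w
    diag(M) <- -rowSums(M)
    M
  }
  list(A = mk(tt$base), B = mk(tt$ca_coef), C = mk(tt$g_coef),
       table = tt, states = states)
}

#' Intensity matrix of the release-site chain
#'
#' Assembles the 24 x 24 generator Q at a given instant: element (i, j),
#' i != j, is the transition rate from state i to state j in s^-1
#' (tethering, untethering, docking into `D[d2,0]`, undocking, fusion back
#' to `E[d2]` preserving the site's Doc2alpha state, and all calcium
#' binding/unbinding steps under the shared five-ion budget); diagonals make
#' every row sum to zero.
#'
#' @param ca free calcium, uM (>= 0).
#' @param syt7_occupancy fractions of sites with 0..2 ions on syt7.
#' @param params a `vesikin_params` object.
#' @return 24 x 24 matrix with state labels as dimnames.
#' @export
build_intensity_matrix <- function(ca, syt7_occupancy, params) {
  if (ca < 0) stop("ca must be >= 0")
  g <- syt7_factor(syt7_occupancy, params)
  qc <- q_components(params)
  Q <- qc$A + ca * qc$B + g * qc$C
  dimnames(Q) <- list(qc$states$labels, qc$states$labels)
  Q
}

#' syt7 occupancy at steady state
#'
#' Closed form by detailed balance on the sequential two-site scheme:
#' `S[1]/S[0] = 2 ca k7+ / k7-` and `S[2]/S[1] = ca k7+ / (2 b7 k7-)`,
#' normalised to sum to one.
#'
#' @param params a `vesikin_params` object.
#' @param ca free calcium, uM.
#' @return named fractions `S[0]`, `S[1]`, `S[2]`.
#' @export
syt7_steady_state <- function(params, ca) {
  k7p <- params$syt7$k_plus; k7m <- params$syt7$k_minus; b7 <- params$syt7$b
  s <- c(1,
         2 * ca * k7p / k7m,
         2 * ca * k7p / k7m * ca * k7p / (2 * b7 * k7m))
  stats::setNames(s / sum(s), sprintf("S[%d]", 0:2))
}

#' Steady state of the release-site system at fixed calcium
#'
#' The syt7 occupancy is solved in closed form ([syt7_steady_state()]); the
#' 24-state site distribution is then the stationary distribution of the
#' intensity matrix at that calcium and syt7 occupancy. The primary route
#' solves the null space of t(Q) (singular value decomposition); the
#' `"expm"` route instead propagates the all-sites-empty vector through
#' `expm(Q * t_long)` (default 1000 s), which must agree — the two serve as
#' mutual cross-checks.
#'
#' @param params a `vesikin_params` object.
#' @param ca free calcium, uM (default: resting).
#' @param method `"null"` (default) or `"expm"`.
#' @param t_long horizon for the matrix-exponential route, s.
#' @return list with `sites` (named occupancies over the 24 states, summing
#'   to `n_sites`), `syt7` (named fractions), `ca`, and `Q`.
#' @export
steady_state <- function(params, ca = params$ca_rest,
                         method = c("null", "expm"), t_long = 1000) {
  method <- match.arg(method)
  s7 <- syt7_steady_state(params, ca)
  Q <- build_intensity_matrix(ca, s7, params)
  n <- nrow(Q)
  if (method == "null") {
    sv <- svd(t(Q))
    small <- sum(sv$d < max(sv$d) * 1e-9)
    if (small != 1)
      stop("intensity matrix has a ", small, "-dimensional null space; ",
           "expected exactly 1")
    v <- sv$v[, n]
    v <- v / sum(v)
    if (any(v < -1e-9)) stop("stationary distribution has negative entries")
    pi_ss <- pmax(v, 0)
    pi_ss <- pi_ss / sum(pi_ss)
  } else {
    p0 <- c(1, rep(0, n - 1))   # all sites empty and calcium-free
    pi_ss <- as.numeric(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * t_long))))
    pi_ss <- pi_ss / sum(pi_ss)
  }
  list(sites = stats::setNames(pi_ss * params$n_sites, rownames(Q)),
       syt7 = s7, ca = ca, Q = Q)
}
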