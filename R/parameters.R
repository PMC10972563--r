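#' Default model parameters
#'
#' Returns the full parameter set of the release-site model: site cycling
#' rates, the fusion-rate function constants, the calcium-transient shape,
#' and one block per calcium sensor (syt1, Doc2alpha, syt7). All rates are
#' per second, concentrations in micromolar, binding rates in uM^-1 s^-1.
#' Timing constants of the transient (`gauss_mean`, `gauss_sd`, `t0_offset`,
#' `km_smooth`) are in milliseconds and converted to seconds internally when
#' the transient is built; everything else is already in seconds.
#'
#' Unbinding rate constants for Doc2alpha and syt7 are derived from the
#' dissociation constant (`k_minus = k_plus * K_D`), which with the default
#' `K_D` of 1.5 uM and `k_plus` of 28 uM^-1 s^-1 gives 42 s^-1.
#'
#' @param ... named overrides, e.g. `n_sites = 100`, or whole sensor blocks
#'   such as `doc2 = list(k_plus = 0)` (partial blocks are merged over the
#'   defaults).
#' @return an object of class `vesikin_params`: a named list with fields
#'   `n_sites`, `k_tet`, `k_untet`, `k_docking`, `k_undocking`, `l_plus`,
#'   `amplitude_ap`, `amplitude_residual`, `tau_residual`, `km_smooth`,
#'   `ca_rest`, `t0_offset`, `gauss_mean`, `gauss_sd`, sensor blocks `syt1`,
#'   `doc2`, `syt7` (each with `n`, `k_plus`, `k_minus`, optional `K_D`,
#'   `b`, `f`) and a `protocol` list (`n_aps`, `freq`).
#' @examples
#' p <- default_parameters()
#' p$l_plus                 # basal fusion rate, s^-1
#' p$syt7$k_minus           # 28 * 1.5 = 42 s^-1, derived from K_D
#' @export
default_parameters <- function(...) {
  p <- list(
    n_sites            = 200,    # release sites
    k_tet              = 7,      # s^-1
    k_untet            = 7,      # s^-1, same as k_tet
    k_docking          = 5,      # s^-1
    k_undocking        = 5,      # s^-1, same as k_docking
    l_plus             = 3.5e-4, # basal fusion rate, s^-1
    amplitude_ap       = 30,     # peak of synchronous transient, uM
    amplitude_residual = 0.75,   # residual amplitude, uM
    tau_residual       = 0.2,    # residual decay constant, s
    km_smooth          = 0.1,    # residual onset smoothing, ms
    ca_rest            = 0.05,   # resting calcium, uM
    t0_offset          = 1.6,    # residual onset after AP onset, ms
    gauss_mean         = 1.5,    # synchronous peak time after AP onset, ms
    gauss_sd           = 0.2,    # synchronous peak width, ms
    syt1 = list(n = 5, k_plus = 140, k_minus = 4000, K_D = NULL,
                b = 0.5, f = 27.98),
    doc2 = list(n = 2, k_plus = 28, k_minus = NULL, K_D = 1.5,
                b = 0.5, f = 16),
    syt7 = list(n = 2, k_plus = 28, k_minus = NULL, K_D = 1.5,
                b = 0.5, f = 10),
    protocol = list(n_aps = 10, freq = 20)
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    for (nm in names(dots)) {
      if (nm %in% c("syt1", "doc2", "syt7", "protocol")) {
        # modifyList semantics: an explicit NULL removes the entry (used to
        # clear a stale K_D when a bare k_minus is supplied)
        p[[nm]] <- utils::modifyList(p[[nm]], dots[[nm]])
      } else {
        p[[nm]] <- dots[[nm]]
      }
    }
  }
  p <- resolve_kd(p)
  validate_parameters(p)
  structure(p, class = "vesikin_params")
}

# k_minus derived from K_D where a K_D is given; on conflict the K_D-derived
# value wins with a warning.
resolve_kd <- function(p) {
  for (s in c("syt1", "doc2", "syt7")) {
    blk <- p[[s]]
    if (!is.null(blk$K_D)) {
      derived <- blk$k_plus * blk$K_D
      if (!is.null(blk$k_minus) &&
          abs(blk$k_minus - derived) > 1e-9 * max(1, derived))
        warning(sprintf(
          "%s: k_minus (%g) inconsistent with k_plus * K_D (%g); using %g",
          s, blk$k_minus, derived, derived))
      p[[s]]$k_minus <- derived
    }
    if (is.null(p[[s]]$k_minus))
      stop(s, ": need k_minus or K_D")
  }
  p
}

validate_parameters <- function(p) {
  pos <- c("n_sites", "k_tet", "k_untet", "k_docking", "k_undocking",
           "l_plus", "amplitude_ap", "amplitude_residual", "tau_residual",
           "km_smooth", "ca_rest", "gauss_sd")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive number")
  }
  for (s in c("syt1", "doc2", "syt7")) {
    blk <- p[[s]]
    if (blk$n < 1 || blk$n != round(blk$n))
      stop(s, ": ion capacity n must be a positive integer")
    if (blk$k_plus < 0) stop(s, ": k_plus must be >= 0")
    if (blk$k_minus <= 0) stop(s, ": k_minus must be > 0")
    if (blk$b <= 0 || blk$b > 1) stop(s, ": need 0 < b <= 1")
    if (blk$f <= 0) stop(s, ": f must be > 0")
  }
  pr <- p$protocol
  if (pr$n_aps < 1 || pr$n_aps != round(pr$n_aps))
    stop("protocol: n_aps must be a positive integer")
  if (pr$freq <= 0) stop("protocol: freq must be > 0")
  invisible(p)
}

#' Apply a genotype preset to a parameter set
#'
#' Knockouts are modelled by neutralising the corresponding sensor:
#' Doc2alpha knockout sets its calcium-binding rate to zero (`k2+ = 0`);
#' syt7 knockout sets its per-ion docking multiplier to one (`f7 = 1`), so
#' docking rates stay at their basal value whatever syt7's occupancy; the
#' double knockout applies both.
#'
#' @param params a `vesikin_params` object.
#' @param genotype one of `"wt"`, `"doc2_ko"`, `"syt7_ko"`, `"dko"`.
#' @return the modified `vesikin_params` object.
#' @export
apply_genotype <- function(params, genotype = c("wt", "doc2_ko", "syt7_ko", "dko")) {
  genotype <- match.arg(genotype)
  if (genotype %in% c("doc2_ko", "dko")) {
    params$doc2$k_plus <- 0
    params$doc2$K_D <- NULL       # k_minus kept; K_D no longer meaningful
  }
  if (genotype %in% c("syt7_ko", "dko"))
    params$syt7$f <- 1
  params
}

#' @export
print.vesikin_params <- function(x, ...) {
  cat("Release-site model parameters\n")
  cat(sprintf("  sites: %d;  tether %g/%g s^-1;  dock %g/%g s^-1;  l+ %g s^-1\n",
              x$n_sites, x$k_tet, x$k_untet, x$k_docking, x$k_undocking,
              x$l_plus))
  cat(sprintf("  Ca transient: AP peak %g uM; residual %g uM (tau %g s, km %g ms); rest %g uM\n",
              x$amplitude_ap, x$amplitude_residual, x$tau_residual,
              x$km_smooth, x$ca_rest))
  for (s in c("syt1", "doc2", "syt7")) {
    blk <- x[[s]]
    cat(sprintf("  %s: n=%d  k+=%g uM^-1 s^-1  k-=%g s^-1  b=%g  f=%g\n",
                s, blk$n, blk$k_plus, blk$k_minus, blk$b, blk$f))
  }
  cat(sprintf("  protocol: %d APs at %g Hz\n", x$protocol$n_aps, x$protocol$freq))
  invisible(x)
}

#' Read or write a flat parameter configuration
#'
#' The on-disk format is a flat YAML (or JSON) mapping with scalar keys
#' `n_sites, k_tet, ..., f_1`; sensor-block fields use suffixed names
#' (`n_1, k_1_plus, k_1_minus, b_1, f_1`, `n_2, k_2_plus, K_D2, ...`,
#' `n_7, ...`) plus `n_aps` and `freq`. Unknown keys are rejected; missing
#' keys fall back to the defaults.
#'
#' @param path file to read.
#' @return `read_parameters`: a `vesikin_params` object.
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  flat_to_parameters(raw)
}

#' @rdname read_parameters
#' @param params a `vesikin_params` object to serialise.
#' @param path destination file (YAML).
#' @return `write_parameters`: `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(parameters_to_flat(params), path)
  invisible(path)
}

sensor_key <- c(syt1 = "1", doc2 = "2", syt7 = "7")

parameters_to_flat <- function(p) {
  flat <- p[c("n_sites", "k_tet", "k_untet", "k_docking", "k_undocking",
              "l_plus", "amplitude_ap", "amplitude_residual", "tau_residual",
              "km_smooth", "ca_rest", "t0_offset", "gauss_mean", "gauss_sd")]
  for (s in names(sensor_key)) {
    k <- sensor_key[[s]]
    blk <- p[[s]]
    flat[[paste0("n_", k)]] <- blk$n
    flat[[paste0("k_", k, "_plus")]] <- blk$k_plus
    flat[[paste0("k_", k, "_minus")]] <- blk$k_minus
    if (!is.null(blk$K_D)) flat[[paste0("K_D", k)]] <- blk$K_D
    flat[[paste0("b_", k)]] <- blk$b
    flat[[paste0("f_", k)]] <- blk$f
  }
  flat$n_aps <- p$protocol$n_aps
  flat$freq <- p$protocol$freq
  flat
}

flat_to_parameters <- function(flat) {
  over <- list()
  scalar <- c("n_sites", "k_tet", "k_untet", "k_docking", "k_undocking",
              "l_plus", "amplitude_ap", "amplitude_residual", "tau_residual",
              "km_smooth", "ca_rest", "t0_offset", "gauss_mean", "gauss_sd")
  known <- scalar
  for (s in names(sensor_key)) {
    k <- sensor_key[[s]]
    blk <- list()
    map <- c(n = paste0("n_", k), k_plus = paste0("k_", k, "_plus"),
             k_minus = paste0("k_", k, "_minus"), K_D = paste0("K_D", k),
             b = paste0("b_", k), f = paste0("f_", k))
    known <- c(known, unname(map))
    for (fld in names(map))
      if (!is.null(flat[[map[[fld]]]])) blk[[fld]] <- flat[[map[[fld]]]]
    # a k_minus given without a K_D stands on its own
    if (!is.null(blk$k_minus) && is.null(blk$K_D)) blk["K_D"] <- list(NULL)
    if (length(blk)) over[[s]] <- blk
  }
  known <- c(known, "n_aps", "freq")
  unknown <- setdiff(names(flat), known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  for (nm in scalar) if (!is.null(flat[[nm]])) over[[nm]] <- flat[[nm]]
  proto <- list()
  if (!is.null(flat$n_aps)) proto$n_aps <- flat$n_aps
  if (!is.null(flat$freq)) proto$freq <- flat$freq
  if (length(proto)) over$protocol <- proto
  do.call(default_parameters, over)
}

#' Set a parameter by flat key
#'
#' Multiplies or replaces one parameter addressed by its flat configuration
#' key (see [read_parameters()]), re-deriving `k_minus` from `K_D` where
#' applicable. Used by the one-at-a-time sweep.
#'
#' @param params a `vesikin_params` object.
#' @param name flat key, e.g. `"f_2"`, `"k_docking"`, `"amplitude_ap"`.
#' @param value new value.
#' @return the modified `vesikin_params`.
#' @export
set_parameter <- function(params, name, value) {
  flat <- parameters_to_flat(params)
  if (!name %in% names(flat)) stop("unknown parameter key: ", name)
  flat[[name]] <- value
  # keep k_minus and K_D consistent: the freshly set one wins, its stale
  # counterpart is dropped
  if (grepl("^k_[127]_minus$", name))
    flat[[sub("^k_([127])_minus$", "K_D\\1", name)]] <- NULL
  if (grepl("^K_D[127]$", name))
    flat[[sub("^K_D([127])$", "k_\\1_minus", name)]] <- NULL
  flat_to_parameters(flat)
}

#' Look up a parameter by flat key
#' @inheritParams set_parameter
#' @return the current value.
#' @export
get_parameter <- function(params, name) {
  flat <- parameters_to_flat(params)
  if (!name %in% names(flat)) stop("unknown parameter key: ", name)
  flat[[name]]
}
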