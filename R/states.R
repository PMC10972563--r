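#' Enumerate the release-site and syt7 state spaces
#'
#' A release site is empty (`E`), holds a tethered vesicle (`T`), or holds a
#' docked vesicle (`D`). Doc2alpha sits on the release site and can carry
#' d2 = 0..2 calcium ions in any site state; syt1 sits on the vesicle and can
#' carry s1 = 0..5 ions, but only while the vesicle is docked. The joint
#' budget d2 + s1 is capped at five ions, so three of the 18 nominal docked
#' states (`D[1,5]`, `D[2,4]`, `D[2,5]`) are unreachable; they are kept in
#' the enumeration — the kinetics give them no inbound binding rate — so the
#' state vector always has 24 elements. syt7 occupancy is tracked separately
#' as the fraction of sites with s7 = 0..2 ions bound.
#'
#' The ordering is fixed: `E[0..2]`, `T[0..2]`, then `D[d2,s1]` row-major
#' with d2 outer and s1 inner. Indices are 1-based.
#'
#' @return an object of class `vesikin_states`: list with `labels` (24
#'   release-site state labels in order), `d2`, `s1` (per-state ion counts;
#'   `s1` is `NA` off the docked block), `kind` (factor E/T/D), `docked`,
#'   `tethered`, `empty` (logical masks), `forbidden` (docked with
#'   d2 + s1 > 5), and `syt7_labels` (`S[0..2]`).
#' @examples
#' ss <- enumerate_states()
#' ss$labels[1]            # "E[0]"
#' sum(ss$docked)          # 18 docked states, 15 reachable
#' @export
enumerate_states <- function() {
  d2_et <- 0:2
  lab_E <- sprintf("E[%d]", d2_et)
  lab_T <- sprintf("T[%d]", d2_et)
  grid <- expand.grid(s1 = 0:5, d2 = 0:2)   # s1 inner, d2 outer
  lab_D <- sprintf("D[%d,%d]", grid$d2, grid$s1)
  labels <- c(lab_E, lab_T, lab_D)
  d2 <- c(d2_et, d2_et, grid$d2)
  s1 <- c(rep(NA_integer_, 6), grid$s1)
  kind <- factor(c(rep("E", 3), rep("T", 3), rep("D", 18)),
                 levels = c("E", "T", "D"))
  structure(list(
    labels = labels,
    index = stats::setNames(seq_along(labels), labels),
    d2 = d2, s1 = s1, kind = kind,
    empty = kind == "E", tethered = kind == "T", docked = kind == "D",
    forbidden = kind == "D" & (d2 + ifelse(is.na(s1), 0L, s1)) > 5,
    syt7_labels = sprintf("S[%d]", 0:2)
  ), class = "vesikin_states")
}

#' @export
print.vesikin_states <- function(x, ...) {
  cat(sprintf("Release-site state space: %d states (%d docked, %d of them unreachable under the 5-ion budget)\n",
              length(x$labels), sum(x$docked), sum(x$forbidden)))
  cat("  ", paste(x$labels, collapse = " "), "\n")
  cat("  syt7:", paste(x$syt7_labels, collapse = " "), "\n")
  invisible(x)
}

#' Position of a state label in the canonical ordering
#' @param label character vector of state labels, e.g. `"D[1,3]"`.
#' @param states a `vesikin_states` object (defaults to a fresh enumeration).
#' @return integer positions (1-based).
#' @export
state_index <- function(label, states = enumerate_states()) {
  idx <- states$index[label]
  if (anyNA(idx)) stop("unknown state label(s): ",
                       paste(label[is.na(idx)], collapse = ", "))
  unname(idx)
}
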