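# Canonical temporal archetypes of EMT expression waves.
#
# TGFbeta-induced EMT time courses show coordinated expression waves with
# transitions concentrated at a few windows; each wave carries both an
# up-regulated and a down-regulated gene program (e.g. immune programs up
# while cell-cycle programs go down at the same transition). The module
# generator therefore separates the wave *shape* (archetype, below) from
# the program *orientation* (+1 up, -1 down):
#
#   1 "wave_early":     transition in the 8-16 h window, sustained after.
#                       Orientation -1 is the classic "down-regulated after
#                       8 h" pattern; +1 the "up-regulated 8-16 h" pattern.
#   2 "wave_mid":       rising 24-72 h, elevated from 72 h, partial decay
#                       at the final stage ("increases slowly, decreases
#                       after 168 h").
#   3 "wave_late":      changes only at very late stages (72-168 h).
#   4 "wave_transient": induced in the 8-16 h window and decayed again by
#                       72 h (a pulse, as in early-induction groups that
#                       decay mid-course).
#
# Each archetype is a piecewise-linear function of log2(hours + 1), which
# makes it evaluable on any stage grid; beyond the last breakpoint the
# value extrapolates flat, so a grid that stops before a wave's transition
# (e.g. a 96 h endpoint vs wave_late) simply sees the plateau.

archetype_nodes <- list(
  wave_early     = cbind(hours = c(0, 8, 16),           value = c(-1, -1, 1)),
  wave_mid       = cbind(hours = c(0, 24, 72, 96, 168), value = c(-1, -1, 1, 1, 0)),
  wave_late      = cbind(hours = c(0, 96, 168),         value = c(-1, -1, 1)),
  wave_transient = cbind(hours = c(0, 8, 16, 24, 72),   value = c(-1, -1, 1, 1, -1))
)

#' Names of the canonical temporal archetypes
#' @return Character vector of length 4.
#' @export
archetype_names <- function() names(archetype_nodes)

#' Evaluate a temporal archetype on a stage grid
#'
#' @param id archetype, 1-4 or one of [archetype_names()].
#' @param hours numeric vector of stage times in hours.
#' @return Numeric vector in `[-1, 1]`, one value per stage.
#' @examples
#' archetype_profile("wave_early", c(0, 1, 2, 4, 6, 8, 16, 24, 72, 168))
#' @export
archetype_profile <- function(id, hours) {
  if (is.numeric(id)) id <- archetype_names()[id]
  nodes <- archetype_nodes[[id]]
  if (is.null(nodes)) abort_field("id", "unknown archetype")
  t <- log2(hours + 1)
  tn <- log2(nodes[, "hours"] + 1)
  # rule = 2: flat extrapolation on both sides
  stats::approx(tn, nodes[, "value"], xout = t, rule = 2)$y
}
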