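#' Steady state of the two-branch first-order pathway
#'
#' Two enzymes compete for a single shared substrate S1, supplied at constant
#' rate C and consumed by first-order kinetics v = k * e * s. At steady state
#' the substrate level balances supply against total consumption:
#' S1 = C / (k1*e1 + k2*e2), v1 = k1*e1*S1, v2 = k2*e2*S1, and mass balance
#' gives v1 + v2 = C exactly. Because S1 is a dynamic variable rather than an
#' imposed parameter, correlated changes in e1 and e2 can make v1 *decrease*
#' as e1 rises -- the motif that breaks the naive one-enzyme/one-rate
#' expectation.
#'
#' @param k1,k2 first-order rate constants (>= 0, not both zero with the
#'   paired enzyme levels).
#' @param C substrate supply rate (> 0).
#' @param e1,e2 enzyme concentrations (>= 0).
#' @return list with elements `S1`, `v1`, `v2`. Vectorized over its arguments.
#' @examples
#' toy_steady_state(k1 = 1, k2 = 1, C = 2, e1 = 1, e2 = 1)  # S1 = v1 = v2 = 1
#' @export
toy_steady_state <- function(k1, k2, C, e1, e2) {
  if (any(c(k1, k2, e1, e2) < 0)) stop("rate constants and enzyme levels must be >= 0")
  if (any(C <= 0)) stop("supply rate C must be > 0")
  denom <- k1 * e1 + k2 * e2
  if (any(denom <= 0)) stop("k1*e1 + k2*e2 must be > 0")
  S1 <- C / denom
  list(S1 = S1, v1 = k1 * e1 * S1, v2 = k2 * e2 * S1)
}

#' Sweep the focal enzyme level and record covariation with its rate
#'
#' Evaluates the branched-pathway steady state over a grid of focal enzyme
#' levels e1 with the competitor set by a coupling function e2 = f(e1), and
#' reports the Spearman correlation between e1 and v1. Proportional coupling
#' (e2 = a*e1) makes v1 constant, in which case the correlation is flagged as
#' zero-variance rather than fabricated.
#'
#' @param k1,k2,C kinetic parameters, as in [toy_steady_state()].
#' @param e1_grid at least 3 distinct positive focal enzyme levels.
#' @param coupling function mapping e1 to the competitor level e2.
#' @return list with `table` (data.frame e1, e2, S1, v1, v2), `spearman_rho`
#'   (NA when flagged), and `zero_variance_flag`.
#' @export
toy_covariation_sweep <- function(k1, k2, C, e1_grid,
                                  coupling = function(e1) rep(1, length(e1))) {
  e1 <- as.numeric(e1_grid)
  if (length(unique(e1)) < 3L) stop("e1_grid must contain at least 3 distinct values")
  e2 <- coupling(e1)
  ss <- toy_steady_state(k1, k2, C, e1, e2)
  tab <- data.frame(e1 = e1, e2 = e2, S1 = ss$S1, v1 = ss$v1, v2 = ss$v2)
  rho <- spearman_rho(e1, ss$v1)
  list(table = tab,
       spearman_rho = rho$rho,
       zero_variance_flag = rho$zero_variance_flag)
}
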