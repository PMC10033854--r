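#' Age-specific damage rate
#'
#' Probability that a healthy cell gets damaged during time step `t`.
#' Genomic instability increases linearly with age, `alpha * t`, capped at 1
#' once `t > 1/alpha`.
#'
#' @param alpha Non-negative slope of the per-step damage rate. Aggregates
#'   division rate, mutation rate and repair efficiency per unit of model
#'   time.
#' @param t Non-negative integer age (in model time steps); vectorized.
#' @return `min(1, alpha * t)`, in `[0, 1]`.
#' @export
#' @examples
#' damage_rate(0.006, 10)
#' damage_rate(0.006, 200) # capped at 1
damage_rate <- function(alpha, t) {
  stopifnot(is.numeric(alpha), is.numeric(t))
  if (any(alpha < 0) || any(t < 0)) {
    stop("`alpha` and `t` must be non-negative")
  }
  pmin(1, alpha * t)
}

#' Fraction of the tissue newly damaged in one step
#'
#' The healthy pool `1 - S - D` gets damaged at the age-specific rate
#' `alpha_t`, inflated by the senescence feedback `(1 + S^r_damage_to_cs)`
#' (senescent cells compromise tissue function and raise the damage rate of
#' dividing cells). The result is clamped to the healthy pool so that tissue
#' proportions stay in the simplex.
#'
#' @param S,D Proportions of senescent and damaged cells (`S + D <= 1`).
#' @param alpha_t Damage rate at the current age, in `[0, 1]`
#'   (see [damage_rate()]).
#' @param r_damage_to_cs Non-negative tissue-resilience exponent: small
#'   values mean even few senescent cells inflate the damage rate.
#' @return The newly damaged proportion `delta_t`, in `[0, 1 - S - D]`.
#' @export
#' @examples
#' new_damage_fraction(S = 0.5, D = 0.2, alpha_t = 0.1, r_damage_to_cs = 2)
new_damage_fraction <- function(S, D, alpha_t, r_damage_to_cs) {
  check_state(S, D)
  stopifnot(alpha_t >= 0, alpha_t <= 1, r_damage_to_cs >= 0)
  pool <- 1 - S - D
  if (pool <= 0) {
    return(0)
  }
  feedback <- if (S > 0) S^r_damage_to_cs else 0
  min(pool * alpha_t * (1 + feedback), pool)
}

#' Advance the tissue one time step
#'
#' One application of the cell-dynamics recurrences. All damaged cells
#' (carried over plus newly damaged) are checked first for apoptosis
#' (probability `gamma`), then for senescence entry (probability `sigma`).
#' Apoptotic cells are replaced by compensatory division of the remaining
#' mitotic pool, so a share `D / (1 - S)` of the replacements is damaged
#' again:
#' \deqn{D_{t+1} = (D_t + \delta_t)(1-\gamma)(1-\sigma) +
#'       \gamma (D_t + \delta_t) D_t / (1 - S_t)}
#' \deqn{S_{t+1} = S_t + (D_t + \delta_t)(1-\gamma)\sigma}
#' When `S = 1` the tissue is frozen (no mitotic pool): the replacement term
#' is 0 rather than a division by zero.
#'
#' @param S,D Current proportions of senescent and damaged cells.
#' @param t Current age (time step), used for the damage rate.
#' @param alpha,gamma,sigma,r_damage_to_cs Cell parameters: damage-rate
#'   slope, apoptosis probability, senescence-entry probability,
#'   tissue-resilience exponent.
#' @return A list with the updated `S`, `D` and the `delta` used.
#' @export
#' @examples
#' tissue_step(S = 0.2, D = 0.1, t = 5, alpha = 0.006, gamma = 0.5,
#'             sigma = 0.4, r_damage_to_cs = 2)
tissue_step <- function(S, D, t, alpha, gamma, sigma, r_damage_to_cs) {
  check_state(S, D)
  stopifnot(gamma >= 0, gamma <= 1, sigma >= 0, sigma <= 1)
  delta <- new_damage_fraction(S, D, damage_rate(alpha, t), r_damage_to_cs)
  d_tot <- D + delta
  repl <- if (1 - S > 0) gamma * d_tot * D / (1 - S) else 0
  list(
    S = S + d_tot * (1 - gamma) * sigma,
    D = d_tot * (1 - gamma) * (1 - sigma) + repl,
    delta = delta
  )
}

#' Simulate a tissue trajectory
#'
#' Iterates the cell-dynamics recurrences from `S = D = 0` at age 0 (growth
#' cessation / first reproduction) until the healthy pool is exhausted
#' (`1 - S - D < stop_eps`) or the horizon is reached.
#'
#' @inheritParams tissue_step
#' @param horizon Maximum number of time steps (default 50000).
#' @param stop_eps Healthy-pool threshold below which iteration stops
#'   (default 1e-9).
#' @param init Optional starting state, a list/vector with `t`, `S`, `D`;
#'   used e.g. to resume a trajectory after senolysis.
#' @return A data.frame with one row per age: `t`, `S`, `D`, `delta`.
#' @export
#' @examples
#' traj <- simulate_tissue(alpha = 0.006, gamma = 0.765, sigma = 0.01,
#'                         r_damage_to_cs = 2)
#' head(traj)
simulate_tissue <- function(alpha, gamma, sigma, r_damage_to_cs,
                            horizon = 50000L, stop_eps = 1e-9,
                            init = list(t = 0L, S = 0, D = 0)) {
  stopifnot(horizon >= 1, alpha >= 0, gamma >= 0, gamma <= 1,
            sigma >= 0, sigma <= 1, r_damage_to_cs >= 0)
  check_state(init$S, init$D)
  m <- .tissue_path_cpp(alpha, gamma, sigma, r_damage_to_cs,
                        as.integer(init$t), init$S, init$D,
                        as.integer(horizon), stop_eps)
  as.data.frame(m)
}

#' Cell-line undamaged life expectancy
#'
#' Expected number of time steps a cell line remains undamaged when only
#' apoptosis removes damaged cells (`sigma = 0`) and the organism does not
#' die: the sum over ages of `1 - D_t`. Calibrates the model's unitless
#' time axis.
#'
#' @inheritParams simulate_tissue
#' @return The life expectancy (in time steps), with attribute `capped`
#'   set to `TRUE` (plus a warning) if the sum was still growing at the
#'   horizon (e.g. `gamma = 1`, where damage never accumulates).
#' @export
#' @examples
#' cell_line_life_expectancy(0.006, 0.765)  # ~ 100 steps
cell_line_life_expectancy <- function(alpha, gamma, horizon = 50000L,
                                      stop_eps = 1e-9) {
  traj <- simulate_tissue(alpha, gamma, sigma = 0, r_damage_to_cs = 0,
                          horizon = horizon, stop_eps = stop_eps)
  undamaged <- 1 - traj$D
  capped <- undamaged[nrow(traj)] >= stop_eps &&
    traj$t[nrow(traj)] >= horizon
  if (capped) {
    warning("cell-line life expectancy did not converge before the horizon")
  }
  structure(sum(undamaged), capped = capped)
}

# shared state validation
check_state <- function(S, D) {
  stopifnot(is.numeric(S), is.numeric(D), length(S) == 1, length(D) == 1)
  if (S < 0 || D < 0 || S + D > 1 + 1e-12) {
    stop("invalid tissue state: need S >= 0, D >= 0, S + D <= 1")
  }
  invisible(TRUE)
}
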