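#' Construct and validate a full parameter set
#'
#' Bundles the seven model parameters describing one "organism type":
#' cell-level dynamics (`alpha`, `gamma`, `r_damage_to_cs`), organism
#' resilience to the two intrinsic causes of death (`r_cancer_to_dc`,
#' `r_senesc_to_cs`) and life history (`ext_m`, `senesc_repro`). The
#' senescence-entry probability `sigma` is kept separate: it is the
#' variable optimized over.
#'
#' @param alpha Damage-rate slope (per step), non-negative.
#' @param gamma Apoptosis probability of a damaged cell, in `[0, 1]`.
#' @param r_cancer_to_dc Resilience-to-cancer exponent (> 0): survival of
#'   cancer at age t is `1 - D_t^r_cancer_to_dc`.
#' @param r_senesc_to_cs Resilience-to-ageing exponent (>= 0): survival of
#'   other ageing-related causes is `1 - S_t^r_senesc_to_cs`.
#' @param r_damage_to_cs Tissue-resilience exponent feeding senescent-cell
#'   load back into the damage rate.
#' @param ext_m Extrinsic (age-independent) mortality per step, in `[0, 1)`.
#' @param senesc_repro Linear rate of fertility decline with age.
#' @return A named list with class `"senodem_params"`.
#' @export
#' @examples
#' p <- param_set(alpha = 0.003, gamma = 0.9, r_cancer_to_dc = 2,
#'                r_senesc_to_cs = 3, r_damage_to_cs = 5,
#'                ext_m = 0.002, senesc_repro = 0.0005)
param_set <- function(alpha, gamma, r_cancer_to_dc, r_senesc_to_cs,
                      r_damage_to_cs, ext_m = 0, senesc_repro = 0) {
  p <- list(alpha = alpha, gamma = gamma,
            r_cancer_to_dc = r_cancer_to_dc,
            r_senesc_to_cs = r_senesc_to_cs,
            r_damage_to_cs = r_damage_to_cs,
            ext_m = ext_m, senesc_repro = senesc_repro)
  stopifnot(all(vapply(p, is.numeric, logical(1))),
            all(vapply(p, length, integer(1)) == 1),
            all(is.finite(unlist(p))))
  if (alpha < 0 || gamma < 0 || gamma > 1 || r_cancer_to_dc <= 0 ||
      r_senesc_to_cs < 0 || r_damage_to_cs < 0 || ext_m < 0 || ext_m >= 1 ||
      senesc_repro < 0) {
    stop("parameter out of range; see ?param_set")
  }
  structure(p, class = "senodem_params")
}

as_param_set <- function(p) {
  if (inherits(p, "senodem_params")) return(p)
  p <- as.list(p)
  param_set(alpha = p$alpha, gamma = p$gamma,
            r_cancer_to_dc = p$r_cancer_to_dc,
            r_senesc_to_cs = p$r_senesc_to_cs,
            r_damage_to_cs = p$r_damage_to_cs,
            ext_m = if (is.null(p$ext_m)) 0 else p$ext_m,
            senesc_repro = if (is.null(p$senesc_repro)) 0 else p$senesc_repro)
}

#' @export
print.senodem_params <- function(x, ...) {
  cat("<senodem parameter set>\n")
  print(unlist(x))
  invisible(x)
}

#' Age-specific survival components
#'
#' Probability of surviving each cause of death at one age, given the
#' tissue state: cancer survival `1 - D^r_cancer_to_dc`, ageing survival
#' `1 - S^r_senesc_to_cs`, extrinsic survival `1 - ext_m`. The convention
#' `0^r = 0` also for `r = 0` keeps an undamaged organism (D = S = 0) free
#' of intrinsic mortality whatever the resilience exponents.
#'
#' @param S,D Tissue proportions of senescent and damaged cells (vectors).
#' @inheritParams param_set
#' @return A data.frame with columns `p_cancer`, `p_ageing`, `p_ext`.
#' @export
#' @examples
#' survival_components(S = 0.5, D = 0.3, r_cancer_to_dc = 2,
#'                     r_senesc_to_cs = 3, ext_m = 0.01)
survival_components <- function(S, D, r_cancer_to_dc, r_senesc_to_cs,
                                ext_m = 0) {
  stopifnot(all(S >= 0), all(D >= 0), all(S + D <= 1 + 1e-12),
            ext_m >= 0, ext_m < 1)
  data.frame(
    p_cancer = 1 - ifelse(D > 0, D^r_cancer_to_dc, 0),
    p_ageing = 1 - ifelse(S > 0, S^r_senesc_to_cs, 0),
    p_ext = rep(1 - ext_m, length.out = max(length(S), length(D)))
  )
}

#' Age-specific fertility
#'
#' Fertility declines linearly with age, `B_x = 1 - senesc_repro * x`,
#' clamped at 0 once the line crosses zero.
#'
#' @param x Age (vectorized).
#' @inheritParams param_set
#' @return Fertility in `[0, 1]`.
#' @export
#' @examples
#' fertility(10, 0.02)
fertility <- function(x, senesc_repro) {
  stopifnot(all(x >= 0), senesc_repro >= 0)
  pmax(0, 1 - senesc_repro * x)
}

#' Full demographic schedule for one organism type
#'
#' Runs the tissue recurrences and translates them age by age into the
#' survival components, survivorship `l_x` (with `l_0 = 1`), fertility
#' `B_x` and the unconditional cancer incidence `1 - p_xC`. Iteration stops
#' once survivorship falls below `tail_eps` or at the horizon.
#'
#' @param params A [param_set()] (or coercible list / data.frame row).
#' @param sigma Senescence-entry probability used for the trajectory.
#' @param include_ext_m If `FALSE`, extrinsic mortality is removed from
#'   survivorship (the "captive" setting); the tissue dynamics are
#'   unaffected.
#' @param horizon,tail_eps Truncation rule (defaults 50000 steps, 1e-9).
#' @param init Optional starting state (`t`, `S`, `D`), e.g. post-senolysis.
#' @return A data.frame with columns `x`, `S`, `D`, `delta`, `p_cancer`,
#'   `p_ageing`, `p_ext`, `lx`, `Bx`, `incidence`, and attribute `capped`
#'   (`TRUE` if the tail had not converged at the horizon).
#' @export
#' @examples
#' p <- param_set(alpha = 0.006, gamma = 0.765, r_cancer_to_dc = 1,
#'                r_senesc_to_cs = 2, r_damage_to_cs = 3, ext_m = 0.01)
#' sched <- demographic_schedule(p, sigma = 0.02)
#' head(sched)
demographic_schedule <- function(params, sigma, include_ext_m = TRUE,
                                 horizon = 50000L, tail_eps = 1e-9,
                                 init = list(t = 0L, S = 0, D = 0)) {
  p <- as_param_set(params)
  stopifnot(sigma >= 0, sigma <= 1)
  ext_m <- if (include_ext_m) p$ext_m else 0
  m <- .demographic_path_cpp(p$alpha, p$gamma, sigma, p$r_damage_to_cs,
                             p$r_cancer_to_dc, p$r_senesc_to_cs, ext_m,
                             as.integer(init$t), init$S, init$D,
                             as.integer(horizon), tail_eps)
  out <- as.data.frame(m)
  names(out)[1] <- "x"
  out$p_ext <- 1 - ext_m
  out$Bx <- fertility(out$x, p$senesc_repro)
  out$incidence <- 1 - out$p_cancer
  n <- nrow(out)
  capped <- out$x[n] >= horizon &&
    out$lx[n] * out$p_cancer[n] * out$p_ageing[n] * (1 - ext_m) >= tail_eps
  attr(out, "capped") <- capped
  out
}

#' Lifetime reproductive success
#'
#' `LRS = sum_x l_x B_x`, the fitness proxy maximized over the
#' senescence-entry probability. With `senesc_repro = 0` it equals life
#' expectancy `e_0 = sum_x l_x`.
#'
#' @param schedule A [demographic_schedule()].
#' @return The truncated sum; a warning is raised if the schedule was
#'   horizon-capped (unconverged tail).
#' @export
lrs <- function(schedule) {
  if (isTRUE(attr(schedule, "capped"))) {
    warning("survivorship tail had not converged at the horizon")
  }
  sum(schedule$lx * schedule$Bx)
}

#' Lifetime cancer prevalence
#'
#' Lifetime probability of dying of cancer,
#' `prevC = sum_x l_x (1 - p_xC)`. Build the schedule with
#' `include_ext_m = FALSE` for the "captive" variant, in which extrinsic
#' mortality no longer censors late-life cancer deaths.
#'
#' @inheritParams lrs
#' @return A probability in `[0, 1]`.
#' @export
cancer_prevalence <- function(schedule) {
  if (isTRUE(attr(schedule, "capped"))) {
    warning("survivorship tail had not converged at the horizon")
  }
  sum(schedule$lx * schedule$incidence)
}

#' Cause-specific cumulative incidence
#'
#' Cumulative probability, by each age, of dying from one cause in a
#' population where that cause is the only source of mortality:
#' `1 - prod_(t<x) p_tC` for cancer, `1 - prod_(t<x) p_tS` for
#' ageing-related causes.
#'
#' @inheritParams lrs
#' @param cause `"cancer"` or `"ageing"`.
#' @return A data.frame with columns `x` and `cum_incidence`
#'   (non-decreasing in `x`, 0 at the first age).
#' @export
cumulative_cause_incidence <- function(schedule,
                                       cause = c("cancer", "ageing")) {
  cause <- match.arg(cause)
  p <- if (cause == "cancer") schedule$p_cancer else schedule$p_ageing
  n <- length(p)
  surv <- c(1, cumprod(p))[seq_len(n)]
  data.frame(x = schedule$x, cum_incidence = 1 - surv)
}

#' Derived life-expectancy metrics for a parameter set
#'
#' Computes the calibration metrics of an organism type: the cell-line
#' undamaged life expectancy `e0_cell_line` (sigma = 0, no organism death),
#' the cancer-only life expectancy `e0_cancer` (sigma = 0, no extrinsic or
#' ageing mortality), the extrinsic-only life expectancy
#' `e0_ext = 1/ext_m`, the resilience differential
#' `delta_r = r_senesc_to_cs - r_cancer_to_dc`, and — when `sigma` is
#' supplied — the captive life expectancy at that sigma (both intrinsic
#' causes, extrinsic mortality removed).
#'
#' @inheritParams demographic_schedule
#' @param sigma Senescence-entry probability for `e0_captive`; `NA` skips it.
#' @return One-row data.frame with columns `e0_cell_line`, `e0_cancer`,
#'   `e0_ext`, `delta_r`, `e0_captive`, `capped` (TRUE if any summed metric
#'   hit the horizon before converging, e.g. `alpha = 0`).
#' @export
#' @examples
#' p <- param_set(alpha = 0.006, gamma = 0.765, r_cancer_to_dc = 1,
#'                r_senesc_to_cs = 1, r_damage_to_cs = 1, ext_m = 0.02)
#' life_expectancies(p, sigma = 0.01)
life_expectancies <- function(params, sigma = NA_real_,
                              horizon = 50000L, tail_eps = 1e-9) {
  p <- as_param_set(params)
  e0cl <- suppressWarnings(
    cell_line_life_expectancy(p$alpha, p$gamma, horizon, tail_eps))
  capped <- isTRUE(attr(e0cl, "capped"))

  cancer_only <- param_set(alpha = p$alpha, gamma = p$gamma,
                           r_cancer_to_dc = p$r_cancer_to_dc,
                           r_senesc_to_cs = 0, r_damage_to_cs = 0,
                           ext_m = 0, senesc_repro = 0)
  sc <- suppressWarnings(
    demographic_schedule(cancer_only, sigma = 0, horizon = horizon,
                         tail_eps = tail_eps))
  capped <- capped || isTRUE(attr(sc, "capped"))
  e0C <- sum(sc$lx)

  e0_captive <- NA_real_
  if (!is.na(sigma)) {
    scap <- suppressWarnings(
      demographic_schedule(p, sigma = sigma, include_ext_m = FALSE,
                           horizon = horizon, tail_eps = tail_eps))
    capped <- capped || isTRUE(attr(scap, "capped"))
    e0_captive <- sum(scap$lx)
  }

  data.frame(
    e0_cell_line = as.numeric(e0cl),
    e0_cancer = e0C,
    e0_ext = if (p$ext_m > 0) 1 / p$ext_m else Inf,
    delta_r = p$r_senesc_to_cs - p$r_cancer_to_dc,
    e0_captive = e0_captive,
    capped = capped
  )
}
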