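#' Optimal senescence-entry probability for one organism type
#'
#' Evaluates lifetime reproductive success on a uniform grid of `sigma`
#' values in `[0, 1]` (the grid always contains 0) and returns the smallest
#' grid value attaining the maximum — the "optimal" senescence strategy —
#' together with the percentage LRS gain relative to no senescence at all.
#'
#' @param params A [param_set()] (or coercible row).
#' @param grid_size Number of grid points (default 1000).
#' @param horizon,tail_eps Truncation rule for the LRS sums.
#' @return A list: `sigma_star`, `lrs_at_star`, `lrs_at_zero`, `gain_pct`
#'   (`100 * (LRS(sigma*) - LRS(0)) / LRS(0)`, always >= 0), and the full
#'   `grid` / `lrs` vectors.
#' @export
#' @examples
#' p <- param_set(alpha = 0.006, gamma = 0.8, r_cancer_to_dc = 1,
#'                r_senesc_to_cs = 4, r_damage_to_cs = 5, ext_m = 0.01)
#' opt <- optimize_sigma(p, grid_size = 101)
#' opt$sigma_star
optimize_sigma <- function(params, grid_size = 1000L,
                           horizon = 50000L, tail_eps = 1e-9) {
  p <- as_param_set(params)
  stopifnot(grid_size >= 2)
  grid <- seq(0, 1, length.out = as.integer(grid_size))
  lrs_vals <- .lrs_grid_cpp(p$alpha, p$gamma, p$r_damage_to_cs,
                            p$r_cancer_to_dc, p$r_senesc_to_cs,
                            p$ext_m, p$senesc_repro, grid,
                            as.integer(horizon), tail_eps)
  if (any(!is.finite(lrs_vals))) {
    stop("non-finite LRS on the sigma grid (first at sigma = ",
         grid[which(!is.finite(lrs_vals))[1]], ")")
  }
  k <- which.max(lrs_vals)  # first maximum = smallest sigma on ties
  list(
    sigma_star = grid[k],
    lrs_at_star = lrs_vals[k],
    lrs_at_zero = lrs_vals[1],
    gain_pct = 100 * (lrs_vals[k] - lrs_vals[1]) / lrs_vals[1],
    grid = grid,
    lrs = lrs_vals
  )
}

#' Classify acceleration, deceleration and decline of an incidence series
#'
#' Works on the per-age slope `h_t = i_{t+1} - i_t` of the unconditional
#' cancer incidence `i_t = 1 - p_tC`. An age is *declining* when
#' `h_t < 0`, *decelerating* when `h_t >= 0` but the next slope is smaller
#' (`h_{t+1} < h_t`, including the drop into negative territory), and
#' *accelerating/constant* otherwise (`h_{t+1} >= h_t > 0`, with flat-zero
#' stretches grouped here too).
#'
#' @param incidence Numeric vector of per-age incidence over the
#'   evaluation window (at least 3 ages).
#' @return A list: `labels` (factor, one per classifiable age),
#'   `has_deceleration`, `has_decline` (any slope < 0 in the window).
#' @export
#' @examples
#' classify_incidence_phases(c(0, 0.10, 0.15, 0.12))
classify_incidence_phases <- function(incidence) {
  stopifnot(is.numeric(incidence), all(is.finite(incidence)))
  m <- length(incidence)
  if (m < 3) stop("incidence window must cover at least 3 ages")
  h <- diff(incidence)
  nh <- length(h)
  lab <- character(nh - 1)
  for (j in seq_len(nh - 1)) {
    lab[j] <- if (h[j] < 0) {
      "declining"
    } else if (h[j + 1] < h[j]) {
      "decelerating"
    } else {
      "accelerating/constant"
    }
  }
  labels <- factor(lab, levels = c("accelerating/constant",
                                   "decelerating", "declining"))
  list(
    labels = labels,
    has_deceleration = any(labels == "decelerating"),
    has_decline = any(h < 0)
  )
}

#' Evaluation window for incidence-phase classification
#'
#' Ages 1 up to the last age at which intrinsic survivorship (the product
#' of cancer and ageing survival, extrinsic mortality removed) is still at
#' least `surv_floor`. The window reaches deep into the late-life tail —
#' where deceleration and decline occur — without including numerically
#' void ages.
#'
#' @param captive_schedule A [demographic_schedule()] built with
#'   `include_ext_m = FALSE`.
#' @param surv_floor Survivorship floor (default 1e-4).
#' @return Integer indices of the window rows within the schedule.
#' @export
incidence_window <- function(captive_schedule, surv_floor = 1e-4) {
  keep <- which(captive_schedule$x >= 1 & captive_schedule$lx >= surv_floor)
  keep
}

#' Run the sigma* search over a table of parameter sets
#'
#' For each sampled organism type: optimize `sigma` on the grid, then at
#' `sigma*` compute lifetime cancer prevalence in the wild (with extrinsic
#' mortality) and captive (without) settings, the captive life expectancy,
#' and the late-life incidence-phase booleans.
#'
#' @param sets Output of [sample_parameter_space()].
#' @param grid_size Sigma-grid size (default 1000).
#' @param surv_floor Survivorship floor defining the classification window.
#' @inheritParams optimize_sigma
#' @return A data.frame with one row per set: `id`, `sigma_star`,
#'   `lrs_at_star`, `lrs_at_zero`, `gain_pct`, `prev_wild`, `prev_captive`,
#'   `e0_captive`, `has_deceleration`, `has_decline`.
#' @export
run_sigma_scan <- function(sets, grid_size = 1000L, surv_floor = 1e-4,
                           horizon = 50000L, tail_eps = 1e-9) {
  n <- nrow(sets)
  out <- data.frame(
    id = sets$id,
    sigma_star = numeric(n), lrs_at_star = numeric(n),
    lrs_at_zero = numeric(n), gain_pct = numeric(n),
    prev_wild = numeric(n), prev_captive = numeric(n),
    e0_captive = numeric(n),
    has_deceleration = logical(n), has_decline = logical(n)
  )
  for (i in seq_len(n)) {
    p <- as_param_set(sets[i, ])
    opt <- optimize_sigma(p, grid_size = grid_size,
                          horizon = horizon, tail_eps = tail_eps)
    out$sigma_star[i] <- opt$sigma_star
    out$lrs_at_star[i] <- opt$lrs_at_star
    out$lrs_at_zero[i] <- opt$lrs_at_zero
    out$gain_pct[i] <- opt$gain_pct

    wild <- demographic_schedule(p, sigma = opt$sigma_star,
                                 horizon = horizon, tail_eps = tail_eps)
    out$prev_wild[i] <- cancer_prevalence(wild)

    capt <- demographic_schedule(p, sigma = opt$sigma_star,
                                 include_ext_m = FALSE,
                                 horizon = horizon, tail_eps = tail_eps)
    out$prev_captive[i] <- cancer_prevalence(capt)
    out$e0_captive[i] <- sum(capt$lx)

    win <- incidence_window(capt, surv_floor)
    if (length(win) >= 3) {
      cls <- classify_incidence_phases(capt$incidence[win])
      out$has_deceleration[i] <- cls$has_deceleration
      out$has_decline[i] <- cls$has_decline
    }
  }
  out
}

#' Size-proxy covariates for the body-size analysis
#'
#' Emits, per parameter set, the quantities expected to change with
#' increasing body size: the relative deviation of the cancer-only from
#' the cell-line life expectancy `(e0_cell_line - e0_cancer)/e0_cell_line`
#' (more cell lines, more cancer-prone for the same cell-line longevity),
#' the ratio `e0_ext/e0_cancer` (lower extrinsic mortality), and the
#' reproductive-senescence rate scaled by `e0_cancer`; alongside the
#' experiment outputs used as responses (`sigma_star`, wild and captive
#' prevalence).
#'
#' @param sets Output of [sample_parameter_space()].
#' @param scan Matching output of [run_sigma_scan()].
#' @return A data.frame keyed by `id`.
#' @export
size_covariates <- function(sets, scan) {
  stopifnot(identical(sets$id, scan$id))
  data.frame(
    id = sets$id,
    dev_cancer = (sets$e0_cell_line - sets$e0_cancer) / sets$e0_cell_line,
    ratio_ext = sets$e0_ext / sets$e0_cancer,
    repro_scaled = sets$senesc_repro * sets$e0_cancer,
    sigma_star = scan$sigma_star,
    gain_pct = scan$gain_pct,
    prev_wild = scan$prev_wild,
    prev_captive = scan$prev_captive
  )
}

#' Senolytic perturbation of a tissue state
#'
#' Clears a fraction of the senescent cells and replaces them by
#' compensatory division of the remaining mitotic pool, so a damaged
#' share `D / (1 - S_post)` of the replacements is damaged again
#' (the same replacement logic apoptosis follows in the step
#' recurrence, with the post-removal senescent proportion in the
#' denominator).
#'
#' @param S,D Tissue state at the age of senolysis.
#' @param clearance Fraction of senescent cells removed (default 0.5).
#' @return A list with the perturbed `S` and `D` (still a valid state:
#'   `S + D <= 1`).
#' @export
#' @examples
#' senolysis_perturb(S = 0.4, D = 0.2) # S 0.2, D 0.25
senolysis_perturb <- function(S, D, clearance = 0.5) {
  check_state(S, D)
  stopifnot(clearance >= 0, clearance <= 1)
  removed <- S * clearance
  S_new <- S - removed
  D_new <- if (removed > 0) D + removed * D / (1 - S_new) else D
  list(S = S_new, D = D_new)
}

#' One in-silico senolysis experiment
#'
#' At a given (or uniformly drawn) age, half of the senescent cells are
#' cleared. The cleared fraction is replaced by compensatory division of
#' the remaining mitotic pool, so a damaged share
#' `D_a / (1 - S_a/2)` of the replacements is damaged again:
#' `S <- S_a/2`, `D <- D_a + (S_a/2) * D_a / (1 - S_a/2)`. The recurrences
#' then resume and the cause-specific cumulative incidences (cancer-only
#' and ageing-only populations, no extrinsic mortality — a controlled
#' environment) are compared with the unperturbed baseline at a common
#' final age.
#'
#' @param params A [param_set()] (or coercible row).
#' @param sigma Senescence-entry probability (normally the set's
#'   `sigma_star`).
#' @param age Age at senolysis; if `NULL`, drawn uniformly on the integers
#'   `1 .. floor(captive life expectancy)` using the current RNG state.
#' @inheritParams optimize_sigma
#' @return One-row data.frame: `age_senolysis`, `pct_change_cancer`,
#'   `pct_change_ageing` (percentage changes of the lifetime cumulative
#'   incidence of each cause, after vs before).
#' @export
run_senolysis <- function(params, sigma, age = NULL,
                          horizon = 50000L, tail_eps = 1e-9) {
  p <- as_param_set(params)
  base <- demographic_schedule(p, sigma = sigma, include_ext_m = FALSE,
                               horizon = horizon, tail_eps = tail_eps)
  if (is.null(age)) {
    e0_captive <- sum(base$lx)
    age <- sample.int(max(1L, as.integer(floor(e0_captive))), 1L)
  }
  age <- min(age, base$x[nrow(base)])
  i <- match(age, base$x)
  S_a <- base$S[i]
  D_a <- base$D[i]
  if (S_a <= 0) {
    return(data.frame(age_senolysis = age,
                      pct_change_cancer = 0, pct_change_ageing = 0))
  }
  pert <- senolysis_perturb(S_a, D_a, clearance = 0.5)

  t_end <- base$x[nrow(base)]
  post <- demographic_schedule(p, sigma = sigma, include_ext_m = FALSE,
                               horizon = t_end, tail_eps = 0,
                               init = list(t = age, S = pert$S, D = pert$D))

  pre_rows <- base$x < age
  change <- function(p_base, p_pre, p_post) {
    before <- 1 - prod(p_base)
    after <- 1 - prod(p_pre) * prod(p_post)
    # a cause that never occurs in either arm (e.g. D identically 0 at
    # sigma = 1) has no change, not an indeterminate ratio
    if (before == 0 && after == 0) return(0)
    100 * (after / before - 1)
  }
  data.frame(
    age_senolysis = age,
    pct_change_cancer = change(base$p_cancer, base$p_cancer[pre_rows],
                               post$p_cancer),
    pct_change_ageing = change(base$p_ageing, base$p_ageing[pre_rows],
                               post$p_ageing)
  )
}

#' Senolysis experiment over a cohort of parameter sets
#'
#' Runs [run_senolysis()] once per set, each at its own `sigma_star`,
#' with one seeded uniform age draw per set. By default the cohort is the
#' sets whose optimal senescence strategy raises LRS by more than 1%.
#'
#' @inheritParams size_covariates
#' @param seed Integer seed for the age draws.
#' @param cohort `"gain"` (gain > 1% sets, default) or `"all"`.
#' @inheritParams optimize_sigma
#' @return A data.frame with one row per record: `id`, `age_senolysis`,
#'   `pct_change_cancer`, `pct_change_ageing`.
#' @export
senolysis_experiment <- function(sets, scan, seed, cohort = c("gain", "all"),
                                 horizon = 50000L, tail_eps = 1e-9) {
  cohort <- match.arg(cohort)
  stopifnot(identical(sets$id, scan$id))
  keep <- if (cohort == "gain") which(scan$gain_pct > 1) else seq_len(nrow(sets))
  set.seed(as.integer(seed))
  recs <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    rec <- run_senolysis(sets[i, ], sigma = scan$sigma_star[i],
                         horizon = horizon, tail_eps = tail_eps)
    rec$id <- sets$id[i]
    recs[[j]] <- rec
  }
  out <- do.call(rbind, recs)
  out[, c("id", "age_senolysis", "pct_change_cancer", "pct_change_ageing")]
}

#' Full in-silico study: sampling, optimization, classification, senolysis
#'
#' Convenience driver running the whole pipeline: Latin-hypercube sample,
#' sigma* search with prevalences and incidence-phase classification,
#' size-proxy covariates, and the senolysis experiment on the gain > 1%
#' cohort.
#'
#' @inheritParams sample_parameter_space
#' @inheritParams run_sigma_scan
#' @return A list with elements `sets`, `scan`, `covariates`, `senolysis`.
#' @export
#' @examples
#' \donttest{
#' run <- run_experiments(n = 50, seed = 1, grid_size = 100)
#' mean(run$scan$sigma_star > 0)
#' }
run_experiments <- function(n, seed, grid_size = 1000L,
                            horizon = 50000L, tail_eps = 1e-9) {
  sets <- sample_parameter_space(n, seed, horizon = horizon,
                                 tail_eps = tail_eps)
  scan <- run_sigma_scan(sets, grid_size = grid_size,
                         horizon = horizon, tail_eps = tail_eps)
  covariates <- size_covariates(sets, scan)
  senolysis <- senolysis_experiment(sets, scan, seed = seed,
                                    horizon = horizon, tail_eps = tail_eps)
  list(sets = sets, scan = scan, covariates = covariates,
       senolysis = senolysis)
}
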