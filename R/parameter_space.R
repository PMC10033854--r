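#' Default sampling ranges for the parameter sweep
#'
#' Box ranges for the five directly sampled dimensions. They are calibrated
#' so that, without senescent-cell accumulation, the cell-line undamaged
#' life expectancy spans 100–2000 time steps and the cancer-only life
#' expectancy spans 27–2000 steps. `delta_r` is the differential
#' `r_senesc_to_cs - r_cancer_to_dc`; `r_senesc_to_cs` is always derived
#' from it, never sampled directly.
#'
#' @return A named list of `c(min, max)` ranges for `alpha`, `gamma`,
#'   `r_cancer_to_dc`, `delta_r`, `r_damage_to_cs`.
#' @export
default_ranges <- function() {
  list(
    alpha = c(0.000497, 0.006),
    gamma = c(0.765, 0.99),
    r_cancer_to_dc = c(1, 4),
    delta_r = c(-1, 4),
    r_damage_to_cs = c(1, 10)
  )
}

#' Latin-hypercube sample of the parameter space
#'
#' Draws `n` organism types by Latin hypercube sampling. A 7-dimensional
#' unit hypercube is drawn once (preserving one-dimensional stratification
#' in every dimension); dimensions 1–5 are rescaled onto the
#' [default_ranges()] boxes, and dimensions 6–7 are rescaled per set onto
#' ranges that depend on the set's own cancer-only life expectancy
#' `e0_cancer`:
#' * extrinsic mortality: `ext_m` uniform on the interval for which the
#'   extrinsic-only life expectancy `1/ext_m` stays within
#'   `[0.5, 2.5] * e0_cancer` (with `ext_sampling = "e0E"`, the life
#'   expectancy itself is drawn uniformly on that interval and inverted
#'   instead: same support, different marginal);
#' * reproductive senescence: `senesc_repro` uniform on
#'   `[0, 0.5/e0_cancer]`, so fertility declines by 0–50% by age
#'   `e0_cancer`.
#'
#' Constraints are enforced by construction (mapping, not rejection), so
#' every returned set satisfies them exactly.
#'
#' @param n Number of parameter sets (>= 1).
#' @param seed Integer seed; the same `(n, seed)` reproduces the sample
#'   bit for bit.
#' @param ranges Optional override of [default_ranges()].
#' @param ext_sampling Which quantity is uniform in the extrinsic-mortality
#'   dimension: `"extM"` (default) or `"e0E"`.
#' @param horizon,tail_eps Truncation rule for the derived life
#'   expectancies.
#' @return A data.frame with one row per set: `id`, the seven parameters,
#'   `delta_r`, the derived metrics `e0_cell_line`, `e0_cancer`, `e0_ext`,
#'   a `capped` flag, and `seed`.
#' @export
#' @examples
#' sets <- sample_parameter_space(20, seed = 1)
#' summary(sets$e0_cancer)
sample_parameter_space <- function(n, seed, ranges = default_ranges(),
                                   ext_sampling = c("extM", "e0E"),
                                   horizon = 50000L, tail_eps = 1e-9) {
  stopifnot(n >= 1, is.numeric(seed), length(seed) == 1)
  ext_sampling <- match.arg(ext_sampling)
  rng <- utils::modifyList(default_ranges(), ranges)
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(as.integer(n), 7L)

  scale_to <- function(col, box) box[1] + u[, col] * (box[2] - box[1])
  out <- data.frame(
    id = seq_len(n),
    alpha = scale_to(1, rng$alpha),
    gamma = scale_to(2, rng$gamma),
    r_cancer_to_dc = scale_to(3, rng$r_cancer_to_dc),
    delta_r = scale_to(4, rng$delta_r),
    r_damage_to_cs = scale_to(5, rng$r_damage_to_cs)
  )
  out$r_senesc_to_cs <- out$r_cancer_to_dc + out$delta_r

  dm <- attach_derived_metrics(out, horizon = horizon, tail_eps = tail_eps)
  out$e0_cell_line <- dm$e0_cell_line
  out$e0_cancer <- dm$e0_cancer
  out$capped <- dm$capped

  # life-history dimensions, conditional on each set's e0_cancer
  if (ext_sampling == "extM") {
    out$ext_m <- (1 / 2.5 + u[, 6] * (1 / 0.5 - 1 / 2.5)) / out$e0_cancer
  } else {
    out$ext_m <- 1 / ((0.5 + 2 * u[, 6]) * out$e0_cancer)
  }
  out$e0_ext <- 1 / out$ext_m
  out$senesc_repro <- u[, 7] * 0.5 / out$e0_cancer
  out$seed <- as.integer(seed)
  out[, c("id", "alpha", "gamma", "r_cancer_to_dc", "delta_r",
          "r_senesc_to_cs", "r_damage_to_cs", "ext_m", "senesc_repro",
          "e0_cell_line", "e0_cancer", "e0_ext", "capped", "seed")]
}

#' Attach derived life-expectancy metrics to parameter rows
#'
#' Computes `e0_cell_line` and `e0_cancer` (both under sigma = 0, no
#' extrinsic mortality) for each row of a parameter table, plus
#' `e0_ext = 1/ext_m` and `delta_r` when the corresponding columns are
#' present.
#'
#' @param sets Data.frame with at least `alpha`, `gamma`,
#'   `r_cancer_to_dc` columns.
#' @inheritParams sample_parameter_space
#' @return `sets` with columns `e0_cell_line`, `e0_cancer`, `capped`
#'   (TRUE where a metric hit the horizon), and recomputed `e0_ext` /
#'   `delta_r` where applicable.
#' @export
attach_derived_metrics <- function(sets, horizon = 50000L,
                                   tail_eps = 1e-9) {
  stopifnot(all(c("alpha", "gamma", "r_cancer_to_dc") %in% names(sets)))
  n <- nrow(sets)
  e0cl <- numeric(n)
  e0C <- numeric(n)
  capped <- logical(n)
  for (i in seq_len(n)) {
    v <- suppressWarnings(
      cell_line_life_expectancy(sets$alpha[i], sets$gamma[i],
                                horizon, tail_eps))
    e0cl[i] <- as.numeric(v)
    sc <- .demographic_path_cpp(sets$alpha[i], sets$gamma[i], 0,
                                0, sets$r_cancer_to_dc[i], 0, 0,
                                0L, 0, 0, as.integer(horizon), tail_eps)
    e0C[i] <- sum(sc[, "lx"])
    capped[i] <- isTRUE(attr(v, "capped")) ||
      (sc[nrow(sc), "t"] >= horizon &&
         sc[nrow(sc), "lx"] * sc[nrow(sc), "p_cancer"] >= tail_eps)
  }
  sets$e0_cell_line <- e0cl
  sets$e0_cancer <- e0C
  sets$capped <- capped
  if (!is.null(sets$ext_m)) sets$e0_ext <- 1 / sets$ext_m
  if (!is.null(sets$r_senesc_to_cs)) {
    sets$delta_r <- sets$r_senesc_to_cs - sets$r_cancer_to_dc
  }
  sets
}
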