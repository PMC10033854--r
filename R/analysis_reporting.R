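#' Pearson product-moment correlation
#'
#' Thin validated front end over the usual product-moment estimator, with
#' the error contract the reporting layer relies on (equal lengths, at
#' least 3 pairs, non-degenerate variance).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (var(x) == 0 || var(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  cor(x, y)
}

# model-matrix vocabulary shared by the regression helpers
input_params <- c("alpha", "gamma", "r_cancer_to_dc", "r_senesc_to_cs",
                  "r_damage_to_cs", "ext_m", "senesc_repro")
derived_metrics <- c("e0_cell_line", "e0_cancer", "delta_r")

interaction_terms <- function(variant) {
  groups <- list(
    derived = c("e0_cell_line", "e0_cancer"),
    resilience = c("r_damage_to_cs", "r_cancer_to_dc"),
    life_history = c("ext_m", "senesc_repro")
  )
  vars <- unlist(groups, use.names = FALSE)
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  if (variant == "cross") {
    grp <- rep(names(groups), lengths(groups))
    names(grp) <- vars
    pairs <- Filter(function(p) grp[p[1]] != grp[p[2]], pairs)
  }
  vapply(pairs, paste, character(1), collapse = ":")
}

sweep_formula <- function(response, interactions) {
  poly_terms <- unlist(lapply(input_params, function(v) {
    c(v, sprintf("I(%s^2)", v), sprintf("I(%s^3)", v))
  }))
  rhs <- c(poly_terms, derived_metrics, interaction_terms(interactions))
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Logistic regression of a sweep outcome on the full term structure
#'
#' Maximum-likelihood logistic fit of a Boolean outcome (e.g.
#' `sigma_star > 0`, or "deceleration or decline observed") on the seven
#' input parameters with their quadratic and cubic effects, the derived
#' metrics (`e0_cell_line`, `e0_cancer`, `delta_r`; the extrinsic-only
#' life expectancy is represented by `ext_m` itself), and two-term
#' interactions among the derived-metric, resilience and life-history
#' groups. The exact interaction list is ambiguous between cross-group
#' pairs only and all pairs; both are available.
#'
#' @param table Results table joining parameters, derived metrics and
#'   experiment outputs (one row per parameter set).
#' @param response Name of a logical/0-1 column, default `"sigma_pos"`
#'   (created from `sigma_star` if absent).
#' @param interactions `"cross"` (pairs spanning two groups, default) or
#'   `"all"` (every pairwise combination).
#' @return A list: `fit` (the `glm` object), `deviance_table`
#'   (sequential deviance reductions per term), `converged`.
#'   Non-convergence or separation is reported, never silently dropped.
#' @export
fit_sigma_logistic <- function(table, response = "sigma_pos",
                               interactions = c("cross", "all")) {
  interactions <- match.arg(interactions)
  if (!response %in% names(table) && "sigma_star" %in% names(table)) {
    table[[response]] <- table$sigma_star > 0
  }
  y <- table[[response]]
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("outcome `", response, "` is constant: logistic fit undefined")
  }
  fml <- sweep_formula(response, interactions)
  warn <- NULL
  fit <- withCallingHandlers(
    glm(fml, data = table, family = binomial(link = "logit")),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) warning("logistic fit did not converge")
  if (any(grepl("fitted probabilities numerically 0 or 1", warn))) {
    warning("possible separation: fitted probabilities at 0/1")
  }
  list(fit = fit,
       deviance_table = anova(fit),
       converged = fit$converged)
}

#' Sequential (type-I) ANOVA variance shares
#'
#' Fits a linear model and reports, per term, the fraction of the total
#' response variance absorbed sequentially in the order the terms appear
#' in the formula. Type-I shares are order-dependent; the order used is
#' recorded in the result's `term_order` attribute and shares should be
#' read at ranking level only.
#'
#' @param formula Linear-model formula with a documented term order.
#' @param data Results table.
#' @return Named numeric vector of per-term shares (non-negative, summing
#'   with the residual share to 1), with attributes `term_order` and
#'   `residual_share`.
#' @export
#' @examples
#' d <- data.frame(x = rnorm(50), z = rnorm(50))
#' d$y <- 2 * d$x + rnorm(50)
#' sequential_anova_shares(y ~ x + z, d)
sequential_anova_shares <- function(formula, data) {
  fit <- lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    warning("rank-deficient fit: aliased terms dropped by lm")
  }
  tab <- anova(fit)
  ss <- tab[["Sum Sq"]]
  total <- sum(ss)
  terms <- rownames(tab)
  shares <- ss[terms != "Residuals"] / total
  names(shares) <- terms[terms != "Residuals"]
  structure(shares,
            term_order = terms[terms != "Residuals"],
            residual_share = ss[terms == "Residuals"] / total)
}

#' Headline summary of a full run
#'
#' Pure function of the results tables: fractions, moments and
#' correlations describing the sigma* landscape, the incidence phases and
#' the senolysis experiment. Empty inputs give a zero-count report;
#' sections whose input table is missing are flagged `NA`.
#'
#' @param run A list as returned by [run_experiments()] (`sets`, `scan`,
#'   `covariates`, `senolysis`; any element may be absent).
#' @return A named list of scalar summaries.
#' @export
summarize_run <- function(run) {
  scan <- run$scan
  seno <- run$senolysis
  cov <- run$covariates
  out <- list(n_sets = if (is.null(scan)) 0L else nrow(scan))
  if (!is.null(scan) && nrow(scan) > 0) {
    gain <- scan$gain_pct > 1
    out$frac_sigma_pos <- mean(scan$sigma_star > 0)
    out$frac_gain_gt1 <- mean(gain)
    out$n_gain_gt1 <- sum(gain)
    out$mean_gain <- if (any(gain)) mean(scan$gain_pct[gain]) else NA_real_
    out$sd_gain <- if (sum(gain) > 1) sd(scan$gain_pct[gain]) else NA_real_
    out$cor_sigma_gain <- if (sum(gain) >= 3) {
      pearson(scan$sigma_star[gain], scan$gain_pct[gain])
    } else NA_real_
    out$frac_deceleration <- if (any(gain)) {
      mean(scan$has_deceleration[gain])
    } else NA_real_
    out$frac_decline <- if (any(gain)) mean(scan$has_decline[gain]) else NA_real_
    out$frac_deceleration_lowgain <- if (any(!gain)) {
      mean(scan$has_deceleration[!gain])
    } else NA_real_
    out$frac_decline_lowgain <- if (any(!gain)) {
      mean(scan$has_decline[!gain])
    } else NA_real_
  } else {
    out[c("frac_sigma_pos", "frac_gain_gt1", "mean_gain", "sd_gain",
          "cor_sigma_gain", "frac_deceleration", "frac_decline")] <- NA_real_
    out$n_gain_gt1 <- 0L
  }
  if (!is.null(cov) && !is.null(scan) && nrow(scan) > 0) {
    gain <- scan$gain_pct > 1
    out$cor_dev_sigma <- if (sum(gain) >= 3) {
      pearson(cov$dev_cancer[gain], cov$sigma_star[gain])
    } else NA_real_
  }
  out$n_senolysis <- if (is.null(seno)) 0L else nrow(seno)
  if (!is.null(seno) && nrow(seno) > 0) {
    out$frac_cancer_increase <- mean(seno$pct_change_cancer > 0)
    out$frac_ageing_decrease <- mean(seno$pct_change_ageing < 0)
    out$mean_cancer_change <- mean(seno$pct_change_cancer)
    out$mean_ageing_change <- mean(seno$pct_change_ageing)
    out$frac_cancer_increase_gt10 <- mean(seno$pct_change_cancer > 10)
    out$frac_ageing_decrease_gt10 <- mean(seno$pct_change_ageing < -10)
    out$cor_age_ageing_change <- if (nrow(seno) >= 3) {
      pearson(seno$age_senolysis, seno$pct_change_ageing)
    } else NA_real_
  }
  out
}

#' Write a run summary (JSON) and results tables (CSV)
#'
#' @param run A [run_experiments()] list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summarize_run(run)
  jsonlite::write_json(s, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in intersect(c("sets", "scan", "covariates", "senolysis"),
                       names(run))) {
    write.csv(run[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  invisible(s)
}

#' Plot incidence and survivorship for one organism type
#'
#' Base-graphics view of a demographic schedule: per-age cancer incidence,
#' ageing-related incidence (`1 - p_tS`) and survivorship, the typical
#' display for inspecting late-life deceleration and decline.
#'
#' @param schedule A [demographic_schedule()].
#' @param main Plot title.
#' @export
plot_schedule <- function(schedule, main = "") {
  x <- schedule$x
  graphics::plot(x, schedule$incidence, type = "l", col = "firebrick",
                 xlab = "age (time steps)", ylab = "per-age probability",
                 ylim = c(0, max(schedule$incidence,
                                 1 - schedule$p_ageing, 1e-6)),
                 main = main)
  graphics::lines(x, 1 - schedule$p_ageing, col = "darkgreen")
  graphics::lines(x, schedule$lx * max(schedule$incidence,
                                       1 - schedule$p_ageing, 1e-6),
                  col = "steelblue", lty = 2)
  graphics::legend("topleft", bty = "n", lty = c(1, 1, 2),
                   col = c("firebrick", "darkgreen", "steelblue"),
                   legend = c("cancer incidence", "ageing incidence",
                              "survivorship (scaled)"))
}
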