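make_set <- function() {
  param_set(alpha = 0.004, gamma = 0.85, r_cancer_to_dc = 1.5,
            r_senesc_to_cs = 4, r_damage_to_cs = 5, ext_m = 0.005,
            senesc_repro = 0.002)
}

test_that("sigma optimization returns the smallest maximizer and non-negative gain", {
  # no damage: LRS flat in sigma, tie broken at 0
  p0 <- param_set(alpha = 0, gamma = 0.5, r_cancer_to_dc = 1,
                  r_senesc_to_cs = 1, r_damage_to_cs = 1, ext_m = 0.05)
  opt0 <- optimize_sigma(p0, grid_size = 50)
  expect_equal(opt0$sigma_star, 0)
  expect_equal(opt0$gain_pct, 0)

  opt <- optimize_sigma(make_set(), grid_size = 100)
  expect_true(opt$sigma_star %in% opt$grid)
  expect_gte(opt$gain_pct, 0)
  expect_equal(opt$lrs_at_zero, opt$lrs[1])
})

test_that("gain is never negative across random parameter sets", {
  sets <- sample_parameter_space(15, seed = 21)
  scan <- run_sigma_scan(sets, grid_size = 60)
  expect_true(all(scan$gain_pct >= 0))
  expect_true(all(scan$sigma_star >= 0 & scan$sigma_star <= 1))
  expect_true(all(scan$prev_wild >= 0 & scan$prev_wild <= 1))
  expect_true(all(scan$prev_captive >= 0 & scan$prev_captive <= 1))
})

test_that("a finer sigma grid agrees within one coarse grid step", {
  p <- make_set()
  coarse <- optimize_sigma(p, grid_size = 100)
  fine <- optimize_sigma(p, grid_size = 1000)
  expect_lt(abs(coarse$sigma_star - fine$sigma_star), 1 / 99)
})

test_that("grid LRS values agree with the schedule-based sum", {
  p <- make_set()
  opt <- optimize_sigma(p, grid_size = 10)
  for (k in c(1, 4, 8)) {
    sched <- demographic_schedule(p, sigma = opt$grid[k])
    expect_equal(opt$lrs[k], lrs(sched), tolerance = 1e-10)
  }
})

test_that("incidence phases follow the slope rules", {
  # linear incidence: constant positive slope, no deceleration or decline
  lin <- classify_incidence_phases((0:19) * 0.03125)  # exact constant slope
  expect_false(lin$has_deceleration)
  expect_false(lin$has_decline)
  expect_true(all(lin$labels == "accelerating/constant"))

  cls <- classify_incidence_phases(c(0, 0.10, 0.15, 0.12))
  expect_true(cls$has_deceleration)
  expect_true(cls$has_decline)
  expect_equal(as.character(cls$labels), c("decelerating", "decelerating"))

  expect_error(classify_incidence_phases(c(0, 0.1)), "at least 3")
})

test_that("decline onset follows the peak of new-damage production", {
  sets <- sample_parameter_space(40, seed = 13)
  scan <- run_sigma_scan(sets, grid_size = 150)
  idx <- which(scan$has_decline & scan$gain_pct > 1)
  expect_gt(length(idx), 0)
  checked <- 0
  for (i in head(idx, 5)) {
    p <- as.list(sets[i, ])
    sched <- demographic_schedule(p, sigma = scan$sigma_star[i],
                                  include_ext_m = FALSE)
    win <- incidence_window(sched)
    h <- diff(sched$incidence[win])
    onset <- win[which(h < 0)[1]]
    if (is.na(onset)) next
    # by decline onset, the per-step new-damage fraction is past its
    # maximum: proliferation slow-down drives the late-life decline
    expect_lt(which.max(sched$delta), onset)
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})

test_that("senolysis perturbation follows the compensatory replacement rule", {
  pert <- senolysis_perturb(S = 0.4, D = 0.2)
  expect_equal(pert$S, 0.2)
  expect_equal(pert$D, 0.2 + 0.2 * (0.2 / 0.8))  # 0.25
  # resuming the recurrence from the perturbed state matches a manual step
  st <- tissue_step(pert$S, pert$D, t = 10, alpha = 0.004, gamma = 0.85,
                    sigma = 0.1, r_damage_to_cs = 5)
  tr <- simulate_tissue(0.004, 0.85, 0.1, 5, horizon = 11,
                        init = list(t = 10, S = pert$S, D = pert$D))
  expect_equal(tr$S[2], st$S)
  expect_equal(tr$D[2], st$D)
  # proportions stay valid for any state
  for (S in c(0.1, 0.5, 0.9)) {
    for (D in c(0, 0.05, 1 - S)) {
      q <- senolysis_perturb(S, D)
      expect_lte(q$S + q$D, 1 + 1e-12)
    }
  }
})

test_that("senolysis with no senescent cells is a no-op and runs are reproducible", {
  p0 <- param_set(alpha = 0.004, gamma = 0.85, r_cancer_to_dc = 1.5,
                  r_senesc_to_cs = 4, r_damage_to_cs = 5)
  rec <- run_senolysis(p0, sigma = 0, age = 5)
  expect_equal(rec$pct_change_cancer, 0)
  expect_equal(rec$pct_change_ageing, 0)

  sets <- sample_parameter_space(8, seed = 17)
  scan <- run_sigma_scan(sets, grid_size = 60)
  a <- senolysis_experiment(sets, scan, seed = 4)
  b <- senolysis_experiment(sets, scan, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$age_senolysis >= 1))
})

test_that("size covariates reproduce the longevity-deviation arithmetic", {
  sets <- data.frame(id = 1:2, e0_cell_line = c(100, 100),
                     e0_cancer = c(27, 100), e0_ext = c(50, 200),
                     senesc_repro = c(0.001, 0))
  scan <- data.frame(id = 1:2, sigma_star = c(0.1, 0), gain_pct = c(2, 0),
                     prev_wild = c(0.3, 0.4), prev_captive = c(0.5, 0.6))
  cov <- size_covariates(sets, scan)
  expect_equal(cov$dev_cancer, c(0.73, 0))
  expect_equal(cov$ratio_ext, c(50 / 27, 2))
})
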